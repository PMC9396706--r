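test_that("degenerate config pins the bird to the winter centre", {
  cfg <- sim_config(step_sd_km = 0, spring_window = numeric(0),
                    autumn_window = numeric(0))
  tr <- simulate_migratory_path(cfg, seed = 1)
  expect_true(all(abs(tr$true_lon - cfg$winter_centre[1]) < 1e-9))
  expect_true(all(abs(tr$true_lat - cfg$winter_centre[2]) < 1e-9))
  expect_true(all(compute_nsd(tr)$nsd < 1e-12))
})

test_that("summer plateau NSD matches the squared centre separation", {
  # centres exactly 1200 km apart along a meridian
  d_km <- 1200
  winter <- c(-95, 32)
  summer <- c(-95, 32 + d_km / (6371 * pi / 180))
  cfg <- sim_config(winter_centre = winter, summer_centre = summer,
                    step_sd_km = 2, migration_speed_km_day = 150)
  plateau <- vapply(1:20, function(s) {
    tr <- simulate_migratory_path(cfg, seed = s)
    ns <- compute_nsd(tr)
    mean(ns$nsd[ns$t >= 150 & ns$t <= 260])
  }, numeric(1))
  expect_equal(mean(plateau), d_km^2, tolerance = 0.01)
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config()
  t1 <- simulate_migratory_path(cfg, seed = 99)
  t2 <- simulate_migratory_path(cfg, seed = 99)
  expect_identical(t1$lon, t2$lon)
  expect_identical(t1$time, t2$time)
  c1 <- corrupt_with_argos_error(t1, cfg, seed = 5)
  c2 <- corrupt_with_argos_error(t2, cfg, seed = 5)
  expect_identical(c1$lon, c2$lon)
  expect_identical(c1$lc_class, c2$lc_class)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(spring_window = c(0, 40)), "within")
  expect_error(sim_config(spring_window = c(200, 150)), "within")
  expect_error(sim_config(spring_window = c(100, 290),
                          autumn_window = c(280, 300)), "overlap")
  expect_error(sim_config(argos_class_probs = c(LC3 = 0.5, LC2 = 0.2,
                                                LC1 = 0.2, LC0 = 0.2)),
               "sum to 1")
})

test_that("Argos corruption has the configured error structure", {
  cfg <- sim_config()
  tr <- simulate_migratory_path(cfg, seed = 3)

  # zero error SDs leave positions untouched
  cfg0 <- cfg
  cfg0$argos_class_sd_km[] <- 0
  tr0 <- corrupt_with_argos_error(tr, cfg0, seed = 4)
  expect_equal(tr0$lon, tr$true_lon, tolerance = 1e-12)
  expect_equal(tr0$lat, tr$true_lat, tolerance = 1e-12)

  # isotropic SD of 5 km per axis gives radial RMS 5*sqrt(2)
  cfg5 <- sim_config(sampling = list(list(start_day = 1, end_day = 365,
                                          every_h = 4, burst_h = 1)))
  cfg5$argos_class_sd_km[] <- 5
  tr5 <- simulate_migratory_path(cfg5, seed = 6)
  trc <- corrupt_with_argos_error(tr5, cfg5, seed = 7)
  expect_gt(nrow(trc), 2000)
  d <- gc_dist_oracle(trc$lon, trc$lat, trc$true_lon, trc$true_lat)
  expect_equal(sqrt(mean(d^2)), 5 * sqrt(2), tolerance = 0.05)

  # class frequencies follow the configured probabilities
  cfgq <- sim_config(sampling = list(list(start_day = 1, end_day = 365,
                                          every_h = 1, burst_h = 1)))
  trq <- corrupt_with_argos_error(simulate_migratory_path(cfgq, seed = 8),
                                  cfgq, seed = 9)
  expect_gte(nrow(trq), 8000)
  freq <- table(trq$lc_class)[names(cfgq$argos_class_probs)] / nrow(trq)
  expect_true(all(abs(freq - cfgq$argos_class_probs) < 0.02))
})

test_that("simulated NSD series reproduce the sigmoid curves exactly", {
  # logistic midpoint
  s <- simulate_nsd_series(list(delta = 2e6, theta = 120, phi = 4), times = 120)
  expect_equal(s$nsd, 1e6)

  # spring plateau of a published single-sigmoid bird: at day 250 the curve
  # has converged to the asymptote
  p5 <- as.list(table_single[table_single$id == 5, -1])
  s5 <- simulate_nsd_series(p5, times = 250)
  expect_lt(abs(s5$nsd - p5$delta), 1e-6 * p5$delta)

  # double-sigmoid plateau between the midpoints: direct evaluation of the
  # rise-then-return curve for the published bird-22 parameters at day 180
  p22 <- as.list(table_double[table_double$id == 22, -1])
  s22 <- simulate_nsd_series(p22, times = 180)
  direct <- p22$delta / (1 + exp((p22$theta_s - 180) / p22$phi_s)) -
    p22$delta / (1 + exp((p22$theta_a - 180) / p22$phi_a))
  expect_equal(s22$nsd, direct, tolerance = 1e-12)
  expect_lt(abs(s22$nsd - p22$delta) / p22$delta, 0.02)

  expect_error(simulate_nsd_series(list(delta = 1, theta = 1, phi = -1), 1:10),
               "positive")
})

test_that("climate fields respect invariants and configured moments", {
  cfg <- climate_config()
  ras <- simulate_climate_fields(cfg, seed = 11)
  for (r in ras) {
    expect_true(all(r$vars$tmax >= r$vars$tmin))
    expect_true(all(r$vars$precip >= 0))
    expect_true(all(r$vars$wind >= 0))
  }

  # determinism
  ras2 <- simulate_climate_fields(cfg, seed = 11)
  expect_identical(ras$winter$vars$tmin, ras2$winter$vars$tmin)

  # a config with >= 8 SD separation gives non-overlapping temperature ranges
  cfg_sep <- cfg
  cfg_sep$winter$vars$tmin <- c(0, 0.5)
  cfg_sep$winter$vars$tgap <- c(6, 0.5)
  cfg_sep$summer$vars$tmin <- c(20, 0.5)
  ras_sep <- simulate_climate_fields(cfg_sep, seed = 12)
  expect_lt(max(ras_sep$winter$vars$tmax), min(ras_sep$summer$vars$tmin))

  # wind sample means match configuration within the CLT bound at 1e4 cells
  cfg_big <- cfg
  cfg_big$winter$n_cells <- 100
  cfg_big$summer$n_cells <- 100
  ras_big <- simulate_climate_fields(cfg_big, seed = 13)
  for (season in c("winter", "summer")) {
    mu <- cfg_big[[season]]$vars$wind[1]
    sd <- cfg_big[[season]]$vars$wind[2]
    expect_lt(abs(mean(ras_big[[season]]$vars$wind) - mu), 3 * sd / 100)
  }

  cfg_bad <- cfg
  cfg_bad$winter$vars$wind <- c(3, -1)
  expect_error(simulate_climate_fields(cfg_bad, seed = 1), "negative SD")
})
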