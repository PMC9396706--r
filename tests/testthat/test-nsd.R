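test_that("NSD from a track is squared great-circle distance from the origin", {
  tr <- track_from_plan(c(0, 1, 2), c(0, 3, 0), c(0, 4, 0))
  ns <- compute_nsd(tr)
  expect_equal(ns$nsd[1], 0)
  # the helper's degree conversion is locally planar, so allow ~0.05%
  expect_equal(ns$nsd[2], 25, tolerance = 5e-4)

  # a fix one degree north of an equatorial origin
  tr2 <- cm_track("a", as.POSIXct("2000-03-01", tz = "UTC") + c(0, 3600),
                  c(10, 10), c(0, 1))
  expect_equal(compute_nsd(tr2)$nsd[2], (6371 * pi / 180)^2, tolerance = 2e-3)

  expect_error(compute_nsd(tr2[1, ]), "two fixes")
})

test_that("single-sigmoid fits recover published parameters from their curves", {
  t <- seq(1, 250, by = 0.1)
  for (id in c(5, 36)) {
    p <- as.list(table_single[table_single$id == id, -1])
    fit <- fit_single_sigmoid(simulate_nsd_series(p, t))
    expect_true(fit$converged)
    co <- coef(fit)
    expect_equal(unname(co["delta"]), p$delta, tolerance = 1e-3)
    expect_equal(unname(co["theta"]), p$theta, tolerance = 1e-3)
    expect_equal(unname(co["phi"]), p$phi, tolerance = 1e-3)
  }
})

test_that("degenerate NSD series yield flagged non-convergence, not errors", {
  flat <- nsd_series(1:100, rep(0, 100))
  fit <- fit_single_sigmoid(flat)
  expect_false(fit$converged)
  fit2 <- fit_double_sigmoid(flat)
  expect_false(fit2$converged)

  # a series that only rises has no autumn limb for the double model
  rise <- simulate_nsd_series(list(delta = 1e6, theta = 100, phi = 3),
                              seq(1, 200))
  fit3 <- fit_double_sigmoid(rise)
  expect_false(fit3$converged)
  expect_match(fit3$message, "autumn")
})

test_that("double-sigmoid fits are self-consistent round trips", {
  p <- list(delta = 2.1e6, theta_s = 118, theta_a = 260, phi_s = 3.3,
            phi_a = 7.7)
  fit <- fit_double_sigmoid(simulate_nsd_series(p, 1:365))
  expect_true(fit$converged)
  expect_equal(as.list(coef(fit))[names(p)], p, tolerance = 1e-6)

  # curve is in its lower logistic tail well before the spring midpoint
  early <- double_sigmoid(p$theta_s - 10 * p$phi_s, p$delta, p$theta_s,
                          p$theta_a, p$phi_s, p$phi_a)
  expect_lt(early, 1e-3 * p$delta)
})

test_that("fits tolerate noise: median asymptote error below 2 percent", {
  p <- list(delta = 2e6, theta = 115, phi = 4)
  t <- seq(1, 250)
  rel_err <- vapply(1:100, function(s) {
    series <- simulate_nsd_series(p, t, noise_sd = 0.05 * p$delta, seed = s)
    fit <- fit_single_sigmoid(series)
    if (!fit$converged) return(NA_real_)
    abs(coef(fit)["delta"] - p$delta) / p$delta
  }, numeric(1))
  expect_true(all(is.finite(rel_err)))
  expect_lt(median(rel_err), 0.02)
})

test_that("fitting is invariant to uniform time translation", {
  p <- list(delta = 3e6, theta = 110, phi = 5)
  base <- simulate_nsd_series(p, seq(1, 250, by = 0.5))
  shifted <- nsd_series(base$t + 50, base$nsd)
  f1 <- coef(fit_single_sigmoid(base))
  f2 <- coef(fit_single_sigmoid(shifted))
  expect_equal(unname(f2["theta"] - f1["theta"]), 50, tolerance = 1e-6)
  expect_equal(unname(f2["delta"]), unname(f1["delta"]), tolerance = 1e-8)
  expect_equal(unname(f2["phi"]), unname(f1["phi"]), tolerance = 1e-8)
})

test_that("derived metrics follow the logistic algebra", {
  # 2*phi for a published bird with phi = 8.43
  p16 <- as.list(table_single[table_single$id == 16, -1])
  fit <- fit_single_sigmoid(simulate_nsd_series(p16, seq(1, 250, by = 0.1)))
  m <- derive_migration_metrics(fit)
  expect_equal(unname(m$two_phi["spring"]), 16.86, tolerance = 1e-3)

  # sqrt(delta) as the migration-distance surrogate for the farthest bird
  p5 <- as.list(table_single[table_single$id == 5, -1])
  fit5 <- fit_single_sigmoid(simulate_nsd_series(p5, seq(1, 250, by = 0.1)))
  m5 <- derive_migration_metrics(fit5)
  expect_equal(round(m5$sqrt_delta_km, 2), 2314.29)

  # quartile span is 2*phi*log(3): 2.1972 days for phi = 1
  pu <- list(delta = 1e6, theta = 100, phi = 1)
  fitu <- fit_single_sigmoid(simulate_nsd_series(pu, seq(1, 200, by = 0.1)))
  mu <- derive_migration_metrics(fitu)
  expect_equal(unname(mu$quartile_span["spring"]), 2 * log(3), tolerance = 1e-6)
  expect_equal(mu$quantile_time(0.75) - mu$quantile_time(0.25),
               2 * log(3), tolerance = 1e-6)
})

test_that("timing segmentation follows the analytic crossing rule", {
  p <- list(delta = 1e6, theta = 100, phi = 5)
  series <- simulate_nsd_series(p, seq(1, 250, by = 0.1))
  fit <- fit_single_sigmoid(series)
  tm <- segment_timing(series, fit, frac = 0.025)
  dep <- 100 + 5 * log(0.025 / 0.975)
  expect_equal(tm$spring_departure, dep, tolerance = 1e-6)
  expect_equal(tm$spring_arrival, 200 - dep, tolerance = 1e-6)
  expect_equal(tm$spring_duration, 2 * 5 * log(0.975 / 0.025), tolerance = 1e-6)

  # at frac = 0.25 the duration equals the quartile span 2*phi*log(3)
  tm25 <- segment_timing(series, fit, frac = 0.25)
  expect_equal(tm25$spring_duration, 2 * 5 * log(3), tolerance = 1e-6)

  expect_error(segment_timing(series, fit, frac = 0.6), "frac")

  # crossings outside the observed span are flagged
  late <- simulate_nsd_series(list(delta = 1e6, theta = 95, phi = 10),
                              seq(90, 250))
  fit_late <- fit_single_sigmoid(late)
  tm_late <- segment_timing(late, fit_late)
  expect_true("spring_departure" %in% tm_late$censored)
})

test_that("double-sigmoid timing covers both seasons symmetrically", {
  p <- list(delta = 2e6, theta_s = 120, theta_a = 270, phi_s = 4, phi_a = 6)
  series <- simulate_nsd_series(p, 1:365)
  fit <- fit_double_sigmoid(series)
  tm <- segment_timing(series, fit, frac = 0.025)
  lo <- log(0.025 / 0.975)
  expect_equal(tm$autumn_departure, 270 + 6 * lo, tolerance = 1e-4)
  expect_equal(tm$autumn_arrival, 270 - 6 * lo, tolerance = 1e-4)
  expect_equal(tm$autumn_duration, tm$autumn_arrival - tm$autumn_departure)
  expect_lt(tm$spring_arrival, tm$autumn_departure)
})
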