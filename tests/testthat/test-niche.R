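make_test_raster <- function(seed = 1, n = 20, season = "winter",
                             bbox = c(-91, 30, -90, 31)) {
  set.seed(seed)
  tmin <- matrix(rnorm(n * n, 5, 1), n, n)
  cm_raster(bbox, (bbox[3] - bbox[1]) / n, tmin, tmin + abs(rnorm(n * n, 10, 1)),
            matrix(abs(rnorm(n * n, 100, 10)), n, n),
            matrix(abs(rnorm(n * n, 3.3, 0.4)), n, n), season = season)
}

test_that("climate extraction is an exact nearest-cell lookup", {
  ras <- make_test_raster()
  cn <- migrniche:::raster_centres(ras)

  # a location at a cell centre returns that cell's values
  env <- extract_climate(data.frame(lon = cn$lon[3], lat = cn$lat[7]), ras)
  expect_equal(env$tmin, ras$vars$tmin[7, 3])
  expect_equal(env$wind, ras$vars$wind[7, 3])
  expect_equal(env$season, "winter")

  # 100 random lookups match a brute-force nearest-centre scan
  set.seed(2)
  pts <- random_locations(ras, 100)
  env100 <- extract_climate(pts, ras)
  brute <- vapply(seq_len(100), function(i) {
    ic <- which.min(abs(cn$lon - pts$lon[i]))
    ir <- which.min(abs(cn$lat - pts$lat[i]))
    ras$vars$precip[ir, ic]
  }, numeric(1))
  expect_equal(env100$precip, brute)

  # constant raster gives identical rows
  rc <- cm_raster(c(0, 0, 1, 1), 0.1, matrix(1, 10, 10), matrix(2, 10, 10),
                  matrix(3, 10, 10), matrix(4, 10, 10), season = "summer")
  envc <- extract_climate(data.frame(lon = runif(5), lat = runif(5)), rc)
  expect_true(all(envc$tmax == 2))

  # out-of-bbox locations are dropped with a count
  expect_warning(
    out <- extract_climate(data.frame(lon = c(cn$lon[1], 50),
                                      lat = c(cn$lat[1], 50)), ras),
    "1 of 2")
  expect_equal(nrow(out), 1)
})

test_that("environmental PCA conserves and attributes variance correctly", {
  # variance in a single variable puts 100% on PC1
  env1 <- data.frame(tmin = rnorm(100), tmax = 0, precip = 0, wind = 0)
  env1$tmax <- env1$tmin * 0 + 1  # constant columns must be rejected
  expect_error(pca_env(env1), "zero-variance")

  set.seed(3)
  env2 <- data.frame(tmin = rnorm(200), tmax = rnorm(200, sd = 1e-4),
                     precip = rnorm(200, sd = 1e-4),
                     wind = rnorm(200, sd = 1e-4))
  # scaling equalises variances, so instead check conservation
  p2 <- pca_env(env2)
  expect_equal(sum(p2$explained), 100, tolerance = 1e-9)

  # known covariance: explained fractions match the eigenvalue ratios
  Sigma <- matrix(c(4, 2, 0, 0,
                    2, 3, 0, 0,
                    0, 0, 2, 0.5,
                    0, 0, 0.5, 1), 4, 4)
  set.seed(4)
  Z <- matrix(rnorm(1e5 * 4), ncol = 4) %*% chol(Sigma)
  env3 <- as.data.frame(Z)
  names(env3) <- c("tmin", "tmax", "precip", "wind")
  p3 <- pca_env(env3)
  # oracle: eigenvalues of the correlation matrix implied by Sigma
  D <- diag(1 / sqrt(diag(Sigma)))
  ev <- eigen(D %*% Sigma %*% D, symmetric = TRUE)$values
  expect_equal(p3$explained, 100 * ev / sum(ev), tolerance = 0.01)
})

test_that("kernel densities on the grid match brute-force kernel sums", {
  set.seed(5)
  occ <- matrix(rnorm(40), ncol = 2)
  bg <- matrix(rnorm(400, sd = 2), ncol = 2)
  g <- occupancy_grid(occ, bg, R = 25)
  probes <- cbind(sample(25, 10, replace = TRUE), sample(25, 10, replace = TRUE))
  for (k in 1:10) {
    i <- probes[k, 1]; j <- probes[k, 2]
    brute_o <- sum(dnorm((g$x[i] - occ[, 1]) / g$bw[1]) *
                     dnorm((g$y[j] - occ[, 2]) / g$bw[2])) /
      (nrow(occ) * g$bw[1] * g$bw[2])
    brute_e <- sum(dnorm((g$x[i] - bg[, 1]) / g$bw[1]) *
                     dnorm((g$y[j] - bg[, 2]) / g$bw[2])) /
      (nrow(bg) * g$bw[1] * g$bw[2])
    expect_equal(g$o[i, j], brute_o, tolerance = 1e-8)
    expect_equal(g$e[i, j], brute_e, tolerance = 1e-8)
  }
})

test_that("concentrated occurrences saturate a single cell", {
  occ <- matrix(rep(c(0.5, 0.5), each = 20), ncol = 2)
  bg <- as.matrix(expand.grid(seq(0, 1, 0.05), seq(0, 1, 0.05)))
  g <- occupancy_grid(occ, bg, R = 21, extent = c(0, 1, 0, 1),
                      bw = c(0.01, 0.01), correction = FALSE)
  at <- which.min(abs(g$x - 0.5))
  expect_equal(g$z[at, at], 1)
  far <- g$z[1, 1]
  expect_lt(far, 1e-6)
})

test_that("overlap statistics match hand-computed values", {
  # identical grids
  set.seed(6)
  occ <- matrix(rnorm(60), ncol = 2)
  bg <- matrix(rnorm(300, sd = 2), ncol = 2)
  g <- occupancy_grid(occ, bg, R = 30)
  expect_equal(schoener_D(g, g), 1)
  expect_equal(hellinger_I(g, g), 1)

  # hand-specified occupancy distributions
  g1 <- grid_from_z(matrix(c(0.5, 0.5, 0), 3, 1))
  g2 <- grid_from_z(matrix(c(0, 0.5, 0.5), 3, 1))
  expect_equal(schoener_D(g1, g2), 0.5)
  p1 <- c(1, 0); p2 <- c(0.5, 0.5)
  gI1 <- grid_from_z(matrix(p1, 2, 1))
  gI2 <- grid_from_z(matrix(p2, 2, 1))
  expect_equal(hellinger_I(gI1, gI2),
               1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2), tolerance = 1e-12)
  expect_equal(round(hellinger_I(gI1, gI2), 4), 0.7071)

  # disjoint supports
  gd1 <- grid_from_z(matrix(c(1, 0, 0, 0), 4, 1))
  gd2 <- grid_from_z(matrix(c(0, 0, 0, 1), 4, 1))
  expect_equal(schoener_D(gd1, gd2), 0)
  expect_equal(hellinger_I(gd1, gd2), 0)

  # geometry mismatch is an error
  gbad <- occupancy_grid(occ, bg, R = 31)
  expect_error(schoener_D(g, gbad), "geometry")
})

test_that("overlap decreases monotonically as one niche is translated away", {
  set.seed(7)
  base <- matrix(rnorm(400), ncol = 2)
  bg <- matrix(rnorm(2000, sd = 3), ncol = 2)
  shifts <- c(0, 1, 2, 4, 8)
  ext <- shared_extent(list(rbind(base, sweep(base, 2, c(-max(shifts), 0)), bg)))
  Ds <- vapply(shifts, function(s) {
    g1 <- occupancy_grid(base, bg, R = 60, extent = ext, bw = c(0.3, 0.3))
    g2 <- occupancy_grid(sweep(base, 2, c(s, 0)), bg, R = 60, extent = ext,
                         bw = c(0.3, 0.3))
    schoener_D(g1, g2)
  }, numeric(1))
  expect_true(all(diff(Ds) < 0))
  Is <- vapply(shifts, function(s) {
    g1 <- occupancy_grid(base, bg, R = 60, extent = ext, bw = c(0.3, 0.3))
    g2 <- occupancy_grid(sweep(base, 2, c(s, 0)), bg, R = 60, extent = ext,
                         bw = c(0.3, 0.3))
    hellinger_I(g1, g2)
  }, numeric(1))
  expect_true(all(diff(Is) < 0))
})

test_that("D is stable to doubling the grid resolution", {
  set.seed(8)
  occ1 <- matrix(rnorm(400), ncol = 2)
  occ2 <- matrix(rnorm(400, mean = 1), ncol = 2)
  bg <- matrix(rnorm(3000, sd = 2), ncol = 2)
  ext <- shared_extent(list(rbind(occ1, occ2, bg)))
  D_at <- function(R) {
    g1 <- occupancy_grid(occ1, bg, R = R, extent = ext, bw = c(0.4, 0.4))
    g2 <- occupancy_grid(occ2, bg, R = R, extent = ext, bw = c(0.4, 0.4))
    schoener_D(g1, g2)
  }
  expect_lt(abs(D_at(100) - D_at(200)), 0.02)
})

test_that("one-dimensional variable overlap behaves as a shared area", {
  set.seed(9)
  v <- rnorm(500, 3.3, 0.4)
  expect_equal(variable_overlap_1d(v, v), 1, tolerance = 1e-6)
  expect_lt(variable_overlap_1d(v, v + 100 * 0.4), 1e-6)

  # seasonal wind speeds: empirical overlap matches the closed-form normal
  # overlap of N(3.33, 0.4^2) and N(3.26, 0.34^2)
  f <- function(x) pmin(dnorm(x, 3.33, 0.4), dnorm(x, 3.26, 0.34))
  oracle <- integrate(f, 0, 8)$value
  set.seed(10)
  w1 <- rnorm(1e4, 3.33, 0.4)
  w2 <- rnorm(1e4, 3.26, 0.34)
  ov <- variable_overlap_1d(w1, w2)
  expect_equal(ov, oracle, tolerance = 0.03)
  expect_gt(ov, 0.85)
})
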