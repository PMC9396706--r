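## Published single-sigmoid spring-migration parameter estimates
## (asymptote km^2, midpoint day, time-elapse days) for 12 birds.
table_single <- data.frame(
  id    = c(5, 16, 17, 18, 20, 21, 26, 27, 28, 33, 36, 46),
  delta = c(5355946.16, 4721621.13, 2429528.95, 2093731.29, 2718863.72,
            2433822.63, 2090535.46, 1622824.09, 3176429.01, 2658532.82,
            1979773.66, 1260050.02),
  theta = c(125.77, 128.40, 131.06, 130.27, 108.66, 112.55, 140.29, 129.27,
            112.09, 112.02, 102.57, 114.85),
  phi   = c(3.64, 8.43, 5.58, 3.02, 6.02, 2.98, 7.60, 0.67, 2.30, 1.28,
            1.18, 2.53)
)

## Published double-sigmoid annual parameter estimates for 9 birds.
table_double <- data.frame(
  id      = c(22, 34, 47, 48, 49, 51, 52, 53, 54),
  delta   = c(2542838.60, 1488701.72, 1861991.00, 2598861.00, 1934719.44,
              2958255.99, 2376075.74, 3329986.49, 3857982.16),
  theta_s = c(135.28, 96.66, 131.11, 114.57, 96.54, 110.30, 137.44, 128.87,
              122.42),
  theta_a = c(237.15, 295.36, 167.39, 274.45, 272.86, 262.93, 301.32, 301.01,
              282.24),
  phi_s   = c(6.14, 0.08, 0.83, 0.41, 0.27, 2.88, 1.42, 7.24, 3.37),
  phi_a   = c(13.01, 0.45, 1.93, 6.96, 2.23, 6.92, 1.53, 5.64, 4.85)
)

## Great-circle distance oracle used by geometry tests (spherical law of
## cosines, R = 6371 km), independent of the package's haversine path.
gc_dist_oracle <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  cosd <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  6371 * acos(pmin(1, pmax(-1, cosd)))
}

## Build a track with fixes at given hour offsets and planar km offsets from
## a reference point (small-offset degree conversion).
track_from_plan <- function(hours, x_km, y_km, ref = c(-90, 40),
                            id = "t", lc_class = NULL) {
  lat <- ref[2] + y_km / 111.1949
  lon <- ref[1] + x_km / (111.1949 * cos(ref[2] * pi / 180))
  cm_track(id, as.POSIXct("2000-01-01", tz = "UTC") + hours * 3600,
           lon, lat, lc_class = lc_class, true_lon = lon, true_lat = lat)
}

## Simulate a track from the exact integrated-OU (CRW) model plus Gaussian
## measurement noise; used for parameter-recovery checks.
simulate_iou_track <- function(beta, sigma, n, dt_h, meas_sd, seed,
                               ref = c(-90, 40)) {
  set.seed(seed)
  M <- migrniche:::iou_matrices(beta, sigma^2, dt_h)
  L <- t(chol(M$Q))
  pos <- matrix(0, n, 2)
  st <- matrix(0, 2, 2)  # columns are the (position, velocity) of each axis
  for (i in 2:n) {
    for (ax in 1:2) st[, ax] <- M$T %*% st[, ax] + L %*% rnorm(2)
    pos[i, ] <- st[1, ]
  }
  obs <- pos + matrix(rnorm(2 * n, 0, meas_sd), n, 2)
  tr <- track_from_plan(seq_len(n) * dt_h, obs[, 1], obs[, 2], ref = ref)
  attr(tr, "true_xy") <- pos
  tr
}

## Minimal niche_grid wrapper so overlap formulas can be checked on
## hand-specified occupancy distributions.
grid_from_z <- function(z) {
  R <- nrow(z)
  structure(list(x = seq_len(R), y = seq_len(ncol(z)), o = z, e = z, z = z,
                 bw = c(1, 1), extent = c(0, 1, 0, 1), R = R,
                 correction = FALSE),
            class = "niche_grid")
}

## Random occurrence locations inside a raster's bounding box.
random_locations <- function(raster, n) {
  bb <- raster$bbox
  data.frame(lon = stats::runif(n, bb[1], bb[3]),
             lat = stats::runif(n, bb[2], bb[4]))
}
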