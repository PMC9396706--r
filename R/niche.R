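#' Extract climate values at occurrence locations
#'
#' Nearest-cell lookup of the four climate variables at each location; the
#' raster's season label is attached to every row. Locations outside the
#' raster bounding box are dropped with a warning reporting their count.
#'
#' @param locations Data.frame with `lon`, `lat` columns (e.g. a `cm_track`).
#' @param raster A [cm_raster()].
#' @return An environment table: data.frame with `tmin`, `tmax`, `precip`,
#'   `wind`, `season`.
#' @export
extract_climate <- function(locations, raster) {
  stopifnot(inherits(raster, "cm_raster"))
  lon <- locations$lon
  lat <- locations$lat
  bb <- raster$bbox
  inside <- lon >= bb[1] & lon <= bb[3] & lat >= bb[2] & lat <= bb[4]
  if (any(!inside)) {
    warning(sprintf("%d of %d locations outside the raster bbox were dropped",
                    sum(!inside), length(lon)))
    lon <- lon[inside]; lat <- lat[inside]
  }
  d <- dim(raster$vars$tmin)
  col <- pmin(d[2], pmax(1L, ceiling((lon - bb[1]) / raster$cell_size)))
  row <- pmin(d[1], pmax(1L, ceiling((lat - bb[2]) / raster$cell_size)))
  idx <- cbind(row, col)
  data.frame(tmin = raster$vars$tmin[idx],
             tmax = raster$vars$tmax[idx],
             precip = raster$vars$precip[idx],
             wind = raster$vars$wind[idx],
             season = raster$season,
             stringsAsFactors = FALSE)
}

#' Environment table of all raster cells
#'
#' The background climate sample for the ordination: one row per raster cell.
#'
#' @param raster A [cm_raster()].
#' @return A data.frame like [extract_climate()]'s output.
#' @export
raster_env_table <- function(raster) {
  data.frame(tmin = as.vector(raster$vars$tmin),
             tmax = as.vector(raster$vars$tmax),
             precip = as.vector(raster$vars$precip),
             wind = as.vector(raster$vars$wind),
             season = raster$season,
             stringsAsFactors = FALSE)
}

#' Principal component analysis of the pooled climate space
#'
#' PCA of the centred, unit-variance-scaled climate variables over the pooled
#' background and occurrence rows of both seasons. Niche comparisons happen
#' in the space of the first two components.
#'
#' @param env Pooled environment table (rows from both seasons).
#' @param vars Climate variable columns to use.
#' @return A list with the `prcomp` object, `scores` (matrix), and
#'   `explained` (percent variance per component, summing to 100).
#' @export
pca_env <- function(env, vars = c("tmin", "tmax", "precip", "wind")) {
  stopifnot(all(vars %in% names(env)), nrow(env) >= 3)
  X <- as.matrix(env[, vars])
  if (anyNA(X)) stop("missing values in the environment table", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ", paste(vars[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  explained <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(prcomp = p, scores = p$x, explained = explained)
}

## Gaussian product-kernel density of `pts` (n x 2) evaluated at the tensor
## grid (gx, gy); returns a length(gx) x length(gy) matrix. Plain kernel sums
## so tests can verify against a brute-force double loop.
kde2d_grid <- function(pts, gx, gy, bw) {
  n <- nrow(pts)
  Kx <- outer(gx, pts[, 1], function(g, p) stats::dnorm((g - p) / bw[1]))
  Ky <- outer(gy, pts[, 2], function(g, p) stats::dnorm((g - p) / bw[2]))
  (Kx %*% t(Ky)) / (n * bw[1] * bw[2])
}

## Scott's bandwidth per axis for d = 2: sd * n^(-1/6).
scott_bw <- function(pts) {
  apply(pts, 2, stats::sd) * nrow(pts)^(-1 / 6)
}

#' Kernel occupancy grid in PC space
#'
#' Maps occurrences and background environment onto an `R x R` grid over the
#' first two principal components, estimates Gaussian kernel densities of
#' both at the cell centres, and rescales occupancy to `[0, 1]`. With
#' `correction = TRUE` (default) the occupancy is the ratio of occurrence
#' density to background environment density (`z` proportional to `o/e` where
#' `e` exceeds a small threshold, 0 elsewhere), which compares niches while
#' accounting for what climates were available; `correction = FALSE` uses the
#' raw occurrence density.
#'
#' @param occ_scores Matrix (n x 2) of occurrence scores on PC1-PC2.
#' @param bg_scores Matrix (m x 2) of background scores on the same axes.
#' @param R Grid resolution per axis (default 100).
#' @param extent Numeric `c(x_min, x_max, y_min, y_max)`; supply a shared
#'   extent (see [shared_extent()]) when two grids will be compared. Defaults
#'   to the pooled score range expanded by a 10% margin.
#' @param bw Length-2 bandwidths; default Scott's rule on the pooled scores.
#' @param correction Logical; background-corrected occupancy (default).
#' @param e_thresh Fraction of `max(e)` below which a cell is treated as
#'   outside the available environment (`z = 0` there). The occurrence and
#'   environment kernel densities both decay like Gaussian tails far from
#'   their data, so their ratio is numerically unstable where `e` is
#'   negligible; the default 0.05 confines the correction to cells with a
#'   non-trivial amount of available environment.
#' @return A `niche_grid` with cell-centre coordinates, occurrence density
#'   `o`, environment density `e` and rescaled occupancy `z`.
#' @export
occupancy_grid <- function(occ_scores, bg_scores, R = 100, extent = NULL,
                           bw = NULL, correction = TRUE, e_thresh = 0.05) {
  occ_scores <- as.matrix(occ_scores)[, 1:2, drop = FALSE]
  bg_scores <- as.matrix(bg_scores)[, 1:2, drop = FALSE]
  if (nrow(occ_scores) < 5) stop("need at least 5 occurrences", call. = FALSE)
  pooled <- rbind(occ_scores, bg_scores)
  if (is.null(extent)) extent <- shared_extent(list(pooled))
  if (is.null(bw)) bw <- scott_bw(pooled)
  if (any(bw <= 0)) stop("kernel bandwidth must be positive", call. = FALSE)
  gx <- seq(extent[1], extent[2], length.out = R)
  gy <- seq(extent[3], extent[4], length.out = R)
  o <- kde2d_grid(occ_scores, gx, gy, bw)
  e <- kde2d_grid(bg_scores, gx, gy, bw)
  if (correction) {
    eps <- e_thresh * max(e)
    z <- ifelse(e > eps, o / e, 0)
  } else {
    z <- o
  }
  if (max(z) > 0) z <- z / max(z)
  structure(list(x = gx, y = gy, o = o, e = e, z = z, bw = bw,
                 extent = extent, R = R, correction = correction),
            class = "niche_grid")
}

#' @export
print.niche_grid <- function(x, ...) {
  cat(sprintf("<niche_grid> %d x %d cells, extent [%.2f, %.2f] x [%.2f, %.2f], %s\n",
              x$R, x$R, x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              if (x$correction) "background-corrected" else "uncorrected"))
  invisible(x)
}

#' Common grid extent for comparable niche grids
#'
#' @param score_list List of score matrices (n x 2) to cover.
#' @param margin Fractional range expansion per side (default 10%).
#' @return Numeric `c(x_min, x_max, y_min, y_max)`.
#' @export
shared_extent <- function(score_list, margin = 0.1) {
  all_pts <- do.call(rbind, lapply(score_list, function(s) as.matrix(s)[, 1:2]))
  rx <- range(all_pts[, 1]); ry <- range(all_pts[, 2])
  mx <- margin * diff(rx); my <- margin * diff(ry)
  c(rx[1] - mx, rx[2] + mx, ry[1] - my, ry[2] + my)
}

check_same_geometry <- function(g1, g2) {
  if (g1$R != g2$R || any(abs(g1$extent - g2$extent) > 1e-12)) {
    stop("niche grids have different geometry", call. = FALSE)
  }
  invisible(TRUE)
}

## normalized occupancy distributions over the cells
norm_occupancy <- function(g) {
  s <- sum(g$z)
  if (s == 0) stop("empty occupancy grid", call. = FALSE)
  g$z / s
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|p1 - p2|)` over the occupancies normalised to sum 1;
#' ranges from 0 (no overlap) to 1 (identical niches).
#'
#' @param g1,g2 `niche_grid` objects on identical geometry.
#' @return D in `[0, 1]`.
#' @export
schoener_D <- function(g1, g2) {
  check_same_geometry(g1, g2)
  p1 <- norm_occupancy(g1)
  p2 <- norm_occupancy(g2)
  max(0, min(1, 1 - 0.5 * sum(abs(p1 - p2))))
}

#' Hellinger-based I niche similarity
#'
#' `I = 1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2)`, i.e. one minus half the
#' squared Hellinger distance between the normalised occupancies; ranges
#' from 0 to 1.
#'
#' @inheritParams schoener_D
#' @return I in `[0, 1]`.
#' @export
hellinger_I <- function(g1, g2) {
  check_same_geometry(g1, g2)
  p1 <- norm_occupancy(g1)
  p2 <- norm_occupancy(g2)
  max(0, min(1, 1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2)))
}

#' One-dimensional overlap of a single climate variable
#'
#' Gaussian kernel densities of the two seasonal samples are evaluated on a
#' common grid, each normalised to integrate to 1; the overlap is the
#' integrated minimum of the two densities (the shared area, in `[0, 1]`).
#' Used for the seasonal wind-speed comparison.
#'
#' @param values1,values2 Numeric samples (>= 5 values each).
#' @param n_grid Number of grid points.
#' @return Overlap in `[0, 1]`.
#' @export
variable_overlap_1d <- function(values1, values2, n_grid = 512) {
  stopifnot(length(values1) >= 5, length(values2) >= 5)
  s1 <- stats::sd(values1); s2 <- stats::sd(values2)
  if (s1 == 0 && s2 == 0) {
    if (values1[1] == values2[1]) {
      warning("both samples are degenerate point masses; overlap is 1")
      return(1)
    }
    return(0)
  }
  bw1 <- stats::bw.nrd0(values1)
  bw2 <- stats::bw.nrd0(values2)
  lo <- min(values1, values2) - 3 * max(bw1, bw2)
  hi <- max(values1, values2) + 3 * max(bw1, bw2)
  g <- seq(lo, hi, length.out = n_grid)
  dx <- g[2] - g[1]
  d1 <- vapply(g, function(x) mean(stats::dnorm(x, values1, bw1)), numeric(1))
  d2 <- vapply(g, function(x) mean(stats::dnorm(x, values2, bw2)), numeric(1))
  d1 <- d1 / (sum(d1) * dx)
  d2 <- d2 / (sum(d2) * dx)
  min(1, sum(pmin(d1, d2)) * dx)
}

#' Seasonal niche overlap from occurrences and climate rasters
#'
#' Convenience wrapper running the full ordination comparison: pools the two
#' seasons' backgrounds (all raster cells) and occurrence climates, fits the
#' PCA, builds one background-corrected occupancy grid per season on a shared
#' extent, and computes Schoener's D, the I statistic and the 1-D wind
#' overlap.
#'
#' @param occ_winter,occ_summer Data.frames with `lon`, `lat` of thinned
#'   occurrence locations.
#' @param raster_winter,raster_summer [cm_raster()] objects.
#' @param R Grid resolution.
#' @param correction Background-corrected occupancy (default TRUE).
#' @return A list with `D`, `I`, `wind_overlap`, `explained` (percent
#'   variance per PC), `bw`, and the two `niche_grid`s.
#' @export
niche_overlap <- function(occ_winter, occ_summer, raster_winter, raster_summer,
                          R = 100, correction = TRUE) {
  env_occ_w <- extract_climate(occ_winter, raster_winter)
  env_occ_s <- extract_climate(occ_summer, raster_summer)
  env_bg_w <- raster_env_table(raster_winter)
  env_bg_s <- raster_env_table(raster_summer)
  pooled <- rbind(env_occ_w, env_occ_s, env_bg_w, env_bg_s)
  role <- rep(c("occ_w", "occ_s", "bg_w", "bg_s"),
              c(nrow(env_occ_w), nrow(env_occ_s), nrow(env_bg_w), nrow(env_bg_s)))
  pca <- pca_env(pooled)
  sc <- pca$scores[, 1:2, drop = FALSE]
  ext <- shared_extent(list(sc))
  bw <- scott_bw(sc)
  gw <- occupancy_grid(sc[role == "occ_w", ], sc[role == "bg_w", ],
                       R = R, extent = ext, bw = bw, correction = correction)
  gs <- occupancy_grid(sc[role == "occ_s", ], sc[role == "bg_s", ],
                       R = R, extent = ext, bw = bw, correction = correction)
  list(D = schoener_D(gw, gs),
       I = hellinger_I(gw, gs),
       wind_overlap = variable_overlap_1d(env_occ_w$wind, env_occ_s$wind),
       explained = pca$explained,
       bw = bw,
       grid_winter = gw,
       grid_summer = gs)
}
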