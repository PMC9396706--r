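#' @keywords internal
"_PACKAGE"

## Earth radius (km) used for all great-circle geometry in this package.
EARTH_RADIUS_KM <- 6371

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after seeding the RNG, then restores the caller's RNG state so
#' package functions never disturb the global random stream. A `NULL` seed
#' evaluates `code` with the current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Fractional day of year
#'
#' Converts UTC timestamps to fractional Julian day within the track's first
#' calendar year (January 1st 00:00 is day 1.0). Timestamps after December 31st
#' keep counting upwards so annual series remain strictly increasing.
#'
#' @param time `POSIXct` vector (UTC).
#' @return Numeric vector of fractional days.
#' @export
day_of_year <- function(time) {
  stopifnot(inherits(time, "POSIXct"))
  year_start <- as.POSIXct(format(time[1], "%Y-01-01 00:00:00"), tz = "UTC")
  as.numeric(difftime(time, year_start, units = "days")) + 1
}

#' Draw from a normal distribution truncated at zero
#'
#' Inverse-CDF sampler for X ~ N(mean, sd) conditioned on X >= 0; used for
#' precipitation fields, which must be non-negative.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the untruncated normal.
#' @return Numeric vector of non-negative draws.
#' @keywords internal
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(max(mean, 0), n))
  }
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  u <- stats::runif(n, min = lo, max = 1)
  stats::qnorm(u, mean = mean, sd = sd)
}

## Great-circle step lengths (km) between successive rows of a lon/lat matrix.
step_lengths_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) {
    return(numeric(0))
  }
  p <- cbind(lon, lat)
  geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                           r = EARTH_RADIUS_KM)
}

## Great-circle distance (km) between points and a single reference point.
dist_to_point_km <- function(lon, lat, ref_lon, ref_lat) {
  geosphere::distHaversine(cbind(lon, lat), c(ref_lon, ref_lat),
                           r = EARTH_RADIUS_KM)
}
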