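#' Hourly movement speeds from successive fixes
#'
#' For each pair of successive fixes whose time gap lies in the closed
#' `interval_window` (default 30-60 minutes), the hourly distance is the
#' great-circle step length (km, R = 6371 km) divided by the gap in hours.
#' Pairs outside the window are excluded; an empty result is allowed.
#'
#' @param traj A `cm_track`.
#' @param interval_window Closed interval of admissible gaps, in hours.
#' @return A data.frame with `animal_id`, `time` (start of the step),
#'   `dt_h`, `step_km`, `speed_kmh` and a `season` label from
#'   [season_from_months()].
#' @export
hourly_speeds <- function(traj, interval_window = c(0.5, 1.0)) {
  stopifnot(inherits(traj, "cm_track"))
  n <- nrow(traj)
  if (n < 2) {
    return(data.frame(animal_id = character(), time = as.POSIXct(character()),
                      dt_h = numeric(), step_km = numeric(),
                      speed_kmh = numeric(), season = character()))
  }
  dt_h <- diff(as.numeric(traj$time)) / 3600
  keep <- dt_h >= interval_window[1] & dt_h <= interval_window[2]
  step <- step_lengths_km(traj$lon, traj$lat)
  out <- data.frame(animal_id = traj$animal_id[-n][keep],
                    time = traj$time[-n][keep],
                    dt_h = dt_h[keep],
                    step_km = step[keep],
                    speed_kmh = step[keep] / dt_h[keep],
                    stringsAsFactors = FALSE)
  out$season <- season_from_months(out$time)
  out
}

#' Total trip distance over a time interval
#'
#' Sum of great-circle step lengths between successive fixes whose times fall
#' in `[start, end]`; used for spring/autumn migration trip distance.
#'
#' @param traj A `cm_track`.
#' @param start,end Interval bounds, either `POSIXct` or numeric day of year.
#' @return Distance in km (0 with a warning if fewer than two fixes qualify).
#' @export
trip_distance <- function(traj, start, end) {
  stopifnot(inherits(traj, "cm_track"))
  tt <- if (inherits(start, "POSIXct")) traj$time else day_of_year(traj$time)
  if (start >= end) stop("start must precede end", call. = FALSE)
  sel <- which(tt >= start & tt <= end)
  if (length(sel) < 2) {
    warning("fewer than two fixes in the interval; distance is 0")
    return(0)
  }
  sum(step_lengths_km(traj$lon[sel], traj$lat[sel]))
}

#' Seasonal speed summary across animals
#'
#' Aggregates per-step hourly speeds to one mean per animal and season, then
#' summarises each season across animals (so the sampling unit is the animal,
#' avoiding pseudo-replication): mean of per-animal means with a
#' normal-approximation 95% CI (mean +/- 1.96 SE across animals). The
#' `"ci_overlap"` attribute reports, for each pair of seasons, whether the
#' CIs overlap.
#'
#' @param speeds A data.frame with columns `animal_id`, `season`,
#'   `speed_kmh` (e.g. rbind-ed outputs of [hourly_speeds()]).
#' @return A data.frame with one row per season: `season`, `n_animals`,
#'   `mean_kmh`, `ci_lo`, `ci_hi`, `ci_defined`.
#' @export
summarize_speeds <- function(speeds) {
  stopifnot(all(c("animal_id", "season", "speed_kmh") %in% names(speeds)))
  speeds <- speeds[!is.na(speeds$season), , drop = FALSE]
  per_animal <- stats::aggregate(speed_kmh ~ animal_id + season, data = speeds,
                                 FUN = mean)
  out <- do.call(rbind, lapply(split(per_animal, per_animal$season), function(d) {
    n <- nrow(d)
    m <- mean(d$speed_kmh)
    if (n >= 2) {
      se <- stats::sd(d$speed_kmh) / sqrt(n)
      data.frame(season = d$season[1], n_animals = n, mean_kmh = m,
                 ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
                 ci_defined = TRUE)
    } else {
      data.frame(season = d$season[1], n_animals = n, mean_kmh = m,
                 ci_lo = NA_real_, ci_hi = NA_real_, ci_defined = FALSE)
    }
  }))
  rownames(out) <- NULL
  if (nrow(out) >= 2) {
    pairs <- utils::combn(seq_len(nrow(out)), 2)
    ov <- apply(pairs, 2, function(ij) {
      a <- out[ij[1], ]; b <- out[ij[2], ]
      if (!a$ci_defined || !b$ci_defined) return(NA)
      a$ci_lo <= b$ci_hi && b$ci_lo <= a$ci_hi
    })
    names(ov) <- apply(pairs, 2, function(ij) {
      paste(out$season[ij[1]], out$season[ij[2]], sep = "~")
    })
    attr(out, "ci_overlap") <- ov
  }
  out
}

#' Ordinary least-squares regression of observed on model-based metrics
#'
#' Used to relate track-segmentation metrics (observed migration duration or
#' trip distance) to their model-based surrogates (`2 phi`, `sqrt(delta)`).
#'
#' @param x Model-based metric (predictor).
#' @param y Observed metric (response).
#' @return A list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_observed_vs_model <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(x))
}
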