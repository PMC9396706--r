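#' Single (spring) sigmoid model of net squared displacement
#'
#' `NSD(t) = delta / (1 + exp((theta - t) / phi))`: a logistic rise from 0 to
#' the asymptote `delta` (km^2), reaching `delta/2` at the spring midpoint
#' `theta` (day of year) with time-elapse scale `phi` (days).
#'
#' @param t Day of year (may be fractional).
#' @param delta Asymptote (km^2).
#' @param theta Midpoint (day).
#' @param phi Time-elapse scale (days), > 0.
#' @return Numeric vector of NSD values (km^2).
#' @export
single_sigmoid <- function(t, delta, theta, phi) {
  delta / (1 + exp((theta - t) / phi))
}

#' Double sigmoid model of an annual NSD trajectory
#'
#' Rise-plateau-return form
#' `NSD(t) = delta/(1+exp((theta_s-t)/phi_s)) - delta/(1+exp((theta_a-t)/phi_a))`:
#' the spring limb rises from 0 to `delta` around `theta_s` and the autumn
#' limb returns the curve toward 0 around `theta_a`. For well-separated
#' midpoints the summer plateau sits at `delta`.
#'
#' @param t Day of year.
#' @param delta Asymptote (km^2).
#' @param theta_s,theta_a Spring and autumn midpoints (days), `theta_s < theta_a`.
#' @param phi_s,phi_a Spring and autumn time-elapse scales (days), > 0.
#' @return Numeric vector of NSD values (km^2).
#' @export
double_sigmoid <- function(t, delta, theta_s, theta_a, phi_s, phi_a) {
  delta / (1 + exp((theta_s - t) / phi_s)) -
    delta / (1 + exp((theta_a - t) / phi_a))
}

#' Construct an NSD time series
#'
#' @param t Numeric vector of (fractional) days of year, strictly increasing.
#' @param nsd Numeric vector of net squared displacements (km^2).
#' @param animal_id Identifier.
#' @param from_trajectory Logical; series computed from a real trajectory must
#'   be non-negative with a zero first value, while model-simulated series
#'   with additive noise may dip below zero.
#' @return An `nsd_series` data.frame with columns `t`, `nsd`.
#' @export
nsd_series <- function(t, nsd, animal_id = "animal", from_trajectory = TRUE) {
  stopifnot(length(t) == length(nsd))
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (from_trajectory && any(nsd < 0)) {
    stop("NSD from a trajectory cannot be negative", call. = FALSE)
  }
  structure(data.frame(t = t, nsd = nsd),
            animal_id = animal_id,
            class = c("nsd_series", "data.frame"))
}

#' Net squared displacement of a track
#'
#' Squared planar distance (km^2) of every fix from the track's first fix,
#' using an azimuthal-equidistant projection centred at that first fix (so
#' the displacement of each fix from the origin is its exact great-circle
#' distance).
#'
#' @param traj A `cm_track` with at least two fixes.
#' @return An [nsd_series()] with `t` as fractional day of year.
#' @export
compute_nsd <- function(traj) {
  stopifnot(inherits(traj, "cm_track"))
  if (nrow(traj) < 2) stop("need at least two fixes", call. = FALSE)
  origin <- c(traj$lon[1], traj$lat[1])
  xy <- project_to_plane(traj$lon, traj$lat, origin)
  nsd_series(day_of_year(traj$time), xy$x_km^2 + xy$y_km^2,
             animal_id = traj$animal_id[1])
}

## ---- sigmoid fitting ------------------------------------------------------

## Interpolated crossing of level `lev` on (t, y); direction "up" finds the
## first upward crossing, "down" the last downward one. Returns c(t, slope).
level_crossing <- function(t, y, lev, direction = c("up", "down")) {
  direction <- match.arg(direction)
  above <- y >= lev
  idx <- if (direction == "up") {
    which(!above[-length(above)] & above[-1])
  } else {
    which(above[-length(above)] & !above[-1])
  }
  if (!length(idx)) {
    return(NULL)
  }
  i <- if (direction == "up") idx[1] else idx[length(idx)]
  slope <- (y[i + 1] - y[i]) / (t[i + 1] - t[i])
  tc <- t[i] + (lev - y[i]) / slope
  c(tc, abs(slope))
}

## phi guess from the local slope at the half-asymptote crossing: a logistic
## has slope delta/(4 phi) at its midpoint.
phi_from_slope <- function(delta, slope) {
  if (!is.finite(slope) || slope <= 0) {
    return(5)
  }
  min(100, max(1e-3, delta / (4 * slope)))
}

nlslm_try <- function(formula, data, start, lower, upper) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL
  )
}

failed_fit <- function(kind, animal_id, message) {
  structure(list(kind = kind, coefficients = NULL, se = NULL,
                 residual_sd = NA_real_, rss = NA_real_,
                 converged = FALSE, message = message,
                 animal_id = animal_id, t_range = c(NA_real_, NA_real_)),
            class = "sigmoid_fit")
}

make_fit <- function(obj, kind, animal_id, t_range) {
  s <- summary(obj)
  co <- stats::coef(obj)
  fit <- list(kind = kind,
              coefficients = co,
              se = s$coefficients[, "Std. Error"],
              residual_sd = s$sigma,
              rss = sum(stats::residuals(obj)^2),
              converged = obj$convInfo$isConv,
              message = obj$convInfo$stopMessage,
              animal_id = animal_id,
              t_range = t_range)
  structure(fit, class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> %s model, animal %s, converged: %s\n",
              x$kind, x$animal_id, x$converged))
  if (!is.null(x$coefficients)) {
    est <- rbind(estimate = x$coefficients, se = x$se)
    print(signif(est, 6))
    cat(sprintf("  residual SD %.4g km^2\n", x$residual_sd))
  } else {
    cat("  ", x$message, "\n")
  }
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' Fit the single sigmoid NSD model
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' [single_sigmoid()] to an NSD series. Starting values are derived from the
#' data: `delta` from the series maximum, `theta` from the interpolated
#' half-asymptote crossing, and `phi` from the local slope there (a logistic
#' has slope `delta/(4 phi)` at its midpoint); a small deterministic
#' multi-start over `phi` guards against very abrupt, step-like migrations.
#' Degenerate series (no rise, e.g. all zero) yield a non-converged fit
#' object rather than an error.
#'
#' @param series An [nsd_series()].
#' @param init Optional named list overriding the automatic start values.
#' @return A `sigmoid_fit` with estimates, asymptotic standard errors,
#'   residual SD and a convergence flag.
#' @export
fit_single_sigmoid <- function(series, init = NULL) {
  stopifnot(inherits(series, "nsd_series"))
  id <- attr(series, "animal_id")
  t <- series$t
  y <- series$nsd
  delta0 <- max(y)
  if (!is.finite(delta0) || delta0 <= 0 || stats::sd(y) == 0) {
    return(failed_fit("single", id, "no NSD rise detected"))
  }
  cross <- level_crossing(t, y, delta0 / 2, "up")
  if (is.null(cross)) {
    return(failed_fit("single", id, "no half-asymptote crossing"))
  }
  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- init
  } else {
    phi0 <- phi_from_slope(delta0, cross[2])
    starts[[1]] <- list(delta = delta0, theta = cross[1], phi = phi0)
    for (p in c(0.05, 0.5, 5, 20)) {
      starts[[length(starts) + 1]] <- list(delta = delta0, theta = cross[1], phi = p)
    }
  }
  lower <- c(delta = delta0 * 1e-6, theta = min(t) - 50, phi = 1e-3)
  upper <- c(delta = Inf, theta = max(t) + 50, phi = 100)
  best <- NULL
  for (st in starts) {
    obj <- nlslm_try(nsd ~ delta / (1 + exp((theta - t) / phi)),
                     data = series, start = st, lower = lower, upper = upper)
    if (!is.null(obj) &&
        (is.null(best) || sum(stats::residuals(obj)^2) < sum(stats::residuals(best)^2))) {
      best <- obj
    }
    # noiseless data: stop once the fit is essentially exact
    if (!is.null(best) &&
        sum(stats::residuals(best)^2) < (1e-8 * delta0)^2 * length(y)) break
  }
  if (is.null(best)) {
    return(failed_fit("single", id, "optimizer failed from all starts"))
  }
  make_fit(best, "single", id, range(t))
}

#' Fit the double sigmoid NSD model
#'
#' Levenberg-Marquardt fit of [double_sigmoid()] (rise-plateau-return form)
#' to an annual NSD series. Starting midpoints come from the first upward and
#' last downward half-asymptote crossings; `phi` starts from the local slopes
#' with the same multi-start fallback as [fit_single_sigmoid()]. A series
#' with no autumn (downward) limb yields a non-converged fit object.
#'
#' @inheritParams fit_single_sigmoid
#' @return A `sigmoid_fit`.
#' @export
fit_double_sigmoid <- function(series, init = NULL) {
  stopifnot(inherits(series, "nsd_series"))
  id <- attr(series, "animal_id")
  t <- series$t
  y <- series$nsd
  delta0 <- max(y)
  if (!is.finite(delta0) || delta0 <= 0 || stats::sd(y) == 0) {
    return(failed_fit("double", id, "no NSD rise detected"))
  }
  up <- level_crossing(t, y, delta0 / 2, "up")
  down <- level_crossing(t, y, delta0 / 2, "down")
  if (is.null(up)) {
    return(failed_fit("double", id, "no spring limb detected"))
  }
  if (is.null(down) || down[1] <= up[1]) {
    return(failed_fit("double", id, "no autumn limb detected"))
  }
  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- init
  } else {
    starts[[1]] <- list(delta = delta0, theta_s = up[1], theta_a = down[1],
                        phi_s = phi_from_slope(delta0, up[2]),
                        phi_a = phi_from_slope(delta0, down[2]))
    for (p in c(0.05, 0.5, 5, 20)) {
      starts[[length(starts) + 1]] <-
        list(delta = delta0, theta_s = up[1], theta_a = down[1],
             phi_s = p, phi_a = p)
    }
  }
  lower <- c(delta = delta0 * 1e-6, theta_s = min(t) - 50, theta_a = min(t) - 50,
             phi_s = 1e-3, phi_a = 1e-3)
  upper <- c(delta = Inf, theta_s = max(t) + 50, theta_a = max(t) + 50,
             phi_s = 100, phi_a = 100)
  best <- NULL
  for (st in starts) {
    obj <- nlslm_try(
      nsd ~ delta / (1 + exp((theta_s - t) / phi_s)) -
        delta / (1 + exp((theta_a - t) / phi_a)),
      data = series, start = st, lower = lower, upper = upper)
    if (!is.null(obj) &&
        (is.null(best) || sum(stats::residuals(obj)^2) < sum(stats::residuals(best)^2))) {
      best <- obj
    }
    if (!is.null(best) &&
        sum(stats::residuals(best)^2) < (1e-8 * delta0)^2 * length(y)) break
  }
  if (is.null(best)) {
    return(failed_fit("double", id, "optimizer failed from all starts"))
  }
  fit <- make_fit(best, "double", id, range(t))
  co <- fit$coefficients
  if (co["theta_s"] >= co["theta_a"]) {
    fit$converged <- FALSE
    fit$message <- "midpoints out of order (theta_s >= theta_a)"
  }
  fit
}

#' Model-based migration metrics from a sigmoid fit
#'
#' Derives the movement surrogates used with the NSD phenology models:
#' `sqrt(delta)` (km) as a surrogate of migration distance, `2 phi` (days,
#' per season for double fits) as a surrogate of migration duration, and the
#' analytic quantile-crossing times `t(q) = theta + phi * log(q / (1 - q))`
#' of each logistic limb. The quartile span `t(0.75) - t(0.25)` equals
#' `2 phi log(3)`, slightly larger than `2 phi`; both are reported.
#'
#' @param fit A converged `sigmoid_fit`.
#' @return A list with `sqrt_delta_km`, per-season `two_phi` and
#'   `quartile_span`, and a `quantile_time(q, season)` function.
#' @export
derive_migration_metrics <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  co <- fit$coefficients
  if (fit$kind == "single") {
    theta <- c(spring = unname(co["theta"]))
    phi <- c(spring = unname(co["phi"]))
  } else {
    theta <- c(spring = unname(co["theta_s"]), autumn = unname(co["theta_a"]))
    phi <- c(spring = unname(co["phi_s"]), autumn = unname(co["phi_a"]))
  }
  quantile_time <- function(q, season = "spring") {
    stopifnot(q > 0, q < 1, season %in% names(theta))
    theta[[season]] + phi[[season]] * log(q / (1 - q))
  }
  list(sqrt_delta_km = sqrt(unname(co["delta"])),
       two_phi = 2 * phi,
       quartile_span = 2 * phi * log(3),
       quantile_time = quantile_time)
}

#' Migration timing from a fitted NSD model
#'
#' Replaces interactive inspection of NSD plots with a deterministic analytic
#' rule: spring departure/arrival are the times at which the fitted spring
#' limb crosses `frac * delta` and `(1 - frac) * delta`; the autumn limb is
#' treated symmetrically (departure when the plateau starts to drop below
#' `(1 - frac) * delta`, arrival when the curve falls to `frac * delta`).
#' For a logistic limb these crossings are
#' `theta + phi * log(frac / (1 - frac))` and its mirror image. Crossings
#' outside the observed time span are flagged as censored.
#'
#' @param series The fitted [nsd_series()] (used only for its time span).
#' @param fit A converged `sigmoid_fit`.
#' @param frac Threshold fraction of the asymptote, in (0, 0.5); default 0.025.
#' @return A `migration_timing` list with departure/arrival days, durations
#'   and censoring flags.
#' @export
segment_timing <- function(series, fit, frac = 0.025) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (frac <= 0 || frac >= 0.5) stop("frac must be in (0, 0.5)", call. = FALSE)
  co <- fit$coefficients
  span <- range(series$t)
  lo <- log(frac / (1 - frac))       # negative
  out <- list(frac = frac)
  if (fit$kind == "single") {
    th <- co["theta"]; ph <- co["phi"]
    out$spring_departure <- unname(th + ph * lo)
    out$spring_arrival <- unname(th - ph * lo)
  } else {
    out$spring_departure <- unname(co["theta_s"] + co["phi_s"] * lo)
    out$spring_arrival <- unname(co["theta_s"] - co["phi_s"] * lo)
    out$autumn_departure <- unname(co["theta_a"] + co["phi_a"] * lo)
    out$autumn_arrival <- unname(co["theta_a"] - co["phi_a"] * lo)
    out$autumn_duration <- out$autumn_arrival - out$autumn_departure
  }
  out$spring_duration <- out$spring_arrival - out$spring_departure
  events <- unlist(out[grep("departure|arrival", names(out))])
  out$censored <- names(events)[events < span[1] | events > span[2]]
  structure(out, class = "migration_timing")
}

#' @export
print.migration_timing <- function(x, ...) {
  cat("<migration_timing>\n")
  for (nm in grep("departure|arrival|duration", names(x), value = TRUE)) {
    cat(sprintf("  %-17s %8.2f\n", nm, x[[nm]]))
  }
  if (length(x$censored)) {
    cat("  censored:", paste(x$censored, collapse = ", "), "\n")
  }
  invisible(x)
}
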