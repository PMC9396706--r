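#' Parameters of the continuous-time correlated random walk
#'
#' The movement model is an integrated Ornstein-Uhlenbeck process per planar
#' axis: velocity v satisfies `dv = -beta_vel * v dt + sigma_vel dW` and
#' position integrates v. `beta_vel` (1/hour) controls how fast velocity
#' decorrelates; `sigma_vel` (km h^-3/2) scales the velocity diffusion;
#' `meas_sd` maps Argos location classes to measurement SDs (km).
#'
#' @param beta_vel Velocity autocorrelation rate (1/hour), > 0.
#' @param sigma_vel Velocity process scale, >= 0.
#' @param meas_sd Named numeric vector of per-class measurement SDs (km), or
#'   a single unnamed value applied to all fixes.
#' @return A `crw_params` list.
#' @export
crw_params <- function(beta_vel, sigma_vel,
                       meas_sd = c(LC3 = 0.25, LC2 = 0.5, LC1 = 1.5, LC0 = 5)) {
  if (beta_vel <= 0) stop("beta_vel must be positive", call. = FALSE)
  if (sigma_vel < 0 || any(meas_sd < 0)) {
    stop("sigma_vel and measurement SDs must be non-negative", call. = FALSE)
  }
  structure(list(beta_vel = beta_vel, sigma_vel = sigma_vel,
                 meas_sd = meas_sd), class = "crw_params")
}

## Exact discrete transition and process-noise matrices of the integrated OU
## over a gap dt (hours). State is (position, velocity).
iou_matrices <- function(beta, sigsq, dt) {
  b <- beta * dt
  e1 <- exp(-b)
  e2 <- exp(-2 * b)
  if (b > 1e-4) {
    t12 <- (1 - e1) / beta
    qvv <- sigsq * (1 - e2) / (2 * beta)
    qxv <- sigsq * (1 - e1)^2 / (2 * beta^2)
    # the bracket is O((beta*dt)^3); for small b it cancels catastrophically,
    # hence the Taylor branch below
    qxx <- sigsq / beta^2 * (dt - 2 * (1 - e1) / beta + (1 - e2) / (2 * beta))
  } else {
    t12 <- dt * (1 - b / 2 + b^2 / 6)
    qvv <- sigsq * dt * (1 - b + 2 * b^2 / 3)
    qxv <- sigsq * dt^2 / 2 * (1 - b + 7 * b^2 / 12)
    qxx <- sigsq * dt^3 * (1 / 3 - b / 4 + 7 * b^2 / 60)
  }
  Tm <- matrix(c(1, 0, t12, e1), 2, 2)
  Qm <- matrix(c(qxx, qxv, qxv, qvv), 2, 2)
  list(T = Tm, Q = Qm)
}

## Per-fix measurement SDs for a track under given parameters.
meas_sd_for <- function(traj, params) {
  ms <- params$meas_sd
  if (is.null(traj$lc_class) || is.null(names(ms))) {
    if (length(ms) == 1L) {
      return(rep(unname(ms), nrow(traj)))
    }
    stop("track has no location classes; supply a single meas_sd", call. = FALSE)
  }
  missing_cls <- setdiff(unique(traj$lc_class), names(ms))
  if (length(missing_cls)) {
    stop("no measurement SD configured for class ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  unname(ms[traj$lc_class])
}

## Kalman filter for one axis. z may contain NA (no observation at that time).
## Returns the log-likelihood, per-observation contributions and the filtered
## and one-step-predicted moments needed by the RTS smoother.
kalman_axis <- function(z, t_h, meas_var, beta, sigsq, p0 = 1e4, m0 = NULL) {
  n <- length(z)
  if (is.null(m0)) m0 <- c(z[which(!is.na(z))[1]], 0)
  mp <- matrix(NA_real_, 2, n); Pp <- array(NA_real_, c(2, 2, n))
  mf <- matrix(NA_real_, 2, n); Pf <- array(NA_real_, c(2, 2, n))
  Ts <- vector("list", n)
  ll <- rep(NA_real_, n)
  m <- m0
  P <- diag(c(p0, p0))
  for (i in seq_len(n)) {
    if (i > 1) {
      mats <- iou_matrices(beta, sigsq, t_h[i] - t_h[i - 1])
      Ts[[i]] <- mats$T
      m <- mats$T %*% m
      P <- mats$T %*% P %*% t(mats$T) + mats$Q
    }
    mp[, i] <- m
    Pp[, , i] <- P
    if (!is.na(z[i])) {
      S <- P[1, 1] + meas_var[i]
      innov <- z[i] - m[1]
      ll[i] <- -0.5 * (log(2 * pi * S) + innov^2 / S)
      K <- P[, 1] / S
      m <- m + K * innov
      P <- P - outer(K, P[1, ])
      P <- (P + t(P)) / 2
    }
    mf[, i] <- m
    Pf[, , i] <- P
  }
  list(loglik = sum(ll, na.rm = TRUE), by_obs = ll,
       mp = mp, Pp = Pp, mf = mf, Pf = Pf, Ts = Ts)
}

## Rauch-Tung-Striebel fixed-interval smoother for one filtered axis.
rts_axis <- function(kf) {
  n <- ncol(kf$mf)
  ms <- kf$mf
  Ps <- kf$Pf
  for (k in seq(n - 1, 1)) {
    Tk <- kf$Ts[[k + 1]]
    C <- kf$Pf[, , k] %*% t(Tk) %*% solve(kf$Pp[, , k + 1])
    ms[, k] <- kf$mf[, k] + C %*% (ms[, k + 1] - kf$mp[, k + 1])
    Ps[, , k] <- kf$Pf[, , k] +
      C %*% (Ps[, , k + 1] - kf$Pp[, , k + 1]) %*% t(C)
  }
  list(ms = ms, Ps = Ps)
}

#' Log-likelihood of a track under the CRW model
#'
#' Exact Gaussian prediction-error log-likelihood from the Kalman recursion,
#' treating the two planar axes (azimuthal-equidistant projection at the
#' first fix) as independent position/velocity linear-Gaussian systems with
#' exact discrete transition over each time gap. The state is initialised at
#' the first fix with zero velocity and diffuse variance (10^4 km^2).
#'
#' @param traj A `cm_track` with strictly increasing timestamps.
#' @param params A [crw_params()].
#' @return The log-likelihood (scalar), with attribute `"by_fix"` holding the
#'   per-fix contributions (both axes combined).
#' @export
crw_loglik <- function(traj, params) {
  stopifnot(inherits(traj, "cm_track"), inherits(params, "crw_params"))
  xy <- project_to_plane(traj$lon, traj$lat, c(traj$lon[1], traj$lat[1]))
  t_h <- as.numeric(difftime(traj$time, traj$time[1], units = "hours"))
  mv <- meas_sd_for(traj, params)^2
  sigsq <- params$sigma_vel^2
  kx <- kalman_axis(xy$x_km, t_h, mv, params$beta_vel, sigsq)
  ky <- kalman_axis(xy$y_km, t_h, mv, params$beta_vel, sigsq)
  structure(kx$loglik + ky$loglik, by_fix = kx$by_obs + ky$by_obs)
}

#' Fit the CRW model to a track by maximum likelihood
#'
#' Maximises [crw_loglik()] over `log(beta_vel)` and `log(sigma_vel)` by
#' quasi-Newton (BFGS) optimisation; the per-class measurement SDs are held
#' fixed at their configured values (standard Argos accuracy tiers by
#' default), which keeps the velocity process identifiable. On
#' non-convergence the best parameters found are returned with the flag set.
#'
#' @param traj A `cm_track` with at least 10 fixes.
#' @param init A [crw_params()] giving starting values (and the fixed
#'   measurement SDs). By default `beta_vel` starts at 0.5/h and `sigma_vel`
#'   at a moment-based guess from the observed step speeds.
#' @return A `crw_fit` with elements `params`, `log_likelihood`, `converged`
#'   and `predicted` (smoothed positions at the original fix times).
#' @export
fit_crw <- function(traj, init = NULL) {
  stopifnot(inherits(traj, "cm_track"))
  if (nrow(traj) < 10) stop("need at least 10 fixes to fit", call. = FALSE)
  if (is.null(init)) {
    dt_h <- diff(as.numeric(traj$time)) / 3600
    step <- step_lengths_km(traj$lon, traj$lat)
    v_med <- stats::median(step / dt_h)
    beta0 <- 0.5
    # stationary velocity SD is sigma/sqrt(2 beta); match it to median speed
    init <- crw_params(beta0, max(v_med, 0.1) * sqrt(2 * beta0))
  }
  negll <- function(par) {
    b <- exp(par[1]); s <- exp(par[2])
    if (!is.finite(b) || b <= 0 || !is.finite(s)) {
      return(1e12)
    }
    p <- crw_params(b, s, meas_sd = init$meas_sd)
    v <- -as.numeric(crw_loglik(traj, p))
    if (!is.finite(v)) 1e12 else v
  }
  opt <- stats::optim(c(log(init$beta_vel), log(init$sigma_vel)), negll,
                      method = "L-BFGS-B",
                      lower = log(c(1e-5, 1e-5)), upper = log(c(1e3, 1e4)),
                      # factr * eps ~ 1e-8 relative change in the log-likelihood
                      control = list(factr = 4.5e7, maxit = 500))
  params <- crw_params(exp(opt$par[1]), exp(opt$par[2]), meas_sd = init$meas_sd)
  fit <- structure(list(params = params,
                        log_likelihood = -opt$value,
                        converged = opt$convergence == 0,
                        init = init),
                   class = "crw_fit")
  fit$predicted <- smooth_positions(traj, fit)
  fit
}

#' @export
print.crw_fit <- function(x, ...) {
  cat(sprintf("<crw_fit> logLik %.3f, converged: %s\n", x$log_likelihood,
              x$converged))
  cat(sprintf("  beta_vel %.4g /h, sigma_vel %.4g\n",
              x$params$beta_vel, x$params$sigma_vel))
  invisible(x)
}

#' Smoothed positions from a fitted CRW model
#'
#' Runs the Kalman filter and Rauch-Tung-Striebel fixed-interval smoother
#' under `fit$params` and returns position means and variances at the
#' requested times (the original fix times by default). Requested times
#' outside the observed span are extrapolated with a warning; their variance
#' grows with distance from the data.
#'
#' @param traj The observed `cm_track`.
#' @param fit A `crw_fit` (or any list with a `params` element); a
#'   non-converged fit is used with a warning.
#' @param times Optional `POSIXct` vector of prediction times.
#' @return A data.frame with `time`, `pred_x_km`, `pred_y_km`,
#'   `pred_var_km2` (summed axis variances), and back-projected `lon`, `lat`.
#' @export
smooth_positions <- function(traj, fit, times = NULL) {
  stopifnot(inherits(traj, "cm_track"))
  params <- fit$params
  if (isFALSE(fit$converged)) {
    warning("CRW fit did not converge; smoothing with best-found parameters")
  }
  if (is.null(times)) times <- traj$time
  if (min(times) < min(traj$time) || max(times) > max(traj$time)) {
    warning("prediction times outside the track span: extrapolating")
  }
  origin <- c(traj$lon[1], traj$lat[1])
  xy <- project_to_plane(traj$lon, traj$lat, origin)

  ## augment the observation grid with the requested times (as missing obs)
  all_t <- sort(unique(c(as.numeric(traj$time), as.numeric(times))))
  idx_obs <- match(as.numeric(traj$time), all_t)
  zx <- rep(NA_real_, length(all_t)); zy <- zx; mv <- zx
  zx[idx_obs] <- xy$x_km
  zy[idx_obs] <- xy$y_km
  mv[idx_obs] <- meas_sd_for(traj, params)^2
  t_h <- (all_t - all_t[1]) / 3600
  sigsq <- params$sigma_vel^2

  sx <- rts_axis(kalman_axis(zx, t_h, mv, params$beta_vel, sigsq))
  sy <- rts_axis(kalman_axis(zy, t_h, mv, params$beta_vel, sigsq))
  keep <- match(as.numeric(times), all_t)
  ll <- plane_to_lonlat(sx$ms[1, keep], sy$ms[1, keep], origin)
  data.frame(time = as.POSIXct(all_t[keep], origin = "1970-01-01", tz = "UTC"),
             pred_x_km = sx$ms[1, keep],
             pred_y_km = sy$ms[1, keep],
             pred_var_km2 = sx$Ps[1, 1, keep] + sy$Ps[1, 1, keep],
             lon = ll$lon, lat = ll$lat)
}
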