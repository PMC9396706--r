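## Independent oracle: the joint Gaussian distribution of the observed
## positions implied by the integrated-OU state-space model, assembled from
## numerically integrated transition/process-noise matrices (matrix
## exponential + Simpson quadrature) rather than the package's closed forms
## or Kalman recursion.
joint_gaussian_loglik <- function(track, params) {
  xy <- project_to_plane(track$lon, track$lat, c(track$lon[1], track$lat[1]))
  t_h <- as.numeric(difftime(track$time, track$time[1], units = "hours"))
  r2 <- migrniche:::meas_sd_for(track, params)^2
  n <- length(t_h)
  A <- matrix(c(0, 0, 1, -params$beta_vel), 2, 2)
  B <- matrix(c(0, 0, 0, params$sigma_vel^2), 2, 2)
  phi_of <- function(d) pracma::expm(A * d)
  q_of <- function(d) {
    m <- 2000  # Simpson panels
    s <- seq(0, d, length.out = m + 1)
    w <- c(1, rep(c(4, 2), length.out = m - 1), 1) * (d / m) / 3
    out <- matrix(0, 2, 2)
    for (k in seq_along(s)) {
      P <- phi_of(d - s[k])
      out <- out + w[k] * P %*% B %*% t(P)
    }
    out
  }
  axis_ll <- function(z) {
    m0 <- c(z[1], 0)
    P0 <- diag(c(1e4, 1e4))
    V <- vector("list", n)    # marginal state covariances
    mu <- matrix(NA_real_, 2, n)
    V[[1]] <- P0
    mu[, 1] <- m0
    phis <- vector("list", n)
    for (i in 2:n) {
      d <- t_h[i] - t_h[i - 1]
      phis[[i]] <- phi_of(d)
      V[[i]] <- phis[[i]] %*% V[[i - 1]] %*% t(phis[[i]]) + q_of(d)
      mu[, i] <- phis[[i]] %*% mu[, i - 1]
    }
    S <- matrix(0, n, n)
    for (i in 1:n) {
      S[i, i] <- V[[i]][1, 1] + r2[i]
      if (i < n) {
        acc <- diag(2)
        for (j in (i + 1):n) {
          acc <- phis[[j]] %*% acc
          cov_ij <- V[[i]] %*% t(acc)   # Cov(s_i, s_j)
          S[i, j] <- S[j, i] <- cov_ij[1, 1]
        }
      }
    }
    resid <- z - mu[1, ]
    ch <- chol(S)
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(backsolve(ch, resid, transpose = TRUE)^2))
  }
  axis_ll(xy$x_km) + axis_ll(xy$y_km)
}
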