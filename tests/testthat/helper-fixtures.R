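# shared fixture builders (everything generated in code; no stored data)

disk_mask <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  X <- matrix(seq_len(n), n, n)
  Y <- t(X)
  (X - center[1])^2 + (Y - center[2])^2 <= r^2
}

# detection parameters matched to the white-noise synthetic fixtures
# (small smoothing scale; see the methods vignette)
fx_params <- function(sigma = 3, radius = 100, ...) {
  detection_params(sigma = sigma, beta = 0.3, delta_beta = 0.08,
                   n_thresholds = 5, radius = radius, ...)
}

# simple two-level wound frame: cells bright, disk wound dark
wound_frame <- function(n = 128, r = 40, cell = 0.8, wound = 0.05,
                        center = c((n + 1) / 2, (n + 1) / 2)) {
  f <- matrix(cell, n, n)
  f[disk_mask(n, r, center)] <- wound
  f
}

# weight-space oracle for the GP posterior: the kernel C + (s2 + t t')^2 is
# phi(t)' diag(C + s2^2, 2 s2, 1) phi(t') with phi(t) = (1, t, t^2), so the
# posterior is Bayesian quadratic regression. Independent of the package's
# function-space (Cholesky) implementation.
gp_oracle_predict <- function(gp, times) {
  nm <- gp$norm
  ts <- (gp$times - nm$t0) / nm$t_range
  qs <- (times - nm$t0) / nm$t_range
  y <- (gp$values - nm$y_mean) / nm$y_scale
  nv <- gp$noise_var / nm$y_scale^2 + gp$.extra + gp$jitter
  C <- gp$theta[["C"]]; s2 <- gp$theta[["sigma_k2"]]
  A <- diag(c(C + s2^2, 2 * s2, 1))
  Phi <- cbind(1, ts, ts^2)
  Phiq <- cbind(1, qs, qs^2)
  Sninv <- diag(1 / nv)
  Sw <- solve(t(Phi) %*% Sninv %*% Phi + solve(A))
  wbar <- Sw %*% t(Phi) %*% Sninv %*% y
  mu <- drop(Phiq %*% wbar)
  s2post <- pmax(0, rowSums((Phiq %*% Sw) * Phiq))
  list(mean = mu * nm$y_scale + nm$y_mean,
       sd = sqrt(s2post) * nm$y_scale)
}
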