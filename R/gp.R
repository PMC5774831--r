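#' Evaluate the constant-plus-quadratic covariance kernel
#'
#' `k(t, t') = C + (sigma_k^2 + t t')^2`, the sum of a constant and a
#' homogeneous quadratic (polynomial degree-2) kernel. Its feature space is
#' spanned by `1, t, t^2`, so GP posteriors under this prior are Bayesian
#' quadratic curves — a good match for wound area under a constant-velocity
#' front (exactly quadratic in time for a disk) while still weighting data by
#' their detection uncertainty.
#'
#' @param t,tp input times (vectors allowed; outer combinations via
#'   `outer(t, tp, kernel_eval, C = ..., sigma_k = ...)`).
#' @param C constant kernel variance, >= 0.
#' @param sigma_k offset hyperparameter of the quadratic term.
#' @return covariance value(s).
#' @export
kernel_eval <- function(t, tp, C, sigma_k) {
  if (any(C < 0)) abort("`C` must be >= 0.")
  C + (sigma_k^2 + t * tp)^2
}

kmat <- function(ts, tps, C, s2) C + (s2 + outer(ts, tps))^2

#' Fit a Gaussian process to a measured series
#'
#' Fits a zero-mean GP with kernel `C + (sigma_k^2 + t t')^2` to a time series
#' with known per-point noise variances (the detection variances). Targets are
#' centered and scaled to unit standard deviation (making the zero prior mean
#' consistent) and times mapped to [0, 1]; noise variances are divided by the
#' squared target scale. Hyperparameters maximize the log marginal likelihood
#' `-1/2 y' K^-1 y - 1/2 log|K| - n/2 log(2 pi)` via multi-restart
#' Nelder-Mead over log-hyperparameters from a fixed deterministic design (no
#' randomness, so fits are exactly reproducible). A jitter starting at
#' `1e-8 * trace(K)/n` and escalating tenfold up to `1e-4 * trace(K)/n` keeps
#' the Cholesky factorization positive definite.
#'
#' @param times observation times (hours), >= 3 distinct values.
#' @param values observed series (area px^2 or perimeter px).
#' @param noise_var per-point noise variances (recycled); >= 0.
#' @param learn_noise if `TRUE`, an additional homoscedastic noise variance is
#'   learned as a third hyperparameter (off by default; the detection
#'   variances are normally the only noise model).
#' @param n_restarts number of optimizer starts from the fixed design.
#' @return an object of class `wound_gp`.
#' @export
gp_fit <- function(times, values, noise_var = 0, learn_noise = FALSE,
                   n_restarts = 10) {
  times <- as.numeric(times); values <- as.numeric(values)
  n <- length(times)
  if (n < 3) abort("need at least 3 measurements to fit a GP")
  if (length(values) != n) abort("`times` and `values` lengths differ")
  noise_var <- rep_len(as.numeric(noise_var), n)
  if (any(noise_var < 0)) abort("`noise_var` must be >= 0")
  t0 <- min(times); tr <- max(times) - t0
  if (tr <= 0) abort("all times are equal")
  ts <- (times - t0) / tr
  ym <- mean(values)
  ys <- sd(values)
  if (!is.finite(ys) || ys <= 0) ys <- 1
  y <- (values - ym) / ys
  nv <- noise_var / ys^2

  nll <- function(theta) {
    C <- exp(theta[1]); s2 <- exp(theta[2])
    extra <- if (learn_noise) exp(theta[3]) else 0
    K <- kmat(ts, ts, C, s2)
    ch <- chol_jitter(K + diag(nv + extra, n))
    if (is.null(ch)) return(1e10)
    a <- backsolve(ch$L, forwardsolve(t(ch$L), y), upper.tri = TRUE)
    0.5 * sum(y * a) + sum(log(diag(ch$L))) + n / 2 * log(2 * pi)
  }

  starts <- gp_start_design(learn_noise)
  starts <- starts[seq_len(min(n_restarts, nrow(starts))), , drop = FALSE]
  fits <- apply(starts, 1, function(th0) {
    opt <- optim(th0, nll, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    list(par = opt$par, value = opt$value, init = nll(th0))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  C <- exp(best$par[1]); s2 <- exp(best$par[2])
  extra <- if (learn_noise) exp(best$par[3]) else 0

  K <- kmat(ts, ts, C, s2)
  ch <- chol_jitter(K + diag(nv + extra, n))
  if (is.null(ch)) abort("kernel matrix not positive definite even after jitter escalation")
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), y), upper.tri = TRUE)

  structure(
    list(times = times, values = values, noise_var = noise_var,
         theta = c(C = unname(C), sigma_k2 = unname(s2)),
         learned_noise = if (learn_noise) extra * ys^2 else NA_real_,
         log_marginal_likelihood = -best$value,
         norm = list(t0 = t0, t_range = tr, y_mean = ym, y_scale = ys),
         jitter = ch$jitter,
         restarts = tibble(
           restart = seq_along(fits),
           lml_init = -vapply(fits, `[[`, 0, "init"),
           lml_opt = -vapply(fits, `[[`, 0, "value")
         ),
         .ts = ts, .L = ch$L, .alpha = alpha, .extra = extra),
    class = "wound_gp"
  )
}

# fixed quasi-random design over log-hyperparameter space (deterministic)
gp_start_design <- function(learn_noise) {
  g <- as.matrix(expand.grid(logC = c(-6, -2, 0, 2),
                             logs2 = c(-3, -1, 0.5, 2)))
  # interleave corners and center-out ordering so small n_restarts still spans
  ord <- c(6, 11, 1, 16, 4, 13, 7, 10, 2, 15, 3, 14, 5, 12, 8, 9)
  g <- g[ord, , drop = FALSE]
  if (learn_noise) g <- cbind(g, lognoise = rep(c(-6, -3), length.out = nrow(g)))
  g
}

chol_jitter <- function(A) {
  n <- nrow(A)
  base <- sum(diag(A)) / n
  for (j in c(0, base * 10^(-8:-4))) {
    L <- tryCatch(chol(A + diag(j, n)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  NULL
}

#' Posterior prediction from a fitted wound GP
#'
#' Standard GP posterior mean and standard deviation at arbitrary query times,
#' de-normalized to original units. Query times outside the training range are
#' allowed (imputation/extrapolation) and flagged.
#'
#' @param object a [gp_fit()] result.
#' @param times query times in hours; default a 101-point grid over the
#'   training range.
#' @param ... unused.
#' @return tibble: `time`, `.pred`, `.pred_sd`, `extrapolated`.
#' @export
predict.wound_gp <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    times <- seq(min(object$times), max(object$times), length.out = 101)
  }
  nm <- object$norm
  qs <- (times - nm$t0) / nm$t_range
  C <- object$theta[["C"]]; s2 <- object$theta[["sigma_k2"]]
  Ks <- kmat(qs, object$.ts, C, s2)
  mu <- drop(Ks %*% object$.alpha)
  V <- forwardsolve(t(object$.L), t(Ks))
  kss <- C + (s2 + qs^2)^2
  s2post <- pmax(0, kss - colSums(V^2))
  tibble(
    time = times,
    .pred = mu * nm$y_scale + nm$y_mean,
    .pred_sd = sqrt(s2post) * nm$y_scale,
    extrapolated = times < min(object$times) - 1e-9 | times > max(object$times) + 1e-9
  )
}

#' @export
print.wound_gp <- function(x, ...) {
  cat(sprintf("<wound_gp> n = %d, C = %.4g, sigma_k^2 = %.4g, logLik = %.3f\n",
              length(x$times), x$theta[["C"]], x$theta[["sigma_k2"]],
              x$log_marginal_likelihood))
  invisible(x)
}

#' @rdname gp_fit
#' @param x a `wound_gp` object.
#' @method tidy wound_gp
#' @export
tidy.wound_gp <- function(x, ...) {
  tibble(term = c("C", "sigma_k2"),
         estimate = c(x$theta[["C"]], x$theta[["sigma_k2"]]))
}

#' @rdname gp_fit
#' @method glance wound_gp
#' @export
glance.wound_gp <- function(x, ...) {
  tibble(logLik = x$log_marginal_likelihood, nobs = length(x$times),
         jitter = x$jitter,
         y_scale = x$norm$y_scale)
}

#' Serialize a fitted GP to JSON (provenance record)
#' @param x a `wound_gp`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
gp_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "wound_gp"))
  obj <- list(
    kernel = "C + (sigma_k^2 + t*t')^2",
    hyperparameters = as.list(x$theta),
    learned_noise = x$learned_noise,
    log_marginal_likelihood = x$log_marginal_likelihood,
    normalization = x$norm,
    jitter = x$jitter,
    n = length(x$times),
    times = x$times, values = x$values, noise_var = x$noise_var
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
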