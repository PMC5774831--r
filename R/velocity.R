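#' Concerted cell velocity profile from the two fitted GPs
#'
#' Evaluates both GP posteriors on a uniform time grid and derives the
#' concerted cell velocity
#' `v(t) = -(d/dt A_hat(t)) / P_hat(t)`,
#' the rate of area closure normalized by the wound perimeter — the front
#' speed itself, independent of wound geometry for a front advancing at
#' constant normal speed. The area derivative uses the second-order central
#' difference on the grid, so the velocity is defined on interior grid points
#' only. Standard errors follow first-order (independent) error propagation:
#' `sd(Adot) = sqrt(sd_A(t+h)^2 + sd_A(t-h)^2) / (2h)` and
#' `sd_v^2 = (sd(Adot)/P)^2 + (Adot * sd_P / P^2)^2`.
#' GP cross-covariances between `t-h` and `t+h` are neglected, which is
#' conservative for a smooth posterior.
#'
#' @param gp_area,gp_perim [gp_fit()] results for area and perimeter.
#' @param times optional explicit uniform grid; default `n_grid` points over
#'   the common training range.
#' @param n_grid grid size (default 101, denser than any measurement series).
#' @param pixel_scale um/px; when not 1, columns in physical units
#'   (`velocity_um_h` etc.) are appended.
#' @return tibble of class `velocity_profile`: `time`, `area`, `area_sd`,
#'   `perim`, `perim_sd`, `velocity`, `velocity_sd` (px units; `NA` velocity
#'   at the two grid endpoints).
#' @export
velocity_profile <- function(gp_area, gp_perim, times = NULL, n_grid = 101,
                             pixel_scale = 1) {
  stopifnot(inherits(gp_area, "wound_gp"), inherits(gp_perim, "wound_gp"))
  if (is.null(times)) {
    lo <- max(min(gp_area$times), min(gp_perim$times))
    hi <- min(max(gp_area$times), max(gp_perim$times))
    if (hi <= lo) abort("area and perimeter fits have no overlapping time range")
    times <- seq(lo, hi, length.out = n_grid)
  }
  times <- sort(as.numeric(times))
  if (length(times) < 3) abort("need at least 3 grid points for central differences")
  h <- diff(times)
  if (max(h) - min(h) > 1e-8 * max(h)) abort("`times` must be a uniform grid")
  h <- mean(h)
  pa <- predict(gp_area, times)
  pp <- predict(gp_perim, times)
  if (any(pp$.pred <= 0)) {
    abort("predicted perimeter is non-positive on the grid; wound closed or fit invalid there")
  }
  n <- length(times)
  i <- 2:(n - 1)
  adot <- rep(NA_real_, n)
  adot_sd <- rep(NA_real_, n)
  adot[i] <- (pa$.pred[i + 1] - pa$.pred[i - 1]) / (2 * h)
  adot_sd[i] <- sqrt(pa$.pred_sd[i + 1]^2 + pa$.pred_sd[i - 1]^2) / (2 * h)
  v <- -adot / pp$.pred
  v_sd <- sqrt((adot_sd / pp$.pred)^2 + (adot * pp$.pred_sd / pp$.pred^2)^2)
  out <- tibble(
    time = times,
    area = pa$.pred, area_sd = pa$.pred_sd,
    perim = pp$.pred, perim_sd = pp$.pred_sd,
    velocity = v, velocity_sd = v_sd
  )
  if (pixel_scale != 1) {
    out$velocity_um_h <- out$velocity * pixel_scale
    out$velocity_um_h_sd <- out$velocity_sd * pixel_scale
  }
  attr(out, "pixel_scale") <- pixel_scale
  class(out) <- c("velocity_profile", class(out))
  out
}

#' Precision-weighted mean velocity of a profile
#'
#' Summarizes a velocity profile as the mean over interior grid points
#' weighted by the velocity precision `1 / sd_v^2`, with reported standard
#' error `(sum of weights)^(-1/2)`. To keep a single (near-)noise-free point
#' from dominating, weights are capped at `cap_factor` times the median
#' finite weight.
#'
#' @param profile a [velocity_profile()] tibble.
#' @param cap_factor weight cap as a multiple of the median weight.
#' @return one-row tibble: `estimate`, `std_error`, `n`.
#' @export
weighted_mean_velocity <- function(profile, cap_factor = 1e6) {
  ok <- is.finite(profile$velocity) & is.finite(profile$velocity_sd)
  v <- profile$velocity[ok]
  s <- profile$velocity_sd[ok]
  if (!length(v)) abort("no interior grid points with finite velocity")
  w <- 1 / s^2
  finite_w <- w[is.finite(w) & w > 0]
  if (!length(finite_w)) abort("all velocity standard deviations are zero or infinite")
  cap <- cap_factor * median(finite_w)
  w <- pmin(w, cap)
  tibble(estimate = sum(w * v) / sum(w),
         std_error = 1 / sqrt(sum(w)),
         n = length(v))
}

#' Ordinary least-squares slope of the area series
#'
#' The conventional wound-healing readout: the slope of a linear regression
#' of measured wound area on time, using retained (pre-closure) measurements.
#' Unlike the concerted velocity this readout is confounded by wound geometry:
#' equal front speeds on wounds of different perimeter give different slopes.
#'
#' @param data data frame of measurements.
#' @param time,area column names (tidy-eval) holding times (h) and areas
#'   (px^2).
#' @return one-row tibble: `estimate` (px^2/h), `std_error`, `n`.
#' @export
area_slope <- function(data, time = time, area = area) {
  t <- dplyr::pull(data, {{ time }})
  a <- dplyr::pull(data, {{ area }})
  if (length(t) < 2) abort("need at least 2 measurements for a slope")
  if (max(t) - min(t) <= 0) abort("all times are equal; slope undefined")
  fit <- lm(a ~ t)
  # summary() warns on exact fits; the zero standard error is still correct
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble(estimate = sm["t", "Estimate"],
         std_error = sm["t", "Std. Error"],
         n = length(t))
}

#' Per-condition summary and signal-to-noise ratio against a baseline
#'
#' Computes group mean and standard deviation of each metric per condition,
#' and the assay signal-to-noise ratio of every non-baseline condition:
#' `SNR = (mu_condition - mu_baseline) / sd_baseline`.
#' A baseline with zero spread leaves the SNR undefined (`NA`).
#'
#' @param data data frame with one row per replicate.
#' @param condition column (tidy-eval) with condition labels.
#' @param value column with the per-replicate metric value.
#' @param baseline label of the baseline condition (e.g. the non-migrating
#'   control).
#' @param metric optional column distinguishing several metrics (summaries
#'   and SNRs are computed per metric).
#' @return tibble: `condition` (and `metric` if given), `n`, `mean`, `sd`,
#'   `snr` (`NA` for the baseline itself).
#' @export
condition_snr <- function(data, condition, value, baseline, metric = NULL) {
  cond_q <- rlang::enquo(condition)
  val_q <- rlang::enquo(value)
  met_q <- rlang::enquo(metric)
  groups <- if (rlang::quo_is_null(met_q)) dplyr::group_by(data, !!cond_q)
            else dplyr::group_by(data, !!met_q, !!cond_q)
  sums <- dplyr::summarise(groups,
                           n = dplyr::n(),
                           mean = mean(!!val_q),
                           sd = sd(!!val_q),
                           .groups = "drop_last")
  cond_col <- rlang::as_name(cond_q)
  if (!baseline %in% sums[[cond_col]]) {
    abort(sprintf("baseline condition '%s' not present", baseline))
  }
  out <- dplyr::mutate(sums,
    snr = {
      b <- .data[[cond_col]] == baseline
      mu_b <- mean[b][1]
      sd_b <- sd[b][1]
      if (!is.finite(sd_b) || sd_b <= 0) {
        warn(sprintf("baseline '%s' has zero/undefined spread; SNR undefined", baseline))
        rep(NA_real_, dplyr::n())
      } else {
        ifelse(b, NA_real_, (mean - mu_b) / sd_b)
      }
    }
  )
  dplyr::ungroup(out)
}
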