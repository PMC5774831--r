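#' Analyze one wound-healing sequence end to end
#'
#' Runs the complete pipeline on a sequence: per-frame detection with
#' threshold-replicate uncertainty, closure filtering, one GP fit each for
#' area and perimeter (heteroscedastic noise from the detection variances), a
#' dense velocity profile with propagated uncertainty, and the two summary
#' readouts (precision-weighted mean velocity; OLS area slope).
#'
#' @param x a [frame_sequence()].
#' @param params a [detection_params()].
#' @param preprocess `"none"` or `"scharr"` (see [measure_sequence()]).
#' @param n_grid velocity grid size.
#' @param learn_noise passed to [gp_fit()].
#' @return object of class `wound_analysis`: list with `measurements`
#'   (tibble incl. `retained`), `gp_area`, `gp_perim`, `profile`
#'   ([velocity_profile()]), `velocity` (weighted-mean tibble), `area_slope`
#'   (tibble), `params`, `config_hash`.
#' @export
analyze_sequence <- function(x, params = detection_params(),
                             preprocess = c("none", "scharr"),
                             n_grid = 101, learn_noise = FALSE) {
  preprocess <- match.arg(preprocess)
  meas <- measure_sequence(x, params, preprocess = preprocess)
  d <- dim(x$frames[[1]])
  meas <- filter_closure(meas, prod(d), params$closure_fraction)
  train <- dplyr::filter(meas, .data$retained)
  if (nrow(train) < 3) {
    abort(sprintf("only %d retained measurements; need >= 3 to fit the GPs", nrow(train)))
  }
  gp_a <- gp_fit(train$time, train$area, train$area_var, learn_noise = learn_noise)
  gp_p <- gp_fit(train$time, train$perim, train$perim_var, learn_noise = learn_noise)
  prof <- velocity_profile(gp_a, gp_p, n_grid = n_grid,
                           pixel_scale = x$pixel_scale)
  structure(
    list(measurements = meas,
         gp_area = gp_a, gp_perim = gp_p,
         profile = prof,
         velocity = weighted_mean_velocity(prof),
         area_slope = area_slope(train, time, area),
         params = params,
         config_hash = config_hash(params, preprocess, n_grid, learn_noise)),
    class = "wound_analysis"
  )
}

config_hash <- function(params, preprocess, n_grid, learn_noise) {
  rlang::hash(list(unclass(params), preprocess, n_grid, learn_noise))
}

#' @export
print.wound_analysis <- function(x, ...) {
  n <- nrow(x$measurements)
  cat(sprintf("<wound_analysis> %d frames (%d retained)\n",
              n, sum(x$measurements$retained)))
  cat(sprintf("  weighted mean velocity: %.4g +/- %.2g px/h\n",
              x$velocity$estimate, x$velocity$std_error))
  cat(sprintf("  area slope: %.4g px^2/h\n", x$area_slope$estimate))
  invisible(x)
}

#' @rdname analyze_sequence
#' @param x a `wound_analysis`.
#' @param ... unused.
#' @method tidy wound_analysis
#' @export
tidy.wound_analysis <- function(x, ...) {
  dplyr::select(x$measurements, -dplyr::any_of("contour"))
}

#' @rdname analyze_sequence
#' @method glance wound_analysis
#' @export
glance.wound_analysis <- function(x, ...) {
  tibble(
    velocity = x$velocity$estimate,
    velocity_se = x$velocity$std_error,
    area_slope = x$area_slope$estimate,
    area_slope_se = x$area_slope$std_error,
    n_frames = nrow(x$measurements),
    n_retained = sum(x$measurements$retained),
    logLik_area = x$gp_area$log_marginal_likelihood,
    logLik_perim = x$gp_perim$log_marginal_likelihood,
    config_hash = x$config_hash
  )
}

#' Analyze a multi-condition study
#'
#' Applies [analyze_sequence()] to every replicate of every condition,
#' aggregates per-condition group statistics for both readouts (weighted mean
#' velocity and area slope), and, when a baseline condition is named, the
#' signal-to-noise ratio of each other condition against it. Replicates that
#' fail (e.g. no wound detected) are reported and excluded, not fatal.
#'
#' @param sequences named list of conditions, each a list of
#'   [frame_sequence()] replicates; or a tibble with columns `condition` and
#'   `sequence` (list-column).
#' @param baseline optional baseline condition name for SNR.
#' @param params,preprocess,n_grid,learn_noise see [analyze_sequence()].
#' @return object of class `wound_study`: list with `replicates` (tibble:
#'   condition, replicate, velocity, area_slope, ...), `summary`
#'   (per-condition, per-metric stats incl. SNR), `failures` (tibble),
#'   `baseline`, `analyses` (list of `wound_analysis`).
#' @export
analyze_study <- function(sequences, baseline = NULL,
                          params = detection_params(),
                          preprocess = c("none", "scharr"),
                          n_grid = 101, learn_noise = FALSE) {
  preprocess <- match.arg(preprocess)
  if (is.data.frame(sequences)) {
    conds <- split(sequences$sequence, sequences$condition)
  } else {
    conds <- sequences
  }
  if (is.null(names(conds)) || any(names(conds) == "")) {
    abort("conditions must be named")
  }
  rows <- list(); fails <- list(); analyses <- list()
  for (cond in names(conds)) {
    reps <- conds[[cond]]
    for (j in seq_along(reps)) {
      res <- tryCatch(
        analyze_sequence(reps[[j]], params = params, preprocess = preprocess,
                         n_grid = n_grid, learn_noise = learn_noise),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        warn(sprintf("replicate %s/%d failed: %s", cond, j, conditionMessage(res)))
        fails[[length(fails) + 1L]] <- tibble(condition = cond, replicate = j,
                                              error = conditionMessage(res))
        next
      }
      analyses[[sprintf("%s_%d", cond, j)]] <- res
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(condition = cond, replicate = j), glance(res)
      )
    }
  }
  if (!length(rows)) abort("every replicate failed; nothing to summarize")
  reps <- dplyr::bind_rows(rows)
  long <- tidyr::pivot_longer(
    dplyr::select(reps, "condition", "replicate", "velocity", "area_slope"),
    c("velocity", "area_slope"), names_to = "metric", values_to = "value"
  )
  summary <- if (!is.null(baseline)) {
    condition_snr(long, condition, value, baseline = baseline, metric = metric)
  } else {
    dplyr::ungroup(dplyr::summarise(
      dplyr::group_by(long, .data$metric, .data$condition),
      n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
      .groups = "drop"
    ))
  }
  structure(
    list(replicates = reps, summary = summary,
         failures = if (length(fails)) dplyr::bind_rows(fails) else tibble(),
         baseline = baseline, analyses = analyses),
    class = "wound_study"
  )
}

#' @export
print.wound_study <- function(x, ...) {
  cat(sprintf("<wound_study> %d replicates, %d conditions%s\n",
              nrow(x$replicates), length(unique(x$replicates$condition)),
              if (nrow(x$failures)) sprintf(" (%d failed)", nrow(x$failures)) else ""))
  print(x$summary)
  invisible(x)
}

#' @rdname analyze_study
#' @param x a `wound_study`.
#' @param ... unused.
#' @method tidy wound_study
#' @export
tidy.wound_study <- function(x, ...) x$replicates

#' @rdname analyze_study
#' @method glance wound_study
#' @export
glance.wound_study <- function(x, ...) x$summary

#' Write analysis outputs as CSV files
#'
#' For a `wound_analysis`: `measurements.csv` (frame, time_h, area_px2,
#' area_var, perimeter_px, perimeter_var, closed, retained, cx, cy) and
#' `velocity_profile.csv` (t, area, area_std, perim, perim_std, v, v_std).
#' For a `wound_study`: `replicates.csv`, `summary.csv` and, when a baseline
#' was set, `snr_comparison.csv`. Every file carries the configuration hash
#' in a leading comment line for provenance.
#'
#' @param x a `wound_analysis` or `wound_study`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  put <- function(df, name, hash) {
    p <- file.path(dir, name)
    writeLines(sprintf("# config_hash: %s", hash), p)
    readr::write_csv(df, p, append = TRUE, col_names = TRUE)
    p
  }
  if (inherits(x, "wound_analysis")) {
    meas <- dplyr::select(
      dplyr::rename(tidy(x), time_h = "time", area_px2 = "area",
                    perimeter_px = "perim", perimeter_var = "perim_var"),
      "frame", "time_h", "area_px2", "area_var", "perimeter_px",
      "perimeter_var", "closed", "retained", "cx", "cy"
    )
    prof <- dplyr::select(
      dplyr::rename(tibble::as_tibble(x$profile), t = "time",
                    area_std = "area_sd", perim_std = "perim_sd",
                    v = "velocity", v_std = "velocity_sd"),
      "t", "area", "area_std", "perim", "perim_std", "v", "v_std"
    )
    paths <- c(put(meas, "measurements.csv", x$config_hash),
               put(prof, "velocity_profile.csv", x$config_hash))
  } else if (inherits(x, "wound_study")) {
    h <- if (nrow(x$replicates)) x$replicates$config_hash[1] else ""
    paths <- c(put(x$replicates, "replicates.csv", h),
               put(x$summary, "summary.csv", h))
    if (!is.null(x$baseline) && "snr" %in% names(x$summary)) {
      snr <- dplyr::filter(
        dplyr::select(x$summary, dplyr::any_of(c("metric", "condition", "snr"))),
        !is.na(.data$snr)
      )
      paths <- c(paths, put(snr, "snr_comparison.csv", h))
    }
  } else {
    abort("`x` must be a wound_analysis or wound_study")
  }
  invisible(paths)
}
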