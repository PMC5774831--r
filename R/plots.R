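#' Plot a velocity profile
#'
#' Predicted velocity over time with a one-standard-deviation ribbon. The
#' hallmark of a constant-speed front is a flat profile.
#'
#' @param object a [velocity_profile()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot velocity_profile
#' @export
autoplot.velocity_profile <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), is.finite(.data$velocity))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$velocity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$velocity - .data$velocity_sd,
                                      ymax = .data$velocity + .data$velocity_sd),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (h)", y = "concerted cell velocity (px/h)") +
    ggplot2::theme_minimal()
}

#' Plot a full single-sequence analysis
#'
#' Three stacked panels against time: measured wound area and perimeter
#' (points, error bars of one detection standard deviation) over the GP
#' posterior (line and ribbon), and the derived velocity profile. Excluded
#' (post-closure) measurements are hollow.
#'
#' @param object a [analyze_sequence()] result.
#' @param ... unused.
#' @return a ggplot (facetted).
#' @method autoplot wound_analysis
#' @export
autoplot.wound_analysis <- function(object, ...) {
  meas <- tidy(object)
  prof <- tibble::as_tibble(object$profile)
  md <- dplyr::bind_rows(
    tibble(panel = "area (px^2)", time = meas$time, value = meas$area,
           sd = sqrt(meas$area_var), retained = meas$retained),
    tibble(panel = "perimeter (px)", time = meas$time, value = meas$perim,
           sd = sqrt(meas$perim_var), retained = meas$retained)
  )
  pd <- dplyr::bind_rows(
    tibble(panel = "area (px^2)", time = prof$time, value = prof$area,
           sd = prof$area_sd),
    tibble(panel = "perimeter (px)", time = prof$time, value = prof$perim,
           sd = prof$perim_sd),
    tibble(panel = "velocity (px/h)", time = prof$time, value = prof$velocity,
           sd = prof$velocity_sd)
  )
  pd <- dplyr::filter(pd, is.finite(.data$value))
  lv <- c("area (px^2)", "perimeter (px)", "velocity (px/h)")
  md$panel <- factor(md$panel, lv); pd$panel <- factor(pd$panel, lv)
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sd,
                                      ymax = .data$value + .data$sd),
                         alpha = 0.2, fill = "firebrick") +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_errorbar(data = md,
                           ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0, color = "steelblue") +
    ggplot2::geom_point(data = md,
                        ggplot2::aes(shape = .data$retained), color = "steelblue") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-condition study summaries
#'
#' Group mean with one-standard-deviation error bars for each readout
#' (velocity, area slope), one panel per metric; replicate values overlaid.
#'
#' @param object a [analyze_study()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot wound_study
#' @export
autoplot.wound_study <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$replicates, "condition", "velocity", "area_slope"),
    c("velocity", "area_slope"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_jitter(data = long, ggplot2::aes(y = .data$value),
                         width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay the detected wound contour on a frame
#'
#' @param x a [frame_sequence()].
#' @param analysis the corresponding [analyze_sequence()] result.
#' @param frame frame index to show.
#' @return a ggplot with the grayscale frame and the traced contour.
#' @export
plot_wound_overlay <- function(x, analysis, frame = 1) {
  f <- x$frames[[frame]]
  img <- tibble(
    row = as.vector(row(f)), col = as.vector(col(f)), intensity = as.vector(f)
  )
  ctr <- analysis$measurements$contour[[frame]]
  p <- ggplot2::ggplot(img, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(ctr) && !ctr$empty) {
    cd <- tibble(row = ctr$vertices[, 1], col = ctr$vertices[, 2])
    p <- p + ggplot2::geom_path(data = cd, color = "deepskyblue", linewidth = 0.6)
  }
  p
}
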