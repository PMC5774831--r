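#' Detection parameters
#'
#' Bundles the tunable parameters of wound detection. The defaults are the
#' settings used for 10x fluorescent high-content-screening images at
#' 1.3 um/px (`sigma = 18`, `beta = 0.3 +/- 0.08`, `radius = 100`); `sigma`
#' should be matched to the noise correlation length of the images at hand
#' (white-noise synthetic fixtures need only a few px).
#'
#' @param sigma Gaussian smoothing standard deviation in px (> 0).
#' @param beta relative threshold in (0, 1); the absolute threshold is
#'   `beta * I_c` with `I_c` the confluency intensity of the frame.
#' @param delta_beta half-range of the threshold perturbation used to estimate
#'   detection variance (`beta - delta_beta > 0`, `beta + delta_beta < 1`).
#' @param n_thresholds number of threshold replicates, evenly spaced in
#'   `[beta - delta_beta, beta + delta_beta]`; odd so that `beta` itself is
#'   sampled.
#' @param radius spatial gating radius r in px: from the third frame on, only
#'   components whose centroid lies within `radius` of the reference point are
#'   wound candidates.
#' @param closure_fraction wound considered closed when its area falls below
#'   this fraction of the image area (default 0.005, i.e. 5 per mille).
#' @param ic_on `"smoothed"` (default) computes the confluency intensity on
#'   the smoothed frame, so threshold and compared pixels share one intensity
#'   scale; `"raw"` uses the unsmoothed frame.
#' @param perimeter_method contour tracer, `"marching_squares"` or
#'   `"chain_code"`.
#' @param border_correction see [perimeter_excluding_border()].
#' @param contour_sigma pre-smoothing for the marching-squares tracer, px.
#' @param truncate Gaussian kernel truncation radius in units of `sigma`.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(sigma = 18, beta = 0.3, delta_beta = 0.08,
                             n_thresholds = 5, radius = 100,
                             closure_fraction = 0.005,
                             ic_on = c("smoothed", "raw"),
                             perimeter_method = c("marching_squares", "chain_code"),
                             border_correction = c("geometric", "pixel_count"),
                             contour_sigma = 3, truncate = 4) {
  ic_on <- match.arg(ic_on)
  perimeter_method <- match.arg(perimeter_method)
  border_correction <- match.arg(border_correction)
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (beta <= 0 || beta >= 1) abort("`beta` must lie in (0, 1).")
  if (delta_beta < 0 || beta - delta_beta <= 0 || beta + delta_beta >= 1) {
    abort("`beta +/- delta_beta` must stay inside (0, 1).")
  }
  if (n_thresholds < 1) abort("`n_thresholds` must be >= 1.")
  if (radius <= 0) abort("`radius` must be positive.")
  if (closure_fraction < 0 || closure_fraction >= 1) {
    abort("`closure_fraction` must lie in [0, 1).")
  }
  structure(
    list(sigma = sigma, beta = beta, delta_beta = delta_beta,
         n_thresholds = as.integer(n_thresholds), radius = radius,
         closure_fraction = closure_fraction, ic_on = ic_on,
         perimeter_method = perimeter_method,
         border_correction = border_correction,
         contour_sigma = contour_sigma, truncate = truncate),
    class = "detection_params"
  )
}

#' Confluency intensity of a frame
#'
#' The intensity-weighted mean pixel intensity, `I_c = sum(p^2) / sum(p)`.
#' Because bright (confluent) pixels dominate the weighting, `I_c` tracks the
#' cell-field intensity level even when a large dark wound is present, which
#' makes `beta * I_c` a stable relative threshold across frames and
#' illumination levels. Always lies between `min(p)` and `max(p)`.
#'
#' @param frame numeric matrix with nonnegative intensities, at least one
#'   positive pixel.
#' @return scalar `I_c` in grayscale units.
#' @export
confluency_intensity <- function(frame) {
  if (min(frame) < 0) abort("negative intensities are not allowed")
  s <- sum(frame)
  if (s == 0) abort("all-zero frame: confluency intensity undefined")
  sum(frame^2) / s
}

#' Binarize a smoothed frame at the confluency threshold
#'
#' Marks candidate wound pixels: those strictly below `beta * ic` (ties count
#' as cells). Masks are nested in `beta`: a lower `beta` gives a subset mask.
#'
#' @param frame numeric matrix (normally the smoothed frame).
#' @param beta relative threshold in (0, 1).
#' @param ic confluency intensity; defaults to `confluency_intensity(frame)`.
#' @return logical matrix, `TRUE` for below-threshold pixels.
#' @export
binarize_frame <- function(frame, beta, ic = confluency_intensity(frame)) {
  if (beta <= 0 || beta >= 1) abort("`beta` must lie in (0, 1).")
  frame < beta * ic
}

#' Select the wound component from a below-threshold mask
#'
#' Labels the mask into 4-connected (Von Neumann) components, optionally
#' discards components whose centroid lies farther than `radius` from the
#' reference point `ref`, keeps the largest survivor by pixel count, and fills
#' its interior holes so the region is simply connected (drifting cells inside
#' the wound are absorbed into it).
#'
#' @param mask logical matrix from [binarize_frame()].
#' @param ref optional reference point `(row, col)`; `NULL` disables spatial
#'   gating (used for the first two frames).
#' @param radius gating radius in px.
#' @return an object of class `wound_region`: list with `mask` (logical,
#'   filled), `centroid` `(row, col)`, `area` (px), `touches_border`, and
#'   `closed` (`TRUE` when no component survives; the mask is then empty).
#' @export
select_wound_region <- function(mask, ref = NULL, radius = Inf) {
  mask <- mask_logical(mask)
  empty <- function() {
    structure(list(mask = matrix(FALSE, nrow(mask), ncol(mask)),
                   centroid = c(NA_real_, NA_real_), area = 0,
                   touches_border = FALSE, closed = TRUE),
              class = "wound_region")
  }
  if (!any(mask)) return(empty())
  lab <- as_plain_matrix(EBImage::bwlabel(mask * 1))
  labv <- as.integer(lab)
  sizes <- tabulate(labv)
  keep <- seq_along(sizes)
  if (!is.null(ref) && is.finite(radius)) {
    rows <- as.integer(row(lab))[labv > 0]
    cols <- as.integer(col(lab))[labv > 0]
    lv <- labv[labv > 0]
    cx <- rowsum(rows, lv)[, 1] / sizes
    cy <- rowsum(cols, lv)[, 1] / sizes
    keep <- which(sqrt((cx - ref[1])^2 + (cy - ref[2])^2) <= radius)
    if (!length(keep)) return(empty())
  }
  best <- keep[which.max(sizes[keep])]
  region <- lab == best
  filled <- as_plain_matrix(EBImage::fillHull(region * 1)) > 0.5
  idx <- which(filled)
  nr <- nrow(filled)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  structure(
    list(mask = filled,
         centroid = c(mean(rows), mean(cols)),
         area = length(idx),
         touches_border = any(rows == 1 | rows == nr | cols == 1 | cols == ncol(filled)),
         closed = FALSE),
    class = "wound_region"
  )
}

#' @export
print.wound_region <- function(x, ...) {
  if (x$closed) cat("<wound_region> empty (closed)\n")
  else cat(sprintf("<wound_region> area %d px, centroid (%.1f, %.1f)%s\n",
                   x$area, x$centroid[1], x$centroid[2],
                   if (x$touches_border) ", touches border" else ""))
  invisible(x)
}

#' Wound area of a region
#'
#' Pixel count of the (filled) wound region; 0 for an empty region.
#'
#' @param region a [select_wound_region()] result (or a logical mask).
#' @return area in px^2.
#' @export
wound_area <- function(region) {
  if (inherits(region, "wound_region")) return(sum(region$mask))
  sum(mask_logical(region))
}

#' Reference point from the first two detections
#'
#' The midpoint of the wound centers of mass at the first two time points,
#' used to gate wound candidates spatially in all later frames. If one of the
#' two detections is missing the single available center is used (with a
#' warning); if both are missing the sequence cannot be analyzed.
#'
#' @param c1,c2 centroids `(row, col)` at the first and second time point;
#'   either may be `NULL`/`NA` when the wound was not detected.
#' @return reference point `(row, col)`.
#' @export
reference_point <- function(c1, c2) {
  bad <- function(x) is.null(x) || anyNA(x)
  if (bad(c1) && bad(c2)) abort("wound detected in neither of the first two frames")
  if (bad(c1)) { warn("no wound in frame 1; reference from frame 2 only"); return(c2) }
  if (bad(c2)) { warn("no wound in frame 2; reference from frame 1 only"); return(c1) }
  (c1 + c2) / 2
}

#' Detect the wound in one frame with threshold-replicate uncertainty
#'
#' Runs the full single-frame pipeline: Gaussian smoothing, confluency
#' intensity, binarization at `n_thresholds` values evenly spaced in
#' `beta +/- delta_beta`, component selection with optional spatial gating,
#' hole filling, area and border-excluded perimeter measurement. The mean and
#' (unbiased) variance across threshold replicates quantify the detection
#' uncertainty of the fuzzy wound boundary; the contour at the central `beta`
#' is attached for visualization.
#'
#' @param frame numeric intensity matrix (raw; smoothing happens here).
#' @param params a [detection_params()].
#' @param ref optional reference point for spatial gating.
#' @return one-row tibble: `area`, `area_var`, `perim`, `perim_var`, `cx`,
#'   `cy` (centroid at central beta), `closed`, `touches_border`,
#'   `n_detected` (replicates with a wound), and list-column `contour`.
#' @export
detect_wound <- function(frame, params = detection_params(), ref = NULL) {
  stopifnot(inherits(params, "detection_params"))
  sm <- gaussian_smooth(frame, params$sigma, params$truncate)
  ic <- confluency_intensity(if (params$ic_on == "smoothed") sm else frame)
  betas <- if (params$n_thresholds == 1L) params$beta else {
    seq(params$beta - params$delta_beta, params$beta + params$delta_beta,
        length.out = params$n_thresholds)
  }
  central <- which.min(abs(betas - params$beta))
  areas <- perims <- rep(NA_real_, length(betas))
  centroid <- c(NA_real_, NA_real_)
  touches <- FALSE
  contour <- NULL
  for (i in seq_along(betas)) {
    mask <- binarize_frame(sm, betas[i], ic)
    region <- select_wound_region(mask, ref = ref, radius = params$radius)
    if (region$closed) next
    areas[i] <- region$area
    ctr <- trace_contour(region$mask, method = params$perimeter_method,
                         smooth_sigma = params$contour_sigma)
    perims[i] <- perimeter_excluding_border(ctr, dim(frame),
                                            correction = params$border_correction)
    if (i == central) {
      centroid <- region$centroid
      touches <- region$touches_border
      contour <- ctr
    }
  }
  ok <- !is.na(areas)
  if (!any(ok)) {
    return(tibble(area = 0, area_var = 0, perim = 0, perim_var = 0,
                  cx = NA_real_, cy = NA_real_, closed = TRUE,
                  touches_border = FALSE, n_detected = 0L,
                  contour = list(NULL)))
  }
  if (is.na(areas[central])) {
    # central threshold lost the wound; fall back to nearest detected replicate
    j <- which(ok)[which.min(abs(which(ok) - central))]
    mask <- binarize_frame(sm, betas[j], ic)
    region <- select_wound_region(mask, ref = ref, radius = params$radius)
    centroid <- region$centroid
    touches <- region$touches_border
    contour <- trace_contour(region$mask, method = params$perimeter_method,
                             smooth_sigma = params$contour_sigma)
  }
  tibble(
    area = mean(areas[ok]),
    area_var = if (sum(ok) > 1) var(areas[ok]) else 0,
    perim = mean(perims[ok]),
    perim_var = if (sum(ok) > 1) var(perims[ok]) else 0,
    cx = centroid[1], cy = centroid[2],
    closed = FALSE, touches_border = touches,
    n_detected = sum(ok), contour = list(contour)
  )
}

#' Measure a whole sequence
#'
#' Applies [detect_wound()] to every frame. The first two frames are gated
#' only by largest-component selection; their centroids define the reference
#' point (midpoint of the two centers of mass) that spatially gates all later
#' frames within `params$radius`.
#'
#' @param x a [frame_sequence()].
#' @param params a [detection_params()].
#' @param preprocess `"none"` or `"scharr"`; the Scharr gradient magnitude is
#'   applied before detection for non-fluorescent (phase-contrast) inputs.
#' @return tibble with one row per frame: `frame`, `time`, measurement columns
#'   of [detect_wound()], and attribute `reference_point`.
#' @export
measure_sequence <- function(x, params = detection_params(),
                             preprocess = c("none", "scharr")) {
  stopifnot(inherits(x, "frame_sequence"))
  preprocess <- match.arg(preprocess)
  frames <- x$frames
  if (preprocess == "scharr") frames <- lapply(frames, scharr_gradient)
  n <- length(frames)
  rows <- vector("list", n)
  for (i in 1:min(2L, n)) {
    rows[[i]] <- detect_wound(frames[[i]], params, ref = NULL)
  }
  c1 <- unname(unlist(rows[[1]][, c("cx", "cy")]))
  c2 <- if (n >= 2) unname(unlist(rows[[2]][, c("cx", "cy")])) else c(NA, NA)
  ref <- reference_point(if (anyNA(c1)) NULL else c1,
                         if (anyNA(c2)) NULL else c2)
  if (n > 2) {
    for (i in 3:n) rows[[i]] <- detect_wound(frames[[i]], params, ref = ref)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble(frame = seq_len(n), time = x$times), out)
  attr(out, "reference_point") <- ref
  attr(out, "pixel_scale") <- x$pixel_scale
  out
}

#' Truncate a measurement series at wound closure
#'
#' A wound is considered closed from the first time point whose area falls
#' below `closure_fraction` of the image area; that time point and all later
#' ones are excluded from model training (`retained = FALSE`). A sequence
#' already closed at the first frame cannot be modeled.
#'
#' @param measurements tibble from [measure_sequence()] (columns `area`,
#'   `closed`), time-ordered.
#' @param frame_area image area in px^2 (rows x cols).
#' @param closure_fraction see [detection_params()].
#' @return the measurements tibble with a logical `retained` column.
#' @export
filter_closure <- function(measurements, frame_area, closure_fraction = 0.005) {
  thr <- closure_fraction * frame_area
  below <- measurements$area < thr | measurements$closed
  first <- if (any(below)) which(below)[1] else length(below) + 1L
  if (first == 1L) abort("wound is closed at the first time point; nothing to model")
  dplyr::mutate(measurements, retained = dplyr::row_number() < first)
}
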