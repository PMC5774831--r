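#' Build a frame sequence from in-memory matrices
#'
#' A `frame_sequence` is the container every downstream step consumes: an
#' ordered list of 2-D grayscale intensity matrices with acquisition times in
#' hours and an optional physical pixel scale. Pixel values are nonnegative
#' reals at native scale (no rescaling is performed). All frames must share the
#' same dimensions and times must be strictly increasing; frames supplied out
#' of order are sorted by time.
#'
#' Coordinates throughout the package are 1-based `(row, col)` at pixel
#' centers, so the image borders lie at 0.5 and `nrow + 0.5` / `ncol + 0.5`.
#'
#' @param frames list of numeric matrices (equal dimensions, values >= 0).
#' @param times numeric vector of acquisition times in hours, one per frame.
#'   Defaults to `0, interval, 2*interval, ...`.
#' @param interval frame interval in hours, used when `times` is not given.
#' @param pixel_scale physical size of one pixel in micrometres (um/px).
#'   Areas convert to um^2 via `pixel_scale^2`, velocities to um/h via
#'   `pixel_scale`.
#' @param source optional character vector of file paths of origin.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, times = NULL, interval = 1,
                           pixel_scale = 1, source = NULL) {
  if (!is.list(frames) || length(frames) < 1) {
    abort("`frames` must be a non-empty list of matrices.")
  }
  frames <- lapply(frames, function(f) {
    if (is.array(f) && length(dim(f)) == 2) f <- matrix(as.numeric(f), nrow(f), ncol(f))
    if (!is.matrix(f) || !is.numeric(f)) abort("each frame must be a numeric matrix")
    f
  })
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1)) {
      abort(sprintf("frame %d has dimensions %dx%d, expected %dx%d",
                    i, nrow(frames[[i]]), ncol(frames[[i]]), d1[1], d1[2]))
    }
    if (anyNA(frames[[i]]) || min(frames[[i]]) < 0) {
      abort(sprintf("frame %d contains NA or negative intensities", i))
    }
  }
  if (is.null(times)) times <- (seq_along(frames) - 1) * interval
  if (length(times) != length(frames)) {
    abort("`times` must have one entry per frame.")
  }
  ord <- order(times)
  times <- times[ord]
  frames <- frames[ord]
  if (!is.null(source) && length(source) == length(frames)) source <- source[ord]
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  structure(
    list(frames = frames, times = as.numeric(times),
         pixel_scale = pixel_scale, source = source),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %d x %d px\n",
              length(x$frames), d[1], d[2]))
  cat(sprintf("  times: %g .. %g h;  pixel scale: %g um/px\n",
              min(x$times), max(x$times), x$pixel_scale))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Load an image sequence from TIFF or PNG files
#'
#' Reads single-frame files (one per time point) or a single multi-page TIFF
#' stack. RGB inputs are flattened to grayscale; the default flattening is the
#' unweighted channel mean, or a single channel can be selected. Intensities
#' are kept at native bit depth as nonnegative reals.
#'
#' @param paths character vector of file paths (TIFF or PNG), or one multi-page
#'   TIFF path.
#' @param times,interval,pixel_scale see [frame_sequence()].
#' @param channel one of `"mean"`, `"gray"`, `"r"`, `"g"`, `"b"`. `"gray"`
#'   requires single-channel input; `"mean"` averages RGB channels.
#' @return a [frame_sequence()].
#' @export
read_sequence <- function(paths, times = NULL, interval = 1,
                          pixel_scale = 1, channel = c("mean", "gray", "r", "g", "b")) {
  channel <- match.arg(channel)
  frames <- list()
  src <- character()
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("cannot read '%s': file not found", p))
    lower <- tolower(p)
    imgs <- if (grepl("\\.tiff?$", lower)) {
      img <- tryCatch(tiff::readTIFF(p, all = TRUE, as.is = TRUE),
                      error = function(e) abort(sprintf("cannot read '%s': %s", p, conditionMessage(e))))
      if (!is.list(img)) list(img) else img
    } else if (grepl("\\.png$", lower)) {
      list(png::readPNG(p))
    } else {
      abort(sprintf("cannot read '%s': only TIFF and PNG are supported", p))
    }
    for (img in imgs) {
      frames[[length(frames) + 1L]] <- flatten_gray(img, channel, p)
      src <- c(src, p)
    }
  }
  if (length(frames) < 2) abort("need at least 2 readable frames")
  frame_sequence(frames, times = times, interval = interval,
                 pixel_scale = pixel_scale, source = src)
}

flatten_gray <- function(img, channel, path) {
  if (length(dim(img)) == 2) {
    if (channel %in% c("r", "g", "b")) {
      abort(sprintf("'%s' is single-channel; channel='%s' unavailable", path, channel))
    }
    return(matrix(as.numeric(img), nrow(img), ncol(img)))
  }
  if (length(dim(img)) == 3) {
    nc <- dim(img)[3]
    out <- switch(channel,
      mean = apply(img[, , seq_len(min(nc, 3)), drop = FALSE], c(1, 2), mean),
      gray = abort(sprintf("'%s' is multi-channel; use channel='mean' or a channel letter", path)),
      r = img[, , 1], g = img[, , min(2, nc)], b = img[, , min(3, nc)]
    )
    return(matrix(as.numeric(out), dim(img)[1], dim(img)[2]))
  }
  abort(sprintf("'%s': unsupported image dimensionality", path))
}

#' Gaussian smoothing of a frame
#'
#' Convolves a frame with a normalized 2-D Gaussian kernel of standard
#' deviation `sigma`, truncated at `truncate * sigma` (default 4), with
#' reflective boundary handling so that constant images are reproduced exactly
#' and image borders do not darken (which would otherwise be misread as wound).
#'
#' @param frame numeric matrix.
#' @param sigma kernel standard deviation in pixels, > 0.
#' @param truncate kernel truncation radius in units of `sigma`.
#' @return smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(frame, sigma, truncate = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  k <- max(1L, as.integer(ceiling(truncate * sigma)))
  br <- EBImage::makeBrush(2L * k + 1L, shape = "Gaussian", sigma = sigma)
  br <- br / sum(br)
  padded <- pad_reflect(frame, k)
  sm <- EBImage::filter2(padded, br, boundary = 0)
  as_plain_matrix(sm)[(k + 1):(k + nrow(frame)), (k + 1):(k + ncol(frame)), drop = FALSE]
}

# mirror-pad a matrix by k pixels on all sides (reflection without edge repeat
# would need k < dim; use reflection including the edge row for robustness)
pad_reflect <- function(m, k) {
  ridx <- c(pmin(k:1, nrow(m)), 1:nrow(m), nrow(m) + 1 - pmin(1:k, nrow(m)))
  cidx <- c(pmin(k:1, ncol(m)), 1:ncol(m), ncol(m) + 1 - pmin(1:k, ncol(m)))
  m[ridx, cidx, drop = FALSE]
}

as_plain_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' Scharr gradient magnitude
#'
#' Computes the gradient magnitude sqrt(Gx^2 + Gy^2) with the 3x3 Scharr
#' operator pair (weights 3, 10, 3, normalized by 1/16), with replicated edges.
#' Used to preprocess non-fluorescent (phase-contrast / bright-field) images:
#' textured cell regions become bright and the optically flat wound dark, which
#' is the intensity ordering the wound detector assumes. The output is
#' invariant to adding a constant to the input.
#'
#' @param frame numeric matrix.
#' @return gradient-magnitude matrix of the same dimensions.
#' @export
scharr_gradient <- function(frame) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16 # d/drow
  ky <- t(kx)
  padded <- pad_reflect(frame, 1L)
  gx <- as_plain_matrix(EBImage::filter2(padded, kx, boundary = 0))
  gy <- as_plain_matrix(EBImage::filter2(padded, ky, boundary = 0))
  g <- sqrt(gx^2 + gy^2)
  g[2:(nrow(frame) + 1), 2:(ncol(frame) + 1), drop = FALSE]
}
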