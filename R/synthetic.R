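#' Specify a synthetic shrinking-wound sequence
#'
#' Defines a synthetic time-lapse in which a bright confluent cell field
#' surrounds a dark wound that closes at a constant normal-front velocity
#' `velocity`: the wound at time t is the erosion of the initial shape by a
#' disk of radius `velocity * t`. This is the geometry under which the
#' concerted cell velocity is exactly `velocity` for any wound shape
#' (dA/dt = -v * P), making every downstream stage testable against closed
#' forms without external data.
#'
#' Shapes and their `size` parameter:
#' * `"disk"`: radius r0 (px).
#' * `"ellipse"`: full axis lengths `c(major, minor)` (px).
#' * `"rectangle"`: side lengths `c(width, height)` (px).
#' * `"polygon"`: convex polygon; pass `vertices` (n x 2, (row, col) px,
#'   any orientation), `size` is ignored.
#'
#' Intensities live on a [0, 1] scale (as written to / read from 16-bit TIFF):
#' cells at `cell_level`, wound at `wound_level`, i.i.d. Gaussian noise of
#' standard deviation `noise_sd` added and clipped to [0, 1]. `n_artifacts`
#' bright "drifting cell" blobs (disks at `cell_level`, diameter
#' `artifact_diameter`) are placed independently per frame well inside the
#' wound; they must be removed by the simply-connected fill during detection.
#'
#' @param shape one of `"disk"`, `"ellipse"`, `"rectangle"`, `"polygon"`.
#' @param size shape size parameters in px (see above).
#' @param velocity true normal-front velocity in px/hour (>= 0).
#' @param interval frame interval in hours.
#' @param n_frames number of frames (>= 2); times are `0, interval, ...`.
#' @param dim image dimensions `c(rows, cols)` in px.
#' @param center shape center `(row, col)`; default image center. A center
#'   placed on or beyond an image edge produces an open (border-touching)
#'   wound, which exercises the border-excluded perimeter; analytic ground
#'   truth is then reported as `NA`.
#' @param cell_level,wound_level intensities of cell field and wound
#'   (`wound_level < cell_level`).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param n_artifacts,artifact_diameter bright blobs inside the wound.
#' @param vertices convex polygon vertices for `shape = "polygon"`.
#' @param pixel_scale physical pixel size in um/px (metadata only).
#' @param seed integer seed; the same spec and seed give bit-identical frames.
#' @return an object of class `wound_spec`.
#' @seealso [simulate_wound()], [write_sequence()]
#' @export
wound_spec <- function(shape = c("disk", "ellipse", "rectangle", "polygon"),
                       size = 100, velocity = 5, interval = 1, n_frames = 16,
                       dim = c(512, 512), center = NULL,
                       cell_level = 0.8, wound_level = 0.05, noise_sd = 0.008,
                       n_artifacts = 0, artifact_diameter = 5,
                       vertices = NULL, pixel_scale = 1, seed = 1) {
  shape <- match.arg(shape)
  if (velocity < 0) abort("`velocity` must be >= 0.")
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  if (wound_level >= cell_level) abort("`wound_level` must be below `cell_level`.")
  if (interval <= 0) abort("`interval` must be positive.")
  if (shape == "polygon") {
    if (is.null(vertices) || !is.matrix(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3) {
      abort("`shape = 'polygon'` needs `vertices` as an (n >= 3) x 2 matrix.")
    }
    if (!is_convex_polygon(vertices)) abort("`vertices` must describe a convex polygon.")
  }
  if (shape %in% c("ellipse", "rectangle") && length(size) != 2) {
    abort(sprintf("`size` for shape '%s' must have 2 elements.", shape))
  }
  if (any(size <= 0)) abort("`size` must be positive.")
  if (is.null(center)) center <- (dim + 1) / 2
  structure(
    list(shape = shape, size = as.numeric(size), velocity = velocity,
         interval = interval, n_frames = as.integer(n_frames),
         dim = as.integer(dim), center = as.numeric(center),
         cell_level = cell_level, wound_level = wound_level,
         noise_sd = noise_sd, n_artifacts = as.integer(n_artifacts),
         artifact_diameter = artifact_diameter,
         vertices = vertices, pixel_scale = pixel_scale,
         seed = as.integer(seed)),
    class = "wound_spec"
  )
}

#' Simulate a synthetic wound sequence with analytic ground truth
#'
#' Rasterizes the eroded initial shape at each time point (erosion is applied
#' to the analytic shape, not to a raster, so ground truth stays closed-form),
#' paints cells at `cell_level` and wound at `wound_level`, adds artifacts and
#' clipped Gaussian noise. Ground truth:
#' * disk radius r0: A = pi (r0 - v t)^2, P = 2 pi (r0 - v t);
#' * rectangle w x h: A = (w - 2vt)(h - 2vt), P = 2(w + h - 4vt);
#' * ellipse: inner Steiner formula A0 - P0 d + pi d^2 and P0 - 2 pi d with
#'   d = v t and P0 from the Ramanujan approximation; exact for a smooth
#'   convex boundary while d is below the minimum curvature radius b^2/a,
#'   `NA` beyond it (frames are still generated from the exact eroded set);
#' * polygon: shoelace area/perimeter of the analytically eroded polygon.
#'
#' Once the wound vanishes (or ground truth area falls to 0) remaining frames
#' are marked `closed` and contain pure cell field.
#'
#' @param spec a [wound_spec()].
#' @return a [frame_sequence()] with attributes `ground_truth` (tibble:
#'   `frame`, `time_h`, `area_px2`, `perimeter_px`, `v_true`, `closed`) and
#'   `spec`.
#' @export
simulate_wound <- function(spec) {
  stopifnot(inherits(spec, "wound_spec"))
  times <- (seq_len(spec$n_frames) - 1) * spec$interval
  nr <- spec$dim[1]; nc <- spec$dim[2]
  X <- matrix(seq_len(nr), nr, nc)
  Y <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  frames <- vector("list", spec$n_frames)
  gt <- vector("list", spec$n_frames)

  withr::with_seed(spec$seed, {
    for (i in seq_len(spec$n_frames)) {
      d <- spec$velocity * times[i]
      mask <- rasterize_eroded(spec, d, X, Y)
      ana <- analytic_truth(spec, d)
      closed <- !any(mask)
      img <- matrix(spec$cell_level, nr, nc)
      img[mask] <- spec$wound_level
      if (!closed && spec$n_artifacts > 0) {
        img <- add_artifacts(img, mask, spec)
      }
      if (spec$noise_sd > 0) {
        img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
        img[img < 0] <- 0
        img[img > 1] <- 1
      }
      frames[[i]] <- img
      gt[[i]] <- tibble(
        frame = i, time_h = times[i],
        area_px2 = if (closed) 0 else ana$area,
        perimeter_px = if (closed) 0 else ana$perimeter,
        v_true = spec$velocity, closed = closed
      )
    }
  })

  seq <- frame_sequence(frames, times = times, pixel_scale = spec$pixel_scale)
  attr(seq, "ground_truth") <- dplyr::bind_rows(gt)
  attr(seq, "spec") <- spec
  seq
}

#' Ground-truth table of a simulated sequence
#' @param x a [frame_sequence()] produced by [simulate_wound()].
#' @return tibble with columns `frame`, `time_h`, `area_px2`, `perimeter_px`,
#'   `v_true`, `closed`, or `NULL` when `x` carries no ground truth.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

# ---- shape machinery --------------------------------------------------------

rasterize_eroded <- function(spec, d, X, Y) {
  cx <- spec$center[1]; cy <- spec$center[2]
  switch(spec$shape,
    disk = {
      r <- spec$size[1] - d
      if (r <= 0) return(X < 0)
      (X - cx)^2 + (Y - cy)^2 <= r^2
    },
    rectangle = {
      hw <- spec$size[1] / 2 - d; hh <- spec$size[2] / 2 - d
      if (hw <= 0 || hh <= 0) return(X < 0)
      abs(X - cx) <= hw & abs(Y - cy) <= hh
    },
    ellipse = {
      a <- spec$size[1] / 2; b <- spec$size[2] / 2
      if (d >= min(a, b)) return(X < 0)
      inside <- ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
      if (d == 0 || !any(inside)) return(inside)
      poly <- ellipse_polygon(cx, cy, a, b, n = 720)
      idx <- which(inside)
      dist <- dist_to_polygon(X[idx], Y[idx], poly)
      out <- inside
      out[idx] <- dist >= d
      out
    },
    polygon = {
      poly <- eroded_convex_polygon(spec$vertices, d)
      if (is.null(poly)) return(X < 0)
      in_convex_polygon(X, Y, poly)
    }
  )
}

analytic_truth <- function(spec, d) {
  switch(spec$shape,
    disk = {
      r <- spec$size[1] - d
      if (r <= 0) list(area = 0, perimeter = 0)
      else list(area = pi * r^2, perimeter = 2 * pi * r)
    },
    rectangle = {
      w <- spec$size[1] - 2 * d; h <- spec$size[2] - 2 * d
      if (w <= 0 || h <= 0) list(area = 0, perimeter = 0)
      else list(area = w * h, perimeter = 2 * (w + h))
    },
    ellipse = {
      a <- spec$size[1] / 2; b <- spec$size[2] / 2
      lo <- min(a, b); hi <- max(a, b)
      if (d >= lo) return(list(area = 0, perimeter = 0))
      if (d >= lo^2 / hi) return(list(area = NA_real_, perimeter = NA_real_))
      p0 <- ramanujan_perimeter(a, b)
      list(area = pi * a * b - p0 * d + pi * d^2, perimeter = p0 - 2 * pi * d)
    },
    polygon = {
      poly <- eroded_convex_polygon(spec$vertices, d)
      if (is.null(poly)) list(area = 0, perimeter = 0)
      else list(area = shoelace_area(poly), perimeter = polygon_perimeter(poly))
    }
  )
}

ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

ellipse_polygon <- function(cx, cy, a, b, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(th), cy + b * sin(th))
}

# min distance from points (px, py) to the closed polygon boundary
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- ((px - ax) * vx + (py - ay) * vy) / L2
    t[t < 0] <- 0; t[t > 1] <- 1
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    dmin <- pmin(dmin, dx * dx + dy * dy)
  }
  sqrt(dmin)
}

is_convex_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  s <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    cc <- v[if (i >= n - 1) i - n + 2L else i + 2L, ]
    cr <- (b[1] - a[1]) * (cc[2] - b[2]) - (b[2] - a[2]) * (cc[1] - b[1])
    if (abs(cr) > 1e-9) {
      if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
    }
  }
  TRUE
}

# erosion of a convex polygon by a disk of radius d = intersection of its edge
# half-planes shifted inward by d; computed by Sutherland-Hodgman clipping.
# Returns vertex matrix or NULL when the eroded set is empty/degenerate.
eroded_convex_polygon <- function(v, d) {
  if (shoelace_signed(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE] # CCW
  bb <- rbind(c(min(v[, 1]) - 1, min(v[, 2]) - 1), c(max(v[, 1]) + 1, min(v[, 2]) - 1),
              c(max(v[, 1]) + 1, max(v[, 2]) + 1), c(min(v[, 1]) - 1, max(v[, 2]) + 1))
  subject <- bb
  n <- nrow(v)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    len <- sqrt(ex^2 + ey^2)
    # inward normal for CCW polygon is (-ey, ex)/len; keep points with
    # (p - a) . n >= d  <=>  shifted half-plane
    nx <- -ey / len; ny <- ex / len
    subject <- clip_halfplane(subject, nx, ny, a[1] * nx + a[2] * ny + d)
    if (is.null(subject)) return(NULL)
  }
  if (nrow(subject) < 3 || shoelace_area(subject) < 1e-9) return(NULL)
  subject
}

# keep region nx*x + ny*y >= c
clip_halfplane <- function(poly, nx, ny, c) {
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    fa <- nx * a[1] + ny * a[2] - c
    fb <- nx * b[1] + ny * b[2] - c
    if (fa >= 0) out <- rbind(out, a)
    if ((fa < 0) != (fb < 0)) {
      t <- fa / (fa - fb)
      out <- rbind(out, a + t * (b - a))
    }
  }
  if (nrow(out) < 3) NULL else out
}

in_convex_polygon <- function(X, Y, poly) {
  if (shoelace_signed(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  n <- nrow(poly)
  inside <- TRUE
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    inside <- inside & ((b[1] - a[1]) * (Y - a[2]) - (b[2] - a[2]) * (X - a[1]) >= 0)
  }
  inside
}

shoelace_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

shoelace_area <- function(v) abs(shoelace_signed(v))

polygon_perimeter <- function(v) {
  d <- diff(rbind(v, v[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

add_artifacts <- function(img, mask, spec) {
  rad <- spec$artifact_diameter / 2
  margin <- as.integer(ceiling(rad) + 2L)
  core <- EBImage::erode(mask * 1, EBImage::makeBrush(2L * margin + 1L, "disc"))
  core <- as_plain_matrix(core) > 0.5
  idx <- which(core)
  if (!length(idx)) return(img)
  pick <- idx[sample.int(length(idx), min(spec$n_artifacts, length(idx)))]
  nr <- nrow(img)
  for (p in pick) {
    r0 <- ((p - 1) %% nr) + 1
    c0 <- ((p - 1) %/% nr) + 1
    rr <- pmax(1, floor(r0 - rad)):pmin(nr, ceiling(r0 + rad))
    cc <- pmax(1, floor(c0 - rad)):pmin(ncol(img), ceiling(c0 + rad))
    sub <- expand.grid(r = rr, c = cc)
    hit <- (sub$r - r0)^2 + (sub$c - c0)^2 <= rad^2
    img[cbind(sub$r[hit], sub$c[hit])] <- spec$cell_level
  }
  img
}

#' Write a frame sequence to disk
#'
#' Writes one 16-bit grayscale image per frame, named `frame_001.tif` (or
#' `.png`) onward, plus `times.csv` (`frame`, `time_h`) and, when the sequence
#' carries simulation ground truth, `ground_truth.csv`. Intensities are
#' clipped to [0, 1] and quantized to 16 bits.
#'
#' @param x a [frame_sequence()].
#' @param dir output directory (created if missing).
#' @param format `"tiff"` or `"png"`.
#' @return invisibly, the vector of frame file paths.
#' @export
write_sequence <- function(x, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "frame_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "png"
  paths <- file.path(dir, sprintf("frame_%03d.%s", seq_along(x$frames), ext))
  for (i in seq_along(x$frames)) {
    f <- x$frames[[i]]
    f[f < 0] <- 0; f[f > 1] <- 1
    f <- round(f * 65535) / 65535
    if (format == "tiff") {
      tiff::writeTIFF(f, paths[i], bits.per.sample = 16)
    } else {
      png::writePNG(f, paths[i])
    }
  }
  readr::write_csv(tibble(frame = seq_along(x$frames), time_h = x$times),
                   file.path(dir, "times.csv"))
  gt <- ground_truth(x)
  if (!is.null(gt)) readr::write_csv(gt, file.path(dir, "ground_truth.csv"))
  invisible(paths)
}

#' Simulate a multi-condition study of synthetic wound sequences
#'
#' Builds a study layout for [analyze_study()]: for each named condition
#' (mean front velocity in px/h) it simulates `n_replicates` sequences.
#' Replicates emulate two features of real screening data: biological
#' replicate-to-replicate variability (each replicate's true velocity is
#' drawn from a normal with sd `velocity_sd`, folded at zero so front speeds
#' stay nonnegative without collapsing a slow condition's spread) and wound-shape
#' heterogeneity (replicates cycle through a disk, a larger disk, an ellipse
#' and a rectangle, with sizes jittered by `size_jitter`). This is the
#' geometry confound under which the area-slope readout spreads while the
#' concerted velocity does not.
#'
#' @param conditions named numeric vector of mean velocities (px/h), e.g.
#'   `c(fast = 6, slow = 2, control = 0)`.
#' @param n_replicates replicates per condition.
#' @param velocity_sd biological replicate variability of the velocity
#'   (px/h). Keep it large enough that the implied spread in total front
#'   displacement over the sequence exceeds one pixel; far below that the
#'   raster cannot resolve the variability and a near-static condition
#'   degenerates toward zero spread.
#' @param dim image dimensions.
#' @param n_frames,interval frames per sequence and spacing (h).
#' @param base_size reference wound scale in px; shape sizes are proportional
#'   to it.
#' @param size_jitter relative size jitter across replicates.
#' @param noise_sd,cell_level,wound_level passed to [wound_spec()].
#' @param seed master seed; every replicate derives its own sub-seed.
#' @return named list (one element per condition) of lists of
#'   [frame_sequence()] objects, each carrying its ground truth; suitable for
#'   [analyze_study()].
#' @export
simulate_study <- function(conditions, n_replicates = 5, velocity_sd = 0.25,
                           dim = c(256, 256), n_frames = 12, interval = 1,
                           base_size = 50, size_jitter = 0.1,
                           noise_sd = 0.008, cell_level = 0.8,
                           wound_level = 0.05, seed = 1) {
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    abort("`conditions` must be a named vector of velocities")
  }
  shapes <- list(
    function(s) list(shape = "disk", size = s),
    function(s) list(shape = "disk", size = 1.3 * s),
    function(s) list(shape = "ellipse", size = c(2.2 * s, 1.4 * s)),
    function(s) list(shape = "rectangle", size = c(2.4 * s, 1.8 * s))
  )
  out <- list()
  k <- 0L
  for (cond in names(conditions)) {
    reps <- vector("list", n_replicates)
    for (j in seq_len(n_replicates)) {
      k <- k + 1L
      sub_seed <- seed + 1000L * k
      draw <- withr::with_seed(sub_seed, list(
        v = abs(rnorm(1, conditions[[cond]], velocity_sd)),
        s = base_size * (1 + runif(1, -size_jitter, size_jitter))
      ))
      geom <- shapes[[(j - 1L) %% length(shapes) + 1L]](draw$s)
      spec <- wound_spec(shape = geom$shape, size = geom$size,
                         velocity = draw$v, interval = interval,
                         n_frames = n_frames, dim = dim,
                         cell_level = cell_level, wound_level = wound_level,
                         noise_sd = noise_sd, seed = sub_seed)
      reps[[j]] <- simulate_wound(spec)
    }
    out[[cond]] <- reps
  }
  out
}
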