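test_that("confluency intensity is the intensity-weighted mean", {
  expect_equal(confluency_intensity(matrix(7, 5, 5)), 7)
  expect_equal(confluency_intensity(matrix(c(0, 2), 1, 2)), 2)
  expect_equal(confluency_intensity(matrix(c(1, 1, 3, 3), 2, 2)), 2.5)
  f <- matrix(runif(100, 1, 9), 10, 10)
  ic <- confluency_intensity(f)
  expect_gte(ic, min(f)); expect_lte(ic, max(f))
  expect_error(confluency_intensity(matrix(0, 3, 3)), "all-zero")
})

test_that("binarization marks sub-threshold pixels and is monotone in beta", {
  expect_false(any(binarize_frame(matrix(4, 6, 6), beta = 0.3)))
  f <- wound_frame(n = 64, r = 20, cell = 100, wound = 10)
  m <- binarize_frame(f, 0.3)
  expect_equal(sum(m), sum(disk_mask(64, 20)))  # wound pixels only
  prev <- binarize_frame(f, 0.05)
  for (b in c(0.2, 0.4, 0.6, 0.8, 0.95)) {
    cur <- binarize_frame(f, b)
    expect_true(all(cur[prev]))                 # nested masks
    prev <- cur
  }
})

test_that("component selection is 4-connected, gated and hole-filling", {
  m <- matrix(FALSE, 9, 9); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  # diagonal touch only: two Von Neumann components, largest has 1 px
  expect_equal(select_wound_region(m)$area, 1)

  # dark corner far from the wound is rejected by the radius gate
  m2 <- matrix(FALSE, 200, 200)
  m2[disk_mask(200, 18, c(100, 100))] <- TRUE        # ~1000 px wound
  m2[1:7, 1:7] <- TRUE                               # 49 px corner blob
  gated <- select_wound_region(m2, ref = c(100, 100), radius = 50)
  expect_equal(gated$area, sum(disk_mask(200, 18, c(100, 100))))
  expect_equal(gated$centroid, c(100, 100), tolerance = 0.01)
  # without a reference the largest component wins regardless of position
  expect_equal(select_wound_region(m2)$area, gated$area)
  # gate that excludes everything -> closed
  expect_true(select_wound_region(m2, ref = c(190, 190), radius = 5)$closed)

  # interior hole (drifting cell) is filled: area grows by the hole size
  m3 <- matrix(FALSE, 40, 40); m3[10:30, 10:30] <- TRUE
  m3[19:22, 19:22] <- FALSE                          # 16-px hole
  reg <- select_wound_region(m3)
  expect_equal(reg$area, 21 * 21)
  # simply connected (Euler characteristic 1): one component, and the
  # complement is a single piece that touches the border (no enclosed holes)
  expect_equal(max(EBImage::bwlabel(reg$mask * 1)), 1)
  comp <- EBImage::bwlabel((!reg$mask) * 1)
  expect_equal(max(comp), 1)
  expect_true(any(comp[1, ] == 1))

  expect_true(select_wound_region(matrix(FALSE, 5, 5))$closed)
})

test_that("reference point is the midpoint of the first two centroids", {
  expect_equal(reference_point(c(100, 100), c(110, 90)), c(105, 95))
  expect_equal(reference_point(c(42, 17), c(42, 17)), c(42, 17))
  expect_warning(p <- reference_point(NULL, c(5, 6)), "frame 2 only")
  expect_equal(p, c(5, 6))
  expect_error(
    suppressWarnings(reference_point(NULL, NULL)), "neither")
})

test_that("centroid of a stationary rasterized disk matches its center", {
  m <- disk_mask(151, 40, c(76, 76))
  reg <- select_wound_region(m)
  expect_equal(reg$centroid, c(76, 76), tolerance = 0.5)
})

test_that("wound area counts pixels of the filled region", {
  m <- matrix(FALSE, 10, 10); m[3:7, 3:7] <- TRUE
  expect_equal(wound_area(select_wound_region(m)), 25)
  expect_equal(wound_area(select_wound_region(matrix(FALSE, 4, 4))), 0)
  r <- 45
  expect_equal(wound_area(select_wound_region(disk_mask(121, r))),
               pi * r^2, tolerance = 0.02)
})

test_that("threshold replicates quantify boundary uncertainty", {
  f <- wound_frame(n = 128, r = 40)
  # degenerate replicate: single threshold -> zero variance
  one <- detect_wound(f, detection_params(sigma = 2, n_thresholds = 1))
  expect_equal(one$area_var, 0)
  expect_equal(one$perim_var, 0)
  expect_equal(one$n_detected, 1L)

  # noiseless hard step edge: threshold-insensitive detection. With the
  # smoothing scale well below the pixel pitch every replicate threshold
  # falls into the same inter-level gap, so all masks coincide.
  hard <- detect_wound(f, detection_params(sigma = 0.3, delta_beta = 0.08))
  expect_equal(hard$n_detected, 5L)
  expect_lt(sqrt(hard$area_var) / hard$area, 1e-3)

  # wound absent at all thresholds -> closed measurement
  blank <- detect_wound(matrix(0.8, 64, 64) + 0, fx_params(sigma = 2))
  expect_true(blank$closed)
  expect_equal(blank$area, 0)
})

test_that("drifting-cell artifacts are absorbed by the fill", {
  base <- wound_spec("disk", size = 40, velocity = 0, n_frames = 2,
                     dim = c(128, 128), noise_sd = 0, seed = 5)
  with_art <- wound_spec("disk", size = 40, velocity = 0, n_frames = 2,
                         dim = c(128, 128), noise_sd = 0, seed = 5,
                         n_artifacts = 3, artifact_diameter = 4)
  a0 <- detect_wound(simulate_wound(base)$frames[[1]], fx_params(sigma = 2))
  a1 <- detect_wound(simulate_wound(with_art)$frames[[1]], fx_params(sigma = 2))
  expect_equal(a1$area, a0$area, tolerance = 0.01)
  expect_equal(a1$perim, a0$perim, tolerance = 0.02)
})

test_that("closure filter drops the first sub-threshold point and later ones", {
  meas <- tibble::tibble(time = 1:4, area = c(9000, 6000, 4000, 3000),
                         closed = FALSE)
  out <- filter_closure(meas, frame_area = 1e6, closure_fraction = 0.005)
  expect_equal(out$retained, c(TRUE, TRUE, FALSE, FALSE))  # threshold 5000

  none <- filter_closure(tibble::tibble(time = 1:3, area = c(9, 8, 7) * 1e3,
                                        closed = FALSE),
                         frame_area = 1e6, closure_fraction = 0.005)
  expect_true(all(none$retained))

  expect_error(
    filter_closure(tibble::tibble(time = 1, area = 10, closed = FALSE),
                   frame_area = 1e6, closure_fraction = 0.005),
    "first time point")
})

test_that("measurement gating starts at the third frame", {
  spec <- wound_spec("disk", size = 35, velocity = 2, n_frames = 4,
                     dim = c(128, 128), seed = 2)
  sim <- simulate_wound(spec)
  meas <- measure_sequence(sim, fx_params(sigma = 2, radius = 60))
  expect_equal(nrow(meas), 4)
  expect_false(any(meas$closed))
  ref <- attr(meas, "reference_point")
  expect_equal(ref, c(64.5, 64.5), tolerance = 1)
  # absolute areas carry the constant threshold-offset bias of ~0.5*sigma px
  # along the normal; it shifts all frames alike (and cancels in velocity)
  gt <- ground_truth(sim)
  expect_equal(meas$area, gt$area_px2, tolerance = 0.10)
  rel <- meas$area / gt$area_px2 - 1
  expect_lt(diff(range(rel)), 0.03)
})

test_that("detected areas track the analytic disk within 3% for large wounds", {
  # smoothing scale matched to the white-noise fixture keeps the threshold
  # offset well below the wound radius
  spec <- wound_spec("disk", size = 100, velocity = 5, n_frames = 6,
                     dim = c(256, 256), seed = 6)
  sim <- simulate_wound(spec)
  meas <- measure_sequence(sim, fx_params(sigma = 1.5))
  gt <- ground_truth(sim)
  expect_true(all(abs(meas$area / gt$area_px2 - 1) < 0.03))
  expect_true(all(abs(meas$perim / gt$perimeter_px - 1) < 0.03))
})
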