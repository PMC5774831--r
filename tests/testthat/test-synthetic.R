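test_that("disk ground truth follows the closed forms", {
  spec <- wound_spec("disk", size = 100, velocity = 5, n_frames = 16,
                     noise_sd = 0, seed = 1)
  gt <- ground_truth(simulate_wound(spec))
  expect_equal(gt$area_px2[1], pi * 100^2, tolerance = 1e-10)
  expect_equal(gt$perimeter_px[1], 2 * pi * 100, tolerance = 1e-10)
  # t = 10 h: radius 50
  expect_equal(gt$area_px2[gt$time_h == 10], pi * 50^2, tolerance = 1e-10)
  expect_equal(gt$perimeter_px[gt$time_h == 10], 2 * pi * 50, tolerance = 1e-10)
})

test_that("rectangle erosion shrinks each side by twice the depth", {
  spec <- wound_spec("rectangle", size = c(200, 100), velocity = 10,
                     n_frames = 3, dim = c(300, 300), noise_sd = 0, seed = 1)
  sim <- simulate_wound(spec)
  gt <- ground_truth(sim)
  # eroded by 10 px after 1 h: 180 x 80
  expect_equal(gt$area_px2[2], 180 * 80)
  expect_equal(gt$perimeter_px[2], 2 * (180 + 80))
  # raster agrees exactly for the axis-aligned case (pixel centers)
  wound_px <- sum(sim$frames[[2]] < 0.4)
  expect_equal(wound_px, 180 * 80, tolerance = 0.02)
})

test_that("rasterized disk area matches pi r^2 within 2% for r >= 30", {
  for (r in c(30, 60, 100)) {
    spec <- wound_spec("disk", size = r, velocity = 0, n_frames = 2,
                       dim = c(2 * r + 21, 2 * r + 21), noise_sd = 0, seed = 1)
    sim <- simulate_wound(spec)
    expect_equal(sum(sim$frames[[1]] < 0.4), pi * r^2, tolerance = 0.02)
  }
})

test_that("consecutive analytic values recover v as -(dA/dt)/P for the disk", {
  spec <- wound_spec("disk", size = 100, velocity = 5, n_frames = 12,
                     noise_sd = 0, seed = 1)
  gt <- ground_truth(simulate_wound(spec))
  dA <- diff(gt$area_px2)
  Pbar <- (gt$perimeter_px[-1] + gt$perimeter_px[-nrow(gt)]) / 2
  v_hat <- -(dA / diff(gt$time_h)) / Pbar
  expect_true(all(abs(v_hat / 5 - 1) < 0.01))
})

test_that("same seed gives bit-identical frames, different seed does not", {
  spec <- wound_spec("disk", size = 40, velocity = 3, n_frames = 3,
                     dim = c(128, 128), seed = 42)
  s1 <- simulate_wound(spec)
  s2 <- simulate_wound(spec)
  expect_identical(s1$frames, s2$frames)
  spec2 <- wound_spec("disk", size = 40, velocity = 3, n_frames = 3,
                      dim = c(128, 128), seed = 43)
  expect_false(identical(simulate_wound(spec2)$frames, s1$frames))
})

test_that("a vanishing wound truncates ground truth and marks frames closed", {
  spec <- wound_spec("disk", size = 20, velocity = 5, n_frames = 8,
                     dim = c(96, 96), noise_sd = 0, seed = 1)
  gt <- ground_truth(simulate_wound(spec))
  expect_true(all(gt$closed[gt$time_h >= 4]))  # radius 20 - 5t <= 0
  expect_true(all(gt$area_px2[gt$closed] == 0))
  expect_false(any(gt$closed[gt$time_h < 4]))
})

test_that("ellipse raster area matches the inner Steiner formula while valid", {
  spec <- wound_spec("ellipse", size = c(160, 100), velocity = 4,
                     n_frames = 4, dim = c(256, 256), noise_sd = 0, seed = 1)
  sim <- simulate_wound(spec)
  gt <- ground_truth(sim)
  # min curvature radius b^2/a = 50^2/80 = 31.25 px > max depth 12 px: valid
  expect_false(anyNA(gt$area_px2))
  for (i in 1:4) {
    expect_equal(sum(sim$frames[[i]] < 0.4), gt$area_px2[i], tolerance = 0.02)
  }
  # past the curvature limit ground truth is NA but frames are still made
  spec2 <- wound_spec("ellipse", size = c(160, 100), velocity = 10,
                      n_frames = 5, dim = c(256, 256), noise_sd = 0, seed = 1)
  gt2 <- ground_truth(simulate_wound(spec2))
  expect_true(anyNA(gt2$area_px2))
})

test_that("convex polygon erosion agrees with the rectangle closed form", {
  # a square given as a generic convex polygon must reproduce the rectangle
  # formulas: (s - 2d)^2 area, 4(s - 2d) perimeter
  v <- rbind(c(50, 50), c(50, 150), c(150, 150), c(150, 50))
  spec <- wound_spec("polygon", vertices = v, velocity = 5, n_frames = 4,
                     dim = c(200, 200), noise_sd = 0, seed = 1)
  gt <- ground_truth(simulate_wound(spec))
  d <- gt$time_h * 5
  expect_equal(gt$area_px2, (100 - 2 * d)^2, tolerance = 1e-9)
  expect_equal(gt$perimeter_px, 4 * (100 - 2 * d), tolerance = 1e-9)
})

test_that("write_sequence + read_sequence round-trips frames and times", {
  spec <- wound_spec("disk", size = 30, velocity = 2, n_frames = 3,
                     dim = c(96, 96), interval = 0.5, seed = 9)
  sim <- simulate_wound(spec)
  dir <- withr::local_tempdir()
  paths <- write_sequence(sim, dir)
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  back <- read_sequence(paths, times = sim$times)
  q <- lapply(sim$frames, function(f) round(pmin(pmax(f, 0), 1) * 65535))
  got <- lapply(back$frames, function(f) round(f))  # as.is=TRUE gives 0..65535
  expect_equal(got, q)
  expect_equal(back$times, c(0, 0.5, 1))
})
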