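# GP fits on analytic series (no imaging) keep these tests fast and make the
# expected values exact closed forms.

gp_pair_from_truth <- function(gt, noise_area = 0, noise_perim = 0) {
  keep <- !gt$closed & !is.na(gt$area_px2)
  list(
    area = gp_fit(gt$time_h[keep], gt$area_px2[keep], noise_area),
    perim = gp_fit(gt$time_h[keep], gt$perimeter_px[keep], noise_perim)
  )
}

test_that("a shrinking disk yields a flat profile at the true front speed", {
  gt <- ground_truth(simulate_wound(
    wound_spec("disk", size = 100, velocity = 5, n_frames = 16, noise_sd = 0)))
  gps <- gp_pair_from_truth(gt, noise_area = 50^2, noise_perim = 2^2)
  prof <- velocity_profile(gps$area, gps$perim, n_grid = 101)
  v <- prof$velocity[is.finite(prof$velocity)]
  expect_equal(mean(v), 5, tolerance = 0.02)
  expect_lt(sd(v) / mean(v), 0.02)                  # constant over time
  wm <- weighted_mean_velocity(prof)
  expect_equal(wm$estimate, 5, tolerance = 0.02)
})

test_that("a static wound has zero velocity", {
  t <- 0:10
  area <- rep(12000, 11); perim <- rep(400, 11)
  gp_a <- gp_fit(t, area, 30^2)
  gp_p <- gp_fit(t, perim, 2^2)
  prof <- velocity_profile(gp_a, gp_p)
  expect_equal(max(abs(prof$velocity), na.rm = TRUE), 0, tolerance = 1e-6)
})

test_that("velocity scales linearly with area and inversely with perimeter", {
  gt <- ground_truth(simulate_wound(
    wound_spec("disk", size = 80, velocity = 4, n_frames = 10, noise_sd = 0)))
  g <- gp_pair_from_truth(gt)
  base <- velocity_profile(g$area, g$perim)$velocity
  gt2 <- dplyr::mutate(gt, area_px2 = 2 * area_px2)
  g2 <- gp_pair_from_truth(gt2)
  expect_equal(velocity_profile(g2$area, g2$perim)$velocity, 2 * base,
               tolerance = 1e-6)
  gt3 <- dplyr::mutate(gt, perimeter_px = 2 * perimeter_px)
  g3 <- gp_pair_from_truth(gt3)
  expect_equal(velocity_profile(g3$area, g3$perim)$velocity, base / 2,
               tolerance = 1e-6)
})

test_that("velocity uncertainty follows the propagation formula", {
  set.seed(21)
  t <- 0:9
  gp_a <- gp_fit(t, 30000 - 1500 * t + 20 * t^2 + rnorm(10, 0, 100), 100^2)
  gp_p <- gp_fit(t, 600 - 12 * t + rnorm(10, 0, 4), 4^2)
  grid <- seq(0, 9, length.out = 31)
  prof <- velocity_profile(gp_a, gp_p, times = grid)
  pa <- predict(gp_a, grid); pp <- predict(gp_p, grid)
  h <- diff(grid)[1]
  i <- 5L  # arbitrary interior index
  adot <- (pa$.pred[i + 1] - pa$.pred[i - 1]) / (2 * h)
  adot_sd <- sqrt(pa$.pred_sd[i + 1]^2 + pa$.pred_sd[i - 1]^2) / (2 * h)
  expect_equal(prof$velocity[i], -adot / pp$.pred[i], tolerance = 1e-12)
  expect_equal(prof$velocity_sd[i],
               sqrt((adot_sd / pp$.pred[i])^2 +
                    (adot * pp$.pred_sd[i] / pp$.pred[i]^2)^2),
               tolerance = 1e-12)
  # endpoints carry no central difference
  expect_true(is.na(prof$velocity[1]) && is.na(prof$velocity[31]))
})

test_that("halving the grid spacing changes the velocity by < 1%", {
  gt <- ground_truth(simulate_wound(
    wound_spec("disk", size = 90, velocity = 4, n_frames = 12, noise_sd = 0)))
  g <- gp_pair_from_truth(gt, 40^2, 2^2)
  p1 <- velocity_profile(g$area, g$perim, times = seq(0, 11, length.out = 51))
  p2 <- velocity_profile(g$area, g$perim, times = seq(0, 11, length.out = 101))
  common <- intersect(round(p1$time, 9), round(p2$time, 9))
  v1 <- p1$velocity[match(common, round(p1$time, 9))]
  v2 <- p2$velocity[match(common, round(p2$time, 9))]
  ok <- is.finite(v1) & is.finite(v2)
  expect_lt(max(abs(v1[ok] / v2[ok] - 1)), 0.01)
})

test_that("shrinking detection variance shrinks velocity uncertainty", {
  gt <- ground_truth(simulate_wound(
    wound_spec("disk", size = 90, velocity = 4, n_frames = 12, noise_sd = 0)))
  noisy <- gp_pair_from_truth(gt, noise_area = 200^2, noise_perim = 8^2)
  quiet <- gp_pair_from_truth(gt, noise_area = 50^2, noise_perim = 2^2)
  sd_noisy <- velocity_profile(noisy$area, noisy$perim)$velocity_sd
  sd_quiet <- velocity_profile(quiet$area, quiet$perim)$velocity_sd
  expect_lt(mean(sd_quiet, na.rm = TRUE), mean(sd_noisy, na.rm = TRUE))
})

test_that("the weighted mean reduces correctly in closed-form cases", {
  prof <- tibble::tibble(velocity = c(2, 4, 6), velocity_sd = c(1, 1, 1))
  expect_equal(weighted_mean_velocity(prof)$estimate, 4)   # uniform weights
  expect_equal(weighted_mean_velocity(prof)$std_error, 1 / sqrt(3))
  prof2 <- tibble::tibble(velocity = c(1, 3), velocity_sd = c(1, sqrt(1 / 3)))
  expect_equal(weighted_mean_velocity(prof2)$estimate, 2.5) # w = 1, 3
})

test_that("area slope is the OLS readout and carries the geometry confound", {
  t <- 0:8
  exact <- area_slope(tibble::tibble(time = t, area = 5e4 - 1000 * t))
  expect_equal(exact$estimate, -1000, tolerance = 1e-10)
  flat <- area_slope(tibble::tibble(time = t, area = rep(2e4, 9)))
  expect_equal(flat$estimate, 0, tolerance = 1e-10)
  expect_error(area_slope(tibble::tibble(time = rep(1, 5), area = 1:5)),
               "equal")
  # same true velocity, different radius -> very different slopes
  g1 <- ground_truth(simulate_wound(
    wound_spec("disk", size = 60, velocity = 4, n_frames = 8, noise_sd = 0)))
  g2 <- ground_truth(simulate_wound(
    wound_spec("disk", size = 100, velocity = 4, n_frames = 8, noise_sd = 0)))
  s1 <- area_slope(g1, time_h, area_px2)$estimate
  s2 <- area_slope(g2, time_h, area_px2)$estimate
  expect_gt(abs(s2 / s1), 1.5)
})

test_that("SNR arithmetic and its degenerate cases", {
  df <- tibble::tibble(
    condition = rep(c("a", "base"), each = 3),
    value = c(10, 10, 10, 2, 4, 6)
  )
  out <- condition_snr(df, condition, value, baseline = "base")
  expect_equal(out$snr[out$condition == "a"], (10 - 4) / 2)
  expect_true(is.na(out$snr[out$condition == "base"]))

  same <- tibble::tibble(condition = rep(c("a", "base"), each = 2),
                         value = c(4, 4, 4, 4))
  # equal means -> SNR 0 ... but a zero-spread baseline is undefined instead
  expect_warning(o2 <- condition_snr(same, condition, value, baseline = "base"),
                 "undefined")
  expect_true(all(is.na(o2$snr)))

  shifted <- tibble::tibble(condition = rep(c("a", "base"), each = 2),
                            value = c(5, 5, 4, 6))
  o3 <- condition_snr(shifted, condition, value, baseline = "base")
  expect_equal(o3$snr[o3$condition == "a"],
               (5 - 5) / sd(c(4, 6)) + 0)            # equal means -> 0
  expect_error(condition_snr(df, condition, value, baseline = "nope"),
               "not present")
})
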