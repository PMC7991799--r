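test_that("closure series compute DT and its smoothing correctly", {
  t <- seq(0, 4, by = 0.5)
  # constant areas: DT and smoothed DT identically zero
  s0 <- area_series(t_hours = t, pixel_size_um = 2, wound_length_um = 100,
                    area_px = rep(500, 9))
  expect_true(all(s0$DT_um2 == 0) && all(s0$smoothed_DT_um2 == 0))

  # arithmetic closure: DT = 0, 1000, 2000, ... and smoothing keeps the slope
  s1 <- area_series(t_hours = t, pixel_size_um = 1, wound_length_um = 100,
                    area_um2 = 10000 - 1000 * (0:8))
  expect_equal(s1$DT_um2, 1000 * (0:8))
  expect_equal(diff(s1$smoothed_DT_um2[7:9]), c(1000, 1000))

  # conversion: area_um2 = area_px * pixel_size^2, DT referenced to frame 0
  s2 <- area_series(t_hours = t, pixel_size_um = 2, wound_length_um = 100,
                    area_px = c(100, 90, 95, 80, 70, 60, 50, 40, 30))
  expect_equal(s2$area_um2, c(100, 90, 95, 80, 70, 60, 50, 40, 30) * 4)
  expect_equal(s2$DT_um2[3], abs(100 - 95) * 4)
  expect_equal(s2$DT_um2[1], 0)
  expect_true(all(s2$DT_um2 >= 0))
})

test_that("trailing moving average matches a brute-force oracle", {
  set.seed(31)
  for (k in 1:5) {
    x <- runif(40, 0, 1e4)
    s <- area_series(t_hours = seq_along(x), pixel_size_um = 1,
                     wound_length_um = 10, area_um2 = x[1] + abs(x - x[1]))
    expect_equal(s$smoothed_DT_um2, trailing_mean_oracle(s$DT_um2, 6),
                 tolerance = 1e-12)
  }
})

test_that("build_series accepts wound masks and enforces preconditions", {
  mk <- function(n) { m <- matrix(FALSE, 10, 10); m[1:n, ] <- TRUE; m }
  masks <- lapply(c(5, 4, 3), mk)
  s <- build_series(masks, t_hours = c(0, 1, 2), pixel_size_um = 3,
                    wound_length_um = 30)
  expect_equal(s$area_um2, c(50, 40, 30) * 9)
  expect_error(build_series(list(), 1, 1, 1), "empty")
  expect_error(build_series(masks, c(0, 1, 1), 1, 10), "increasing")
  expect_error(build_series(masks, c(0, 1, 2), 1, -5), "wound_length")
})

test_that("wound length equals the field extent for spanning scratches", {
  # vertical full-height band in a 1000-um-tall field
  band <- matrix(FALSE, 100, 150); band[, 60:90] <- TRUE
  expect_equal(estimate_wound_length(band, 10), 1000)
  # the same geometry rotated 90 degrees measures along the width
  expect_equal(estimate_wound_length(t(band), 10), 1000)
  expect_error(estimate_wound_length(matrix(FALSE, 5, 5), 1), "empty mask")
})

test_that("wound length tracks a tilted synthetic scratch within 2%", {
  cfg <- sim_config(scratch_angle_deg = 10, seed = 13)
  gt <- gt_gap_mask(cfg, 0)
  # programmed length: the field height along a 10-degree tilted axis
  expected <- nrow(gt) * cfg$pixel_size_um / cos(10 * pi / 180)
  est <- estimate_wound_length(gt, cfg$pixel_size_um)
  expect_lt(abs(est - expected) / expected, 0.02)
})

test_that("edge velocity is area rate over length over two edges", {
  expect_equal(edge_velocity(0, 1, 100), 0)
  expect_equal(edge_velocity(2000, 1, 1000), 1)
  set.seed(17)
  for (k in 1:20) {
    dA <- runif(1, 0, 1e5); dt <- runif(1, 0.1, 5); L <- runif(1, 100, 2000)
    expect_equal(edge_velocity(dA, dt, L), dA / dt / L / 2, tolerance = 1e-15)
  }
  expect_error(edge_velocity(100, 0, 10), "dt_hours")
  expect_error(edge_velocity(100, 1, 0), "L_um")
})

test_that("window fits recover exact lines and match closed-form OLS", {
  t <- seq(0, 12, by = 1 / 6)
  L <- 480
  # d(t) = 10 t um exactly: area closes at 2 L * 10 um^2/h
  s <- area_series(t_hours = t, pixel_size_um = 1, wound_length_um = L,
                   area_um2 = 1e6 - 2 * L * 10 * t)
  est <- fit_window(s, c(5, 11))
  expect_equal(est$v_um_per_h, 10, tolerance = 1e-9)
  expect_equal(est$r2, 1, tolerance = 1e-9)

  # constant displacement fits a zero slope
  s0 <- area_series(t_hours = t, pixel_size_um = 1, wound_length_um = L,
                    area_um2 = rep(5e5, length(t)))
  expect_equal(fit_window(s0, c(5, 11))$v_um_per_h, 0)

  # noisy series against the closed-form oracle
  set.seed(23)
  noisy <- 1e6 - 2 * L * 8 * t + rnorm(length(t), sd = 4000)
  sn <- area_series(t_hours = t, pixel_size_um = 1, wound_length_um = L,
                    area_um2 = noisy)
  estn <- fit_window(sn, c(5, 11))
  sel <- t >= 5 & t <= 11
  orc <- ols_oracle(t[sel], sn$smoothed_DT_um2[sel] / (2 * L))
  expect_equal(estn$v_um_per_h, orc$slope, tolerance = 1e-9)
  expect_equal(estn$sem, orc$sem, tolerance = 1e-9)
  expect_equal(estn$r2, orc$r2, tolerance = 1e-9)
  expect_equal(estn$ci95, orc$ci95, tolerance = 1e-9)
  expect_true(estn$ci95[1] <= estn$v_um_per_h && estn$v_um_per_h <= estn$ci95[2])

  expect_error(fit_window(s, c(11, 5)), "window")
  expect_error(fit_window(s, c(11.9, 12)), "fewer than 3")
})

test_that("every window past smoothing warm-up sees the same noiseless slope", {
  t <- seq(0, 12, by = 1 / 6)
  s <- area_series(t_hours = t, pixel_size_um = 1, wound_length_um = 480,
                   area_um2 = 1e6 - 2 * 480 * 12 * t)
  # trailing smoothing is only a pure shift once N frames have accumulated
  for (a in seq(1, 6, 0.5)) {
    expect_equal(fit_window(s, c(a, a + 6))$v_um_per_h, 12, tolerance = 1e-9)
  }
})

test_that("velocity and area scale with pixel size as geometry dictates", {
  mk <- function(n) { m <- matrix(FALSE, 50, 60); m[, 20:(20 + n)] <- TRUE; m }
  masks <- lapply(seq(30, 10, -2), mk)
  t <- seq(0, 10, by = 1)
  s1 <- build_series(masks, t, pixel_size_um = 1,
                     wound_length_um = estimate_wound_length(masks[[1]], 1))
  s2 <- build_series(masks, t, pixel_size_um = 2,
                     wound_length_um = estimate_wound_length(masks[[1]], 2))
  expect_equal(s2$area_um2, 4 * s1$area_um2)    # areas scale with px^2
  v1 <- fit_window(s1, c(2, 10))$v_um_per_h
  v2 <- fit_window(s2, c(2, 10))$v_um_per_h
  expect_equal(v2, 2 * v1, tolerance = 1e-12)   # velocities scale with px
})

test_that("find_linear_window prefers the longest passing window", {
  t <- seq(0, 12, by = 1 / 6)
  lin <- area_series(t_hours = t, pixel_size_um = 1, wound_length_um = 480,
                     area_um2 = 1e6 - 2 * 480 * 10 * t)
  fw <- find_linear_window(lin)
  expect_equal(fw$window, c(0, 12))
  expect_true(fw$meets_threshold)
  expect_gt(fw$estimate$r2, 0.985)

  # pure noise: no window passes; the best sub-threshold fit is flagged
  set.seed(41)
  noise <- area_series(t_hours = t, pixel_size_um = 1, wound_length_um = 480,
                       area_um2 = 5e5 + rnorm(length(t), sd = 2e4))
  fn <- find_linear_window(noise)
  expect_false(fn$meets_threshold)
  expect_lt(fn$estimate$r2, 0.985)

  short <- area_series(t_hours = seq(0, 3, 1 / 6), pixel_size_um = 1,
                       wound_length_um = 480,
                       area_um2 = 1e5 - 100 * seq(0, 3, 1 / 6))
  expect_error(find_linear_window(short), "shorter")
})

test_that("replicate SEM stays below half the predicted 95% CI width", {
  set.seed(53)
  reps <- lapply(1:8, function(i) {
    s <- simulate_noisy_series(15)
    fit_window(s, c(5, 11))
  })
  v <- vapply(reps, function(e) e$v_um_per_h, numeric(1))
  sem_rep <- sd(v) / sqrt(length(v))
  ci_half <- mean(vapply(reps, function(e) diff(e$ci95) / 2, numeric(1)))
  expect_lt(sem_rep, ci_half)
})
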