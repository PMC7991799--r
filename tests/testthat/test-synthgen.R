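test_that("sim_config validates its physical constraints", {
  expect_error(sim_config(scratch_width_um = 900), "smaller than the field")
  expect_error(sim_config(noise_sigma = -1), ">= 0")
  expect_s3_class(preset_config("hard"), "sim_config")
})

test_that("identical configurations render bit-identical sequences", {
  cfg <- preset_config("hard", seed = 99)
  a <- simulate_sequence(cfg, frames = c(1L, 40L))
  b <- simulate_sequence(cfg, frames = c(1L, 40L))
  expect_identical(a$frames[[2]]$pixels, b$frames[[2]]$pixels)
  expect_identical(a$gt_masks, b$gt_masks)
  # a different seed changes the pixels
  c2 <- simulate_sequence(preset_config("hard", seed = 100), frames = 40L)
  expect_false(identical(a$frames[[2]]$pixels, c2$frames[[1]]$pixels))
})

test_that("subset rendering reproduces the same frames as a full render", {
  cfg <- sim_config(seed = 3, duration_hours = 3, pioneer_rate_per_h = 2,
                    debris_count = 3)
  full <- simulate_sequence(cfg)
  sub <- simulate_sequence(cfg, frames = c(2L, 11L, 19L))
  for (j in seq_along(sub$frame_index)) {
    k <- sub$frame_index[j]
    expect_identical(sub$frames[[j]]$pixels, full$frames[[k]]$pixels)
    expect_identical(sub$gt_masks[[j]], full$gt_masks[[k]])
  }
})

test_that("linear kinetics place the edges exactly where programmed", {
  # v = 15 um/h from 500 um: gap width at t = 10 h is 500 - 2*15*10 = 200 um
  cfg <- sim_config(edge_speed_um_per_h = 15, edge_roughness_um = 0, seed = 2)
  gt <- gt_gap_mask(cfg, 10)
  width_px <- colSums(t(gt))  # per-row gap width
  width_px <- width_px[width_px > 0]
  expect_true(all(abs(width_px * cfg$pixel_size_um - 200) <= cfg$pixel_size_um))
  sq <- simulate_sequence(cfg, frames = c(1L, 31L, 61L))
  expect_equal(sq$gt_edge_disp_um, 15 * sq$t_hours)
})

test_that("ground-truth areas follow the analytic shrinking band", {
  cfg <- sim_config(edge_speed_um_per_h = 15, edge_roughness_um = 0, seed = 2)
  sq <- simulate_sequence(cfg, frames = seq(1L, 61L, 10L))
  # analytic: A(t) = L * (w0 - 2 v t); rasterisation adds <= 1 px per row
  L_px <- cfg$grid[1]
  analytic <- L_px * (500 - 2 * 15 * sq$t_hours) / cfg$pixel_size_um
  observed <- sq$gt_area_um2 / cfg$pixel_size_um^2
  expect_true(all(abs(observed - analytic) <= L_px))
  # affine in t with slope -2 v L
  slope <- coef(lm(sq$gt_area_um2 ~ sq$t_hours))[2]
  expect_equal(unname(slope), -2 * 15 * L_px * cfg$pixel_size_um,
               tolerance = 0.01)
})

test_that("fast closure empties the ground truth and stays empty", {
  cfg <- sim_config(edge_speed_um_per_h = 25, seed = 5)  # closes at t = 10
  sq <- simulate_sequence(cfg, frames = c(55L, 61L, 73L))
  expect_gt(sum(sq$gt_masks[[1]]), 0)   # t = 9 h: still open
  expect_equal(sum(sq$gt_masks[[2]]), 0)  # t = 10 h: closed
  expect_equal(sum(sq$gt_masks[[3]]), 0)
})

test_that("rendered frames carry the textured/smooth entropy contrast", {
  cfg <- sim_config(seed = 19, noise_sigma = 0, illumination_gradient_pct = 0)
  sq <- simulate_sequence(cfg, frames = 10L)
  fr <- sq$frames[[1]]; gt <- sq$gt_masks[[1]]
  # noise-free gap: near-zero LOCAL intensity variance (the smooth
  # background field itself may drift on large scales)
  img <- fr$pixels / 65535
  core <- gt & !woundkit:::.with_reflect_pad(1 - gt, 6, function(p)
    as.matrix(EBImage::imageData(EBImage::dilate(
      EBImage::Image(p), EBImage::makeBrush(13, "disc"))))) > 0.5
  highpass <- img - smooth_average(img, 9)
  expect_lt(sd(highpass[core]), 0.01)
  # local entropy medians: monolayer above gap
  ent <- entropy_enhance(img, 4)
  expect_gt(median(ent[!gt]), median(ent[core]) + 0.2)
})

test_that("pioneer cells appear only after hour 6, inside the gap", {
  cfg <- sim_config(seed = 23, pioneer_rate_per_h = 4)
  assets <- woundkit:::.sim_assets(cfg)
  expect_gt(length(assets$pioneers), 0)
  t_appear <- vapply(assets$pioneers, function(p) assets$t_all[p$frame], numeric(1))
  expect_true(all(t_appear > 6))
  # pioneers brighten pixels inside the ground-truth gap
  i <- assets$pioneers[[1]]$frame
  with_p <- simulate_sequence(cfg, frames = i)
  cfg0 <- sim_config(seed = 23, pioneer_rate_per_h = 0)
  without <- simulate_sequence(cfg0, frames = i)
  diffpx <- with_p$frames[[1]]$pixels != without$frames[[1]]$pixels
  expect_gt(sum(diffpx), 0)
  expect_true(all(with_p$gt_masks[[1]][diffpx]))
  # ground truth still counts the pioneer area as gap
  expect_identical(with_p$gt_masks[[1]], without$gt_masks[[1]])
})

test_that("harder imaging conditions degrade segmentation accuracy", {
  err_at <- function(noise, gradient) {
    errs <- c()
    for (s in 1:5) {
      cfg <- sim_config(seed = 200 + s, noise_sigma = noise,
                        illumination_gradient_pct = gradient)
      sq <- simulate_sequence(cfg, frames = 20L)
      wm <- detect_gap(enhance(sq$frames[[1]], benchmark_filter_params()),
                       threshold_config(), min_area_px = 4800)
      errs <- c(errs, area_error_pct(wm, sq$gt_masks[[1]]))
    }
    mean(errs)
  }
  base <- err_at(0.01, 5)
  noisy <- err_at(0.05, 5)
  shaded <- err_at(0.01, 25)
  expect_gt(noisy, base)
  expect_gt(shaded, base)
})

test_that("benchmark libraries round-trip through scan_library", {
  out <- file.path(withr::local_tempdir(), "lib")
  bm <- write_benchmark(out, preset = "linear-easy", n_positions = 3L,
                        seed = 1L, duration_hours = 1)
  man <- scan_library(out)
  expect_identical(man$positions$position_id, c("pos01", "pos02", "pos03"))
  expect_identical(man$positions$n_frames, rep(7L, 3))
  gt_files <- list.files(file.path(bm$gt_root, "pos01"))
  expect_length(gt_files, 7L)
  # written frames decode back to the simulated pixels
  sq <- simulate_sequence(bm$configs$pos01, frames = 3L)
  f <- read_frame(man$files$pos01[3], bit_depth = 16L,
                  pixel_size_um = bm$configs$pos01$pixel_size_um)
  expect_identical(f$pixels, sq$frames[[1]]$pixels)
  gt <- read_mask(file.path(bm$gt_root, "pos01", "frame_0002.png"))
  expect_identical(gt, sq$gt_masks[[1]])
})
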