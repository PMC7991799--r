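# End-to-end orchestration over a library directory: segment every frame of
# every position to mask files + a per-frame table, then turn the tables
# into closure series, window fits and treatment comparisons.

#' Segment every frame of a library
#'
#' Runs [enhance()] + [detect_gap()] over all positions and frames, writes
#' each binary mask to a mirror directory (`<root>_masks` by default,
#' mirroring file names), and returns the per-frame log.
#'
#' @param root Library root directory (see [scan_library()]).
#' @param bit_depth,pixel_size_um Acquisition metadata.
#' @param frame_interval_hours Hours between frames.
#' @param params A [filter_params()]; radii must match the acquisition
#'   resolution.
#' @param cfg A [threshold_config()].
#' @param min_gap_area_um2 Minimum credible gap area in square micrometres
#'   (converted to px internally; default 3e4, several cell areas).
#' @param smooth_radius Mask smoothing radius, px.
#' @param mask_dir Output directory for masks; `NULL` disables writing.
#' @param metadata Optional per-position metadata (see [scan_library()]);
#'   defaults to `<root>/metadata.csv` when present.
#' @param verbose Print one log line per frame.
#' @return Data frame: `position_id`, `frame_index`, `t_hours`,
#'   `threshold`, `retries`, `gap_area_px`, `gap_area_um2`, `is_empty`,
#'   `mask_file`.
#' @export
segment_library <- function(root, bit_depth = 16L, pixel_size_um = 1,
                            frame_interval_hours = 1 / 6,
                            params = filter_params(),
                            cfg = threshold_config(bit_depth = bit_depth),
                            min_gap_area_um2 = 3e4, smooth_radius = 2,
                            mask_dir = paste0(root, "_masks"),
                            metadata = NULL, verbose = FALSE) {
  meta_file <- file.path(root, "metadata.csv")
  if (is.null(metadata) && file.exists(meta_file)) {
    metadata <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
    if ("pixel_size_um" %in% names(metadata)) pixel_size_um <- metadata$pixel_size_um[1]
    if ("frame_interval_hours" %in% names(metadata))
      frame_interval_hours <- metadata$frame_interval_hours[1]
    if ("bit_depth" %in% names(metadata)) {
      bit_depth <- as.integer(metadata$bit_depth[1])
      cfg <- threshold_config(T = cfg$T, bit_depth = bit_depth,
                              low_contrast = cfg$low_contrast,
                              max_retries = cfg$max_retries,
                              retry_factor = cfg$retry_factor)
    }
  }
  manifest <- scan_library(root, frame_interval_hours, metadata)
  min_area_px <- max(1, round(min_gap_area_um2 / pixel_size_um^2))
  rows <- list()
  for (pid in manifest$positions$position_id) {
    fs <- manifest$files[[pid]]
    for (i in seq_along(fs)) {
      fr <- read_frame(fs[i], bit_depth, pixel_size_um,
                       t_hours = (i - 1) * frame_interval_hours,
                       position_id = pid, frame_index = i - 1L)
      wm <- detect_gap(enhance(fr, params), cfg, min_area_px = min_area_px,
                       smooth_radius = smooth_radius)
      mask_file <- NA_character_
      if (!is.null(mask_dir)) {
        mask_file <- file.path(mask_dir, pid,
                               paste0(tools::file_path_sans_ext(basename(fs[i])),
                                      "_mask.png"))
        write_mask(wm, mask_file)
      }
      if (verbose)
        message(sprintf("%s frame %d: thr=%.4g retries=%d area=%d px%s",
                        pid, i - 1L, wm$threshold_used, wm$retries_used,
                        wm$area_px, if (wm$is_empty) " (empty)" else ""))
      rows[[length(rows) + 1]] <- data.frame(
        position_id = pid, frame_index = i - 1L,
        t_hours = fr$t_hours, threshold = wm$threshold_used,
        retries = wm$retries_used, gap_area_px = wm$area_px,
        gap_area_um2 = wm$area_px * pixel_size_um^2,
        is_empty = wm$is_empty, mask_file = mask_file,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "frame_interval_hours") <- frame_interval_hours
  out
}

#' Analyze a segmented library: closure series and window fits
#'
#' Builds one closure series per position from the per-frame segmentation
#' table, estimates the wound length from the first non-empty mask of each
#' position, and fits the edge velocity over the given time window.
#'
#' @param seg Per-frame table from [segment_library()].
#' @param window Fit window `(t_start, t_end)` in hours (default 5-11 h, the
#'   interval where closure is near-linear across cell lines).
#' @param N Smoothing window in frames (default 6).
#' @param wound_length_um Optional fixed wound length override; by default
#'   it is estimated per position from the first non-empty mask.
#' @param mask_dir Directory holding the masks written by
#'   [segment_library()] (needed for the wound-length estimate unless
#'   `wound_length_um` is given).
#' @return List with `series` (closure series per position) and `estimates`
#'   (one `velocity_estimate` per position).
#' @export
analyze_library <- function(seg, window = c(5, 11), N = 6L,
                            wound_length_um = NULL, mask_dir = NULL) {
  px <- attr(seg, "pixel_size_um")
  if (is.null(px)) .stopf("segmentation table lacks pixel size metadata")
  series <- list(); estimates <- list()
  for (pid in unique(seg$position_id)) {
    sub <- seg[seg$position_id == pid, , drop = FALSE]
    sub <- sub[order(sub$frame_index), , drop = FALSE]
    L <- wound_length_um
    if (is.null(L)) {
      nz <- which(!sub$is_empty)
      if (length(nz) == 0) .stopf("position '%s' has no non-empty mask", pid)
      mf <- sub$mask_file[nz[1]]
      if (is.na(mf) && !is.null(mask_dir))
        mf <- file.path(mask_dir, pid, paste0("frame_", sprintf("%04d", nz[1] - 1), "_mask.png"))
      if (is.na(mf) || !file.exists(mf))
        .stopf("no mask file for wound-length estimate of '%s'; pass wound_length_um", pid)
      L <- estimate_wound_length(read_mask(mf), px)
    }
    s <- area_series(t_hours = sub$t_hours, pixel_size_um = px,
                     wound_length_um = L, area_px = sub$gap_area_px,
                     N = N, position_id = pid)
    series[[pid]] <- s
    estimates[[pid]] <- fit_window(s, window)
  }
  list(series = series, estimates = estimates)
}

#' Validate segmentation masks against a ground-truth mirror
#'
#' Pairs each mask under `mask_dir` with the same-position, same-index mask
#' under `gt_dir` and reports per-frame area error and detection success. A
#' frame counts as correctly detected when mask and truth are both empty, or
#' both non-empty with intersection-over-union at least `iou_min`.
#'
#' @param mask_dir Directory of predicted masks ([segment_library()] layout).
#' @param gt_dir Ground-truth directory ([write_benchmark()] layout).
#' @param iou_min IoU threshold for calling a detection correct
#'   (default 0.5).
#' @return Data frame: `position_id`, `frame_index`, `area_error_pct`,
#'   `iou`, `detected`; with attribute `summary` (mean error over frames
#'   with non-empty truth, detection rate).
#' @export
validate_library <- function(mask_dir, gt_dir, iou_min = 0.5) {
  positions <- basename(sort(list.dirs(mask_dir, recursive = FALSE)))
  if (length(positions) == 0) .stopf("no positions under '%s'", mask_dir)
  rows <- list()
  for (pid in positions) {
    pm <- sort(list.files(file.path(mask_dir, pid), full.names = TRUE))
    pg <- sort(list.files(file.path(gt_dir, pid), full.names = TRUE))
    if (length(pm) != length(pg))
      .stopf("frame count mismatch for position '%s'", pid)
    for (i in seq_along(pm)) {
      m <- read_mask(pm[i]); g <- read_mask(pg[i])
      rows[[length(rows) + 1]] <- data.frame(
        position_id = pid, frame_index = i - 1L,
        area_error_pct = area_error_pct(m, g), iou = mask_iou(m, g),
        detected = (sum(m) == 0 && sum(g) == 0) ||
          (sum(m) > 0 && sum(g) > 0 && mask_iou(m, g) >= iou_min),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  has_gt <- is.finite(out$area_error_pct)
  attr(out, "summary") <- list(
    mean_area_error_pct = mean(out$area_error_pct[has_gt]),
    detection_rate = mean(out$detected))
  out
}
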