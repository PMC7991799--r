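#' Construct a single time-lapse frame
#'
#' A frame couples one grayscale intensity grid with the acquisition metadata
#' the downstream kinetics need: camera bit depth, physical pixel size and
#' the acquisition time relative to the scratch.
#'
#' @param pixels Integer matrix of non-negative intensities.
#' @param bit_depth Camera bit depth, 8 or 16.
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param t_hours Acquisition time in hours since the scratch (>= 0).
#' @param position_id Identifier of the imaging position (stage position).
#' @param frame_index Zero-based index of the frame within its position.
#'
#' @return An object of class `wound_frame`.
#' @export
wound_frame <- function(pixels, bit_depth, pixel_size_um, t_hours = 0,
                        position_id = "pos", frame_index = 0L) {
  if (!is.matrix(pixels)) .stopf("pixels must be a matrix")
  if (!bit_depth %in% c(8L, 16L)) .stopf("bit_depth must be 8 or 16")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    .stopf("pixel_size_um must be > 0")
  if (t_hours < 0) .stopf("t_hours must be >= 0")
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0)) .stopf("negative intensities in frame")
  if (max(pixels) >= 2^bit_depth)
    .stopf("intensity %d exceeds %d-bit range", max(pixels), bit_depth)
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um, t_hours = t_hours,
         position_id = position_id, frame_index = as.integer(frame_index)),
    class = "wound_frame")
}

#' @export
print.wound_frame <- function(x, ...) {
  cat(sprintf("<wound_frame> %s #%d  %dx%d px, %d-bit, %.3g um/px, t = %.2f h\n",
              x$position_id, x$frame_index, nrow(x$pixels), ncol(x$pixels),
              x$bit_depth, x$pixel_size_um, x$t_hours))
  invisible(x)
}

#' Read one grayscale image file as a frame
#'
#' Decodes a TIFF/PNG/JPEG image. RGB images are converted to luminance with
#' the Rec. 601 weights (0.299, 0.587, 0.114); multi-plane images use the
#' first plane with a warning.
#'
#' @inheritParams wound_frame
#' @param path Image file path.
#' @return A [wound_frame()].
#' @export
read_frame <- function(path, bit_depth = 16L, pixel_size_um = 1,
                       t_hours = 0, position_id = "pos", frame_index = 0L) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) .stopf("cannot decode '%s': %s", path,
                                             conditionMessage(e)))
  d <- dim(img)
  dat <- EBImage::imageData(img)
  if (length(d) == 3L) {
    if (EBImage::colorMode(img) == EBImage::Color && d[3] >= 3) {
      dat <- 0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    } else {
      warning(sprintf("'%s' has %d planes; using the first", path, d[3]))
      dat <- dat[, , 1]
    }
  }
  # EBImage scales intensities into [0,1]; map back onto integer levels
  px <- round(t(dat) * (2^bit_depth - 1))
  px[px < 0] <- 0L
  wound_frame(px, bit_depth, pixel_size_um, t_hours, position_id, frame_index)
}

#' Scan a time-lapse library directory
#'
#' A library is a directory with one sub-folder per imaging position, each
#' holding the frames of that position as TIFF/PNG/JPEG files. Frames are
#' ordered by the last integer in the file name (natural counter order);
#' positions are listed lexicographically.
#'
#' @param root Library root directory.
#' @param frame_interval_hours Hours between consecutive frames
#'   (default `1/6`, i.e. 10 min).
#' @param metadata Optional data.frame with columns `position_id`,
#'   `treatment` and `control` (logical) supplying per-position labels; or a
#'   path to a CSV with those columns. Positions absent from the table get
#'   `treatment = "none"`, `control = TRUE`.
#' @return A `library_manifest`: list with `root`, `frame_interval_hours`,
#'   `positions` (data.frame: position_id, n_frames, treatment, control) and
#'   `files` (named list of ordered frame paths).
#' @export
scan_library <- function(root, frame_interval_hours = 1 / 6, metadata = NULL) {
  if (!dir.exists(root)) .stopf("library root not found: %s", root)
  pos_dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(pos_dirs) == 0) .stopf("no positions found in '%s'", root)
  exts <- c("tif", "tiff", "png", "jpg", "jpeg")
  files <- list()
  for (d in pos_dirs) {
    fs <- list.files(d, full.names = TRUE)
    fs <- fs[!dir.exists(fs)]
    if (length(fs) == 0) .stopf("no positions found in '%s' (empty folder %s)", root, basename(d))
    bad <- fs[!tolower(tools::file_ext(fs)) %in% exts]
    if (length(bad) > 0)
      .stopf("non-image file in position '%s': %s", basename(d), basename(bad[1]))
    fs <- fs[.natural_order(fs)]
    dims <- vapply(fs, function(f) {
      img <- tryCatch(EBImage::readImage(f),
                      error = function(e) .stopf("cannot decode '%s'", f))
      dim(img)[1:2]
    }, numeric(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      .stopf("inconsistent sequence: mixed image dimensions in position '%s'",
             basename(d))
    files[[basename(d)]] <- fs
  }
  if (is.character(metadata)) metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  ids <- names(files)
  pos <- data.frame(position_id = ids,
                    n_frames = vapply(files, length, integer(1)),
                    treatment = "none", control = TRUE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(metadata)) {
    m <- match(pos$position_id, metadata$position_id)
    hit <- !is.na(m)
    if ("treatment" %in% names(metadata)) pos$treatment[hit] <- metadata$treatment[m[hit]]
    if ("control" %in% names(metadata)) pos$control[hit] <- as.logical(metadata$control[m[hit]])
  }
  structure(list(root = root, frame_interval_hours = frame_interval_hours,
                 positions = pos, files = files),
            class = "library_manifest")
}

#' @export
print.library_manifest <- function(x, ...) {
  cat(sprintf("<library_manifest> %s: %d position(s), interval %.3f h\n",
              x$root, nrow(x$positions), x$frame_interval_hours))
  print(x$positions, row.names = FALSE)
  invisible(x)
}

#' Load all frames of one position
#'
#' Timestamps are derived as `frame_index * frame_interval_hours`.
#'
#' @param manifest A `library_manifest` from [scan_library()].
#' @param position_id Position to load.
#' @param bit_depth,pixel_size_um Acquisition metadata shared by the library.
#' @return List of [wound_frame()] objects in acquisition order.
#' @export
load_position <- function(manifest, position_id, bit_depth = 16L, pixel_size_um = 1) {
  fs <- manifest$files[[position_id]]
  if (is.null(fs)) .stopf("unknown position '%s'", position_id)
  lapply(seq_along(fs), function(i) {
    read_frame(fs[i], bit_depth, pixel_size_um,
               t_hours = (i - 1) * manifest$frame_interval_hours,
               position_id = position_id, frame_index = i - 1L)
  })
}

#' Write a wound mask as a binary 8-bit image
#'
#' An empty mask (fully closed wound) writes an all-zero image rather than
#' failing: closure is a valid outcome of the assay.
#'
#' @param mask A `wound_mask` (see [detect_gap()]) or a logical matrix.
#' @param path Output path; format follows the extension (PNG or TIFF).
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "wound_mask")) mask$mask else mask
  if (!is.matrix(m)) .stopf("mask must be a matrix or wound_mask")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img <- EBImage::Image(t(m * 1))
  EBImage::writeImage(img, path, bits.per.sample = 8L)
  invisible(NULL)
}

#' Read a binary mask image written by [write_mask()]
#'
#' @param path Mask image path.
#' @return Logical matrix, `TRUE` = gap.
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  t(as.matrix(EBImage::imageData(img))) > 0.5
}

#' Write closure series or velocity estimates to CSV
#'
#' Closure series produce one row per (position, frame) with columns
#' `position_id, frame_index, t_hours, gap_area_px, gap_area_um2,
#' displacement_um2, smoothed_displacement_um2, edge_displacement_um`;
#' velocity estimates produce one row per position.
#'
#' @param x A `closure_series`, a list of them, a `velocity_estimate`, or a
#'   list of velocity estimates.
#' @param path Output CSV path.
#' @export
write_results_table <- function(x, path) {
  if (inherits(x, c("closure_series", "velocity_estimate"))) x <- list(x)
  if (!is.list(x) || length(x) == 0) .stopf("empty result collection")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (inherits(x[[1]], "closure_series")) {
    rows <- lapply(x, function(s) {
      data.frame(position_id = s$position_id,
                 frame_index = seq_along(s$t_hours) - 1L,
                 t_hours = s$t_hours,
                 gap_area_px = s$area_px,
                 gap_area_um2 = s$area_um2,
                 displacement_um2 = s$DT_um2,
                 smoothed_displacement_um2 = s$smoothed_DT_um2,
                 edge_displacement_um = s$smoothed_DT_um2 / (2 * s$wound_length_um),
                 stringsAsFactors = FALSE)
    })
  } else if (inherits(x[[1]], "velocity_estimate")) {
    rows <- lapply(x, function(v) {
      data.frame(position_id = v$position_id,
                 t_start_h = v$window[1], t_end_h = v$window[2],
                 v_um_per_h = v$v_um_per_h, r2 = v$r2, sem = v$sem,
                 ci95_lo = v$ci95[1], ci95_hi = v$ci95[2],
                 n_points = v$n_points, stringsAsFactors = FALSE)
    })
  } else .stopf("unsupported collection type")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(NULL)
}
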