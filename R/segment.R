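# Gap segmentation: T-coefficient threshold on the enhanced image, central
# cleft check with threshold recalculation, morphological contour smoothing,
# biggest-central-blob selection, hole filling, contour extraction.

#' Threshold configuration
#'
#' The binarisation threshold is the enhanced image's histogram mean divided
#' by the coefficient `T`. Empirical defaults: 3.14 for 16-bit cameras and
#' 2.2 for 8-bit; low-contrast cell lines (e.g. 3T3, primary fibroblasts)
#' use 2.2 (16-bit) and 1.2 (8-bit). If no central gap candidate is found,
#' the threshold is multiplied by `retry_factor` and segmentation is retried
#' up to `max_retries` times.
#'
#' @param T Threshold coefficient (> 1); `NULL` selects the default for
#'   `bit_depth` and `low_contrast`.
#' @param bit_depth Camera bit depth profile, 8 or 16.
#' @param low_contrast Use the low-contrast cell-line defaults.
#' @param max_retries Maximum threshold recalculations (default 5).
#' @param retry_factor Multiplier applied to the threshold per retry
#'   (default 0.85).
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(T = NULL, bit_depth = 16L, low_contrast = FALSE,
                             max_retries = 5L, retry_factor = 0.85) {
  if (!bit_depth %in% c(8L, 16L)) .stopf("bit_depth must be 8 or 16")
  if (is.null(T)) {
    T <- if (bit_depth == 16L) { if (low_contrast) 2.2 else 3.14 }
         else                  { if (low_contrast) 1.2 else 2.2 }
  }
  if (T <= 1) .stopf("T coefficient must be > 1")
  if (retry_factor <= 0 || retry_factor >= 1) .stopf("retry_factor must be in (0,1)")
  structure(list(T = T, bit_depth = as.integer(bit_depth),
                 low_contrast = low_contrast,
                 max_retries = as.integer(max_retries),
                 retry_factor = retry_factor),
            class = "threshold_config")
}

#' Compute the binarisation threshold
#'
#' @param img Enhanced image (numeric matrix).
#' @param T Threshold coefficient (> 1).
#' @return `mean(img) / T`.
#' @export
compute_threshold <- function(img, T) {
  if (T <= 1) .stopf("T coefficient must be > 1")
  if (length(img) == 0) .stopf("empty image")
  mean(img) / T
}

#' Binarise an enhanced image
#'
#' Gap candidates are pixels *below* the threshold: after enhancement cells
#' are bright and the gap is dark.
#'
#' @param img Numeric matrix.
#' @param thr Intensity threshold.
#' @return Logical matrix, `TRUE` = candidate gap pixel.
#' @export
binarize <- function(img, thr) img < thr

#' Smooth a binary mask
#'
#' Applies closing, dilation, closing, erosion (in that order) with a disk
#' of the given radius. Seals thin isthmuses and clefts in the candidate gap
#' without degrading its overall shape.
#'
#' @param raw Logical matrix.
#' @param radius Disk radius in px (default 2, minimal radius).
#' @return Logical matrix.
#' @export
smooth_mask <- function(raw, radius = 2) {
  if (radius < 1) .stopf("radius must be >= 1")
  brush <- .disk_brush(radius)
  pad <- 4L * as.integer(radius)
  out <- .with_reflect_pad(raw * 1, pad, function(p) {
    i <- EBImage::Image(p)
    i <- EBImage::closing(i, brush)
    i <- EBImage::dilate(i, brush)
    i <- EBImage::closing(i, brush)
    i <- EBImage::erode(i, brush)
    as.matrix(EBImage::imageData(i))
  })
  out > 0.5
}

#' Is a central cleft present?
#'
#' `TRUE` when some 8-connected component has area at least `min_area_px`
#' and its centroid falls inside the central region (the middle third of
#' rows and of columns).
#'
#' @param candidate Logical matrix of gap candidates.
#' @param min_area_px Minimum component area in px.
#' @return Logical scalar.
#' @export
central_cleft_present <- function(candidate, min_area_px) {
  !is.null(.central_components(candidate, min_area_px)$best)
}

# Shared component scan: labels, areas, centroids; returns the largest
# qualifying central component (or NULL).
#' @noRd
.central_components <- function(candidate, min_area_px) {
  lab <- .label8(candidate)
  n <- max(lab)
  if (n == 0) return(list(lab = lab, best = NULL))
  nr <- nrow(candidate); nc <- ncol(candidate)
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  area <- tabulate(comp, nbins = n)
  cr <- tapply(rows, comp, mean)
  cc <- tapply(cols, comp, mean)
  central <- cr >= nr / 3 & cr <= 2 * nr / 3 & cc >= nc / 3 & cc <= 2 * nc / 3
  ok <- which(area >= min_area_px & central)
  best <- if (length(ok) == 0) NULL else ok[which.max(area[ok])]
  list(lab = lab, best = best)
}

#' Detect the wound gap in an enhanced image
#'
#' Thresholds at `mean(img)/T`, binarises, smooths the candidate mask, and
#' checks for a central cleft. If none is found the threshold is multiplied
#' by `retry_factor` and the check repeats, up to `max_retries` times. On
#' success the largest qualifying central component is selected as the gap,
#' its holes (detached pioneer cells) are filled by default, and its closed
#' boundary contour is traced. If no central gap survives all retries an
#' empty mask is returned: a fully closed wound is a valid outcome, not an
#' error.
#'
#' @param img Enhanced image from [enhance()].
#' @param cfg A [threshold_config()].
#' @param min_area_px Minimum gap area in px; default `50 * tophat_radius^2`
#'   with `tophat_radius = 25`, tied to the average mammalian cell size at
#'   high-resolution acquisition. Pass an explicit value for coarser
#'   sampling.
#' @param smooth_radius Disk radius of the mask smoothing (default 2).
#' @param fill_holes Fill holes punched by detached cells inside the gap
#'   (default `TRUE`; their area counts as gap).
#' @return A `wound_mask`: list with `mask` (logical matrix), `area_px`,
#'   `contour` (closed boundary coordinates, row/col), `centroid`,
#'   `is_empty`, `threshold_used`, `retries_used`.
#' @export
detect_gap <- function(img, cfg = threshold_config(), min_area_px = 50 * 25^2,
                       smooth_radius = 2, fill_holes = TRUE) {
  thr <- compute_threshold(img, cfg$T)
  best <- NULL; lab <- NULL; retries <- 0L
  repeat {
    candidate <- smooth_mask(binarize(img, thr), smooth_radius)
    res <- .central_components(candidate, min_area_px)
    if (!is.null(res$best)) { best <- res$best; lab <- res$lab; break }
    if (retries >= cfg$max_retries) break
    retries <- retries + 1L
    thr <- thr * cfg$retry_factor
  }
  if (is.null(best)) return(.empty_wound_mask(dim(img), thr, retries))
  mask <- lab == best
  if (fill_holes) {
    mask <- as.matrix(EBImage::imageData(
      EBImage::fillHull(EBImage::Image(mask * 1)))) > 0.5
  }
  .wound_mask_from(mask, thr, retries)
}

#' @noRd
.empty_wound_mask <- function(dims, thr, retries) {
  structure(list(mask = matrix(FALSE, dims[1], dims[2]), area_px = 0L,
                 contour = matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("row", "col"))),
                 centroid = c(NA_real_, NA_real_), is_empty = TRUE,
                 threshold_used = thr, retries_used = retries),
            class = "wound_mask")
}

#' @noRd
.wound_mask_from <- function(mask, thr, retries) {
  idx <- which(mask)
  nr <- nrow(mask)
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  oc <- EBImage::ocontour(EBImage::Image(t(mask * 1)))
  contour <- if (length(oc) >= 1) {
    xy <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
    # EBImage is (x, y) 0-based with x along matrix columns after transpose
    cbind(row = xy[, 2] + 1, col = xy[, 1] + 1)
  } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  structure(list(mask = mask, area_px = length(idx), contour = contour,
                 centroid = c(mean(rows), mean(cols)), is_empty = FALSE,
                 threshold_used = thr, retries_used = retries),
            class = "wound_mask")
}

#' @export
print.wound_mask <- function(x, ...) {
  cat(sprintf("<wound_mask> %s area = %d px, thr = %.4g, retries = %d\n",
              if (x$is_empty) "EMPTY," else "", x$area_px,
              x$threshold_used, x$retries_used))
  invisible(x)
}

#' Percent area error of a mask against a reference
#'
#' `100 * |area(mask) - area(reference)| / area(reference)`. Both empty is a
#' perfect 0; a non-empty mask against an empty reference returns `Inf`.
#'
#' @param mask A `wound_mask` or logical matrix.
#' @param reference Logical matrix (e.g. a manual outline or ground truth).
#' @return Percent error (scalar).
#' @export
area_error_pct <- function(mask, reference) {
  m <- if (inherits(mask, "wound_mask")) mask$mask else mask
  if (!all(dim(m) == dim(reference))) .stopf("mask/reference dimensions differ")
  a <- sum(m); b <- sum(reference)
  if (b == 0) return(if (a == 0) 0 else Inf)
  100 * abs(a - b) / b
}

#' Intersection-over-union of two masks
#'
#' @param mask A `wound_mask` or logical matrix.
#' @param reference Logical matrix.
#' @return IoU in \[0,1\]; 1 when both are empty.
#' @export
mask_iou <- function(mask, reference) {
  m <- if (inherits(mask, "wound_mask")) mask$mask else mask
  if (!all(dim(m) == dim(reference))) .stopf("mask/reference dimensions differ")
  u <- sum(m | reference)
  if (u == 0) return(1)
  sum(m & reference) / u
}
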