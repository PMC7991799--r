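# Internal helpers shared across modules. All image matrices are plain R
# numeric matrices (rows = image rows); EBImage is used transposed-free by
# treating dim 1 as x, which is irrelevant for the symmetric ops used here.

#' @noRd
.disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Reflect-pad a matrix by `r` pixels on every side (mirror without repeating
# the edge pixel), apply `fun`, and crop back. Keeps filters free of
# frame-edge artifacts that would otherwise read as gap.
#' @noRd
.with_reflect_pad <- function(img, r, fun) {
  nr <- nrow(img); nc <- ncol(img)
  r <- as.integer(r)
  ri <- .reflect_idx(nr, r)
  ci <- .reflect_idx(nc, r)
  padded <- img[ri, ci, drop = FALSE]
  res <- fun(padded)
  res[(r + 1L):(r + nr), (r + 1L):(r + nc), drop = FALSE]
}

#' @noRd
.reflect_idx <- function(n, r) {
  idx <- seq.int(1L - r, n + r)
  period <- if (n > 1L) 2L * n - 2L else 1L
  m <- (idx - 1L) %% period
  ifelse(m < n, m + 1L, period - m + 1L)
}

# Gaussian smoothing with an explicit kernel (radius = ceiling(3*sigma)) so
# padding width is known exactly; filter2's FFT wrap never reaches the
# interior because of the reflect pad.
#' @noRd
.gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- as.integer(ceiling(3 * sigma))
  x <- seq(-r, r)
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k <- k / sum(k)
  .with_reflect_pad(img, r, function(p) {
    as.matrix(EBImage::filter2(p, k, boundary = "circular"))
  })
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a union-find pass.
#' @noRd
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Natural frame order: sort by the last run of digits in the file name.
#' @noRd
.natural_order <- function(files) {
  base <- basename(files)
  nums <- regmatches(base, gregexpr("[0-9]+", base))
  key <- vapply(nums, function(x) {
    if (length(x) == 0) NA_real_ else as.numeric(x[length(x)])
  }, numeric(1))
  order(key, base, na.last = TRUE)
}

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == round(x)
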