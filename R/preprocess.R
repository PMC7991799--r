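# Five-stage enhancement of transmitted-light frames. The goal is a
# fluorescence-like image: textured cell regions bright, the smooth cell-free
# gap dark, illumination gradients removed. Stages run in fixed order:
# (a) intensity powering, (b) difference-of-Gaussians flat-field correction,
# (c) local Shannon entropy, (d) white top-hat background subtraction,
# (e) mean smoothing.

# Fixed gain applied to the difference-of-Gaussians before recentring at
# mid-gray. A data-independent constant keeps the chain linear-shift
# invariant; 2 spreads typical band-pass amplitudes over enough of [0,1]
# that the entropy quantisation resolves cell texture.
.DOG_GAIN <- 2

#' Filter-chain parameters
#'
#' @param power_exponent Exponent of the initial intensity powering (> 0,
#'   default 2). Powering darkens the background relative to cell halos
#'   while preserving intensity order.
#' @param sigma1 Coarse Gaussian sigma of the flat-field correction, px
#'   (default 2).
#' @param sigma2 Fine Gaussian sigma, px (default 1); must satisfy
#'   `sigma1 >= sigma2`.
#' @param entropy_radius Disk radius of the local-entropy filter, px
#'   (default 4, about half a cell-texture wavelength at 10x).
#' @param entropy_bins Gray-level bins of the entropy histogram (default 32).
#' @param tophat_radius Disk radius of the white top-hat, px (default 25,
#'   about one mammalian cell diameter at 10x).
#' @param average_kernel Side of the final mean filter, px, odd (default 3).
#' @return A `filter_params` list.
#' @export
filter_params <- function(power_exponent = 2, sigma1 = 2, sigma2 = 1,
                          entropy_radius = 4, entropy_bins = 32,
                          tophat_radius = 25, average_kernel = 3) {
  if (power_exponent <= 0) .stopf("power_exponent must be > 0")
  if (sigma1 < sigma2) .stopf("sigma1 must be >= sigma2")
  if (entropy_radius < 1 || tophat_radius < 1) .stopf("radii must be >= 1")
  if (average_kernel < 1 || average_kernel %% 2 != 1)
    .stopf("average_kernel must be odd and >= 1")
  structure(list(power_exponent = power_exponent, sigma1 = sigma1,
                 sigma2 = sigma2, entropy_radius = as.integer(entropy_radius),
                 entropy_bins = as.integer(entropy_bins),
                 tophat_radius = as.integer(tophat_radius),
                 average_kernel = as.integer(average_kernel)),
            class = "filter_params")
}

#' Normalise a frame to \[0,1\] and apply intensity powering
#'
#' `out = (pixels / (2^bit_depth - 1))^exponent`. The map is monotone, so
#' pixel intensity order is preserved.
#'
#' @param frame A [wound_frame()].
#' @param exponent Power exponent (> 0).
#' @return Numeric matrix in \[0,1\].
#' @export
normalize_and_power <- function(frame, exponent = 2) {
  if (exponent <= 0) .stopf("exponent must be > 0")
  (frame$pixels / (2^frame$bit_depth - 1))^exponent
}

#' Flat-field correction by difference of Gaussians
#'
#' Subtracts a coarse Gaussian blur (`sigma1`) from a fine one (`sigma2`)
#' and recentres the band-pass residual at mid-gray. Illumination varying on
#' scales much larger than `sigma1` is attenuated toward the constant 0.5.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param sigma1 Coarse sigma, px.
#' @param sigma2 Fine sigma, px; `sigma1 >= sigma2`.
#' @return Numeric matrix in \[0,1\].
#' @export
flat_field_correct <- function(img, sigma1 = 2, sigma2 = 1) {
  if (sigma1 < sigma2) .stopf("sigma1 must be >= sigma2")
  d <- .gaussian_smooth(img, sigma2) - .gaussian_smooth(img, sigma1)
  out <- 0.5 + .DOG_GAIN * d
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Local Shannon entropy enhancement
#'
#' Per-pixel entropy of the intensity histogram in a disk neighbourhood,
#' quantised over the fixed \[0,1\] range, rescaled by `log2(bins)` so the
#' output lies in \[0,1\]. Textured (cell) regions map high, smooth (gap)
#' regions map low.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param radius Disk radius in px (>= 1).
#' @param bins Number of gray-level bins (default 32).
#' @return Numeric matrix in \[0,1\].
#' @export
entropy_enhance <- function(img, radius = 4, bins = 32) {
  if (radius < 1) .stopf("radius must be >= 1")
  .entropy_disk_cpp(img, as.integer(radius), as.integer(bins)) / log2(bins)
}

#' White top-hat background subtraction
#'
#' `img - opening(img, disk(radius))`: structures wider than about twice the
#' radius are treated as background and removed; the output is >= 0.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param radius Disk radius of the structuring element, px.
#' @return Numeric matrix, >= 0.
#' @export
tophat_subtract <- function(img, radius = 25) {
  brush <- .disk_brush(radius)
  opened <- .with_reflect_pad(img, radius, function(p) {
    as.matrix(EBImage::imageData(EBImage::opening(EBImage::Image(p), brush)))
  })
  out <- img - opened
  out[out < 0] <- 0
  out
}

#' Mean (average) smoothing
#'
#' Uniform box filter of odd side `kernel`; removes residual small particles
#' (dust, debris) ahead of thresholding.
#'
#' @param img Numeric matrix.
#' @param kernel Odd kernel side in px; 1 is the identity.
#' @return Numeric matrix.
#' @export
smooth_average <- function(img, kernel = 3) {
  if (kernel < 1 || kernel %% 2 != 1) .stopf("kernel must be odd and >= 1")
  if (kernel == 1) return(img)
  k <- matrix(1 / kernel^2, kernel, kernel)
  r <- (kernel - 1L) / 2L
  .with_reflect_pad(img, r, function(p) {
    as.matrix(EBImage::filter2(p, k, boundary = "circular"))
  })
}

#' Enhance a raw frame into a fluorescence-like image
#'
#' Runs the full chain: powering, flat-field correction, local entropy,
#' top-hat, mean smoothing. On the output, cells are bright and the wound
#' gap is dark, which is what the T-coefficient threshold in [detect_gap()]
#' assumes.
#'
#' @param frame A [wound_frame()].
#' @param params A [filter_params()] object.
#' @return Numeric matrix in \[0,1\].
#' @export
enhance <- function(frame, params = filter_params()) {
  img <- normalize_and_power(frame, params$power_exponent)
  img <- flat_field_correct(img, params$sigma1, params$sigma2)
  img <- entropy_enhance(img, params$entropy_radius, params$entropy_bins)
  img <- tophat_subtract(img, params$tophat_radius)
  img <- smooth_average(img, params$average_kernel)
  # FFT round-off can leave values a hair outside [0,1]
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}
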