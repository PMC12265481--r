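#' Dark-frame subtraction
#'
#' Subtracts the pixel-wise temporal mean of the dark stack from every frame.
#' Negative values are retained: clipping would bias the noise statistics
#' used later by hyperparameter estimation.
#'
#' @param stack A [frame_stack()].
#' @param dark A [frame_stack()] of dark frames with the same frame shape.
#' @return The corrected [frame_stack()].
#' @export
subtract_dark <- function(stack, dark) {
  if (!all(dim(stack$frames)[1:2] == dim(dark$frames)[1:2])) {
    stop("dark frames and stack frames have different shapes")
  }
  dark_mean <- apply(dark$frames, c(1, 2), mean)
  stack$frames <- sweep(stack$frames, c(1, 2), dark_mean, `-`)
  stack
}

#' Central crop
#'
#' Extracts the central `crop_size x crop_size` window; for odd margins the
#' origin is floor-based, so a 2048-pixel frame cropped to 1024 starts at
#' 0-based pixel (512, 512).
#'
#' @param frame Numeric matrix.
#' @param crop_size Side of the square crop, pixels.
#' @return Cropped matrix.
#' @export
crop_center <- function(frame, crop_size) {
  as_image(frame, "frame")
  if (crop_size > min(dim(frame))) stop("crop_size exceeds the frame size")
  oy <- floor((nrow(frame) - crop_size) / 2)
  ox <- floor((ncol(frame) - crop_size) / 2)
  frame[(oy + 1):(oy + crop_size), (ox + 1):(ox + crop_size), drop = FALSE]
}

#' 1-D Tukey (cosine-tapered) window
#'
#' Equals 1 on the central plateau and falls to 0 at the edges over a
#' fraction `alpha/2` of the length at each end; `alpha = 0` is rectangular,
#' `alpha = 1` is the Hann window.
#'
#' @param n Window length.
#' @param alpha Taper fraction in `[0, 1]`.
#' @return Numeric vector of length `n` in `[0, 1]`.
#' @export
tukey_window <- function(n, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (alpha == 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t >= 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(2 * pi / alpha * (t[lo] - alpha / 2)))
  w[hi] <- 0.5 * (1 + cos(2 * pi / alpha * (t[hi] - 1 + alpha / 2)))
  w
}

#' Cosine-taper apodization
#'
#' Multiplies the frame by the outer product of two 1-D Tukey windows,
#' suppressing the edge discontinuities that would otherwise cause ringing
#' and spectral leakage in the FFT-based registration and reconstruction.
#'
#' @param frame Numeric matrix.
#' @param alpha Taper fraction in `[0, 1]` (default 0.2, which keeps at least
#'   64% of the field at unit weight).
#' @return Apodized matrix.
#' @export
apodize <- function(frame, alpha = 0.2) {
  as_image(frame, "frame")
  if (alpha == 0) return(frame)
  frame * outer(tukey_window(nrow(frame), alpha), tukey_window(ncol(frame), alpha))
}

#' Pre-process a raw frame stack
#'
#' Fixed pipeline order: dark subtraction, central crop, apodization.
#'
#' @param stack Raw [frame_stack()].
#' @param dark Dark [frame_stack()].
#' @param crop_size Central crop side, pixels (default: half the frame side).
#' @param taper_fraction Tukey taper fraction (default 0.2).
#' @return Pre-processed [frame_stack()].
#' @export
preprocess_stack <- function(stack, dark, crop_size = NULL, taper_fraction = 0.2) {
  stack <- subtract_dark(stack, dark)
  side <- dim(stack$frames)[1]
  if (is.null(crop_size)) crop_size <- side %/% 2
  n <- n_frames(stack)
  out <- array(0, c(crop_size, crop_size, n))
  w <- outer(tukey_window(crop_size, taper_fraction),
             tukey_window(crop_size, taper_fraction))
  for (j in seq_len(n)) {
    out[, , j] <- crop_center(stack$frames[, , j], crop_size) * w
  }
  stack$frames <- out
  # the taper becomes part of the measurement operator downstream: the MAP
  # data term weights model images by the same window
  stack$window <- w
  stack
}
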