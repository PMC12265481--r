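# FFT helpers shared across the forward model, shift estimation and metrics.
# All images are numeric matrices indexed [row = y, col = x]; physical pixel
# coordinates are 0-based (R index i corresponds to coordinate i - 1).

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' DFT sample frequencies
#'
#' Frequencies associated with the unshifted 2-D FFT layout, in cycles per
#' unit of `d` (e.g. cycles/degree when `d` is the pixel scale in
#' degrees/pixel).
#'
#' @param n Number of samples along the axis.
#' @param d Sample spacing (default 1, giving cycles/pixel).
#' @return Numeric vector of length `n` in FFT bin order.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

# Frequency grids (fy over rows, fx over cols) and radial frequency, all in
# cycles per unit of d.
freq_grid <- function(ny, nx, d = 1) {
  fy <- fft_freq(ny, d)
  fx <- fft_freq(nx, d)
  FY <- matrix(fy, ny, nx)
  FX <- matrix(fx, ny, nx, byrow = TRUE)
  list(fy = FY, fx = FX, rho = sqrt(FY^2 + FX^2))
}

# Complex phase ramp implementing a (dy, dx) shift in this grid's pixel units.
shift_ramp <- function(ny, nx, dy, dx) {
  fy <- fft_freq(ny)
  fx <- fft_freq(nx)
  py <- exp(-2i * pi * fy * dy)
  px <- exp(-2i * pi * fx * dx)
  outer(py, px)
}

# Circular Gaussian low-pass applied in the Fourier domain; sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- freq_grid(nrow(img), ncol(img))
  H <- exp(-2 * pi^2 * sigma^2 * g$rho^2)
  Re(ifft2(fft2(img) * H))
}

as_image <- function(x, arg = "img") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  x
}
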