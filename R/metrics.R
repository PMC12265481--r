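#' Wide-field reference image
#'
#' Conventional flood-illumination reference built from the same raw data as
#' the reconstruction: each frame is counter-shifted by the opposite of its
#' retinal shift and the registered frames are averaged. With good phase
#' coverage the static fringes average out.
#'
#' @param stack A [frame_stack()].
#' @param shifts A [shift_trajectory()] aligned with the stack.
#' @param illum Optional [illumination_model()]; when given (together with
#'   `pixel_scale`), the residual fringe energy of the average is reported in
#'   `attr(, "fringe_energy")`.
#' @param pixel_scale Pixel scale, degrees/pixel (for the fringe report).
#' @return The average frame (matrix).
#' @export
build_widefield <- function(stack, shifts, illum = NULL, pixel_scale = NULL) {
  n <- n_frames(stack)
  if (nrow(shifts) < n) stop("missing shifts for some frames")
  acc <- matrix(0, dim(stack$frames)[1], dim(stack$frames)[2])
  for (j in seq_len(n)) {
    acc <- acc + apply_shift(stack$frames[, , j], c(-shifts$dy[j], -shifts$dx[j]))
  }
  wf <- acc / n
  if (!is.null(illum) && !is.null(pixel_scale)) {
    fe <- vapply(illum$orientations, function(th) {
      fringe_contrast_energy(wf, illum$modulation_frequency_cpd, th, pixel_scale)
    }, numeric(1))
    attr(wf, "fringe_energy") <- stats::setNames(fe, illum$orientations)
  }
  wf
}

#' Radial power spectral density
#'
#' Circularly averaged periodogram `|FFT|^2 / N^2`, binned by radial
#' frequency in cycles/degree. With this normalization the total (sum of
#' per-bin means times bin counts) equals the mean square of the frame
#' (Parseval), and a white-noise frame of variance `v` has a flat spectrum of
#' expectation `v / Npix` per bin.
#'
#' @param frame Square numeric matrix.
#' @param pixel_scale Pixel scale, degrees/pixel.
#' @return An object of class `sio_radial_spectrum`: data.frame with columns
#'   `freq` (cycles/degree), `psd` (per-bin mean) and `n` (bin count).
#' @export
radial_psd <- function(frame, pixel_scale) {
  as_image(frame, "frame")
  if (nrow(frame) != ncol(frame)) stop("frame must be square")
  n <- nrow(frame)
  g <- freq_grid(n, n, d = pixel_scale)
  df <- 1 / (n * pixel_scale)
  P <- Mod(fft2(frame))^2 / length(frame)^2
  rb <- radial_bins(P, g$rho, df)
  structure(data.frame(freq = rb$freq, psd = rb$mean, n = rb$n),
            class = c("sio_radial_spectrum", "data.frame"),
            pixel_scale = pixel_scale, nyquist = 1 / (2 * pixel_scale))
}

#' Effective (noise-limited) cutoff frequency
#'
#' The smallest radial frequency above which the smoothed PSD stays at the
#' noise floor for all higher bins: the frequency at which the image spectrum
#' sinks into the noise, i.e. the SNR-limited resolution. The raw periodogram
#' fluctuates about the floor, so a 3-bin moving average is applied and the
#' `1.1 x` crossing tolerance is widened by a finite-sample allowance of
#' `4 / sqrt(bin count)` (sparse bins fluctuate hard); bins beyond the Nyquist
#' frequency (the anisotropic spectral corners) are ignored. Returns the
#' Nyquist frequency when the spectrum never reaches the floor.
#'
#' @param spectrum A [radial_psd()] result.
#' @param noise_floor Noise PSD level on the same scale (> 0).
#' @param factor Crossing tolerance (default 1.1).
#' @return Cutoff frequency, cycles/degree.
#' @export
effective_cutoff <- function(spectrum, noise_floor, factor = 1.1) {
  if (noise_floor <= 0) stop("noise_floor must be positive")
  nyq <- attr(spectrum, "nyquist")
  keep <- spectrum$freq <= nyq + 1e-9
  f <- spectrum$freq[keep]
  p <- spectrum$psd[keep]
  cnt <- spectrum$n[keep]
  sm <- p
  if (length(p) >= 3) {
    sm <- stats::filter(p, rep(1 / 3, 3), sides = 2)
    sm[1] <- p[1]; sm[length(p)] <- p[length(p)]
    sm <- as.numeric(sm)
  }
  nondc <- which(f > 0)
  below <- sm <= noise_floor * (factor + 4 / sqrt(pmax(cnt, 1)))
  # smallest non-DC frequency from which every higher bin is at the floor
  ok <- rev(cumprod(rev(below))) > 0
  cand <- nondc[ok[nondc]]
  if (length(cand) == 0) return(nyq)
  f[cand[1]]
}

#' Bandpass background correction
#'
#' Fourier-domain bandpass that removes the smooth illumination falloff (and
#' DC) while leaving the cone-mosaic band intact: a Gaussian high-pass times a
#' flat-topped (8th-order super-Gaussian) low-pass,
#' `B(f) = exp(-(f/high_cut)^8 / 2) * (1 - exp(-f^2 / (2 low_cut^2)))`,
#' so frequencies just below `high_cut` pass nearly unattenuated. The output
#' has zero mean.
#'
#' @param frame Numeric matrix.
#' @param low_cut,high_cut Gaussian band edges, cycles/degree
#'   (`0 < low_cut < high_cut`).
#' @param pixel_scale Pixel scale, degrees/pixel.
#' @return Filtered matrix.
#' @export
background_correct <- function(frame, low_cut, high_cut, pixel_scale) {
  as_image(frame, "frame")
  nyq <- 1 / (2 * pixel_scale)
  if (!(low_cut > 0 && high_cut > low_cut)) stop("need 0 < low_cut < high_cut")
  g <- freq_grid(nrow(frame), ncol(frame), d = pixel_scale)
  B <- exp(-(g$rho / high_cut)^8 / 2) * (1 - exp(-g$rho^2 / (2 * low_cut^2)))
  B[1, 1] <- 0
  Re(ifft2(fft2(frame) * B))
}
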