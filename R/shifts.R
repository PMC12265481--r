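#' Notch specification for fringe removal
#'
#' Fourier-domain mask equal to 0 in discs around the conjugate fringe peaks
#' `+/-(f_m, theta)` for every pattern orientation, and 1 elsewhere.
#'
#' @param f_m Fringe frequency, cycles/degree.
#' @param orientations Fringe orientations, degrees.
#' @param pixel_scale Pixel scale, degrees/pixel.
#' @param radius_bins Notch radius in frequency bins (default 3 at the
#'   1024-pixel scale, scaled proportionally to the frame side).
#' @return An object of class `sio_notch_spec`.
#' @export
notch_spec <- function(f_m, orientations, pixel_scale, radius_bins = NULL) {
  stopifnot(f_m > 0, length(orientations) >= 1, pixel_scale > 0)
  structure(list(f_m = f_m, orientations = orientations,
                 pixel_scale = pixel_scale, radius_bins = radius_bins),
            class = "sio_notch_spec")
}

notch_mask <- function(spec, n) {
  # default 3 bins at the 1024-pixel scale, scaled with the frame but floored
  # at 3: the apodization window broadens the fringe peak by a few bins
  # regardless of the frame size
  radius <- spec$radius_bins
  if (is.null(radius)) radius <- max(3, round(3 * n / 1024))
  if (radius < 1) stop("notch radius must be at least 1 bin")
  g <- freq_grid(n, n, d = spec$pixel_scale)
  df <- 1 / (n * spec$pixel_scale)
  if (spec$f_m <= radius * df) stop("notch would cover the DC bin")
  mask <- matrix(1, n, n)
  for (th_deg in spec$orientations) {
    th <- th_deg * pi / 180
    ty <- spec$f_m * sin(th); tx <- spec$f_m * cos(th)
    hit <- (sqrt((g$fy - ty)^2 + (g$fx - tx)^2) <= radius * df) |
           (sqrt((g$fy + ty)^2 + (g$fx + tx)^2) <= radius * df)
    mask[hit] <- 0
  }
  mask
}

#' Notch-filter the fringe frequency out of a frame
#'
#' Zeroes discs around the fringe peaks in the Fourier domain and returns the
#' real part of the inverse transform, yielding an approximate fringe-free
#' wide-field frame suitable for registration. DC is preserved.
#'
#' @param frame Square numeric matrix.
#' @param spec A [notch_spec()].
#' @return Filtered matrix.
#' @export
notch_filter <- function(frame, spec) {
  as_image(frame, "frame")
  if (nrow(frame) != ncol(frame)) stop("frame must be square")
  Re(ifft2(fft2(frame) * notch_mask(spec, nrow(frame))))
}

# Upsampled DFT of the cross-power spectrum R around a coarse peak:
# cc(eta) = (1/N) sum_f R(f) exp(2i pi f . eta), evaluated on a local grid of
# spacing 1/usf. fy/fx are in cycles/pixel.
zoomed_xcorr <- function(R, eta_y, eta_x) {
  fy <- fft_freq(nrow(R))
  fx <- fft_freq(ncol(R))
  Ey <- exp(2i * pi * outer(eta_y, fy))
  Ex <- exp(2i * pi * outer(fx, eta_x))
  (Ey %*% R %*% Ex) / length(R)
}

# One generalized cross-correlation measurement: returns the subpixel peak
# location (dy, dx) and the normalized peak height. `gamma` is the whitening
# exponent (1 = phase correlation, 0.5 = symmetric/SCOT weighting, 0 = plain
# cross-correlation). band (optional) is a logical matrix masking the
# cross-power to the signal passband, so that noise-only frequencies beyond
# the optical cutoff do not jitter the peak.
phase_correlate <- function(a, b, upsample_factor, band = NULL, gamma = 1) {
  Fa <- fft2(a - mean(a))
  Fb <- fft2(b - mean(b))
  num <- Fb * Conj(Fa)
  den <- Mod(num)
  R <- ifelse(den > .Machine$double.eps * max(den, 1), num / den^gamma, 0 + 0i)
  if (!is.null(band)) R[!band] <- 0 + 0i
  cc <- Mod(ifft2(R))
  cc <- cc / max(sum(Mod(R)) / length(R), .Machine$double.xmin)
  peak_val <- max(cc)
  pk <- which(cc == peak_val, arr.ind = TRUE)[1, ]
  ny <- nrow(a); nx <- ncol(a)
  iy <- pk[1] - 1; if (iy > ny / 2) iy <- iy - ny
  ix <- pk[2] - 1; if (ix > nx / 2) ix <- ix - nx
  eta_y <- iy + seq(-1, 1, by = 1 / upsample_factor)
  eta_x <- ix + seq(-1, 1, by = 1 / upsample_factor)
  M <- Mod(zoomed_xcorr(R, eta_y, eta_x))
  mx <- which(M == max(M), arr.ind = TRUE)[1, ]
  list(shift = c(eta_y[mx[1]], eta_x[mx[2]]), peak = peak_val)
}

#' Estimate inter-frame retinal shifts
#'
#' Sub-pixel registration by whitened phase correlation with local Fourier
#' upsampling around the integer peak (upsampling factor >= 20 gives
#' better-than-1/20-pixel quantization). Frames should be notch-filtered
#' ([notch_filter()]) beforehand so the static fringes do not anchor the
#' correlation. The reference defaults to the frame with the highest
#' [gradient_energy()]; its shift is (0, 0).
#'
#' Apodized stacks (those carrying a taper window from [preprocess_stack()])
#' get special handling, because a static taper biases plain phase
#' correlation toward zero shift: frames are smoothly de-apodized (dividing
#' by the window floored at 0.25); a global stage with symmetric (SCOT)
#' whitening locates the shift robustly on the full frame; a local stage
#' iterates counter-shift + fresh window on the interior crop with plain
#' cross-correlation (noise-optimal near alignment, and unbiased there); and
#' finally the per-frame estimates are refined against a template built by
#' averaging the counter-shifted frames, in which the fringe patterns have
#' cancelled out. A frame whose correlation peak falls below `peak_floor` is
#' flagged invalid rather than raising an error.
#'
#' @param stack A [frame_stack()] of (filtered) frames.
#' @param reference_index 1-based index of the reference frame, or `NULL`.
#' @param upsample_factor Local DFT upsampling factor (default 50).
#' @param peak_floor Minimum acceptable normalized correlation peak.
#' @param pixel_scale,max_freq_cpd When both are given, the cross-power
#'   spectrum is restricted to radial frequencies below `max_freq_cpd`
#'   (typically the optical cutoff), suppressing peak jitter from noise-only
#'   frequencies at low SNR; an inner edge at `max_freq_cpd / 8` removes the
#'   smooth scattering background, which otherwise dominates the unwhitened
#'   correlation.
#' @param template_rounds Refinement rounds against the running fringe-free
#'   template (windowed stacks only; default 2).
#' @return A [shift_trajectory()] with per-frame `(dy, dx)` in camera pixels
#'   and a `valid` flag; the reference index is in
#'   `attr(, "reference_index")`.
#' @export
estimate_shifts <- function(stack, reference_index = NULL,
                            upsample_factor = 50, peak_floor = 0.02,
                            pixel_scale = NULL, max_freq_cpd = NULL,
                            template_rounds = 2) {
  n <- n_frames(stack)
  if (n < 2) stop("need at least 2 frames to estimate shifts")
  if (is.null(reference_index)) {
    ge <- vapply(seq_len(n), function(j) gradient_energy(stack$frames[, , j]),
                 numeric(1))
    reference_index <- which.max(ge)
  }
  band_for <- function(side) {
    if (is.null(pixel_scale) || is.null(max_freq_cpd)) return(NULL)
    rho <- freq_grid(side, side, d = pixel_scale)$rho
    rho <= max_freq_cpd & rho >= max_freq_cpd / 8
  }
  w <- stack$window
  dy <- numeric(n); dx <- numeric(n); valid <- rep(TRUE, n)

  if (is.null(w)) {
    ref <- stack$frames[, , reference_index]
    band <- band_for(nrow(ref))
    for (j in seq_len(n)) {
      if (j == reference_index) next
      res <- phase_correlate(ref, stack$frames[, , j], upsample_factor, band)
      dy[j] <- res$shift[1]; dx[j] <- res$shift[2]
      if (!is.finite(res$peak) || res$peak < peak_floor) valid[j] <- FALSE
    }
  } else {
    ny <- nrow(w)
    inv <- 1 / pmax(w, 0.25)
    # interior crop: the window plateau, inset a little further
    mid <- ceiling(ncol(w) / 2)
    plateau <- which(w[, mid] >= 1 - 1e-9)
    margin <- if (length(plateau) > 0) plateau[1] - 1 else ny %/% 8
    margin <- margin + max(4L, ny %/% 32)
    lo <- margin + 1L; hi <- ny - margin
    if (hi - lo < 16) { lo <- ny %/% 4; hi <- ny - ny %/% 4 }
    take <- function(f) f[lo:hi, lo:hi]
    wc <- outer(tukey_window(hi - lo + 1, 0.3), tukey_window(hi - lo + 1, 0.3))
    band_full <- band_for(ny)
    band_crop <- band_for(hi - lo + 1)
    fe_all <- array(0, dim(stack$frames))
    for (j in seq_len(n)) fe_all[, , j] <- stack$frames[, , j] * inv
    refine <- function(target, fe, s) {
      for (pass in 1:12) {
        r2 <- phase_correlate(target, take(apply_shift(fe, -s)) * wc,
                              upsample_factor, band_crop, gamma = 0)
        if (max(abs(r2$shift)) > 2) break  # keep the incoming estimate
        s <- s + r2$shift
        if (max(abs(r2$shift)) < 0.005) break
      }
      s
    }
    ref_e <- fe_all[, , reference_index]
    A <- take(ref_e) * wc
    for (j in seq_len(n)) {
      if (j == reference_index) next
      fe <- fe_all[, , j]
      # global stage: full de-apodized frames are periodic in content, so the
      # correlation is robust to arbitrary shifts (window bias < 1 px)
      res <- phase_correlate(ref_e, fe, upsample_factor, band_full, gamma = 0.5)
      s <- res$shift
      if (!is.finite(res$peak) || res$peak < peak_floor) {
        valid[j] <- FALSE
        dy[j] <- s[1]; dx[j] <- s[2]
        next
      }
      s <- refine(A, fe, s)
      dy[j] <- s[1]; dx[j] <- s[2]
    }
    # template rounds: the average of counter-shifted frames has (nearly)
    # fringe-free content, removing the sideband bias of frame-to-frame
    # correlation
    for (round in seq_len(template_rounds)) {
      tmpl <- matrix(0, ny, ny)
      for (j in seq_len(n)) tmpl <- tmpl + apply_shift(fe_all[, , j], -c(dy[j], dx[j])) / n
      Tc <- take(tmpl) * wc
      for (j in seq_len(n)) {
        if (!valid[j]) next
        s <- refine(Tc, fe_all[, , j], c(dy[j], dx[j]))
        dy[j] <- s[1]; dx[j] <- s[2]
      }
      # re-anchor so the reference frame stays at (0, 0)
      dy <- dy - dy[reference_index]
      dx <- dx - dx[reference_index]
    }
  }
  tr <- shift_trajectory(dy, dx, valid)
  attr(tr, "reference_index") <- reference_index
  tr
}

#' Write / read a shift trajectory as CSV
#'
#' Columns: `frame_index` (0-based), `dy`, `dx`, `valid`.
#'
#' @param trajectory A [shift_trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a [shift_trajectory()] (reader).
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory[, c("frame_index", "dy", "dx", "valid")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  shift_trajectory(d$dy, d$dx, as.logical(d$valid))
}
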