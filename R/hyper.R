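# Radial binning of a 2-D spectral quantity. Bin k collects values with
# round(rho / df) == k; returns bin centre frequencies, per-bin means and
# counts. df is the frequency bin width 1/(N * pixel_scale).
radial_bins <- function(values, rho, df) {
  k <- as.integer(round(rho / df))
  means <- tapply(as.vector(values), k, mean)
  counts <- tapply(as.vector(values), k, length)
  kk <- as.integer(names(means))
  ord <- order(kk)
  list(freq = kk[ord] * df, mean = as.numeric(means)[ord],
       n = as.integer(counts)[ord])
}

# Mean periodogram of a stack in the |FFT|^2 / Npix convention, for which a
# white-noise frame of variance v has expectation v in every bin.
mean_periodogram <- function(stack) {
  n <- n_frames(stack)
  d <- dim(stack$frames)
  P <- matrix(0, d[1], d[2])
  for (j in seq_len(n)) {
    f <- stack$frames[, , j]
    P <- P + Mod(fft2(f))^2 / length(f)
  }
  P / n
}

#' Reconstruction hyperparameters
#'
#' The noise variance, the radially parameterized object power spectral
#' densities of the two layers (model `k / (1 + (f/f0)^p)`), and the
#' regularization weight `lambda` (default 0.3).
#'
#' @param sigma2 Noise variance (> 0), intensity units squared.
#' @param S0,Sd Lists with positive fields `k`, `f0`, `p` for the in-focus and
#'   defocused layer PSDs.
#' @param lambda Regularization weight (> 0).
#' @return An object of class `sio_hyper`.
#' @export
hyperparameters <- function(sigma2, S0, Sd, lambda = 0.3) {
  stopifnot(sigma2 > 0, lambda >= 0)
  for (S in list(S0, Sd)) {
    stopifnot(S$k > 0, S$f0 > 0, S$p > 0)
  }
  structure(list(sigma2 = sigma2, S0 = S0, Sd = Sd, lambda = lambda),
            class = "sio_hyper")
}

psd_profile <- function(S, rho) S$k / (1 + (rho / S$f0)^S$p)

# Equivalent OTF bandwidth: radius of the flat disc with the same integrated
# |OTF| (cycles/degree).
otf_equivalent_bandwidth <- function(otf, d) {
  df2 <- (1 / (nrow(otf) * d)) * (1 / (ncol(otf) * d))
  sqrt(sum(Mod(otf)) * df2 / pi)
}

#' Unsupervised hyperparameter estimation
#'
#' Estimates the homogeneous noise variance from the pure-noise plateau of
#' the circularly averaged frame periodogram above the optical cutoff (where
#' no object signal can live), then fits the in-focus layer PSD model
#' `k / (1 + (f/f0)^p)` to the noise-subtracted periodogram over the
#' passband by least squares in log space. The defocused layer PSD reuses the
#' fit with `f0` shrunk by the ratio of the defocused to in-focus OTF
#' equivalent bandwidths (its content is the same retina, seen through a much
#' narrower transfer function). The PSDs are returned on the object-grid
#' periodogram scale (a factor `q^2` above the camera grid).
#'
#' @param stack A pre-processed [frame_stack()] (>= 10 frames recommended).
#' @param optical An [optical_model()].
#' @param lambda Regularization weight to store (default 0.3).
#' @return A [hyperparameters()] object; the estimated noise floor (camera
#'   periodogram scale) is in `attr(, "noise_floor")`.
#' @export
estimate_hyperparameters <- function(stack, optical, lambda = 0.3) {
  d <- optical$pixel_scale
  nside <- dim(stack$frames)[1]
  fc <- cutoff_cpd(optical)
  g <- freq_grid(nside, nside, d = d)
  df <- 1 / (nside * d)
  P <- mean_periodogram(stack)
  rb <- radial_bins(P, g$rho, df)
  # plateau: above the optical cutoff but within the Nyquist disc (corner
  # bins are sparse and anisotropic)
  plateau <- rb$freq > fc & rb$freq <= 1 / (2 * d)
  if (!any(plateau)) {
    stop("no pure-noise plateau: optical cutoff is at or above the frame Nyquist")
  }
  sigma2 <- mean(rb$mean[plateau])

  # the prior PSD is fitted to the frame periodogram itself (no OTF
  # deconvolution): the optical rolloff baked into the fit makes the prior
  # deliberately conservative at high frequencies, which is what keeps noise
  # amplification in the weakly transferred bands in check. The fit uses the
  # upper passband: the lowest frequencies are dominated by the scattering
  # background's steep rise and by enormous data-term SNR, so the prior
  # hardly matters there, while the fit's job is to set how hard frequencies
  # near and beyond the cutoff are damped.
  band <- rb$freq > 0.15 * fc & rb$freq < fc
  y <- pmax(rb$mean[band] - sigma2, 1e-6 * max(rb$mean))
  f <- rb$freq[band]
  obj_fn <- function(par) {
    S <- list(k = exp(par[1]), f0 = exp(par[2]), p = exp(par[3]))
    sum((log(psd_profile(S, f)) - log(y))^2)
  }
  init <- c(log(max(y)), log(fc / 4), log(2))
  # p is bounded away from runaway exponents (noise-dominated tail bins would
  # otherwise drive the fit); f0 stays inside the passband
  fit <- stats::optim(init, obj_fn, method = "L-BFGS-B",
                      lower = c(log(1e-12 * max(y)), log(f[1]), log(0.5)),
                      upper = c(log(1e6 * max(y)), log(fc), log(8)),
                      control = list(maxit = 500))
  q <- optical$oversampling_factor
  S0 <- list(k = exp(fit$par[1]) * q^2, f0 = exp(fit$par[2]), p = exp(fit$par[3]))

  obj_shape <- dim(stack$frames)[1:2] * q
  d_obj <- object_pixel_scale(optical)
  bw0 <- otf_equivalent_bandwidth(
    make_otf(make_psf(optical, optical$defocus_infocus, obj_shape)), d_obj)
  bwd <- otf_equivalent_bandwidth(
    make_otf(make_psf(optical, optical$defocus_background, obj_shape)), d_obj)
  Sd <- S0
  Sd$f0 <- S0$f0 * min(1, bwd / bw0)

  h <- hyperparameters(sigma2 = max(sigma2, 1e-12 * max(rb$mean)),
                       S0 = S0, Sd = Sd, lambda = lambda)
  attr(h, "noise_floor") <- sigma2
  attr(h, "psd_fit") <- list(freq = f, excess = y)
  h
}
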