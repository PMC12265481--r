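# Shared fixture builders. Everything is generated in code at test time; the
# heavy default-fixture reconstruction is computed once and cached for the
# tests that share it.

# bilinear splat of a point source at 0-based subpixel coordinates
splat_point <- function(img, y, x, a = 1) {
  iy <- floor(y); ix <- floor(x); wy <- y - iy; wx <- x - ix
  for (dd in list(c(0, 0, (1 - wy) * (1 - wx)), c(1, 0, wy * (1 - wx)),
                  c(0, 1, (1 - wy) * wx), c(1, 1, wy * wx))) {
    img[iy + 1 + dd[1], ix + 1 + dd[2]] <- img[iy + 1 + dd[1], ix + 1 + dd[2]] +
      a * dd[3]
  }
  img
}

# count strict 8-neighbour local maxima above floor_frac * max inside a square
# region (vector of 1-based indices)
count_local_maxima <- function(img, region, floor_frac = 0.2) {
  sm <- img[region, region]
  ny <- nrow(sm)
  inner <- sm[2:(ny - 1), 2:(ny - 1)]
  ismax <- inner > sm[1:(ny - 2), 2:(ny - 1)] & inner > sm[3:ny, 2:(ny - 1)] &
           inner > sm[2:(ny - 1), 1:(ny - 2)] & inner > sm[2:(ny - 1), 3:ny] &
           inner > sm[1:(ny - 2), 1:(ny - 2)] & inner > sm[1:(ny - 2), 3:ny] &
           inner > sm[3:ny, 1:(ny - 2)] & inner > sm[3:ny, 3:ny] &
           inner > floor_frac * max(sm)
  sum(ismax)
}

# noiseless acquisition of an arbitrary two-layer object with n_per_orient
# frames per orientation and a drifting trajectory; optionally add Gaussian
# noise at a per-frame SNR (mean in-focus signal over sigma)
acquire_object <- function(obj, optical, illum, n_per_orient = 7, snr = Inf,
                           drift_step = 1, seed = 1) {
  nfr <- 2 * n_per_orient
  acq <- acquisition_spec(n_frames = nfr, frame_rate = 100,
                          switching_rate = 100 / n_per_orient,
                          noise_sigma = 0, drift_step = drift_step,
                          microsaccade_rate = 0, blink_fraction = 0,
                          dark_offset = 0, n_dark = 2)
  tr <- generate_trajectory(acq, nfr, rng_seed = seed)
  sim <- generate_stack(obj, tr, optical, illum, acq, rng_seed = seed)
  sigma <- 0
  if (is.finite(snr)) {
    sigma <- mean(sim$stack$frames) / snr
    set.seed(seed + 1)
    sim$stack$frames <- sim$stack$frames +
      array(rnorm(length(sim$stack$frames), 0, sigma), dim(sim$stack$frames))
  }
  list(stack = sim$stack, trajectory = tr, illum = sim$illum, sigma = sigma)
}

# direct O(N^4) spatial-domain evaluation of the imaging operator (oracle)
forward_direct <- function(obj, shift, optical, illum, orientation) {
  q <- optical$oversampling_factor
  n <- nrow(obj$o0)
  psf0 <- make_psf(optical, optical$defocus_infocus, c(n, n))
  psfd <- make_psf(optical, optical$defocus_background, c(n, n))
  pat0 <- make_pattern(illum, optical, c(n, n), orientation = orientation,
                       layer = "infocus")
  patd <- make_pattern(illum, optical, c(n, n), orientation = orientation,
                       layer = "background")
  conv_circ <- function(img, psf) {
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      # out[i, j] = sum_{a,b} psf[a, b] * img[i - a, j - b] (0-based, periodic)
      ii <- ((i - 1) - (seq_len(n) - 1)) %% n + 1
      jj <- ((j - 1) - (seq_len(n) - 1)) %% n + 1
      out[i, j] <- sum(psf * img[ii, jj])
    }
    out
  }
  s0 <- apply_shift(obj$o0, shift * q)
  sd <- apply_shift(obj$od, shift * q)
  downsample(conv_circ(pat0 * s0, psf0) + conv_circ(patd * sd, psfd), q)
}

# default cone-mosaic fixture at SNR 20, registered and reconstructed; cached
# because several tests interrogate the same result
default_fixture_cache <- new.env(parent = emptyenv())
default_fixture_recon <- function() {
  if (!is.null(default_fixture_cache$res)) return(default_fixture_cache$res)
  optical <- optical_model(oversampling_factor = 1L)
  illum <- illumination_model(contrast_infocus = 0.7)
  ph <- phantom_spec(field_of_view = 256 / 403, background_to_signal_ratio = 1)
  acq <- acquisition_spec(n_frames = 24, frame_rate = 100,
                          switching_rate = 100 / 12, blink_fraction = 0,
                          drift_step = 1, microsaccade_rate = 0, n_dark = 20)
  sim <- simulate_acquisition(ph, acq, optical, illum, seed = 8, snr = 20)
  pre <- preprocess_stack(sim$stack, sim$dark, crop_size = 256,
                          taper_fraction = 0.2)
  ns <- notch_spec(illum$modulation_frequency_cpd, illum$orientations,
                   optical$pixel_scale)
  filt <- pre
  for (j in seq_len(n_frames(filt))) {
    filt$frames[, , j] <- notch_filter(filt$frames[, , j], ns)
  }
  tr <- estimate_shifts(filt, pixel_scale = optical$pixel_scale,
                        max_freq_cpd = cutoff_cpd(optical))
  rec <- reconstruct(pre, tr, optical, sim$illum, max_iter = 100)
  default_fixture_cache$res <- list(optical = optical, illum = sim$illum,
                                    sim = sim, pre = pre, trajectory = tr,
                                    rec = rec)
  default_fixture_cache$res
}
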