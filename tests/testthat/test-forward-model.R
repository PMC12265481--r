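test_that("diffraction-limited PSF and OTF match the circular-pupil model", {
  opt <- optical_model(pupil_diameter = 6.7, imaging_wavelength = 850,
                       oversampling_factor = 1L)
  expect_equal(signif(cutoff_cpd(opt), 2), 140)

  psf <- make_psf(opt, 0, c(128, 128))
  expect_true(all(psf >= 0))
  expect_equal(sum(psf), 1, tolerance = 1e-12)

  otf <- make_otf(psf)
  expect_equal(Mod(otf[1, 1]), 1, tolerance = 1e-12)
  g <- sior:::freq_grid(128, 128, d = opt$pixel_scale)
  expect_lt(max(Mod(otf)[g$rho > cutoff_cpd(opt) * 1.02]), 1e-12)

  # oracle: the in-focus OTF is the autocorrelation of the sampled pupil,
  # computed independently via |FFT|^2 of the pupil indicator
  pupil <- (g$rho <= cutoff_cpd(opt) / 2) + 0
  ac <- Re(stats::fft(Mod(stats::fft(pupil))^2, inverse = TRUE)) / length(pupil)
  ac <- ac / ac[1, 1]
  expect_lt(max(Mod(otf - ac)), 1e-6)

  # defocus spreads the PSF and shrinks the OTF area
  psf_d <- make_psf(opt, 1.5, c(128, 128))
  expect_lt(max(psf_d), max(psf))
  expect_lt(sum(Mod(make_otf(psf_d))), sum(Mod(otf)))

  # sampling guard: a coarse grid below the cutoff must error
  opt_coarse <- optical_model(pixel_scale = 1 / 100, oversampling_factor = 1L)
  expect_error(make_psf(opt_coarse, 0, c(64, 64)), "Nyquist")
})

test_that("fringe patterns have the stated period, range and positivity", {
  opt <- optical_model(oversampling_factor = 1L)
  il0 <- illumination_model(contrast_infocus = 0, mean_level = 1.5)
  expect_equal(make_pattern(il0, opt, c(32, 32), orientation = 45),
               matrix(1.5, 32, 32))

  il1 <- illumination_model(contrast_infocus = 1, phase = 0)
  p <- make_pattern(il1, opt, c(64, 64), orientation = 0)
  expect_equal(p[1, 1], 2)       # cosine peak at the origin
  expect_gte(min(p), 0)

  # FFT-peak oracle: f_m = 34 cpd at 403 px/degree -> period 403/34 px,
  # i.e. the spectral peak falls in bin round(N * f_m * pixel_scale)
  n <- 256
  p <- make_pattern(illumination_model(contrast_infocus = 0.8), opt, c(n, n),
                    orientation = 0)
  P <- Mod(stats::fft(p))^2
  P[1, 1] <- 0
  pk <- unname(which(P == max(P), arr.ind = TRUE)[1, ])
  expect_equal(pk[1], 1)                                  # no y component
  expect_equal(min(pk[2] - 1, n - (pk[2] - 1)),
               round(n * 34 * opt$pixel_scale))
  expect_error(illumination_model(contrast_infocus = 1.2), "contrast")
})

test_that("apply_shift is the periodic subpixel shift with exact inverse", {
  set.seed(1)
  img <- matrix(rnorm(64 * 64), 64)
  expect_identical(apply_shift(img, c(0, 0)), img)

  # integer-roll oracle
  r <- apply_shift(img, c(3, -2))
  roll <- img[((0:63 - 3) %% 64) + 1, ((0:63 + 2) %% 64) + 1]
  expect_equal(r, roll, tolerance = 1e-12)

  # inverse composition is exact on the band the pipeline lives in (no energy
  # at the self-conjugate Nyquist bins; the object grid always satisfies
  # Nyquist >= optical cutoff)
  s <- c(1.37, -4.81)
  Fb <- stats::fft(img)
  Fb[33, ] <- 0; Fb[, 33] <- 0       # zero the self-conjugate Nyquist bins
  band <- Re(stats::fft(Fb, inverse = TRUE)) / length(img)
  err <- max(abs(apply_shift(apply_shift(band, s), -s) - band))
  expect_lt(err / max(abs(band)), 1e-10)
  # and exactly, for integer shifts, on any image
  expect_equal(apply_shift(apply_shift(img, c(5, -3)), c(-5, 3)), img,
               tolerance = 1e-12)
  expect_error(apply_shift(img, c(NA, 0)), "finite")
})

test_that("downsample is comb decimation with zero-insertion adjoint", {
  ramp <- matrix(1:16, 4, 4, byrow = TRUE)
  expect_identical(downsample(ramp, 1L), ramp)
  expect_equal(downsample(ramp, 2L), ramp[c(1, 3), c(1, 3)])
  expect_error(downsample(matrix(0, 5, 5), 2L), "divisible")

  set.seed(2)
  x <- matrix(rnorm(36), 6)
  y <- matrix(rnorm(9), 3)
  expect_equal(sum(downsample(x, 2L) * y), sum(x * upsample_zeros(y, 2L)),
               tolerance = 1e-12)
})

test_that("forward operator: trivial cases, direct-convolution oracle, linearity", {
  opt <- optical_model(oversampling_factor = 1L)
  il <- illumination_model(contrast_infocus = 0, mean_level = 1)

  # uniform object, uniform illumination, zero shift -> constant image
  obj <- two_layer_object(matrix(3, 32, 32), matrix(0, 32, 32))
  m <- forward_image(obj, c(0, 0), opt, il, orientation = 45)
  expect_equal(m, matrix(3, 32, 32), tolerance = 1e-10)

  obj0 <- two_layer_object(matrix(0, 32, 32), matrix(0, 32, 32))
  expect_equal(forward_image(obj0, c(1, 2), opt, il, orientation = 45),
               matrix(0, 32, 32))

  # direct spatial-domain convolution oracle on a 32x32 grid, q = 2
  opt2 <- optical_model(oversampling_factor = 2L)
  il2 <- illumination_model(contrast_infocus = 0.7, contrast_background = 0.2)
  set.seed(3)
  obj2 <- two_layer_object(matrix(runif(32 * 32), 32), matrix(runif(32 * 32), 32))
  m_fft <- forward_image(obj2, c(0.6, -1.2), opt2, il2, orientation = -45)
  m_dir <- forward_direct(obj2, c(0.6, -1.2), opt2, il2, orientation = -45)
  expect_equal(m_fft, m_dir, tolerance = 1e-8)

  # linearity in (o0, od)
  oa <- two_layer_object(matrix(runif(32 * 32), 32), matrix(runif(32 * 32), 32))
  ob <- two_layer_object(matrix(runif(32 * 32), 32), matrix(runif(32 * 32), 32))
  lin <- two_layer_object(2 * oa$o0 - 3 * ob$o0, 2 * oa$od - 3 * ob$od)
  m_lin <- forward_image(lin, c(0.3, 0.4), opt2, il2, orientation = 45)
  m_sum <- 2 * forward_image(oa, c(0.3, 0.4), opt2, il2, orientation = 45) -
           3 * forward_image(ob, c(0.3, 0.4), opt2, il2, orientation = 45)
  expect_equal(m_lin, m_sum, tolerance = 1e-10)

  # shift-equivariance: shifting the object equals passing the shift to t_j
  s <- c(2.25, -0.75)
  shifted <- two_layer_object(apply_shift(oa$o0, s * 2), apply_shift(oa$od, s * 2))
  expect_equal(forward_image(oa, s, opt2, il2, orientation = 45),
               forward_image(shifted, c(0, 0), opt2, il2, orientation = 45),
               tolerance = 1e-9)
})

test_that("adjoint identity holds across q, shift and contrast", {
  set.seed(4)
  for (q in c(1L, 2L)) for (contrast in c(0, 0.8)) {
    opt <- optical_model(oversampling_factor = q)
    il <- illumination_model(contrast_infocus = contrast,
                             contrast_background = contrast / 4)
    n_obj <- 32 * q
    for (k in 1:3) {
      o <- two_layer_object(matrix(rnorm(n_obj^2), n_obj),
                            matrix(rnorm(n_obj^2), n_obj))
      r <- matrix(rnorm(32 * 32), 32)
      s <- rnorm(2, sd = 2)
      f <- forward_image(o, s, opt, il, orientation = 45)
      a <- adjoint_image(r, s, opt, il, orientation = 45)
      lhs <- sum(f * r)
      rhs <- sum(o$o0 * a$g0) + sum(o$od * a$gd)
      expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-12), 1e-10)
    }
  }
  il <- illumination_model()
  opt <- optical_model(oversampling_factor = 1L)
  z <- adjoint_image(matrix(0, 32, 32), c(1, 1), opt, il, orientation = 45)
  expect_equal(z$g0, matrix(0, 32, 32))
  expect_equal(z$gd, matrix(0, 32, 32))
})

test_that("forward output carries no energy beyond the SIM-extended band", {
  opt <- optical_model(oversampling_factor = 2L)
  il <- illumination_model(contrast_infocus = 0.9)
  set.seed(5)
  n_obj <- 128
  obj <- two_layer_object(matrix(runif(n_obj^2), n_obj), matrix(runif(n_obj^2), n_obj))
  # evaluate on the oversampled grid (before decimation): model the frame at
  # q = 1 output resolution but measure the pre-decimation spectrum instead
  ctx <- sior:::model_context(opt, il, c(64, 64))
  s0 <- Re(sior:::ifft2(stats::fft(obj$o0)))
  # pre-decimation field: h0 * (m . o0) + hd * (m_d . od)
  F0 <- stats::fft(sior:::ctx_pattern(ctx, 45, "infocus") * obj$o0) * ctx$otf0
  Fd <- stats::fft(sior:::ctx_pattern(ctx, 45, "background") * obj$od) * ctx$otfd
  field <- F0 + Fd
  g <- sior:::freq_grid(n_obj, n_obj, d = sior:::object_pixel_scale(opt))
  beyond <- g$rho > cutoff_cpd(opt) + il$modulation_frequency_cpd + 1e-9
  expect_lt(sum(Mod(field[beyond])^2) / sum(Mod(field)^2), 1e-8)
})
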