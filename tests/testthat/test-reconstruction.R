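test_that("unsupervised noise-variance estimation hits the plateau", {
  opt <- optical_model(oversampling_factor = 1L)
  # pure white noise of known variance, 20 seeds -> sigma^2 within 5%
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    st <- frame_stack(array(rnorm(64 * 64 * 12, 0, 0.2), c(64, 64, 12)),
                      orientation = rep(c(45, -45), 6))
    estimate_hyperparameters(st, opt)$sigma2 / 0.04 - 1
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.05)

  # noise-free bandlimited stack: no plateau energy
  il <- illumination_model(contrast_infocus = 0.5)
  ph <- generate_phantom(phantom_spec(field_of_view = 64 / 403), opt)
  acq <- acquisition_spec(n_frames = 12, frame_rate = 100, switching_rate = 100 / 6,
                          noise_sigma = 0, blink_fraction = 0, dark_offset = 0,
                          n_dark = 2)
  tr <- generate_trajectory(acq, 12, rng_seed = 1)
  sim <- generate_stack(ph, tr, opt, il, acq, rng_seed = 1)
  hy0 <- estimate_hyperparameters(sim$stack, opt)
  sig_power <- mean(sim$stack$frames^2)
  expect_lt(hy0$sigma2, 1e-6 * sig_power)

  # plateau requires frequencies above the cutoff
  opt_coarse <- optical_model(pixel_scale = 1 / 260, oversampling_factor = 1L)
  st <- frame_stack(array(rnorm(32 * 32 * 10), c(32, 32, 10)),
                    orientation = rep(45, 10))
  expect_error(estimate_hyperparameters(st, opt_coarse), "plateau")
})

test_that("object PSD fit recovers a known power law", {
  opt <- optical_model(oversampling_factor = 1L)
  n <- 128
  g <- sior:::freq_grid(n, n, d = opt$pixel_scale)
  S_true <- 50 / (1 + (g$rho / 30)^3)
  # bandlimit the object (one bin short of f_c, so no straddling bin pollutes
  # the noise plateau)
  S_true[g$rho > cutoff_cpd(opt) - 1 / (n * opt$pixel_scale)] <- 0
  set.seed(42)
  Fo <- stats::fft(matrix(rnorm(n * n), n)) * sqrt(S_true)
  o <- Re(stats::fft(Fo, inverse = TRUE)) / n^2  # periodogram of o ~ S_true
  fr <- array(0, c(n, n, 15))
  for (j in 1:15) {
    set.seed(100 + j)
    fr[, , j] <- o + matrix(rnorm(n * n, 0, 1.5), n)
  }
  hy <- estimate_hyperparameters(frame_stack(fr, orientation = rep(45, 15)), opt)
  expect_lt(abs(hy$sigma2 - 2.25) / 2.25, 0.05)
  expect_lt(abs(hy$S0$p - 3) / 3, 0.20)
  # the defocused layer reuses the fit with a narrower knee
  expect_lt(hy$Sd$f0, hy$S0$f0)
  expect_equal(hy$Sd$p, hy$S0$p)
})

test_that("criterion value matches a naive evaluation and behaves at edges", {
  opt <- optical_model(oversampling_factor = 1L)
  il <- illumination_model(contrast_infocus = 0.6, contrast_background = 0.1)
  hy <- hyperparameters(0.04, list(k = 1, f0 = 30, p = 2),
                        list(k = 1, f0 = 8, p = 2), lambda = 0.3)

  # zero object, zero data -> J = 0
  obj0 <- two_layer_object(matrix(0, 16, 16), matrix(0, 16, 16))
  st0 <- frame_stack(array(0, c(16, 16, 2)), orientation = c(45, -45))
  sh0 <- shift_trajectory(c(0, 0), c(0, 0))
  expect_equal(as.numeric(criterion(obj0, st0, sh0, opt, il, hy)), 0)

  # noise-free consistent pair with lambda = 0 -> J ~ 0
  set.seed(5)
  obj <- two_layer_object(matrix(runif(256), 16), matrix(runif(256), 16))
  sh <- shift_trajectory(c(0, 1.3), c(0, -0.4))
  fr <- array(0, c(16, 16, 2))
  fr[, , 1] <- forward_image(obj, c(0, 0), opt, il, orientation = 45)
  fr[, , 2] <- forward_image(obj, c(1.3, -0.4), opt, il, orientation = -45)
  st <- frame_stack(fr, orientation = c(45, -45))
  hy0 <- hyperparameters(0.04, hy$S0, hy$Sd, lambda = 0)
  expect_lt(as.numeric(criterion(obj, st, sh, opt, il, hy0)), 1e-12)

  # naive double-loop oracle: explicit forward residuals + explicit penalty
  set.seed(6)
  st$frames <- st$frames + array(rnorm(512, 0, 0.1), c(16, 16, 2))
  J <- as.numeric(criterion(obj, st, sh, opt, il, hy))
  g <- sior:::freq_grid(16, 16, d = opt$pixel_scale)
  pen <- function(o, S) {
    sum(Mod(stats::fft(o))^2 / sior:::psd_profile(S, g$rho)) / 256
  }
  Jn <- 0
  for (j in 1:2) {
    M <- forward_image(obj, c(sh$dy[j], sh$dx[j]), opt, il,
                       orientation = st$orientation[j])
    Jn <- Jn + 0.5 * sum((st$frames[, , j] - M)^2) / hy$sigma2
  }
  Jn <- Jn + (hy$lambda / 2) * (pen(obj$o0, hy$S0) + pen(obj$od, hy$Sd))
  expect_lt(abs(J - Jn) / Jn, 1e-10)
})

test_that("criterion gradient matches central finite differences", {
  opt <- optical_model(oversampling_factor = 2L)
  il <- illumination_model(contrast_infocus = 0.6, contrast_background = 0.1)
  hy <- hyperparameters(0.04, list(k = 1, f0 = 30, p = 2),
                        list(k = 1, f0 = 8, p = 2), lambda = 0.3)
  h <- 1e-5
  for (s in 1:5) {
    set.seed(s)
    obj <- two_layer_object(matrix(runif(32 * 32), 32), matrix(runif(32 * 32), 32))
    st <- frame_stack(array(rnorm(16 * 16 * 3), c(16, 16, 3)),
                      orientation = c(45, -45, 45))
    sh <- shift_trajectory(rnorm(3), rnorm(3))
    gr <- criterion_gradient(obj, st, sh, opt, il, hy)
    for (k in 1:2) {
      i <- sample(32, 1); j <- sample(32, 1)
      for (layer in c("o0", "od")) {
        op <- obj; op[[layer]][i, j] <- op[[layer]][i, j] + h
        om <- obj; om[[layer]][i, j] <- om[[layer]][i, j] - h
        fd <- (as.numeric(criterion(op, st, sh, opt, il, hy)) -
               as.numeric(criterion(om, st, sh, opt, il, hy))) / (2 * h)
        gval <- if (layer == "o0") gr$g0[i, j] else gr$gd[i, j]
        expect_lt(abs(fd - gval) / max(abs(fd), 1e-8), 1e-5)
      }
    }
  }

  # closed form: the penalty-only gradient is lambda * F^-1(o~ / S) per layer
  set.seed(9)
  obj <- two_layer_object(matrix(runif(256), 16), matrix(runif(256), 16))
  st0 <- frame_stack(array(0, c(16, 16, 1)), orientation = 45)
  sh0 <- shift_trajectory(0, 0)
  opt1 <- optical_model(oversampling_factor = 1L)
  hy_pen <- hyperparameters(1e30, list(k = 1, f0 = 30, p = 2),
                            list(k = 1, f0 = 8, p = 2), lambda = 0.3)
  gr <- criterion_gradient(obj, st0, sh0, opt1, il, hy_pen)
  g <- sior:::freq_grid(16, 16, d = opt1$pixel_scale)
  S0 <- sior:::psd_profile(hy_pen$S0, g$rho)
  ref <- 0.3 * Re(stats::fft(stats::fft(obj$o0) / S0, inverse = TRUE)) / 256
  expect_equal(gr$g0, ref, tolerance = 1e-10)
})

test_that("reconstruction solves the trivial inverse problem to < 1% error", {
  # identity limit: q = 1, zero shifts, uniform illumination, near-delta PSF
  opt <- optical_model(pupil_diameter = 9.5, imaging_wavelength = 850,
                       oversampling_factor = 1L)   # cutoff 195 cpd ~ 0.97 Nyquist
  il <- illumination_model(contrast_infocus = 0)
  set.seed(7)
  truth <- sior:::gaussian_blur(matrix(runif(64 * 64, 0.2, 1), 64), 1.2)
  truth[truth < 0] <- 0
  obj <- two_layer_object(truth, truth * 0)
  fr <- array(0, c(64, 64, 14))
  for (j in 1:14) fr[, , j] <- forward_image(obj, c(0, 0), opt, il, orientation = 45)
  st <- frame_stack(fr, orientation = rep(c(45, -45), each = 7))
  sh <- shift_trajectory(rep(0, 14), rep(0, 14))
  # strong penalty on od confines the energy to the in-focus layer
  hy <- hyperparameters(1e-6, list(k = 10, f0 = 200, p = 2),
                        list(k = 1e-12, f0 = 10, p = 2), lambda = 1e-6)
  rec <- reconstruct(st, sh, opt, il, hyper = hy, max_iter = 400, tol = 1e-12)
  rel <- sqrt(mean((rec$object$o0 - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(rel, 0.01)

  # trace is non-increasing, object is non-negative, convergence is flagged
  expect_true(all(diff(rec$trace) <= 1e-9 * pmax(abs(rec$trace[-1]), 1)))
  expect_gte(min(rec$object$o0), 0)
  expect_gte(min(rec$object$od), 0)

  # determinism: same inputs, bit-identical result
  rec2 <- reconstruct(st, sh, opt, il, hyper = hy, max_iter = 400, tol = 1e-12)
  expect_identical(rec$object$o0, rec2$object$o0)

  # unbalanced orientations are a precondition error
  st_bad <- sior:::stack_subset(st, 1:10)
  expect_error(reconstruct(st_bad, sh, opt, il, hyper = hy), "unbalanced")
})

test_that("positivity induces spectral extrapolation for a dark-background object", {
  n <- 128
  opt <- optical_model(oversampling_factor = 1L)
  il <- illumination_model(contrast_infocus = 0.7)
  set.seed(3)
  o0 <- matrix(0, n, n)
  idx <- cbind(sample(20:108, 12), sample(20:108, 12))
  o0[idx] <- runif(12, 0.5, 1.5)
  obj <- two_layer_object(o0, o0 * 0)
  acqd <- acquire_object(obj, opt, il, n_per_orient = 7, snr = 20, seed = 4)
  hy <- hyperparameters(acqd$sigma^2, list(k = 1e-3, f0 = 140, p = 2),
                        list(k = 1e-3, f0 = 10, p = 2), lambda = 0.3)
  g <- sior:::freq_grid(n, n, d = opt$pixel_scale)
  beyond <- g$rho > cutoff_cpd(opt) + il$modulation_frequency_cpd
  en <- function(img) sum(Mod(stats::fft(img))[beyond]^2)
  r_pos <- reconstruct(acqd$stack, acqd$trajectory, opt, acqd$illum, hyper = hy,
                       max_iter = 80, tol = 1e-8)
  r_quad <- reconstruct(acqd$stack, acqd$trajectory, opt, acqd$illum, hyper = hy,
                        max_iter = 80, tol = 1e-8, positivity = FALSE)
  expect_gt(en(r_pos$object$o0), en(r_quad$object$o0))
})
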