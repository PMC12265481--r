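test_that("wide-field construction: trivial cases and fringe cancellation", {
  img <- matrix(rnorm(64 * 64), 64)
  st1 <- frame_stack(array(img, c(64, 64, 1)), orientation = 45)
  expect_equal(build_widefield(st1, shift_trajectory(0, 0)), img)

  # two frames with opposite fringe phases cancel exactly
  opt <- optical_model(oversampling_factor = 1L)
  ila <- illumination_model(contrast_infocus = 1, phase = 0)
  ilb <- illumination_model(contrast_infocus = 1, phase = pi)
  pa <- make_pattern(ila, opt, c(64, 64), orientation = 45)
  pb <- make_pattern(ilb, opt, c(64, 64), orientation = 45)
  st2 <- frame_stack(array(c(pa, pb), c(64, 64, 2)), orientation = c(45, 45))
  wf <- build_widefield(st2, shift_trajectory(c(0, 0), c(0, 0)))
  expect_equal(wf, matrix(1, 64, 64), tolerance = 1e-12)
  expect_error(build_widefield(st2, shift_trajectory(0, 0)), "missing")

  # full-length acquisition: residual fringe carrier in the average >= 20 dB
  # below a single frame's. Carrier cancellation by drift-supplied phases
  # converges slowly (the phases are a correlated random walk), so this uses
  # the instrument's full 1000-frame sequence; the carrier is measured by a
  # matched filter at the exact fringe frequency, which object content near
  # f_m cannot pollute.
  il <- illumination_model(contrast_infocus = 0.7)
  ph <- generate_phantom(phantom_spec(field_of_view = 64 / 403), opt)
  acql <- acquisition_spec(n_frames = 1000, noise_sigma = 0, blink_fraction = 0,
                           dark_offset = 0, n_dark = 2, drift_step = 2,
                           microsaccade_rate = 1)
  trl <- generate_trajectory(acql, 1000, rng_seed = 11)
  siml <- generate_stack(ph, trl, opt, il, acql, rng_seed = 11)
  wf <- build_widefield(siml$stack, trl, illum = siml$illum,
                        pixel_scale = opt$pixel_scale)
  carrier_amp <- function(frame, th) {
    n <- nrow(frame)
    x <- (seq_len(n) - 1) * opt$pixel_scale
    thr <- th * pi / 180
    arg <- 2 * pi * 34 * outer(x * sin(thr), x * cos(thr), `+`)
    Mod(sum(frame * exp(-1i * arg))) / length(frame)
  }
  j45 <- which(siml$stack$orientation == 45)[1]
  ratio <- carrier_amp(wf, 45) / carrier_amp(siml$stack$frames[, , j45], 45)
  expect_lt(20 * log10(ratio), -20)
  expect_true(all(attr(wf, "fringe_energy") >= 0))
})

test_that("radial PSD: Parseval, white-noise level, cosine localization", {
  d <- 1 / 403
  set.seed(1)
  x <- matrix(rnorm(64 * 64), 64)
  sp <- radial_psd(x, d)
  expect_error(radial_psd(matrix(0, 4, 6), d), "square")
  expect_true(all(diff(sp$freq) > 0))
  # Parseval: per-bin means weighted by counts recover the mean square
  expect_equal(sum(sp$psd * sp$n), mean(x^2), tolerance = 1e-10)

  # white noise of variance v is flat at v / N per bin (Monte-Carlo; the
  # smallest radial bins hold few independent coefficients, hence many seeds)
  n <- 32; v <- 4; nseed <- 256
  acc <- 0
  for (s in 1:nseed) {
    set.seed(s)
    acc <- acc + radial_psd(matrix(rnorm(n * n, 0, 2), n), d)$psd / nseed
  }
  expect_lt(max(abs(acc[-1] - v / n^2) / (v / n^2)), 0.10)

  # a pure cosine concentrates in the bin at its radial frequency
  k <- 9
  cosx <- outer(rep(1, 64), cos(2 * pi * k * (0:63) / 64))
  spc <- radial_psd(cosx, d)
  expect_equal(which.max(spc$psd), k + 1)
})

test_that("effective cutoff: floor crossing, oracle spectrum, noise monotonicity", {
  d <- 1 / 403
  set.seed(2)
  noise <- matrix(rnorm(128 * 128, 0, 1), 128)
  sp_n <- radial_psd(noise, d)
  floor_v <- 1 / 128^2
  expect_equal(effective_cutoff(sp_n, floor_v), sp_n$freq[2])
  expect_error(effective_cutoff(sp_n, 0), "positive")

  # constructed spectrum: bandlimited content + noise crosses at the band edge
  B <- 120
  g <- sior:::freq_grid(128, 128, d = d)
  Fo <- stats::fft(matrix(rnorm(128 * 128), 128))
  Fo[g$rho > B] <- 0
  content <- Re(stats::fft(Fo, inverse = TRUE)) / 128^2
  content <- content * (30 / stats::sd(content))
  frame <- content + noise
  sp <- radial_psd(frame, d)
  cut <- effective_cutoff(sp, floor_v)
  df <- 1 / (128 * d)
  expect_lt(abs(cut - B), 2 * df)

  # adding white noise never increases the estimated cutoff
  cuts <- vapply(c(0, 1, 3, 10), function(extra) {
    set.seed(5)
    fr <- frame + matrix(rnorm(128 * 128, 0, extra), 128)
    effective_cutoff(radial_psd(fr, d), (1 + extra^2) / 128^2)
  }, numeric(1))
  expect_true(all(diff(cuts) <= df + 1e-9))
})

test_that("bandpass background correction removes the vignette, keeps the cones", {
  d <- 1 / 403
  expect_equal(background_correct(matrix(5, 64, 64), 10, 150, d),
               matrix(0, 64, 64), tolerance = 1e-12)

  # low_cut -> 0, high_cut -> large: identity minus DC
  set.seed(3)
  x <- matrix(rnorm(64 * 64, 2), 64)
  out <- background_correct(x, 1e-6, 1e6, d)
  expect_equal(out, x - mean(x), tolerance = 1e-6)
  expect_error(background_correct(x, 100, 50, d), "low_cut")

  # smooth vignette attenuated > 20 dB; cone-band content < 1 dB
  n <- 256
  g <- sior:::freq_grid(n, n, d = d)
  vignette <- outer(sin(pi * (1:n) / n), sin(pi * (1:n) / n))  # ~2 cpd content
  k <- round(111 * n * d)                                      # cone band ~111 cpd
  cones <- outer(rep(1, n), cos(2 * pi * k * (0:(n - 1)) / n))
  bc_v <- background_correct(vignette, 15, 140, d)
  bc_c <- background_correct(cones, 15, 140, d)
  expect_lt(10 * log10(sum(bc_v^2) / sum((vignette - mean(vignette))^2)), -20)
  expect_gt(10 * log10(sum(bc_c^2) / sum(cones^2)), -1)
})

test_that("cone detection: lattice recall/precision, suppression, blanks", {
  opt <- optical_model(oversampling_factor = 1L)
  ph <- phantom_spec(field_of_view = 256 / 403, spacing_jitter = 0,
                     reflectance_cv = 0.2, background_to_signal_ratio = 0)
  phan <- generate_phantom(ph, opt)
  truth <- attr(phan, "cones")
  um_per_px <- opt$retinal_scale * opt$pixel_scale
  s_px <- ph$cone_spacing / um_per_px
  det <- detect_cones(phan$o0, 0.7 * s_px)

  interior <- truth[, 1] > s_px & truth[, 1] < 255 - s_px &
              truth[, 2] > s_px & truth[, 2] < 255 - s_px
  ti <- truth[interior, ]
  m_ti <- outer(det[, 1], ti[, 1], `-`)^2 + outer(det[, 2], ti[, 2], `-`)^2
  recall <- sum(apply(m_ti, 2, min) < 4) / nrow(ti)
  m_all <- outer(det[, 1], truth[, 1], `-`)^2 + outer(det[, 2], truth[, 2], `-`)^2
  precision <- sum(apply(m_all, 1, min) < 4) / nrow(det)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)

  expect_equal(nrow(detect_cones(matrix(1, 32, 32), 4)), 0)
  expect_error(detect_cones(matrix(1, 32, 32), 1), "at least 2")

  # two points closer than min_separation give a single detection
  two <- matrix(0, 32, 32)
  two[15, 15] <- 1; two[15, 18] <- 0.9
  expect_equal(nrow(detect_cones(two, 5)), 1)
})

test_that("cone density maps: closed-form lattice, Poisson rate, empty input", {
  opt <- optical_model(oversampling_factor = 1L)
  ph <- phantom_spec(field_of_view = 256 / 403, spacing_jitter = 0,
                     background_to_signal_ratio = 0)
  truth <- attr(generate_phantom(ph, opt), "cones")
  dm <- cone_density_map(truth, c(256, 256), opt$pixel_scale,
                         fovea_center = c(128, 128), window_size = 96,
                         stride = 16)
  expected <- 2 / (sqrt(3) * ph$cone_spacing^2) * 1e6   # cones / mm^2
  expect_lt(abs(mean(dm$density) / expected - 1), 0.02)
  prof <- attr(dm, "profile")
  expect_true(all(prof$reliable == (prof$mean > 0 & prof$sd / prof$mean <= 0.1)))

  # uniform random positions at rate rho: mean within 3 standard errors
  set.seed(4)
  n_pts <- 3000
  pos <- cbind(runif(n_pts, 0, 256), runif(n_pts, 0, 256))
  mm_per_px <- opt$pixel_scale * opt$retinal_scale / 1000
  rho <- n_pts / (256 * mm_per_px)^2
  dmp <- cone_density_map(pos, c(256, 256), opt$pixel_scale,
                          window_size = 64, stride = 32)
  w_mm2 <- (64 * mm_per_px)^2
  se <- sqrt(rho / w_mm2) / sqrt(nrow(dmp))
  expect_lt(abs(mean(dmp$density) - rho), 3 * se * 3)

  dme <- cone_density_map(matrix(numeric(0), 0, 2), c(64, 64), opt$pixel_scale,
                          window_size = 32)
  expect_true(all(dme$density == 0))
  expect_false(any(attr(dme, "profile")$reliable))
})
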