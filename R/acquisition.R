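#' Acquisition specification
#'
#' Timing, eye-motion and noise parameters of a synthetic acquisition.
#' Defaults follow the instrument geometry: 100 Hz frame rate with the fringe
#' orientation switching at 2 Hz, so the orientation alternates every 50
#' frames.
#'
#' @param n_frames Number of frames to acquire.
#' @param frame_rate Camera frame rate, Hz.
#' @param switching_rate Fringe orientation switching rate, Hz;
#'   `frame_rate / switching_rate` must be an integer (frames per block).
#' @param noise_sigma Additive homogeneous Gaussian noise standard deviation,
#'   intensity units.
#' @param drift_step RMS per-frame drift increment (vector magnitude), camera
#'   pixels.
#' @param microsaccade_rate Expected microsaccades per second.
#' @param microsaccade_amplitude Microsaccade jump amplitude, camera pixels.
#' @param blink_fraction Fraction of frames degraded by a blink surrogate
#'   (Gaussian blur of 3 px and a 50% intensity drop).
#' @param dark_offset Camera offset, intensity units.
#' @param n_dark Number of dark frames to synthesize.
#' @return An object of class `sio_acq_spec`.
#' @export
acquisition_spec <- function(n_frames = 100L,
                             frame_rate = 100,
                             switching_rate = 2,
                             noise_sigma = 0.05,
                             drift_step = 1,
                             microsaccade_rate = 0.5,
                             microsaccade_amplitude = 30,
                             blink_fraction = 0.05,
                             dark_offset = 100,
                             n_dark = 100L) {
  stopifnot(n_frames >= 1, frame_rate > 0, switching_rate > 0,
            noise_sigma >= 0, drift_step >= 0, microsaccade_rate >= 0,
            blink_fraction >= 0, blink_fraction <= 1, n_dark >= 1)
  fpb <- frame_rate / switching_rate
  if (abs(fpb - round(fpb)) > 1e-9) {
    stop("frame_rate / switching_rate (frames per orientation block) must be an integer")
  }
  structure(c(as.list(environment()), list(frames_per_block = as.integer(round(fpb)))),
            class = "sio_acq_spec")
}

#' Generate an eye-motion shift trajectory
#'
#' Cumulative Gaussian random-walk drift (per-frame increment of RMS magnitude
#' `drift_step`) plus Poisson-timed microsaccade jumps of amplitude
#' `microsaccade_amplitude` in a uniform random direction. Frame 0 is the
#' reference and has shift (0, 0); frames at which a jump occurs are flagged
#' in the `saccade` column.
#'
#' @param spec An [acquisition_spec()].
#' @param n_frames Number of frames (defaults to `spec$n_frames`).
#' @param rng_seed Integer seed.
#' @return A [shift_trajectory()] with an extra logical `saccade` column.
#' @export
generate_trajectory <- function(spec, n_frames = spec$n_frames, rng_seed = 1L) {
  stopifnot(n_frames >= 1)
  with_seed(rng_seed, {
    sd_axis <- spec$drift_step / sqrt(2)
    ddy <- c(0, stats::rnorm(n_frames - 1, 0, sd_axis))
    ddx <- c(0, stats::rnorm(n_frames - 1, 0, sd_axis))
    sacc <- rep(FALSE, n_frames)
    if (spec$microsaccade_rate > 0 && n_frames > 1) {
      p <- spec$microsaccade_rate / spec$frame_rate
      jump <- stats::runif(n_frames - 1) < p
      if (any(jump)) {
        th <- stats::runif(sum(jump), 0, 2 * pi)
        ddy[which(jump) + 1L] <- ddy[which(jump) + 1L] +
          spec$microsaccade_amplitude * sin(th)
        ddx[which(jump) + 1L] <- ddx[which(jump) + 1L] +
          spec$microsaccade_amplitude * cos(th)
        sacc[which(jump) + 1L] <- TRUE
      }
    }
    tr <- shift_trajectory(cumsum(ddy), cumsum(ddx))
    tr$saccade <- sacc
    tr
  })
}

#' Frame stack container
#'
#' Ordered 2-D intensity frames with per-frame metadata: fringe orientation
#' (degrees), timestamp (seconds), 0-based original frame index and quality
#' flags.
#'
#' @param frames 3-D numeric array `[ny, nx, n_frames]`.
#' @param orientation Numeric vector of fringe orientations, degrees.
#' @param timestamp Numeric vector of acquisition times, seconds.
#' @param frame_index Integer vector of 0-based original frame indices.
#' @param blink Logical vector flagging degraded frames (simulator truth).
#' @return An object of class `sio_stack`.
#' @export
frame_stack <- function(frames, orientation,
                        timestamp = seq_len(dim(frames)[3]) - 1,
                        frame_index = seq_len(dim(frames)[3]) - 1L,
                        blink = rep(FALSE, dim(frames)[3])) {
  stopifnot(length(dim(frames)) == 3)
  n <- dim(frames)[3]
  stopifnot(length(orientation) == n, length(timestamp) == n,
            length(frame_index) == n, length(blink) == n)
  structure(list(frames = frames, orientation = orientation,
                 timestamp = timestamp, frame_index = as.integer(frame_index),
                 blink = blink),
            class = "sio_stack")
}

#' @export
print.sio_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("sio_stack: %d frames of %d x %d px; orientations: %s\n",
              d[3], d[1], d[2],
              paste(sprintf("%g deg (n=%d)", unique(x$orientation),
                            tabulate(match(x$orientation, unique(x$orientation)))),
                    collapse = ", ")))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

# subset a stack by frame positions (1-based), keeping metadata aligned
stack_subset <- function(stack, idx) {
  out <- frame_stack(stack$frames[, , idx, drop = FALSE],
                     orientation = stack$orientation[idx],
                     timestamp = stack$timestamp[idx],
                     frame_index = stack$frame_index[idx],
                     blink = stack$blink[idx])
  out$window <- stack$window
  out
}

#' Simulate a structured-illumination acquisition
#'
#' Applies the forward imaging model to the phantom frame by frame along the
#' motion trajectory, with block-switched fringe orientation, then adds the
#' camera offset and homogeneous Gaussian noise. Blink-surrogate frames are
#' low-pass blurred (3 px) and dimmed by 50% before noise. A matching dark
#' stack (offset + noise only) is returned for dark subtraction.
#'
#' @param phantom A [generate_phantom()] result (or any [two_layer_object()]).
#' @param trajectory A [shift_trajectory()]; its length sets the frame count.
#' @param optical An [optical_model()].
#' @param illum An [illumination_model()]; its `frames_per_block` is set from
#'   the acquisition spec.
#' @param acq An [acquisition_spec()].
#' @param rng_seed Integer seed for noise and blink placement.
#' @return List with elements `stack` (a [frame_stack()]), `dark` (a
#'   [frame_stack()]), `trajectory`, `illum` (with block length set), and
#'   `snr` (mean in-focus signal over noise sigma; `Inf` when noiseless).
#' @export
generate_stack <- function(phantom, trajectory, optical, illum, acq,
                           rng_seed = 1L) {
  illum$frames_per_block <- acq$frames_per_block
  n <- nrow(trajectory)
  q <- optical$oversampling_factor
  if (any(dim(phantom$o0) %% q != 0)) stop("phantom grid not divisible by oversampling factor")
  cam_shape <- dim(phantom$o0) %/% q
  ctx <- model_context(optical, illum, cam_shape)
  Fo0 <- fft2(phantom$o0); Fod <- fft2(phantom$od)
  frames <- array(0, c(cam_shape[1], cam_shape[2], n))
  orient <- orientation_for_frame(illum, seq_len(n) - 1L)
  signal_mean <- 0
  for (j in seq_len(n)) {
    m <- forward_frame_fft(ctx, Fo0, Fod,
                           c(trajectory$dy[j], trajectory$dx[j]), orient[j])
    frames[, , j] <- m
    signal_mean <- signal_mean + mean(m) / n
  }
  with_seed(rng_seed, {
    blink <- rep(FALSE, n)
    n_blink <- round(acq$blink_fraction * n)
    if (n_blink > 0) {
      blink[sample.int(n, n_blink)] <- TRUE
      for (j in which(blink)) {
        frames[, , j] <- 0.5 * gaussian_blur(frames[, , j], 3)
      }
    }
    if (acq$noise_sigma > 0) {
      frames <- frames + acq$dark_offset +
        array(stats::rnorm(length(frames), 0, acq$noise_sigma), dim(frames))
    } else {
      frames <- frames + acq$dark_offset
    }
    dk <- array(acq$dark_offset, c(cam_shape[1], cam_shape[2], acq$n_dark))
    if (acq$noise_sigma > 0) {
      dk <- dk + array(stats::rnorm(length(dk), 0, acq$noise_sigma), dim(dk))
    }
    stack <- frame_stack(frames, orientation = orient,
                         timestamp = (seq_len(n) - 1) / acq$frame_rate,
                         blink = blink)
    dark <- frame_stack(dk, orientation = rep(NA_real_, acq$n_dark),
                        timestamp = (seq_len(acq$n_dark) - 1) / acq$frame_rate)
    list(stack = stack, dark = dark, trajectory = trajectory, illum = illum,
         snr = if (acq$noise_sigma > 0) signal_mean / acq$noise_sigma else Inf)
  })
}

#' One-call synthetic acquisition
#'
#' Convenience wrapper: phantom + trajectory + frame stack from specs and a
#' single seed. The per-stage seeds are derived deterministically from
#' `seed`.
#'
#' @param phantom_spec A [phantom_spec()].
#' @param acq An [acquisition_spec()].
#' @param optical An [optical_model()].
#' @param illum An [illumination_model()].
#' @param seed Master integer seed.
#' @param snr If not `NULL`, overrides `acq$noise_sigma` so that the mean
#'   noise-free signal over sigma equals `snr`.
#' @return List as [generate_stack()], plus `phantom` (ground truth).
#' @export
simulate_acquisition <- function(phantom_spec = sior::phantom_spec(),
                                 acq = acquisition_spec(),
                                 optical = optical_model(),
                                 illum = illumination_model(),
                                 seed = 1L, snr = NULL) {
  phantom_spec$rng_seed <- seed
  phantom <- generate_phantom(phantom_spec, optical)
  traj <- generate_trajectory(acq, acq$n_frames, rng_seed = seed + 1L)
  if (!is.null(snr)) {
    # calibrate sigma on a noiseless render of the first frame
    acq0 <- acq; acq0$noise_sigma <- 0; acq0$blink_fraction <- 0
    illum$frames_per_block <- acq$frames_per_block
    m1 <- forward_image(phantom, c(0, 0), optical, illum, frame_index = 0L)
    acq$noise_sigma <- mean(m1) / snr
  }
  out <- generate_stack(phantom, traj, optical, illum, acq, rng_seed = seed + 2L)
  out$phantom <- phantom
  out$acq <- acq
  out$optical <- optical
  out
}
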