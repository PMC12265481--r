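#' Gradient energy of a frame
#'
#' Sum of squared forward differences along x and y (last column/row
#' differences omitted). Sharp frames score high; blur smooths edges and
#' lowers the score, which is what makes this a blink/microsaccade quality
#' metric. Scales as `a^2` under intensity scaling by `a`, so the top-quantile
#' ranking used in selection is invariant to global gain.
#'
#' @param frame Numeric matrix, at least 2 x 2.
#' @return Non-negative scalar.
#' @export
gradient_energy <- function(frame) {
  as_image(frame, "frame")
  if (nrow(frame) < 2 || ncol(frame) < 2) stop("frame must be at least 2 x 2")
  dx <- frame[, -1, drop = FALSE] - frame[, -ncol(frame), drop = FALSE]
  dy <- frame[-1, , drop = FALSE] - frame[-nrow(frame), , drop = FALSE]
  sum(dx^2) + sum(dy^2)
}

#' Fringe-contrast energy of a frame
#'
#' Fraction of the frame's non-DC spectral energy lying in discs of
#' `tolerance_bins` frequency bins around the two conjugate fringe peaks
#' `+/-(f_m, orientation)`. Lies in `[0, 1]`; a pure fringe gives ~1 and a
#' fringe-free frame ~0.
#'
#' @param frame Numeric matrix (square).
#' @param f_m Fringe frequency, cycles/degree.
#' @param orientation Fringe orientation, degrees.
#' @param pixel_scale Pixel scale, degrees/pixel.
#' @param tolerance_bins Disc radius in frequency bins (default 3).
#' @return Scalar in `[0, 1]`.
#' @export
fringe_contrast_energy <- function(frame, f_m, orientation, pixel_scale,
                                   tolerance_bins = 3) {
  as_image(frame, "frame")
  n <- nrow(frame)
  nyq <- 1 / (2 * pixel_scale)
  if (f_m >= nyq) stop("f_m is at or above the frame Nyquist frequency")
  g <- freq_grid(nrow(frame), ncol(frame), d = pixel_scale)
  df <- 1 / (n * pixel_scale)
  th <- orientation * pi / 180
  ty <- f_m * sin(th); tx <- f_m * cos(th)
  disc <- (sqrt((g$fy - ty)^2 + (g$fx - tx)^2) <= tolerance_bins * df) |
          (sqrt((g$fy + ty)^2 + (g$fx + tx)^2) <= tolerance_bins * df)
  P <- Mod(fft2(frame))^2
  total <- sum(P) - P[1, 1]
  if (total <= 0) return(0)
  sum(P[disc]) / total
}

#' Three-step frame selection
#'
#' Step 1 retains the top `quality_quantile` of frames by [gradient_energy()]
#' (ties broken by frame index, earlier first). Step 2 keeps, among the
#' survivors, the contiguous time window of length `window_seconds` that
#' maximizes the mean [fringe_contrast_energy()] (a deterministic surrogate
#' for visual inspection of modulation contrast). Step 3 balances the
#' orientation groups by discarding the lowest-contrast frames of the
#' over-represented orientation until per-orientation counts are equal.
#'
#' @param stack A pre-processed [frame_stack()] with timestamps and
#'   orientation labels.
#' @param illum An [illumination_model()] (fringe frequency).
#' @param pixel_scale Pixel scale of the frames, degrees/pixel.
#' @param window_seconds Length of the step-2 time window (default 2 s).
#' @param quality_quantile Fraction retained in step 1 (default 0.5).
#' @param tolerance_bins Disc radius for the contrast metric (default 3).
#' @return An object of class `sio_selection`: the `selected` stack plus the
#'   per-frame metrics, per-step retention flags and final per-orientation
#'   counts.
#' @export
select_frames <- function(stack, illum, pixel_scale,
                          window_seconds = 2, quality_quantile = 0.5,
                          tolerance_bins = 3) {
  n <- n_frames(stack)
  ge <- vapply(seq_len(n), function(j) gradient_energy(stack$frames[, , j]),
               numeric(1))
  fce <- vapply(seq_len(n), function(j) {
    fringe_contrast_energy(stack$frames[, , j], illum$modulation_frequency_cpd,
                           stack$orientation[j], pixel_scale, tolerance_bins)
  }, numeric(1))

  # step 1: top-quantile quality, earlier frame wins ties
  k <- floor(n * quality_quantile + 1e-9)
  if (k < 1) stop("selection failed at step 1 (quality filter): no survivors")
  ord <- order(-ge, seq_len(n))
  keep1 <- rep(FALSE, n); keep1[ord[seq_len(k)]] <- TRUE

  # step 2: best full-length contiguous window of mean fringe contrast among
  # survivors; starts are clamped so every candidate window spans
  # window_seconds (otherwise a late singleton window wins the mean)
  idx1 <- which(keep1)
  t1 <- stack$timestamp[idx1]
  starts <- unique(pmin(t1, max(t1) - window_seconds))
  best <- -Inf; best_in <- NULL
  for (s in starts) {
    inw <- t1 >= s & t1 <= s + window_seconds
    m <- mean(fce[idx1[inw]])
    if (m > best) { best <- m; best_in <- inw }
  }
  keep2 <- rep(FALSE, n); keep2[idx1[best_in]] <- TRUE
  if (!any(keep2)) stop("selection failed at step 2 (contrast window): no survivors")

  # step 3: balance orientation counts, dropping lowest-contrast frames
  keep3 <- keep2
  ori <- stack$orientation
  groups <- unique(ori[keep3])
  if (length(groups) >= 2) {
    counts <- vapply(groups, function(g) sum(keep3 & ori == g), integer(1))
    target <- min(counts)
    if (target < 1) stop("selection failed at step 3 (orientation balance): an orientation has no survivors")
    for (g in groups) {
      idx_g <- which(keep3 & ori == g)
      excess <- length(idx_g) - target
      if (excess > 0) {
        drop <- idx_g[order(fce[idx_g], idx_g)][seq_len(excess)]
        keep3[drop] <- FALSE
      }
    }
  }

  structure(list(
    selected = stack_subset(stack, which(keep3)),
    gradient_energy = ge,
    fringe_contrast_energy = fce,
    retained_step1 = keep1,
    retained_step2 = keep2,
    retained_step3 = keep3,
    counts = table(ori[keep3]),
    window_seconds = window_seconds,
    quality_quantile = quality_quantile
  ), class = "sio_selection")
}

#' @export
print.sio_selection <- function(x, ...) {
  cat(sprintf("sio_selection: %d -> %d -> %d frames; per-orientation counts: %s\n",
              sum(x$retained_step1), sum(x$retained_step2), sum(x$retained_step3),
              paste(sprintf("%s: %d", names(x$counts), x$counts), collapse = ", ")))
  invisible(x)
}
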