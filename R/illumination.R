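#' Fringe illumination model
#'
#' Sinusoidal fringe patterns projected onto the retina. The pattern seen by
#' the in-focus layer has contrast `contrast_infocus`; the pattern reaching
#' the defocused background layer is blurred out and defaults to contrast 0
#' (uniform illumination), which is what makes the two layers separable.
#' Fringes are static; their orientation alternates in blocks of
#' `frames_per_block` frames (acquisition switching), and the phase diversity
#' needed for reconstruction comes from eye motion, not from phase stepping.
#'
#' @param modulation_frequency_cpd Fringe spatial frequency `f_m`,
#'   cycles/degree (default 34).
#' @param orientations Fringe orientations in degrees (default `c(+45, -45)`).
#' @param phase Fringe phase in radians (scalar; the pattern is static).
#' @param contrast_infocus Modulation contrast on the in-focus layer, in
#'   `[0, 1]`.
#' @param contrast_background Modulation contrast on the defocused layer
#'   (default 0).
#' @param mean_level Mean illumination level (> 0, default 1).
#' @param frames_per_block Frames per orientation block (frame rate /
#'   switching rate; default 50).
#' @return An object of class `sio_illum`.
#' @export
illumination_model <- function(modulation_frequency_cpd = 34,
                               orientations = c(45, -45),
                               phase = 0,
                               contrast_infocus = 0.7,
                               contrast_background = 0,
                               mean_level = 1,
                               frames_per_block = 50L) {
  stopifnot(modulation_frequency_cpd > 0, mean_level > 0,
            length(orientations) >= 1)
  if (contrast_infocus < 0 || contrast_background < 0)
    stop("contrasts must be non-negative")
  if (max(contrast_infocus, contrast_background) > 1)
    stop("contrast > mean-normalized level would give negative illumination")
  structure(
    list(modulation_frequency_cpd = modulation_frequency_cpd,
         orientations = orientations,
         phase = phase,
         contrast_infocus = contrast_infocus,
         contrast_background = contrast_background,
         mean_level = mean_level,
         frames_per_block = as.integer(frames_per_block)),
    class = "sio_illum")
}

#' Orientation of the fringe pattern for a given frame
#'
#' Block arithmetic: orientation index is
#' `floor(frame_index / frames_per_block) mod n_orientations` (frame indices
#' are 0-based).
#'
#' @param illum An [illumination_model()].
#' @param frame_index 0-based frame index (vectorized).
#' @return Orientation(s) in degrees.
#' @export
orientation_for_frame <- function(illum, frame_index) {
  b <- floor(frame_index / illum$frames_per_block)
  illum$orientations[(b %% length(illum$orientations)) + 1]
}

#' Render a fringe illumination pattern
#'
#' Returns `mean_level * (1 + contrast * cos(2*pi*f_m*(x*cos(theta) +
#' y*sin(theta)) + phase))` on the oversampled object grid, with `x`, `y` in
#' degrees of visual angle.
#'
#' @param illum An [illumination_model()].
#' @param optical An [optical_model()] (provides the grid pixel scale).
#' @param grid_shape `c(ny, nx)` of the object grid.
#' @param orientation Orientation in degrees; if `NULL`, derived from
#'   `frame_index` by block arithmetic.
#' @param frame_index 0-based frame index (used when `orientation` is `NULL`).
#' @param layer `"infocus"` or `"background"` (chooses the contrast).
#' @return Non-negative matrix.
#' @export
make_pattern <- function(illum, optical, grid_shape,
                         orientation = NULL, frame_index = NULL,
                         layer = c("infocus", "background")) {
  layer <- match.arg(layer)
  if (is.null(orientation)) {
    if (is.null(frame_index)) stop("give either `orientation` or `frame_index`")
    orientation <- orientation_for_frame(illum, frame_index)
  }
  fm <- illum$modulation_frequency_cpd
  nyq <- 1 / (2 * object_pixel_scale(optical))
  if (fm >= nyq) stop("modulation frequency is at or above the grid Nyquist")
  contrast <- switch(layer, infocus = illum$contrast_infocus,
                     background = illum$contrast_background)
  ny <- grid_shape[1]; nx <- grid_shape[2]
  d <- object_pixel_scale(optical)
  th <- orientation * pi / 180
  x <- (seq_len(nx) - 1) * d
  y <- (seq_len(ny) - 1) * d
  arg <- 2 * pi * fm * (outer(y * sin(th), x * cos(th), `+`)) + illum$phase
  illum$mean_level * (1 + contrast * cos(arg))
}
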