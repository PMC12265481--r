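#' Two-layer object
#'
#' The unknown of the reconstruction: an in-focus layer `o0` (the optical
#' section to be super-resolved) and a defocused layer `od` that absorbs
#' out-of-focus and scattered light, both on the oversampled object grid.
#'
#' @param o0,od Non-negative numeric matrices of identical shape.
#' @return An object of class `sio_object`.
#' @export
two_layer_object <- function(o0, od) {
  as_image(o0, "o0"); as_image(od, "od")
  if (!all(dim(o0) == dim(od))) stop("o0 and od must have the same shape")
  structure(list(o0 = o0, od = od), class = "sio_object")
}

#' Per-frame retinal shift trajectory
#'
#' Sub-pixel displacements `(dy, dx)` of the retina relative to the reference
#' frame, in camera pixels. Frame `j`'s content is the object shifted by
#' `(dy[j], dx[j])`.
#'
#' @param dy,dx Numeric vectors of equal length.
#' @param valid Logical vector; `FALSE` flags frames whose shift could not be
#'   estimated.
#' @return An object of class `sio_trajectory` (a data.frame).
#' @export
shift_trajectory <- function(dy, dx, valid = rep(TRUE, length(dy))) {
  stopifnot(length(dy) == length(dx), length(valid) == length(dy))
  if (!all(is.finite(dy)) || !all(is.finite(dx))) stop("shifts must be finite")
  structure(data.frame(frame_index = seq_along(dy) - 1L,
                       dy = dy, dx = dx, valid = valid),
            class = c("sio_trajectory", "data.frame"))
}

#' Sub-pixel shift of an image (periodic boundary)
#'
#' Fourier-domain shift: integer shifts coincide with a circular roll, and
#' `apply_shift(x, s)` followed by `apply_shift(., -s)` is the identity for
#' any image whose self-conjugate Nyquist bins are empty (a fractional shift
#' has no real-valued representation at the Nyquist frequency itself; the
#' pipeline's grids always place the optical band strictly below it). The
#' shift is in this grid's pixel units.
#'
#' @param img Numeric matrix.
#' @param shift Length-2 numeric `(dy, dx)`.
#' @return Shifted matrix.
#' @export
apply_shift <- function(img, shift) {
  as_image(img)
  if (length(shift) != 2 || !all(is.finite(shift))) {
    stop("`shift` must be two finite numbers (dy, dx)")
  }
  if (all(shift == 0)) return(img)
  Re(ifft2(fft2(img) * shift_ramp(nrow(img), ncol(img), shift[1], shift[2])))
}

#' Comb downsampling
#'
#' Keeps every `q`-th pixel starting at index 0 along each axis (decimation,
#' not binning), mapping the oversampled object grid to the camera grid.
#'
#' @param img Numeric matrix whose dimensions are divisible by `q`.
#' @param q Positive integer decimation factor.
#' @return Matrix of shape `dim(img) / q`.
#' @export
downsample <- function(img, q) {
  as_image(img)
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1")
  if (q == 1L) return(img)
  if (nrow(img) %% q != 0 || ncol(img) %% q != 0) {
    stop("image dimensions must be divisible by q")
  }
  img[seq.int(1L, nrow(img), by = q), seq.int(1L, ncol(img), by = q), drop = FALSE]
}

#' Zero-insertion upsampling (adjoint of [downsample()])
#'
#' @param img Numeric matrix (camera grid).
#' @param q Positive integer factor.
#' @return Matrix of shape `dim(img) * q` with `img` at the comb positions and
#'   zeros elsewhere.
#' @export
upsample_zeros <- function(img, q) {
  as_image(img)
  q <- as.integer(q)
  if (q == 1L) return(img)
  out <- matrix(0, nrow(img) * q, ncol(img) * q)
  out[seq.int(1L, nrow(out), by = q), seq.int(1L, ncol(out), by = q)] <- img
  out
}

# Precomputed per-acquisition quantities for the imaging operator: OTFs on the
# object grid and one illumination pattern per (orientation, layer). Shifts
# are applied as phase ramps on cached object FFTs, so a criterion evaluation
# costs a handful of FFTs per frame.
model_context <- function(optical, illum, camera_shape) {
  q <- optical$oversampling_factor
  obj_shape <- camera_shape * q
  otf0 <- make_otf(make_psf(optical, optical$defocus_infocus, obj_shape))
  otfd <- make_otf(make_psf(optical, optical$defocus_background, obj_shape))
  pats <- lapply(illum$orientations, function(th) list(
    infocus = make_pattern(illum, optical, obj_shape, orientation = th,
                           layer = "infocus"),
    background = make_pattern(illum, optical, obj_shape, orientation = th,
                              layer = "background")))
  names(pats) <- as.character(illum$orientations)
  list(optical = optical, illum = illum, q = q,
       camera_shape = camera_shape, obj_shape = obj_shape,
       otf0 = otf0, otfd = otfd, patterns = pats,
       ny = obj_shape[1], nx = obj_shape[2])
}

ctx_pattern <- function(ctx, orientation, layer) {
  p <- ctx$patterns[[as.character(orientation)]]
  if (is.null(p)) stop(sprintf("orientation %s not part of the illumination model",
                               format(orientation)))
  p[[layer]]
}

# Fast forward model for one frame given cached object FFTs. shift is in
# camera pixels; on the object grid it becomes q * shift.
forward_frame_fft <- function(ctx, Fo0, Fod, shift, orientation) {
  s <- shift * ctx$q
  ramp <- shift_ramp(ctx$ny, ctx$nx, s[1], s[2])
  s0 <- Re(ifft2(Fo0 * ramp))                      # t_j[o0]
  F0 <- fft2(ctx_pattern(ctx, orientation, "infocus") * s0) * ctx$otf0
  sd <- Re(ifft2(Fod * ramp))
  Fd <- fft2(ctx_pattern(ctx, orientation, "background") * sd) * ctx$otfd
  downsample(Re(ifft2(F0 + Fd)), ctx$q)
}

# Adjoint of forward_frame_fft applied to a camera-grid residual; returns the
# gradient contribution on the object grid for both layers.
adjoint_frame <- function(ctx, residual, shift, orientation) {
  s <- shift * ctx$q
  up <- upsample_zeros(residual, ctx$q)
  Fu <- fft2(up)
  c0 <- Re(ifft2(Fu * Conj(ctx$otf0))) * ctx_pattern(ctx, orientation, "infocus")
  cd <- Re(ifft2(Fu * Conj(ctx$otfd))) * ctx_pattern(ctx, orientation, "background")
  ramp <- shift_ramp(ctx$ny, ctx$nx, -s[1], -s[2])
  list(g0 = Re(ifft2(fft2(c0) * ramp)),
       gd = Re(ifft2(fft2(cd) * ramp)))
}

#' Forward imaging model for one frame
#'
#' Model image `M_j = [h0 * (m_j0 . t_j[o0])]_III + [hd * (m_jd . t_j[od])]_III`:
#' each layer is shifted by the frame's retinal shift, multiplied by its
#' illumination pattern, convolved (circularly) with its PSF, and comb
#' downsampled to the camera grid; the two contributions add.
#'
#' @param obj A [two_layer_object()] on the oversampled grid.
#' @param shift Length-2 `(dy, dx)` retinal shift of this frame, camera pixels.
#' @param optical An [optical_model()].
#' @param illum An [illumination_model()].
#' @param orientation Fringe orientation (degrees); if `NULL`, derived from
#'   `frame_index`.
#' @param frame_index 0-based frame index.
#' @return Camera-grid matrix.
#' @export
forward_image <- function(obj, shift, optical, illum,
                          orientation = NULL, frame_index = NULL) {
  if (is.null(orientation)) orientation <- orientation_for_frame(illum, frame_index)
  q <- optical$oversampling_factor
  if (any(dim(obj$o0) %% q != 0)) stop("object grid not divisible by oversampling factor")
  ctx <- model_context(optical, illum, dim(obj$o0) %/% q)
  forward_frame_fft(ctx, fft2(obj$o0), fft2(obj$od), shift, orientation)
}

#' Adjoint of the forward imaging model
#'
#' Exact adjoint of [forward_image()] with respect to the Euclidean inner
#' products on the object and camera grids:
#' `<forward(o), r> == <o, adjoint(r)>`.
#'
#' @param residual Camera-grid matrix.
#' @inheritParams forward_image
#' @return List with object-grid matrices `g0` and `gd`.
#' @export
adjoint_image <- function(residual, shift, optical, illum,
                          orientation = NULL, frame_index = NULL) {
  if (is.null(orientation)) orientation <- orientation_for_frame(illum, frame_index)
  ctx <- model_context(optical, illum, dim(residual))
  adjoint_frame(ctx, residual, shift, orientation)
}
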