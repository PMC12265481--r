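# Shared evaluation of the MAP criterion and (optionally) its gradient.
# Precomputing the model context and the object FFTs keeps the cost to a few
# FFTs per frame.
criterion_eval <- function(obj, stack, shifts, optical, illum, hyper,
                           gradient = FALSE, ctx = NULL) {
  cam_shape <- dim(stack$frames)[1:2]
  if (is.null(ctx)) ctx <- model_context(optical, illum, cam_shape)
  if (!all(dim(obj$o0) == ctx$obj_shape)) {
    stop("object grid does not match the oversampled camera grid")
  }
  if (hyper$sigma2 <= 0) stop("noise variance must be positive")
  n <- n_frames(stack)
  if (nrow(shifts) < n) stop("missing shifts: trajectory shorter than the stack")
  Fo0 <- fft2(obj$o0)
  Fod <- fft2(obj$od)
  # apodized stacks carry their taper window; it weights the data term so the
  # model sees the same border roll-off as the pre-processed frames
  w <- stack$window
  J_data <- 0
  g0 <- if (gradient) matrix(0, ctx$ny, ctx$nx) else NULL
  gd <- if (gradient) matrix(0, ctx$ny, ctx$nx) else NULL
  for (j in seq_len(n)) {
    s <- c(shifts$dy[j], shifts$dx[j])
    M <- forward_frame_fft(ctx, Fo0, Fod, s, stack$orientation[j])
    if (is.null(w)) {
      r <- M - stack$frames[, , j]
      radj <- r / hyper$sigma2
    } else {
      r <- w * M - stack$frames[, , j]
      radj <- w * r / hyper$sigma2
    }
    J_data <- J_data + 0.5 * sum(r * r) / hyper$sigma2
    if (gradient) {
      a <- adjoint_frame(ctx, radj, s, stack$orientation[j])
      g0 <- g0 + a$g0
      gd <- gd + a$gd
    }
  }
  d_obj <- object_pixel_scale(optical)
  g <- freq_grid(ctx$ny, ctx$nx, d = d_obj)
  S0 <- psd_profile(hyper$S0, g$rho)
  Sd <- psd_profile(hyper$Sd, g$rho)
  npix <- ctx$ny * ctx$nx
  J_pen <- (hyper$lambda / 2) *
    (sum(Mod(Fo0)^2 / S0) + sum(Mod(Fod)^2 / Sd)) / npix
  out <- list(value = J_data + J_pen, data = J_data, penalty = J_pen)
  if (gradient) {
    out$g0 <- g0 + hyper$lambda * Re(ifft2(Fo0 / S0))
    out$gd <- gd + hyper$lambda * Re(ifft2(Fod / Sd))
  }
  out
}

#' MAP reconstruction criterion
#'
#' The two-layer maximum a posteriori criterion: a Gaussian data term,
#' `1/2 sum_j ||i_j - M_j(o0, od)||^2 / sigma^2`, plus quadratic spectral
#' penalties `lambda/2 * sum_f |o~(f)|^2 / S(f)` for each layer, where `o~`
#' is the 2-D DFT (the penalty sums are normalized by the pixel count so that
#' `S` is on the periodogram scale).
#'
#' @param obj A [two_layer_object()] on the oversampled grid.
#' @param stack Pre-processed, selected [frame_stack()].
#' @param shifts A [shift_trajectory()] aligned with the stack.
#' @param optical An [optical_model()].
#' @param illum An [illumination_model()].
#' @param hyper A [hyperparameters()] object.
#' @return Scalar criterion value `J >= 0`, with attributes `data` and
#'   `penalty` carrying the two terms.
#' @export
criterion <- function(obj, stack, shifts, optical, illum, hyper) {
  ev <- criterion_eval(obj, stack, shifts, optical, illum, hyper)
  structure(ev$value, data = ev$data, penalty = ev$penalty)
}

#' Gradient of the MAP criterion
#'
#' Analytic gradient with respect to both layers, assembled from the exact
#' adjoint of the imaging operator plus the closed-form gradient
#' `lambda * F^-1(o~ / S)` of each spectral penalty.
#'
#' @inheritParams criterion
#' @return List with object-grid matrices `g0` and `gd`.
#' @export
criterion_gradient <- function(obj, stack, shifts, optical, illum, hyper) {
  ev <- criterion_eval(obj, stack, shifts, optical, illum, hyper, gradient = TRUE)
  list(g0 = ev$g0, gd = ev$gd)
}
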