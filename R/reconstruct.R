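#' Two-layer MAP reconstruction
#'
#' Minimizes the [criterion()] over both non-negative layers with a
#' limited-memory bound-constrained quasi-Newton method (L-BFGS-B), run in
#' short segments so the criterion trace can be recorded; line searches make
#' the trace non-increasing. The in-focus layer is initialized from the
#' non-negative part of the registered frame average (fringe-free and cheap),
#' the defocused layer from its low-pass version through the background OTF.
#' Hyperparameters are estimated from the data ([estimate_hyperparameters()])
#' when not supplied. The result's `o0` is the optically sectioned,
#' super-resolved in-focus layer.
#'
#' @param stack Pre-processed, selected [frame_stack()] with balanced
#'   orientation counts.
#' @param shifts A [shift_trajectory()] aligned with the stack.
#' @param optical An [optical_model()].
#' @param illum An [illumination_model()].
#' @param hyper Optional [hyperparameters()]; estimated when `NULL`.
#' @param lambda Regularization weight used when estimating (default 0.3).
#' @param max_iter Maximum optimizer iterations (default 300).
#' @param tol Relative criterion decrease below which iteration stops
#'   (default 1e-6).
#' @param segment Optimizer iterations per recorded trace point (default 20).
#' @param positivity Enforce `o >= 0` (default `TRUE`). Disabling it gives the
#'   purely quadratic (regularized least-squares) solution, which lacks the
#'   spectral extrapolation the positivity constraint induces for objects on
#'   a dark background.
#' @return An object of class `sio_reconstruction`: `object` (the
#'   [two_layer_object()]), `hyper`, `trace` (criterion values, starting at
#'   the initialization), `iterations`, `converged`.
#' @export
reconstruct <- function(stack, shifts, optical, illum, hyper = NULL,
                        lambda = 0.3, max_iter = 300, tol = 1e-6,
                        segment = 20, positivity = TRUE) {
  n <- n_frames(stack)
  ori <- stack$orientation
  counts <- table(ori)
  if (length(counts) > 1 && length(unique(as.integer(counts))) != 1) {
    stop("orientation counts are unbalanced; run select_frames() first")
  }
  if (min(counts) < 7) {
    warning(sprintf(
      "only %d frames for some orientation; at least 7 frames per orientation are needed for full phase diversity",
      min(counts)))
  }
  if (is.null(hyper)) hyper <- estimate_hyperparameters(stack, optical, lambda = lambda)

  cam_shape <- dim(stack$frames)[1:2]
  ctx <- model_context(optical, illum, cam_shape)
  q <- optical$oversampling_factor

  wf <- build_widefield(stack, shifts)
  wf[wf < 0] <- 0
  base <- kronecker(wf, matrix(1, q, q))
  o0 <- 0.5 * base
  od <- 0.5 * Re(ifft2(fft2(base) * ctx$otfd))
  od[od < 0] <- 0

  npx <- ctx$ny * ctx$nx
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$ev)
    obj <- two_layer_object(matrix(par[1:npx], ctx$ny, ctx$nx),
                            matrix(par[(npx + 1):(2 * npx)], ctx$ny, ctx$nx))
    ev <- criterion_eval(obj, stack, shifts, optical, illum, hyper,
                         gradient = TRUE, ctx = ctx)
    if (!is.finite(ev$value)) {
      stop(sprintf("criterion became non-finite at iteration %d", cache$iter))
    }
    cache$par <- par
    cache$ev <- ev
    ev
  }
  fn <- function(par) evaluate(par)$value
  gr <- function(par) {
    ev <- evaluate(par)
    c(as.vector(ev$g0), as.vector(ev$gd))
  }

  par <- c(as.vector(o0), as.vector(od))
  cache$iter <- 0L
  trace <- fn(par)
  converged <- FALSE
  iters <- 0L
  while (iters < max_iter) {
    res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        lower = if (positivity) 0 else -Inf,
                        control = list(maxit = min(segment, max_iter - iters),
                                       factr = 10))
    par <- res$par
    iters <- iters + res$counts[["function"]]
    cache$iter <- iters
    prev <- trace[length(trace)]
    trace <- c(trace, res$value)
    if (prev - res$value <= tol * max(abs(prev), 1e-300)) {
      converged <- TRUE
      break
    }
    if (res$convergence == 0) {
      converged <- TRUE
      break
    }
  }

  obj <- two_layer_object(matrix(par[1:npx], ctx$ny, ctx$nx),
                          matrix(par[(npx + 1):(2 * npx)], ctx$ny, ctx$nx))
  structure(list(object = obj, hyper = hyper, trace = trace,
                 iterations = iters, converged = converged,
                 widefield = wf),
            class = "sio_reconstruction")
}

#' @export
print.sio_reconstruction <- function(x, ...) {
  cat(sprintf(
    "sio_reconstruction: %d x %d object grid; J %.6g -> %.6g in %d iterations (%s)\n",
    nrow(x$object$o0), ncol(x$object$o0),
    x$trace[1], x$trace[length(x$trace)], x$iterations,
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}
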