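# Evaluate an expression with a temporary RNG state so that generators are
# pure functions of (spec, seed) without clobbering the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic retinal phantom
#'
#' Describes the two ground-truth layers the simulator renders: an in-focus
#' cone mosaic (jittered hexagonal lattice of Gaussian reflectors with
#' log-normal per-cone brightness) over a dark background, and a smooth
#' positive defocused layer standing in for out-of-focus retina and choroidal
#' scatter.
#'
#' Defaults emulate the parafoveal cone mosaic at about 1 degree of
#' eccentricity: 5 micrometre spacing (about 46,000 cones/mm^2), moderate
#' positional jitter and reflectance variability, and a scattering background
#' as strong as the in-focus signal.
#'
#' @param cone_spacing Centre-to-centre cone spacing, micrometres.
#' @param spacing_jitter Positional jitter, fraction of the spacing.
#' @param cone_sigma Gaussian radius of one cone reflector, micrometres.
#' @param reflectance_cv Coefficient of variation of per-cone brightness.
#' @param background_correlation_length Correlation length of the defocused
#'   layer, micrometres.
#' @param background_to_signal_ratio Mean of the defocused layer relative to
#'   the mean of the in-focus layer.
#' @param field_of_view Field of view, degrees.
#' @param rng_seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `sio_phantom_spec`.
#' @export
phantom_spec <- function(cone_spacing = 5,
                         spacing_jitter = 0.12,
                         cone_sigma = 1.1,
                         reflectance_cv = 0.2,
                         background_correlation_length = 15,
                         background_to_signal_ratio = 1,
                         field_of_view = 256 / 403,
                         rng_seed = 1L) {
  stopifnot(cone_spacing > 0, cone_sigma > 0, field_of_view > 0,
            background_correlation_length > 0,
            spacing_jitter >= 0, reflectance_cv >= 0,
            background_to_signal_ratio >= 0)
  structure(as.list(environment()), class = "sio_phantom_spec")
}

# Hexagonal lattice points covering a [0, ny) x [0, nx) pixel box (0-based
# coordinates), spacing in pixels.
hex_lattice <- function(ny, nx, spacing_px) {
  row_step <- spacing_px * sqrt(3) / 2
  rows <- seq(0, ny - 1e-9, by = row_step)
  pts <- lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing_px / 2 else 0
    xs <- seq(off, nx - 1e-9, by = spacing_px)
    cbind(y = rep(rows[i], length(xs)), x = xs)
  })
  do.call(rbind, pts)
}

#' Generate a two-layer ground-truth phantom
#'
#' Renders the phantom on the oversampled object grid of `optical`. The
#' returned object carries the true cone centres (object-grid pixels,
#' 0-based) in `attr(, "cones")` and the spec in `attr(, "spec")`.
#'
#' @param spec A [phantom_spec()].
#' @param optical An [optical_model()].
#' @return A [two_layer_object()] with ground-truth attributes.
#' @export
generate_phantom <- function(spec, optical) {
  if (spec$cone_sigma >= spec$cone_spacing) {
    stop("cone_sigma >= cone_spacing gives a degenerate (merged) mosaic")
  }
  d_obj <- object_pixel_scale(optical)                     # deg/px
  um_per_px <- optical$retinal_scale * d_obj               # um/px
  n_cam <- round(spec$field_of_view / optical$pixel_scale)
  n <- n_cam * optical$oversampling_factor
  s_px <- spec$cone_spacing / um_per_px
  sig_px <- spec$cone_sigma / um_per_px

  with_seed(spec$rng_seed, {
    pts <- hex_lattice(n, n, s_px)
    if (spec$spacing_jitter > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$spacing_jitter * s_px),
                          ncol = 2)
    }
    keep <- pts[, 1] >= 0 & pts[, 1] <= n - 1 & pts[, 2] >= 0 & pts[, 2] <= n - 1
    pts <- pts[keep, , drop = FALSE]
    refl <- if (spec$reflectance_cv > 0) {
      sdlog <- sqrt(log(1 + spec$reflectance_cv^2))
      stats::rlnorm(nrow(pts), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(pts))

    # splat cone centres with bilinear weights, then blur to Gaussian discs
    deltas <- matrix(0, n, n)
    iy <- floor(pts[, 1]); ix <- floor(pts[, 2])
    wy <- pts[, 1] - iy;   wx <- pts[, 2] - ix
    for (k in seq_len(nrow(pts))) {
      y0 <- iy[k] + 1L; x0 <- ix[k] + 1L
      y1 <- min(y0 + 1L, n); x1 <- min(x0 + 1L, n)
      deltas[y0, x0] <- deltas[y0, x0] + refl[k] * (1 - wy[k]) * (1 - wx[k])
      deltas[y1, x0] <- deltas[y1, x0] + refl[k] * wy[k] * (1 - wx[k])
      deltas[y0, x1] <- deltas[y0, x1] + refl[k] * (1 - wy[k]) * wx[k]
      deltas[y1, x1] <- deltas[y1, x1] + refl[k] * wy[k] * wx[k]
    }
    o0 <- gaussian_blur(deltas, sig_px) * (2 * pi * sig_px^2)
    o0[o0 < 0] <- 0

    od <- matrix(0, n, n)
    if (spec$background_to_signal_ratio > 0) {
      corr_px <- spec$background_correlation_length / um_per_px
      z <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), corr_px)
      z <- z - min(z)
      if (mean(z) > 0) z <- z * (spec$background_to_signal_ratio * mean(o0) / mean(z))
      od <- z
    }
    obj <- two_layer_object(o0, od)
    attr(obj, "cones") <- pts
    attr(obj, "spec") <- spec
    obj
  })
}
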