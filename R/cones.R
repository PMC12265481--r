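# Otsu threshold of a numeric vector (maximizes between-class variance over a
# histogram split). Returns -Inf when the values do not separate into two
# classes (unimodal sets keep everything).
otsu_threshold <- function(values, nbins = 64) {
  if (length(values) < 2 || diff(range(values)) == 0) return(-Inf)
  h <- graphics::hist(values, breaks = nbins, plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; thr <- -Inf
  for (i in seq_len(length(mids) - 1)) {
    w0 <- sum(w[1:i]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(w[1:i] * mids[1:i]) / w0
    m1 <- sum(w[(i + 1):length(mids)] * mids[(i + 1):length(mids)]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- h$breaks[i + 1]; cls <- c(m0, m1) }
  }
  # unimodal guard: when the "dim" class is nearly as bright as the "bright"
  # class, the split is spurious -- keep all maxima
  if (is.finite(thr) && cls[1] > 0.4 * cls[2]) return(-Inf)
  thr
}

#' Detect cone photoreceptors
#'
#' Gaussian smoothing (sigma = `min_separation / 3`), strict 8-neighbour
#' local maxima, non-maximum suppression at `min_separation`, and an Otsu
#' intensity threshold over the maxima values (with a unimodal guard so that
#' a field of uniformly bright cones is not half-discarded). Deterministic.
#'
#' @param frame Background-corrected numeric matrix.
#' @param min_separation Minimum centre-to-centre distance, pixels (>= 2).
#' @return Two-column matrix of 0-based `(y, x)` positions, ordered by
#'   decreasing intensity.
#' @export
detect_cones <- function(frame, min_separation) {
  as_image(frame, "frame")
  if (min_separation < 2) stop("min_separation must be at least 2 pixels")
  sm <- gaussian_blur(frame, min_separation / 3)
  ny <- nrow(sm); nx <- ncol(sm)
  inner <- sm[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner > sm[1:(ny - 2), 2:(nx - 1)] & inner > sm[3:ny, 2:(nx - 1)] &
            inner > sm[2:(ny - 1), 1:(nx - 2)] & inner > sm[2:(ny - 1), 3:nx] &
            inner > sm[1:(ny - 2), 1:(nx - 2)] & inner > sm[1:(ny - 2), 3:nx] &
            inner > sm[3:ny, 1:(nx - 2)] & inner > sm[3:ny, 3:nx]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  ys <- idx[, 1] + 1L; xs <- idx[, 2] + 1L      # back to full-frame indices
  vals <- sm[cbind(ys, xs)]
  thr <- otsu_threshold(vals)
  keep <- vals >= thr
  ys <- ys[keep]; xs <- xs[keep]; vals <- vals[keep]
  ord <- order(-vals, ys, xs)
  ys <- ys[ord]; xs <- xs[ord]
  # greedy non-maximum suppression, brightest first
  acc_y <- numeric(0); acc_x <- numeric(0)
  min2 <- min_separation^2
  for (k in seq_along(ys)) {
    if (length(acc_y) == 0 ||
        min((acc_y - ys[k])^2 + (acc_x - xs[k])^2) >= min2) {
      acc_y <- c(acc_y, ys[k]); acc_x <- c(acc_x, xs[k])
    }
  }
  cbind(y = acc_y - 1, x = acc_x - 1)
}

#' Cone density map and eccentricity profile
#'
#' Sliding-window cone counts converted to cones/mm^2 via the retinal scale,
#' plus the per-eccentricity-bin mean and standard deviation of the window
#' densities and the reliability rule: a bin is reliable only while the
#' standard deviation stays within 10% of the mean.
#'
#' @param positions Two-column matrix of 0-based `(y, x)` cone positions,
#'   pixels.
#' @param field_shape `c(ny, nx)` of the analysed frame, pixels.
#' @param pixel_scale Pixel scale, degrees/pixel.
#' @param fovea_center `(y, x)` of the foveal centre, pixels (0-based); in
#'   synthetic runs this is config-supplied.
#' @param window_size Sliding-window side, pixels.
#' @param stride Window stride, pixels (default `window_size / 2`).
#' @param ecc_bin Eccentricity bin width, degrees (default 0.1).
#' @param retinal_scale Micrometres of retina per degree (default 300).
#' @return An object of class `sio_density_map`: data.frame of windows
#'   (`y`, `x` centres in px, `eccentricity` in degrees, `density` in
#'   cones/mm^2) with the eccentricity profile (`mean`, `sd`, `reliable` per
#'   bin) in `attr(, "profile")`.
#' @export
cone_density_map <- function(positions, field_shape, pixel_scale,
                             fovea_center = c(0, 0),
                             window_size = 64, stride = NULL,
                             ecc_bin = 0.1, retinal_scale = 300) {
  if (is.null(stride)) stride <- max(1L, window_size %/% 2L)
  mm_per_px <- pixel_scale * retinal_scale / 1000
  area_mm2 <- (window_size * mm_per_px)^2
  ys <- seq(0, field_shape[1] - window_size, by = stride)
  xs <- seq(0, field_shape[2] - window_size, by = stride)
  if (length(ys) == 0 || length(xs) == 0) {
    stop("window_size exceeds the field")
  }
  grid <- expand.grid(y0 = ys, x0 = xs)
  dens <- vapply(seq_len(nrow(grid)), function(i) {
    y0 <- grid$y0[i]; x0 <- grid$x0[i]
    if (nrow(positions) == 0) return(0)
    sum(positions[, 1] >= y0 & positions[, 1] < y0 + window_size &
        positions[, 2] >= x0 & positions[, 2] < x0 + window_size) / area_mm2
  }, numeric(1))
  cy <- grid$y0 + window_size / 2
  cx <- grid$x0 + window_size / 2
  ecc <- sqrt((cy - fovea_center[1])^2 + (cx - fovea_center[2])^2) * pixel_scale
  d <- data.frame(y = cy, x = cx, eccentricity = ecc, density = dens)
  bin <- floor(ecc / ecc_bin)
  prof <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    v <- dens[bin == b]
    data.frame(eccentricity = (b + 0.5) * ecc_bin,
               mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  }))
  prof$reliable <- prof$mean > 0 & prof$sd / pmax(prof$mean, .Machine$double.eps) <= 0.1
  structure(d, class = c("sio_density_map", "data.frame"), profile = prof,
            window_size = window_size, pixel_scale = pixel_scale,
            retinal_scale = retinal_scale)
}
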