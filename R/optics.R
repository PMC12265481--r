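#' Optical model of the adaptive-optics flood ophthalmoscope
#'
#' Describes the incoherent imaging optics: a circular pupil of diameter `D`
#' at the eye, an imaging wavelength, the camera pixel scale and the
#' oversampling factor of the reconstruction (object) grid. Residual
#' aberration is modelled as a single defocus term, expressed in waves RMS,
#' separately for the in-focus point-spread function `h0` and the defocused
#' background point-spread function `hd`.
#'
#' The diffraction-limited (incoherent) cutoff frequency is `D / lambda`
#' cycles/radian, i.e. `D / lambda * pi / 180` cycles/degree; for a 6.7 mm
#' pupil at 850 nm this is 140 cycles/degree to two significant figures.
#'
#' @param pupil_diameter Pupil diameter at the eye, mm.
#' @param imaging_wavelength Imaging wavelength, nm.
#' @param pixel_scale Camera pixel scale, degrees/pixel.
#' @param oversampling_factor Integer `q >= 1`; the object grid is `q` times
#'   finer than the camera grid.
#' @param defocus_infocus Defocus of the in-focus PSF, waves RMS (default 0).
#' @param defocus_background Defocus of the background PSF, waves RMS
#'   (default 1.5: strong blur so the background layer absorbs out-of-focus
#'   and scattered content).
#' @param retinal_scale Retinal extent per degree of visual angle,
#'   micrometres/degree (default 300, emmetropic eye).
#' @return An object of class `sio_optical`.
#' @export
optical_model <- function(pupil_diameter = 6.7,
                          imaging_wavelength = 850,
                          pixel_scale = 1 / 403,
                          oversampling_factor = 2L,
                          defocus_infocus = 0,
                          defocus_background = 1.5,
                          retinal_scale = 300) {
  stopifnot(pupil_diameter > 0, imaging_wavelength > 0, pixel_scale > 0,
            retinal_scale > 0)
  q <- as.integer(oversampling_factor)
  if (is.na(q) || q < 1L) stop("oversampling_factor must be an integer >= 1")
  opt <- structure(
    list(pupil_diameter = pupil_diameter,
         imaging_wavelength = imaging_wavelength,
         pixel_scale = pixel_scale,
         oversampling_factor = q,
         defocus_infocus = defocus_infocus,
         defocus_background = defocus_background,
         retinal_scale = retinal_scale),
    class = "sio_optical")
  co <- cutoff_cpd(opt)
  if (!is.finite(co) || co <= 0) stop("optical cutoff is not finite and positive")
  opt
}

#' Diffraction-limited cutoff frequency
#'
#' @param optical An [optical_model()].
#' @return Incoherent OTF support radius in cycles/degree.
#' @export
cutoff_cpd <- function(optical) {
  D <- optical$pupil_diameter * 1e-3           # m
  lambda <- optical$imaging_wavelength * 1e-9  # m
  D / lambda * pi / 180
}

# Object-grid pixel scale, degrees/pixel.
object_pixel_scale <- function(optical) {
  optical$pixel_scale / optical$oversampling_factor
}

check_grid_nyquist <- function(optical, what = "object") {
  nyq <- 1 / (2 * object_pixel_scale(optical))
  if (nyq < cutoff_cpd(optical)) {
    stop(sprintf(
      "%s-grid Nyquist (%.1f cpd) is below the optical cutoff (%.1f cpd); increase oversampling_factor or pixel sampling",
      what, nyq, cutoff_cpd(optical)), call. = FALSE)
  }
  invisible(nyq)
}

#' Point-spread function of a circular pupil with defocus
#'
#' Fourier-optics incoherent PSF: the pupil is a circular indicator with a
#' quadratic defocus phase `2*pi*a4*sqrt(3)*(2*rho^2 - 1)` (the normalized
#' defocus polynomial, `a4` in waves RMS); the PSF is the squared modulus of
#' the amplitude spread function and is normalized to unit sum. Its OTF (the
#' pupil autocorrelation) vanishes beyond `cutoff_cpd(optical)`.
#'
#' The PSF is sampled on the oversampled object grid.
#'
#' @param optical An [optical_model()].
#' @param defocus_waves Defocus coefficient, waves RMS.
#' @param grid_shape Integer vector `c(ny, nx)` of the object grid.
#' @return Non-negative matrix summing to 1.
#' @export
make_psf <- function(optical, defocus_waves, grid_shape) {
  check_grid_nyquist(optical)
  ny <- grid_shape[1]; nx <- grid_shape[2]
  g <- freq_grid(ny, nx, d = object_pixel_scale(optical))
  f_coh <- cutoff_cpd(optical) / 2   # coherent (amplitude) cutoff
  sup <- g$rho <= f_coh
  phase <- 2 * pi * defocus_waves * sqrt(3) * (2 * (g$rho / f_coh)^2 - 1)
  pupil <- ifelse(sup, exp(1i * phase), 0 + 0i)
  asf <- ifft2(pupil)
  psf <- Re(asf * Conj(asf))
  psf / sum(psf)
}

#' Optical transfer function of a PSF
#'
#' @param psf A PSF as returned by [make_psf()] (unit sum).
#' @return Complex matrix in FFT layout; value 1 at zero frequency.
#' @export
make_otf <- function(psf) fft2(psf)
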