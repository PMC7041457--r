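#' Define a dispersive spectrometer with a pixelated detector
#'
#' The model records the detector geometry and the (optional) instrument
#' response. Frequencies are expressed as GHz offset from the Rayleigh
#' line, which is centred on the detector; the dispersion `alpha`
#' (um/GHz) converts between detector position and optical frequency,
#' `x ~ alpha * omega`. A zero response FWHM means an ideal instrument
#' (identity response matrix); otherwise the response is a row-normalised
#' discretised Lorentzian of FWHM `response_fwhm_ghz`, so that total
#' intensity is conserved.
#'
#' @param n_pixels Number of detector pixels `N` (>= 4).
#' @param bandwidth_ghz Effective spectral bandwidth spanned by the
#'   detector (GHz).
#' @param pixel_pitch_um Pixel size `Delta` (micrometres).
#' @param response_fwhm_ghz FWHM `gamma` of the spectrometer response
#'   function (GHz); 0 gives the identity response.
#' @param detector_width_um Detector width `X` (micrometres). Defaults to
#'   `n_pixels * pixel_pitch_um`, i.e. the extent of the pixels actually
#'   used.
#' @return An object of class `spectrometer_model` with fields `n_pixels`,
#'   `bandwidth_ghz`, `pixel_pitch_um`, `detector_width_um`,
#'   `dispersion_um_per_ghz`, `response_fwhm_ghz`, `response` (N x N
#'   matrix or `NULL` for identity) and `frequency_ghz` (pixel-centre
#'   axis).
#' @examples
#' m <- spectrometer_model()           # 120 pixels over 60 GHz, 6.5 um pitch
#' m$dispersion_um_per_ghz             # 13 um/GHz
#' @export
spectrometer_model <- function(n_pixels = 120, bandwidth_ghz = 60,
                               pixel_pitch_um = 6.5, response_fwhm_ghz = 0,
                               detector_width_um = n_pixels * pixel_pitch_um) {
  if (!is.finite(n_pixels) || n_pixels < 4)
    stop("invalid spectrometer config: n_pixels must be >= 4")
  n_pixels <- as.integer(n_pixels)
  if (!is.finite(bandwidth_ghz) || bandwidth_ghz <= 0)
    stop("invalid spectrometer config: bandwidth_ghz must be positive")
  if (!is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("invalid spectrometer config: pixel_pitch_um must be positive")
  if (!is.finite(response_fwhm_ghz) || response_fwhm_ghz < 0)
    stop("invalid spectrometer config: response_fwhm_ghz must be >= 0")
  spacing <- bandwidth_ghz / n_pixels
  # pixel-centre frequencies, with a pixel exactly at the detector centre
  freq <- (seq_len(n_pixels) - 1 - n_pixels %/% 2) * spacing
  response <- NULL
  if (response_fwhm_ghz > 0) {
    # R[j, k]: fraction of pixel k's light landing on pixel j -- a
    # discretised Lorentzian of FWHM gamma, normalised per source pixel
    # (column) so that total intensity is conserved exactly
    response <- outer(freq, freq, function(fi, fj)
      (response_fwhm_ghz / 2)^2 /
        ((fi - fj)^2 + (response_fwhm_ghz / 2)^2))
    response <- sweep(response, 2, colSums(response), "/")
  }
  structure(
    list(n_pixels = n_pixels, bandwidth_ghz = bandwidth_ghz,
         pixel_pitch_um = pixel_pitch_um,
         detector_width_um = detector_width_um,
         dispersion_um_per_ghz = pixel_pitch_um / spacing,
         response_fwhm_ghz = response_fwhm_ghz,
         response = response, frequency_ghz = freq),
    class = "spectrometer_model"
  )
}

#' @export
print.spectrometer_model <- function(x, ...) {
  cat(sprintf("Spectrometer: %d pixels, %.4g GHz bandwidth (%.4g GHz/pixel)\n",
              x$n_pixels, x$bandwidth_ghz, x$bandwidth_ghz / x$n_pixels))
  cat(sprintf("  pixel pitch %.4g um, detector width %.4g um, dispersion %.4g um/GHz\n",
              x$pixel_pitch_um, x$detector_width_um, x$dispersion_um_per_ghz))
  cat(sprintf("  response FWHM %.4g GHz (%s)\n", x$response_fwhm_ghz,
              if (is.null(x$response)) "identity" else "Lorentzian"))
  invisible(x)
}

# Internal: apply the instrument response (identity when NULL).
apply_response <- function(model, f) {
  if (is.null(model$response)) f else drop(model$response %*% f)
}

#' Describe the peaks of a Brillouin spectrum
#'
#' A Rayleigh (elastic) line plus a symmetric Stokes/anti-Stokes Brillouin
#' doublet at `+- brillouin_shift_ghz`, all Lorentzian. The defaults are a
#' typical simulated water-like spectrum: Rayleigh amplitude 1e4 and the
#' Brillouin peaks 1e3 counts, all 1 GHz FWHM, shift 10 GHz.
#'
#' @param brillouin_shift_ghz True shift `Omega` (GHz, > 0).
#' @param brillouin_amplitude Peak intensity of each Brillouin peak (counts).
#' @param brillouin_fwhm_ghz Brillouin linewidth `Gamma` (GHz FWHM).
#' @param rayleigh_amplitude Peak intensity of the Rayleigh line (counts).
#' @param rayleigh_fwhm_ghz Rayleigh linewidth (GHz FWHM).
#' @param rayleigh_center_ghz Rayleigh position on the axis (GHz; 0 = centred).
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(brillouin_shift_ghz = 10, brillouin_amplitude = 1e3,
                     brillouin_fwhm_ghz = 1, rayleigh_amplitude = 1e4,
                     rayleigh_fwhm_ghz = 1, rayleigh_center_ghz = 0) {
  if (brillouin_shift_ghz <= 0) stop("brillouin_shift_ghz must be positive")
  if (brillouin_amplitude < 0 || rayleigh_amplitude < 0)
    stop("amplitudes must be non-negative")
  if (brillouin_fwhm_ghz <= 0 || rayleigh_fwhm_ghz <= 0)
    stop("linewidths must be positive")
  structure(
    list(brillouin_shift_ghz = brillouin_shift_ghz,
         brillouin_amplitude = brillouin_amplitude,
         brillouin_fwhm_ghz = brillouin_fwhm_ghz,
         rayleigh_amplitude = rayleigh_amplitude,
         rayleigh_fwhm_ghz = rayleigh_fwhm_ghz,
         rayleigh_center_ghz = rayleigh_center_ghz),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: Brillouin +-%.4g GHz (A = %.4g, FWHM %.4g GHz); Rayleigh at %.4g GHz (A = %.4g, FWHM %.4g GHz)\n",
              x$brillouin_shift_ghz, x$brillouin_amplitude,
              x$brillouin_fwhm_ghz, x$rayleigh_center_ghz,
              x$rayleigh_amplitude, x$rayleigh_fwhm_ghz))
  invisible(x)
}
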