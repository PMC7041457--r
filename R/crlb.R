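#' Average per-pixel signal-to-noise ratio
#'
#' `SNR = I_inf * Delta / (X * sigma)`: the integrated spectral intensity
#' spread over the `X / Delta` pixels of the detector, relative to the
#' noise standard deviation.
#'
#' @param integrated_intensity Integrated spectral intensity `I_inf`
#'   (counts summed over the detector).
#' @param pixel_pitch Pixel size `Delta`.
#' @param detector_width Detector width `X` (same length unit as
#'   `pixel_pitch`).
#' @param noise_sigma Noise standard deviation (counts, > 0).
#' @return The dimensionless per-pixel SNR.
#' @export
per_pixel_snr <- function(integrated_intensity, pixel_pitch, detector_width,
                          noise_sigma) {
  if (noise_sigma <= 0) stop("'noise_sigma' must be positive")
  if (pixel_pitch <= 0 || detector_width <= 0)
    stop("geometry must be positive")
  integrated_intensity * pixel_pitch / (detector_width * noise_sigma)
}

#' Assemble Cramer-Rao parameters from a spectrometer model and peak set
#'
#' Convenience: collects detector geometry, line parameters and noise into
#' the parameter list consumed by [crlb_shift_std()]. The relative
#' Brillouin intensity is `I_pm = brillouin_amplitude /
#' rayleigh_amplitude`, the response FWHM is converted to detector-length
#' units via the dispersion, and the per-pixel SNR follows from the
#' integrated intensity of the noiseless spectrum.
#'
#' @param model A [spectrometer_model()].
#' @param peaks A [peak_set()].
#' @param noise_sigma Noise standard deviation (counts).
#' @return A list with fields `dispersion_um_per_ghz`,
#'   `brillouin_fwhm_ghz`, `response_fwhm_um`, `relative_intensity`,
#'   `pixel_pitch_um`, `detector_width_um`, `per_pixel_snr`.
#' @export
crlb_params <- function(model = spectrometer_model(), peaks = peak_set(),
                        noise_sigma) {
  truth <- synth_truth(peaks, model)
  i_inf <- sum(truth$intensity)
  list(
    dispersion_um_per_ghz = model$dispersion_um_per_ghz,
    brillouin_fwhm_ghz = peaks$brillouin_fwhm_ghz,
    response_fwhm_um = model$response_fwhm_ghz * model$dispersion_um_per_ghz,
    relative_intensity = peaks$brillouin_amplitude / peaks$rayleigh_amplitude,
    pixel_pitch_um = model$pixel_pitch_um,
    detector_width_um = model$n_pixels * model$pixel_pitch_um,
    per_pixel_snr = per_pixel_snr(i_inf, model$pixel_pitch_um,
                                  model$n_pixels * model$pixel_pitch_um,
                                  noise_sigma)
  )
}

#' Cramer-Rao lower bound on the Brillouin-shift standard deviation
#'
#' For a dispersion-limited spectrometer with a pixelated detector and
#' white Gaussian noise, the variance of any unbiased estimator of the
#' shift is bounded by
#' `sigma_Omega^2 >= pi * Delta * (alpha*Gamma + gamma)^3 * (1 + 2 I)^2 /
#' (4 * X^2 * SNR^2 * alpha^2 * I^2)`
#' with `alpha` the dispersion (um/GHz), `Gamma` the Brillouin FWHM (GHz),
#' `gamma` the response FWHM expressed on the detector (um), `I` the
#' Brillouin intensity relative to the Rayleigh line, `Delta` the pixel
#' pitch, `X` the detector width (um) and `SNR` the per-pixel ratio of
#' [per_pixel_snr()]. The grouping of the factors is fixed by dimensional
#' analysis (the bound must carry GHz^2) and is cross-checked against a
#' brute-force Fisher-information computation in the test-suite.
#'
#' @param params A list as produced by [crlb_params()].
#' @return The bound on the standard deviation, in GHz (`Inf` when the
#'   Brillouin intensity or the SNR vanishes).
#' @export
crlb_shift_std <- function(params) {
  p <- params
  if (p$relative_intensity <= 0 || p$per_pixel_snr <= 0) return(Inf)
  alpha <- p$dispersion_um_per_ghz
  num <- pi * p$pixel_pitch_um *
    (alpha * p$brillouin_fwhm_ghz + p$response_fwhm_um)^3 *
    (1 + 2 * p$relative_intensity)^2
  den <- 4 * p$detector_width_um^2 * p$per_pixel_snr^2 * alpha^2 *
    p$relative_intensity^2
  sqrt(num / den)
}
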