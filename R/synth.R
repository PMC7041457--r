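#' Lorentzian line shape
#'
#' `L(x) = A (G/2)^2 / ((x - x0)^2 + (G/2)^2)` so that `L(x0) = A` and the
#' full width at half maximum is `G`.
#'
#' @param x Evaluation points.
#' @param center Peak position `x0`.
#' @param fwhm Full width at half maximum `G` (> 0).
#' @param amplitude Peak height `A`.
#' @return Numeric vector of the same length as `x`.
#' @export
lorentzian <- function(x, center, fwhm, amplitude = 1) {
  hw <- fwhm / 2
  amplitude * hw^2 / ((x - center)^2 + hw^2)
}

# Internal: mean of a Lorentzian over a pixel [a, b] (closed form).
lorentzian_pixel_mean <- function(a, b, center, fwhm, amplitude = 1) {
  hw <- fwhm / 2
  amplitude * hw * (atan((b - center) / hw) - atan((a - center) / hw)) / (b - a)
}

# Internal: evaluate the three-peak model on an axis.
peak_model_intensity <- function(freq, peaks, pixel_integrated = FALSE,
                                 spacing = NULL) {
  comps <- list(
    c(peaks$rayleigh_center_ghz, peaks$rayleigh_fwhm_ghz,
      peaks$rayleigh_amplitude),
    c(peaks$rayleigh_center_ghz - peaks$brillouin_shift_ghz,
      peaks$brillouin_fwhm_ghz, peaks$brillouin_amplitude),
    c(peaks$rayleigh_center_ghz + peaks$brillouin_shift_ghz,
      peaks$brillouin_fwhm_ghz, peaks$brillouin_amplitude)
  )
  out <- numeric(length(freq))
  for (p in comps) {
    if (pixel_integrated) {
      out <- out + lorentzian_pixel_mean(freq - spacing / 2, freq + spacing / 2,
                                         p[1L], p[2L], p[3L])
    } else {
      out <- out + lorentzian(freq, p[1L], p[2L], p[3L])
    }
  }
  out
}

#' Generate a noiseless ground-truth spectrum
#'
#' Evaluates the Rayleigh + Stokes/anti-Stokes Lorentzian sum at the
#' pixel-centre frequencies of the spectrometer and applies the instrument
#' response. By default the line shapes are sampled at pixel centres;
#' `pixel_integrated = TRUE` instead averages the closed-form Lorentzian
#' integral over each pixel.
#'
#' @param peaks A [peak_set()].
#' @param model A [spectrometer_model()].
#' @param pixel_integrated Average over the pixel area instead of sampling
#'   at the centre.
#' @return A noiseless [brillouin_spectrum()] (`sigma = 0`, all pixels
#'   unmasked) whose `meta` records the generator parameters.
#' @examples
#' truth <- synth_truth(peak_set(), spectrometer_model())
#' max(truth$intensity)   # 1e4 at the Rayleigh line (up to pixelation)
#' @export
synth_truth <- function(peaks, model, pixel_integrated = FALSE) {
  stopifnot(inherits(peaks, "peak_set"), inherits(model, "spectrometer_model"))
  freq <- model$frequency_ghz
  span <- range(freq)
  pk <- peaks$rayleigh_center_ghz + c(0, -1, 1) * peaks$brillouin_shift_ghz
  if (any(pk < span[1L] | pk > span[2L]))
    warning("peak centre outside the frequency axis; tails truncated")
  g <- peak_model_intensity(freq, peaks, pixel_integrated,
                            spacing = model$bandwidth_ghz / model$n_pixels)
  g <- apply_response(model, g)
  brillouin_spectrum(freq, g, sigma = 0,
                     meta = list(peaks = peaks, noiseless = TRUE,
                                 pixel_integrated = pixel_integrated))
}

# Internal: run code with a private RNG stream, restoring the caller's.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Add white Gaussian noise at a given signal-to-noise ratio
#'
#' The SNR is defined as the ratio of a reference spectral intensity to the
#' noise standard deviation. By default the reference is the Brillouin peak
#' amplitude (the feature whose parameters are being estimated); it can be
#' switched to the Rayleigh amplitude.
#'
#' @param spectrum A noiseless [brillouin_spectrum()] (as from
#'   [synth_truth()]).
#' @param snr Positive signal-to-noise ratio, or `Inf` for no noise.
#' @param seed Integer seed; the result is fully determined by it and the
#'   caller's RNG state is left untouched.
#' @param reference `"brillouin"` (default) or `"rayleigh"`: which peak
#'   amplitude defines the SNR. Ignored when `sigma` is given.
#' @param sigma Optional explicit noise standard deviation (counts),
#'   overriding the SNR-derived value.
#' @return The spectrum plus i.i.d. `N(0, sigma^2)` noise on every pixel;
#'   `sigma` is recorded per pixel and `meta` gains `snr` and `seed`.
#' @export
add_noise <- function(spectrum, snr, seed, reference = c("brillouin", "rayleigh"),
                      sigma = NULL) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  reference <- match.arg(reference)
  if (!is.finite(snr) && is.null(sigma)) {
    if (is.infinite(snr) && snr > 0) return(spectrum)
    stop("invalid 'snr'")
  }
  if (is.null(sigma)) {
    if (snr <= 0) stop("'snr' must be positive")
    peaks <- spectrum$meta$peaks
    if (is.null(peaks))
      stop("spectrum carries no peak metadata; supply 'sigma' explicitly")
    amp <- switch(reference,
                  brillouin = peaks$brillouin_amplitude,
                  rayleigh = peaks$rayleigh_amplitude)
    sigma <- amp / snr
  }
  n <- length(spectrum$intensity)
  noise <- with_seed(seed, stats::rnorm(n, sd = sigma))
  out <- spectrum
  out$intensity <- spectrum$intensity + noise
  out$sigma <- rep(sigma, n)
  out$meta$snr <- snr
  out$meta$seed <- seed
  out$meta$snr_reference <- reference
  out$meta$noiseless <- FALSE
  out
}

#' Generate one noisy synthetic spectrum
#'
#' Convenience wrapper: [synth_truth()] followed by [add_noise()].
#'
#' @inheritParams synth_truth
#' @inheritParams add_noise
#' @return A noisy [brillouin_spectrum()].
#' @export
simulate_spectrum <- function(snr, seed, peaks = peak_set(),
                              model = spectrometer_model(),
                              reference = c("brillouin", "rayleigh"),
                              pixel_integrated = FALSE) {
  add_noise(synth_truth(peaks, model, pixel_integrated), snr, seed,
            reference = match.arg(reference))
}
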