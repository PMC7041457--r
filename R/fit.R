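#' Initial parameter guesses for a Brillouin fit
#'
#' Peak-picks a 5-pixel median-smoothed copy of the spectrum: the Rayleigh
#' seed is the maximum near the axis centre, and the Brillouin pair is
#' seeded at the mean absolute offset of the two strongest local maxima
#' away from the centre. Widths are seeded at two pixels. When no usable
#' maxima are found the guesses fall back to generic values and the
#' `fallback` flag is set, signalling an elevated risk that the subsequent
#' fit fails.
#'
#' @param spectrum A [brillouin_spectrum()].
#' @param include_rayleigh Seed a Rayleigh component as well.
#' @return A list with `shift_ghz`, `fwhm_ghz`, `amplitude`,
#'   `rayleigh_amplitude`, `rayleigh_fwhm_ghz`, `rayleigh_center_ghz` and
#'   `fallback`.
#' @export
default_init <- function(spectrum, include_rayleigh = TRUE) {
  freq <- spectrum$frequency_ghz
  y <- spectrum$intensity
  n <- length(y)
  spacing <- freq[2L] - freq[1L]
  sm <- stats::runmed(y, k = min(5L, n - (1 - n %% 2)), endrule = "median")
  is_max <- c(FALSE, diff(sign(diff(sm))) < 0, FALSE)
  centre <- if (!is.null(spectrum$meta$peaks))
    spectrum$meta$peaks$rayleigh_center_ghz else 0
  off_centre <- abs(freq - centre) > 3 * spacing
  cand <- which(is_max & off_centre & spectrum$mask)
  fallback <- FALSE
  if (length(cand) >= 2L) {
    top <- cand[order(sm[cand], decreasing = TRUE)][1:2]
    shift <- mean(abs(freq[top] - centre))
    amp <- max(mean(y[top]), 1e-3 * max(abs(y)))
  } else {
    fallback <- TRUE
    warning("no usable peak candidates; falling back to generic guesses")
    shift <- diff(range(freq)) / 4
    amp <- max(max(y), 1)
  }
  ray_amp <- if (include_rayleigh) {
    near <- which(!off_centre & spectrum$mask)
    if (length(near)) max(y[near]) else max(y)
  } else 0
  list(shift_ghz = shift, fwhm_ghz = 2 * spacing, amplitude = amp,
       rayleigh_amplitude = max(ray_amp, 1e-3 * max(abs(y))),
       rayleigh_fwhm_ghz = 2 * spacing, rayleigh_center_ghz = centre,
       fallback = fallback)
}

# Internal: model + analytic Jacobian for the symmetric-pair
# parameterisation th = (shift, fwhm, amp[, ray_amp, ray_fwhm]) and the
# free-pair parameterisation th = (pos-, fwhm-, amp-, pos+, fwhm+, amp+
# [, ray_amp, ray_fwhm]).
fit_model_eval <- function(th, freq, symmetric, include_rayleigh, centre) {
  if (symmetric) {
    shift <- th[1L]; fwhm <- th[2L]; amp <- th[3L]
    y <- lorentzian(freq, centre - shift, fwhm, amp) +
      lorentzian(freq, centre + shift, fwhm, amp)
    k <- 3L
  } else {
    y <- lorentzian(freq, th[1L], th[2L], th[3L]) +
      lorentzian(freq, th[4L], th[5L], th[6L])
    k <- 6L
  }
  if (include_rayleigh)
    y <- y + lorentzian(freq, centre, th[k + 2L], th[k + 1L])
  y
}

# Internal: partial derivatives of a Lorentzian wrt (center, fwhm, amp).
lorentz_partials <- function(x, center, fwhm, amp) {
  hw <- fwhm / 2
  u <- (x - center)
  den <- u^2 + hw^2
  l0 <- hw^2 / den                         # unit-amplitude shape
  dc <- amp * 2 * u * hw^2 / den^2
  dw <- amp * (hw * u^2 / den^2)           # d/dfwhm = (1/2) d/dhw
  da <- l0
  cbind(dc, dw, da)
}

fit_model_jac <- function(th, freq, symmetric, include_rayleigh, centre) {
  if (symmetric) {
    shift <- th[1L]; fwhm <- th[2L]; amp <- th[3L]
    pm <- lorentz_partials(freq, centre - shift, fwhm, amp)
    pp <- lorentz_partials(freq, centre + shift, fwhm, amp)
    jac <- cbind(-pm[, 1L] + pp[, 1L], pm[, 2L] + pp[, 2L],
                 pm[, 3L] + pp[, 3L])
    k <- 3L
  } else {
    p1 <- lorentz_partials(freq, th[1L], th[2L], th[3L])
    p2 <- lorentz_partials(freq, th[4L], th[5L], th[6L])
    jac <- cbind(p1, p2)
    k <- 6L
  }
  if (include_rayleigh) {
    pr <- lorentz_partials(freq, centre, th[k + 2L], th[k + 1L])
    jac <- cbind(jac, pr[, 3L], pr[, 2L])
  }
  jac
}

#' Fit a multi-Lorentzian model to a Brillouin spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt with an analytic Jacobian)
#' of a Stokes/anti-Stokes Lorentzian pair, optionally plus a Rayleigh
#' line, against the unmasked pixels of a spectrum. In the default
#' symmetric mode the pair is constrained to positions `+-Omega` with a
#' common width and amplitude, reflecting the physical Stokes/anti-Stokes
#' symmetry; the free mode fits two unconstrained Lorentzians and reports
#' the half-separation as the shift and the mean width as the linewidth.
#'
#' Optimiser failure or a solution pinned at a bound is reported through
#' `success = FALSE` rather than an error.
#'
#' @param spectrum A [brillouin_spectrum()].
#' @param symmetric_pair Constrain the pair to `+-Omega`, equal width and
#'   amplitude (default `TRUE`).
#' @param include_rayleigh Model the Rayleigh line too (default `TRUE`;
#'   forced off when the central region is fully masked).
#' @param init Optional initial guesses as produced by [default_init()].
#' @param lower,upper Optional box bounds on the parameter vector.
#' @param max_evals Maximum residual evaluations (default 5000).
#' @return An object of class `brillouin_fit` with fields `shift_ghz`,
#'   `linewidth_ghz`, `amplitude`, `rayleigh` (or `NULL`),
#'   `rms_error_pct` (RMS residual as a percentage of the fitted Brillouin
#'   amplitude), `success`, `coefficients`, `covariance`, `fitted`,
#'   `residuals` and the input `spectrum`.
#' @examples
#' truth <- synth_truth(peak_set(), spectrometer_model())
#' fit <- fit_brillouin(truth)
#' coef(fit)
#' @export
fit_brillouin <- function(spectrum, symmetric_pair = TRUE,
                          include_rayleigh = TRUE, init = NULL,
                          lower = NULL, upper = NULL, max_evals = 5000) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  freq <- spectrum$frequency_ghz
  if (diff(range(freq)) <= 0) stop("degenerate frequency axis")
  mask <- spectrum$mask
  y <- spectrum$intensity[mask]
  x <- freq[mask]
  centre <- if (!is.null(spectrum$meta$peaks))
    spectrum$meta$peaks$rayleigh_center_ghz else 0
  # drop the Rayleigh component if its pixels are masked out
  if (include_rayleigh && !any(abs(x - centre) <= 2 * (freq[2] - freq[1])))
    include_rayleigh <- FALSE
  if (is.null(init)) init <- default_init(spectrum, include_rayleigh)
  th0 <- if (symmetric_pair) {
    c(init$shift_ghz, init$fwhm_ghz, init$amplitude)
  } else {
    c(centre - init$shift_ghz, init$fwhm_ghz, init$amplitude,
      centre + init$shift_ghz, init$fwhm_ghz, init$amplitude)
  }
  if (include_rayleigh)
    th0 <- c(th0, init$rayleigh_amplitude, init$rayleigh_fwhm_ghz)
  n_par <- length(th0)
  if (length(y) < 3L * n_par)
    stop("too few unmasked pixels (", length(y), ") for ", n_par,
         " parameters")
  resid_fn <- function(th)
    fit_model_eval(th, x, symmetric_pair, include_rayleigh, centre) - y
  jac_fn <- function(th)
    fit_model_jac(th, x, symmetric_pair, include_rayleigh, centre)
  ctrl <- minpack.lm::nls.lm.control(maxfev = max_evals, maxiter = 1024)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = th0, fn = resid_fn, jac = jac_fn,
                       lower = lower, upper = upper, control = ctrl),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_brillouin_fit(NA_real_, NA_real_, NA_real_, NULL, NA_real_,
                             FALSE, th0, NULL, NULL, NULL, spectrum,
                             symmetric_pair, include_rayleigh, centre,
                             "optimizer error"))
  }
  th <- unname(fit$par)
  if (symmetric_pair) {
    shift <- abs(th[1L]); fwhm <- abs(th[2L]); amp <- th[3L]
    k <- 3L
  } else {
    shift <- (th[4L] - th[1L]) / 2
    fwhm <- (abs(th[2L]) + abs(th[5L])) / 2
    amp <- mean(th[c(3L, 6L)])
    k <- 6L
  }
  rayleigh <- if (include_rayleigh)
    list(amplitude = th[k + 1L], fwhm_ghz = abs(th[k + 2L]),
         center_ghz = centre) else NULL
  res <- fit$fvec
  rms_pct <- sqrt(mean(res^2)) / abs(amp) * 100
  pinned <- FALSE
  if (!is.null(lower)) pinned <- pinned || any(th <= lower + 1e-12)
  if (!is.null(upper)) pinned <- pinned || any(th >= upper - 1e-12)
  success <- fit$info %in% 1:4 && !pinned && is.finite(shift) &&
    shift > 0 && fwhm > 0
  covar <- tryCatch(solve(crossprod(jac_fn(th))) * sum(res^2) /
                      max(length(y) - n_par, 1L),
                    error = function(e) NULL)
  new_brillouin_fit(shift, fwhm, amp, rayleigh, rms_pct, success, th,
                    covar, fit_model_eval(th, freq, symmetric_pair,
                                          include_rayleigh, centre),
                    res, spectrum, symmetric_pair, include_rayleigh,
                    centre, fit$message)
}

# Internal constructor.
new_brillouin_fit <- function(shift, fwhm, amp, rayleigh, rms_pct, success,
                              th, covar, fitted, residuals, spectrum,
                              symmetric, include_rayleigh, centre, msg) {
  names(th) <- fit_par_names(symmetric, include_rayleigh)
  structure(
    list(shift_ghz = shift, linewidth_ghz = fwhm, amplitude = amp,
         rayleigh = rayleigh, rms_error_pct = rms_pct, success = success,
         coefficients = th, covariance = covar, fitted = fitted,
         residuals = residuals, spectrum = spectrum,
         symmetric_pair = symmetric, include_rayleigh = include_rayleigh,
         centre_ghz = centre, message = msg),
    class = "brillouin_fit"
  )
}

fit_par_names <- function(symmetric, include_rayleigh) {
  nm <- if (symmetric) c("shift_ghz", "fwhm_ghz", "amplitude")
  else c("pos_stokes", "fwhm_stokes", "amp_stokes",
         "pos_antistokes", "fwhm_antistokes", "amp_antistokes")
  if (include_rayleigh) nm <- c(nm, "rayleigh_amplitude", "rayleigh_fwhm")
  nm
}

#' @export
print.brillouin_fit <- function(x, ...) {
  cat("Brillouin Lorentzian fit",
      if (!x$success) "(FAILED)" else "", "\n")
  cat(sprintf("  shift: %.4f GHz   linewidth (FWHM): %.4f GHz   amplitude: %.4g\n",
              x$shift_ghz, x$linewidth_ghz, x$amplitude))
  if (!is.null(x$rayleigh))
    cat(sprintf("  Rayleigh: amplitude %.4g, FWHM %.4f GHz\n",
                x$rayleigh$amplitude, x$rayleigh$fwhm_ghz))
  cat(sprintf("  RMS residual: %.3g%% of the Brillouin amplitude\n",
              x$rms_error_pct))
  invisible(x)
}

#' @export
summary.brillouin_fit <- function(object, ...) {
  se <- if (!is.null(object$covariance))
    sqrt(pmax(diag(object$covariance), 0)) else rep(NA_real_,
                                                    length(object$coefficients))
  out <- data.frame(estimate = object$coefficients, std_error = se)
  cat("Call: multi-Lorentzian least squares (",
      if (object$symmetric_pair) "symmetric pair" else "free pair",
      if (object$include_rayleigh) " + Rayleigh" else "", ")\n", sep = "")
  print(out)
  cat(sprintf("\nShift %.4f GHz, linewidth %.4f GHz, RMS residual %.3g%%, success: %s\n",
              object$shift_ghz, object$linewidth_ghz, object$rms_error_pct,
              object$success))
  invisible(out)
}

#' @export
coef.brillouin_fit <- function(object, ...) object$coefficients

#' @export
vcov.brillouin_fit <- function(object, ...) object$covariance

#' @export
fitted.brillouin_fit <- function(object, ...) object$fitted

#' @export
residuals.brillouin_fit <- function(object, ...) object$residuals

#' @export
predict.brillouin_fit <- function(object, newdata = NULL, ...) {
  freq <- if (is.null(newdata)) object$spectrum$frequency_ghz
  else if (is.list(newdata)) newdata$frequency_ghz else newdata
  fit_model_eval(object$coefficients, freq, object$symmetric_pair,
                 object$include_rayleigh, object$centre_ghz)
}

#' @export
plot.brillouin_fit <- function(x, ...) {
  s <- x$spectrum
  graphics::plot(s$frequency_ghz, s$intensity, type = "l", col = "grey",
                 xlab = "Frequency shift (GHz)",
                 ylab = "Intensity (counts)", ...)
  graphics::lines(s$frequency_ghz, predict(x), col = "blue", lwd = 2)
  graphics::abline(v = x$centre_ghz + c(-1, 1) * x$shift_ghz, lty = 3)
  invisible(x)
}

#' Speed of sound from a Brillouin shift
#'
#' In a backscattering-type geometry the acoustic (phonon) velocity
#' follows from the Brillouin shift through
#' `v = Omega * lambda0 / (2 n sin(theta/2))`, with `Omega` the shift,
#' `lambda0` the incident vacuum wavelength, `n` the refractive index and
#' `theta` the scattering angle.
#'
#' @param shift_ghz Brillouin shift (GHz).
#' @param wavelength_nm Incident wavelength in vacuum (nm).
#' @param refractive_index Medium refractive index (>= 1).
#' @param scattering_angle_deg Scattering angle (degrees, in (0, 180]).
#' @return Speed of sound in m/s.
#' @examples
#' speed_of_sound(7.07, 561, 1.33, 180)   # ~1490 m/s, water-like
#' @export
speed_of_sound <- function(shift_ghz, wavelength_nm, refractive_index,
                           scattering_angle_deg = 180) {
  if (scattering_angle_deg <= 0 || scattering_angle_deg > 180)
    stop("'scattering_angle_deg' must be in (0, 180]")
  if (refractive_index < 1) stop("'refractive_index' must be >= 1")
  omega <- shift_ghz * 1e9
  lambda0 <- wavelength_nm * 1e-9
  omega * lambda0 / (2 * refractive_index *
                       sin(scattering_angle_deg / 2 * pi / 180))
}

#' Brillouin shift corresponding to a speed of sound
#'
#' Inverse of [speed_of_sound()].
#'
#' @param speed_m_s Speed of sound (m/s).
#' @inheritParams speed_of_sound
#' @return Brillouin shift in GHz.
#' @export
brillouin_shift_for_speed <- function(speed_m_s, wavelength_nm,
                                      refractive_index,
                                      scattering_angle_deg = 180) {
  if (scattering_angle_deg <= 0 || scattering_angle_deg > 180)
    stop("'scattering_angle_deg' must be in (0, 180]")
  2 * refractive_index * speed_m_s *
    sin(scattering_angle_deg / 2 * pi / 180) / (wavelength_nm * 1e-9) / 1e9
}
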