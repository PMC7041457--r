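#' Shannon entropy of a spectrum
#'
#' The entropy of the normalised spectral distribution `p = f / sum(f)`,
#' `S = -sum(p log p)`, optionally relative to a model distribution `m`
#' (`S = -sum(p log(p/m))`, the negative Kullback-Leibler divergence).
#' Normalising makes the entropy dimensionless and independent of the
#' intensity scale; with a model, the unconstrained maximiser is `m`
#' itself, and a uniform `m` recovers the plain entropy up to the constant
#' `log N`.
#'
#' @param f Strictly positive intensity vector.
#' @param prior Optional model distribution `m` (positive, any scale; it is
#'   normalised internally).
#' @return The entropy (dimensionless). Maximal value `log N` at uniform
#'   `f` (plain form), 0 at `f` proportional to `m` (relative form).
#' @export
shannon_entropy <- function(f, prior = NULL) {
  if (any(f < 0) || any(!is.finite(f)) || sum(f) <= 0)
    stop("entropy requires non-negative finite intensities with positive total")
  p <- f / sum(f)
  nz <- p > 0                      # 0 log 0 = 0 by convention
  if (is.null(prior)) return(-sum(p[nz] * log(p[nz])))
  if (length(prior) != length(f) || any(prior <= 0))
    stop("'prior' must be a positive vector matching 'f'")
  m <- prior / sum(prior)
  -sum(p[nz] * log(p[nz] / m[nz]))
}

#' Normalised chi-squared misfit between a trial spectrum and the data
#'
#' `chi2 = (1/N') sum_j ((R f)_j - d_j)^2 / sigma_j^2` over the `N'`
#' unmasked pixels, where `R` is the instrument response (identity when the
#' model is `NULL` or ideal). Under correct noise statistics the expected
#' value at the true spectrum is 1, which motivates the default consistency
#' target `chi0_sq = 1` (approximately a 95% confidence region).
#'
#' @param f Trial reconstruction (length `N`).
#' @param spectrum The observed [brillouin_spectrum()] (must carry `sigma`).
#' @param model Optional [spectrometer_model()] providing the response.
#' @return The normalised misfit (dimensionless, >= 0).
#' @export
chi_squared <- function(f, spectrum, model = NULL) {
  d <- spectrum$intensity
  if (length(f) != length(d)) stop("'f' and the spectrum differ in length")
  mask <- spectrum$mask
  if (!any(mask)) stop("all pixels are masked; chi-squared is undefined")
  sigma <- spectrum$sigma
  if (is.null(sigma) || any(sigma[mask] <= 0))
    stop("chi-squared requires positive noise sigma on unmasked pixels")
  rf <- if (is.null(model)) f else apply_response(model, f)
  r <- (rf[mask] - d[mask]) / sigma[mask]
  sum(r^2) / sum(mask)
}

#' Gradients of the entropy and the chi-squared misfit
#'
#' Analytic gradients with respect to the reconstruction `f`, used by the
#' conjugate-gradient ascent and by the termination metric. For the
#' normalised entropy, `dS/df_k = (-log(p_k/m_k) - S) / sum(f)`; for the
#' misfit, `dchi2/df_k = (2/N') sum_j R_jk ((Rf)_j - d_j)/sigma_j^2` over
#' unmasked `j`.
#'
#' @inheritParams chi_squared
#' @param prior Optional model distribution (see [shannon_entropy()]).
#' @return A list with elements `grad_entropy` and `grad_chi_sq`.
#' @export
mer_gradients <- function(f, spectrum, model = NULL, prior = NULL) {
  if (any(f <= 0)) stop("gradients require strictly positive 'f'")
  total <- sum(f)
  p <- f / total
  if (is.null(prior)) {
    s <- -sum(p * log(p))
    grad_s <- (-log(p) - s) / total
  } else {
    m <- prior / sum(prior)
    s <- -sum(p * log(p / m))
    grad_s <- (-log(p / m) - s) / total
  }
  mask <- spectrum$mask
  n_eff <- sum(mask)
  sigma <- spectrum$sigma
  rf <- if (is.null(model)) f else apply_response(model, f)
  w <- numeric(length(f))
  w[mask] <- (rf[mask] - spectrum$intensity[mask]) / sigma[mask]^2
  grad_c <- if (is.null(model)) {
    2 * w / n_eff
  } else {
    2 * drop(crossprod(model$response, w)) / n_eff
  }
  if (any(!is.finite(grad_s)) || any(!is.finite(grad_c)))
    stop("non-finite gradient encountered")
  list(grad_entropy = grad_s, grad_chi_sq = grad_c)
}

#' Termination metric of the maximum entropy iteration
#'
#' `0.5 * || gS/|gS| - gC/|gC| ||^2`, the squared distance between the unit
#' vectors of the entropy and misfit gradients. It is 0 when the gradients
#' are parallel -- the stationarity condition of the constrained problem --
#' and 2 when anti-parallel; iteration stops once it falls below the
#' threshold (default 0.01).
#'
#' @param grad_entropy,grad_chi_sq Gradient vectors.
#' @return The metric, in `[0, 2]`.
#' @export
termination_metric <- function(grad_entropy, grad_chi_sq) {
  ns <- sqrt(sum(grad_entropy^2))
  nc <- sqrt(sum(grad_chi_sq^2))
  if (ns == 0 && nc == 0) return(0)
  if (ns == 0 || nc == 0)
    stop("zero-norm gradient: termination metric undefined")
  0.5 * sum((grad_entropy / ns - grad_chi_sq / nc)^2)
}

# Internal: termination metric that treats a vanishing entropy gradient
# (the iteration starts exactly at the unconstrained maximiser) as
# maximally unconverged rather than undefined.
termination_metric_safe <- function(grad_entropy, grad_chi_sq) {
  ns <- sqrt(sum(grad_entropy^2))
  nc <- sqrt(sum(grad_chi_sq^2))
  if (ns == 0 && nc == 0) return(0)
  if (ns == 0 || nc == 0) return(2)
  0.5 * sum((grad_entropy / ns - grad_chi_sq / nc)^2)
}

# Internal: uniform spectrum scaled to the total observed (unmasked)
# intensity -- the unconstrained maximiser of the plain entropy.
uniform_start <- function(spectrum) {
  n <- length(spectrum$intensity)
  total <- sum(spectrum$intensity[spectrum$mask])
  total <- max(total, n * .Machine$double.eps)
  rep(total / n, n)
}

#' Does a maximum entropy solution exist for this spectrum?
#'
#' If the unconstrained entropy maximiser (the uniform spectrum scaled to
#' the total observed intensity) already satisfies the consistency
#' constraint `chi2 <= chi0_sq`, the data
#' are too noisy to pin down any structure and no meaningful constrained
#' maximum exists: by convexity the constrained solution would otherwise
#' lie on the boundary `chi2 = chi0_sq`.
#'
#' @inheritParams chi_squared
#' @param chi0_sq Consistency target (default 1).
#' @return `TRUE` when a meaningful reconstruction exists, `FALSE` when the
#'   data are too noisy.
#' @export
me_solution_exists <- function(spectrum, model = NULL, chi0_sq = 1) {
  chi_squared(uniform_start(spectrum), spectrum, model) > chi0_sq
}

#' Build a prior model spectrum from approximate peak parameters
#'
#' Converts approximately known peak positions/widths into the model
#' distribution `m` used by the relative-entropy form of the
#' reconstruction (see [shannon_entropy()]). The model is the normalised
#' Lorentzian sum of the peak set, floored at a small positive value.
#'
#' @param peaks A [peak_set()] holding the approximate positions, widths
#'   and amplitudes.
#' @param model A [spectrometer_model()] (defines the axis and response).
#' @return A positive vector of length `N` summing to 1.
#' @export
mer_prior <- function(peaks, model) {
  g <- peak_model_intensity(model$frequency_ghz, peaks)
  g <- apply_response(model, g)
  g <- pmax(g, 1e-8 * max(g))
  g / sum(g)
}

#' Options for the maximum entropy reconstruction
#'
#' @param chi0_sq Consistency target `chi0^2` (default 1, roughly a 95%
#'   confidence region for Gaussian noise).
#' @param lambda Positive Lagrange multiplier weighting the misfit against
#'   the entropy, or `NULL` (default) to pick a value from the SNR recorded
#'   in the spectrum metadata via [mer_lambda_default()].
#' @param lambda_search If `TRUE`, bisect on `lambda` so the converged
#'   misfit hits `chi0_sq` (slower; off by default since solutions are
#'   stable over a broad range of `lambda`).
#' @param max_iters Maximum conjugate-gradient iterations.
#' @param term_threshold Stop once the [termination_metric()] falls below
#'   this (default 0.01).
#' @param wolfe_c1,wolfe_c2 Wolfe line-search constants, `0 < c1 < c2 < 1`.
#' @param cg_memory Restart the conjugate direction to steepest ascent
#'   every `cg_memory` iterations (default 2).
#' @param floor_eps_rel Positivity floor, relative to `mean(f)`.
#' @param check_exists Test [me_solution_exists()] before iterating.
#' @param verbose Print per-iteration diagnostics.
#' @return A list of class `mer_options`.
#' @export
mer_options <- function(chi0_sq = 1, lambda = NULL, lambda_search = FALSE,
                        max_iters = 500, term_threshold = 0.01,
                        wolfe_c1 = 1e-4, wolfe_c2 = 0.9, cg_memory = 2,
                        floor_eps_rel = 1e-12, check_exists = TRUE,
                        verbose = FALSE) {
  if (!(wolfe_c1 > 0 && wolfe_c1 < wolfe_c2 && wolfe_c2 < 1))
    stop("need 0 < wolfe_c1 < wolfe_c2 < 1")
  if (chi0_sq <= 0) stop("'chi0_sq' must be positive")
  if (!is.null(lambda) && lambda <= 0) stop("'lambda' must be positive")
  if (term_threshold <= 0) stop("'term_threshold' must be positive")
  structure(list(chi0_sq = chi0_sq, lambda = lambda,
                 lambda_search = lambda_search, max_iters = max_iters,
                 term_threshold = term_threshold, wolfe_c1 = wolfe_c1,
                 wolfe_c2 = wolfe_c2, cg_memory = cg_memory,
                 floor_eps_rel = floor_eps_rel, check_exists = check_exists,
                 verbose = verbose),
            class = "mer_options")
}

#' Default Lagrange multiplier as a function of SNR
#'
#' The reconstruction is insensitive to the exact multiplier over a broad
#' range, so a fixed value per SNR suffices; this table was calibrated once
#' on synthetic three-peak spectra so that the converged misfit sits near
#' the target `chi0_sq = 1`, and is log-interpolated in between. Outside
#' the calibrated range the nearest endpoint is used.
#'
#' @param snr Signal-to-noise ratio (Brillouin-referenced).
#' @return A positive multiplier.
#' @export
mer_lambda_default <- function(snr) {
  tab_snr <- c(0.5, 1, 2, 3, 5, 7, 10, 20)
  tab_lam <- c(0.75, 0.45, 0.42, 0.40, 0.37, 0.34, 0.29, 0.24)
  snr <- min(max(snr, tab_snr[1L]), tab_snr[length(tab_snr)])
  exp(stats::approx(log(tab_snr), log(tab_lam), xout = log(snr))$y)
}

# Internal: Lagrangian Q = S - lambda * (chi2 - chi0^2) and its gradient.
mer_objective <- function(f, spectrum, model, prior, lambda, chi0_sq) {
  s <- shannon_entropy(f, prior)
  c2 <- chi_squared(f, spectrum, model)
  list(q = s - lambda * (c2 - chi0_sq), entropy = s, chi_sq = c2)
}

# Internal: Wolfe line search on phi(mu) (an ascent profile with value $q
# and directional derivative $dq). Returns the accepted step (possibly 0
# on failure).
mer_line_search <- function(phi, q0, dq0, mu_init, c1, c2,
                            max_evals = 30) {
  mu_prev <- 0; q_prev <- q0
  mu <- mu_init
  evals <- 0
  lo <- NULL
  while (evals < max_evals) {
    ev <- phi(mu); evals <- evals + 1
    if (!is.finite(ev$q) || ev$q < q0 + c1 * mu * dq0 ||
        (!is.null(lo) && ev$q <= q_prev)) {
      hi <- list(mu = mu, q = ev$q)
      lo <- if (is.null(lo)) list(mu = mu_prev, q = q_prev) else lo
      # zoom by bisection
      while (evals < max_evals) {
        mid <- 0.5 * (lo$mu + hi$mu)
        evm <- phi(mid); evals <- evals + 1
        if (!is.finite(evm$q) || evm$q < q0 + c1 * mid * dq0 ||
            evm$q <= lo$q) {
          hi <- list(mu = mid, q = evm$q)
        } else {
          if (evm$dq >= c2 * dq0 || abs(evm$dq) <= c2 * abs(dq0))
            return(list(mu = mid, evals = evals))
          if (evm$dq * (hi$mu - lo$mu) >= 0) hi <- lo
          lo <- list(mu = mid, q = evm$q)
        }
        if (abs(hi$mu - lo$mu) < 1e-12 * max(1, abs(hi$mu)))
          return(list(mu = lo$mu, evals = evals))
      }
      return(list(mu = lo$mu, evals = evals))
    }
    if (abs(ev$dq) <= c2 * abs(dq0)) return(list(mu = mu, evals = evals))
    if (ev$dq < 0) {
      # overshot the maximum: zoom between previous and current
      lo <- list(mu = mu_prev, q = q_prev)
      hi <- list(mu = mu, q = ev$q)
      while (evals < max_evals) {
        mid <- 0.5 * (lo$mu + hi$mu)
        evm <- phi(mid); evals <- evals + 1
        if (!is.finite(evm$q) || evm$q <= lo$q) {
          hi <- list(mu = mid, q = evm$q)
        } else if (evm$dq < 0) {
          hi <- list(mu = mid, q = evm$q)
          lo <- lo
        } else {
          if (abs(evm$dq) <= c2 * abs(dq0))
            return(list(mu = mid, evals = evals))
          lo <- list(mu = mid, q = evm$q)
        }
        if (abs(hi$mu - lo$mu) < 1e-12 * max(1, abs(hi$mu)))
          return(list(mu = lo$mu, evals = evals))
      }
      return(list(mu = lo$mu, evals = evals))
    }
    # still ascending: expand
    mu_prev <- mu; q_prev <- ev$q
    mu <- 2 * mu
    lo <- NULL
  }
  list(mu = mu_prev, evals = evals)
}

#' Maximum entropy reconstruction of a noisy spectrum
#'
#' Selects, among all strictly positive spectra consistent with the data
#' (normalised misfit at the target `chi0_sq`), the one of maximum entropy.
#' The constrained problem is solved by conjugate-gradient ascent on the
#' Lagrangian `Q = S - lambda (chi2 - chi0_sq)` with a Wolfe line search;
#' iteration stops when the entropy and misfit gradients are parallel to
#' within the [termination_metric()] threshold. Approximate prior knowledge
#' of the peaks can be supplied, entering as the model of a relative
#' entropy; the reconstruction then balances fidelity to the data against
#' proximity to the prior shape.
#'
#' When the data are too noisy even the featureless unconstrained maximiser
#' satisfies the constraint and no meaningful solution exists; this is
#' detected up front (see [me_solution_exists()]) and reported via the
#' `exists` flag rather than by iterating.
#'
#' @param spectrum A noisy [brillouin_spectrum()] with per-pixel `sigma`.
#' @param model Optional [spectrometer_model()]; its response matrix is
#'   deconvolved implicitly through the misfit.
#' @param prior Optional prior: a [peak_set()] of approximate peak
#'   parameters, or a positive vector of length `N` (a model distribution),
#'   or `NULL` for the maximally non-committal (uniform) prior.
#' @param options A [mer_options()] list.
#' @return An object of class `mer_recon` with fields `f` (the
#'   reconstruction, strictly positive), `entropy`, `chi_sq`,
#'   `term_metric`, `n_iters`, `converged`, `exists`, `lambda`,
#'   `spectrum` (the input) and `floor_eps`.
#' @examples
#' s <- simulate_spectrum(snr = 5, seed = 1)
#' r <- mer_reconstruct(s, prior = peak_set())
#' r
#' @export
mer_reconstruct <- function(spectrum, model = NULL, prior = NULL,
                            options = mer_options()) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  prior_vec <- NULL
  if (!is.null(prior)) {
    prior_vec <- if (inherits(prior, "peak_set")) {
      if (is.null(model)) {
        g <- peak_model_intensity(spectrum$frequency_ghz, prior)
        g <- pmax(g, 1e-8 * max(g))
        g / sum(g)
      } else mer_prior(prior, model)
    } else {
      if (length(prior) != length(spectrum$intensity) || any(prior <= 0))
        stop("'prior' vector must be positive and of length N")
      prior / sum(prior)
    }
  }
  lambda <- options$lambda
  if (is.null(lambda)) {
    snr <- spectrum$meta$snr
    lambda <- if (is.null(snr) || !is.finite(snr)) 5 else mer_lambda_default(snr)
  }
  exists <- me_solution_exists(spectrum, model, options$chi0_sq)
  f0 <- uniform_start(spectrum)
  if (!is.null(prior_vec)) f0 <- prior_vec * sum(f0)
  if (!exists && options$check_exists) {
    ob <- mer_objective(f0, spectrum, model, prior_vec, lambda,
                        options$chi0_sq)
    return(new_mer_recon(f0, ob, NA_real_, 0L, FALSE, FALSE, lambda,
                         spectrum, 0))
  }
  if (!options$lambda_search)
    return(mer_ascend(f0, spectrum, model, prior_vec, lambda, options))
  # outer bisection on log-lambda to land chi^2 on the target
  lo <- lambda / 64; hi <- lambda * 64
  res <- mer_ascend(f0, spectrum, model, prior_vec, lambda, options)
  for (i in 1:12) {
    if (abs(res$chi_sq - options$chi0_sq) < 0.05 * options$chi0_sq) break
    if (res$chi_sq > options$chi0_sq) lo <- res$lambda else hi <- res$lambda
    lam <- sqrt(lo * hi)
    res <- mer_ascend(res$f, spectrum, model, prior_vec, lam, options)
  }
  res
}

# Internal: constructor for the result object.
new_mer_recon <- function(f, ob, term, iters, converged, exists, lambda,
                          spectrum, floor_eps, q_trace = numeric()) {
  structure(list(f = f, entropy = ob$entropy, chi_sq = ob$chi_sq,
                 lagrangian = ob$q, term_metric = term, n_iters = iters,
                 converged = converged, exists = exists, lambda = lambda,
                 spectrum = spectrum, floor_eps = floor_eps,
                 q_trace = q_trace),
            class = "mer_recon")
}

# Internal: conjugate-gradient ascent with Wolfe line search at fixed
# lambda.
mer_ascend <- function(f, spectrum, model, prior_vec, lambda, options) {
  chi0 <- options$chi0_sq
  floor_f <- function(f) pmax(f, options$floor_eps_rel * mean(f))
  f <- floor_f(f)
  # curvature of -Q along direction p: exact for the quadratic misfit,
  # diagonal approximation for the entropy; gives a Newton-like first
  # trial step so the Wolfe search starts near the line optimum
  mask <- spectrum$mask
  n_eff <- sum(mask)
  curv_along <- function(f, p) {
    rp <- if (is.null(model)) p else apply_response(model, p)
    curv_chi <- 2 * sum((rp[mask] / spectrum$sigma[mask])^2) / n_eff
    curv_s <- sum(p^2 / f) / sum(f)
    lambda * curv_chi + curv_s
  }
  # Positivity is handled by projection: pixels sitting at the floor whose
  # gradient still points outward are frozen for the step (their optimal
  # value is effectively zero and only the floor keeps the logarithms
  # finite). Convergence is judged on the interior pixels, where the
  # parallel-gradient condition of the constrained optimum applies.
  floor_val <- function(f) options$floor_eps_rel * mean(f)
  at_floor <- function(f) f <= 1.000001 * floor_val(f)
  interior_metric <- function(f, g) {
    int <- !at_floor(f)
    if (!any(int)) return(0)
    termination_metric_safe(g$grad_entropy[int], g$grad_chi_sq[int])
  }
  g <- mer_gradients(f, spectrum, model, prior_vec)
  gq <- g$grad_entropy - lambda * g$grad_chi_sq
  p <- gq
  term <- interior_metric(f, g)
  converged <- term < options$term_threshold
  iters <- 0L
  since_restart <- 0L
  q_trace <- mer_objective(f, spectrum, model, prior_vec, lambda, chi0)$q
  while (!converged && iters < options$max_iters) {
    frozen <- at_floor(f) & gq < 0
    p[frozen] <- 0
    dq0 <- sum(gq * p)
    if (dq0 <= 0 || since_restart >= options$cg_memory) {
      p <- gq
      p[frozen] <- 0
      dq0 <- sum(gq * p)
      since_restart <- 0L
    }
    if (dq0 <= 0) break                    # KKT point of the floored problem
    ob0 <- mer_objective(f, spectrum, model, prior_vec, lambda, chi0)
    # projected profile: trial points are floored, so the path may bend
    # onto the positivity boundary; clamped components contribute no
    # directional derivative
    phi <- function(mu) {
      ftrial <- f + mu * p
      clamped <- ftrial < options$floor_eps_rel * mean(ftrial)
      ftrial <- floor_f(ftrial)
      s <- shannon_entropy(ftrial, prior_vec)
      c2 <- chi_squared(ftrial, spectrum, model)
      g <- mer_gradients(ftrial, spectrum, model, prior_vec)
      gq_t <- g$grad_entropy - lambda * g$grad_chi_sq
      list(q = s - lambda * (c2 - chi0),
           dq = sum((gq_t * p)[!clamped]))
    }
    mu_init <- dq0 / max(curv_along(f, p), .Machine$double.xmin)
    ls <- mer_line_search(phi, ob0$q, dq0, mu_init,
                          options$wolfe_c1, options$wolfe_c2)
    mu <- ls$mu
    if (mu <= 0) {
      # fall back to steepest ascent with step halving
      p <- gq
      p[frozen] <- 0
      mu_try <- sum(gq * p) / max(curv_along(f, p), .Machine$double.xmin)
      ok <- FALSE
      for (k in 1:30) {
        ftrial <- floor_f(f + mu_try * p)
        obt <- mer_objective(ftrial, spectrum, model, prior_vec, lambda,
                             chi0)
        if (is.finite(obt$q) && obt$q > ob0$q) { ok <- TRUE; break }
        mu_try <- mu_try / 2
      }
      if (!ok) break
      mu <- mu_try
      since_restart <- 0L
    }
    f_new <- floor_f(f + mu * p)
    g_new <- mer_gradients(f_new, spectrum, model, prior_vec)
    gq_new <- g_new$grad_entropy - lambda * g_new$grad_chi_sq
    # Polak-Ribiere with non-negativity
    beta <- max(0, sum(gq_new * (gq_new - gq)) / sum(gq * gq))
    p <- gq_new + beta * p
    f <- f_new; g <- g_new; gq <- gq_new
    iters <- iters + 1L
    since_restart <- since_restart + 1L
    q_trace <- c(q_trace,
                 mer_objective(f, spectrum, model, prior_vec, lambda, chi0)$q)
    term <- interior_metric(f, g)
    converged <- term < options$term_threshold
    if (options$verbose) {
      ob <- mer_objective(f, spectrum, model, prior_vec, lambda, chi0)
      message(sprintf("iter %3d  Q = %.6g  chi2 = %.4f  metric = %.4g  floored = %d",
                      iters, ob$q, ob$chi_sq, term, sum(at_floor(f))))
    }
  }
  ob <- mer_objective(f, spectrum, model, prior_vec, lambda, chi0)
  new_mer_recon(f, ob, term, iters, converged, TRUE, lambda, spectrum,
                floor_val(f), q_trace)
}

#' @export
print.mer_recon <- function(x, ...) {
  cat("Maximum entropy reconstruction\n")
  if (!x$exists) {
    cat("  no ME solution: data too noisy (unconstrained maximiser already consistent)\n")
    return(invisible(x))
  }
  cat(sprintf("  converged: %s after %d iterations (termination metric %.3g)\n",
              x$converged, x$n_iters, x$term_metric))
  cat(sprintf("  entropy %.6g, chi-squared %.4f (lambda = %.3g)\n",
              x$entropy, x$chi_sq, x$lambda))
  invisible(x)
}

#' Reconstructed spectrum from a maximum entropy fit
#'
#' @param recon An object from [mer_reconstruct()].
#' @return A [brillouin_spectrum()] holding the reconstruction on the
#'   original axis (mask and sigma copied from the input).
#' @export
as_spectrum <- function(recon) {
  stopifnot(inherits(recon, "mer_recon"))
  s <- recon$spectrum
  brillouin_spectrum(s$frequency_ghz, recon$f, sigma = s$sigma,
                     mask = s$mask,
                     meta = c(s$meta, list(denoised = "mer")))
}

#' @export
plot.mer_recon <- function(x, ...) {
  s <- x$spectrum
  graphics::plot(s$frequency_ghz, s$intensity, type = "l", col = "grey",
                 xlab = "Frequency shift (GHz)", ylab = "Intensity (counts)",
                 ...)
  graphics::lines(s$frequency_ghz, x$f, col = "red", lwd = 2)
  graphics::legend("topright", c("data", "reconstruction"),
                   col = c("grey", "red"), lwd = c(1, 2), bty = "n")
  invisible(x)
}
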