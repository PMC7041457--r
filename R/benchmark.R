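#' Deterministic per-trial seed stream
#'
#' Maps a base seed plus a `(snr, index)` pair to a reproducible seed
#' below `2^31`. All methods of a benchmark cell share the stream, so
#' every method sees the same noisy spectra, and results do not depend on
#' execution order.
#'
#' @param base_seed Base integer seed of the benchmark.
#' @param snr The cell's signal-to-noise ratio.
#' @param index Trial index (1, 2, ...).
#' @return An integer seed.
#' @export
trial_seed <- function(base_seed, snr, index) {
  m <- 2147483647
  a <- base_seed %% m
  a <- (a * 48271 + round(snr * 1e4) %% m) %% m
  a <- (a * 48271 + index) %% m
  as.integer(a)
}

#' Run one generate / denoise / fit trial
#'
#' Generates a noisy spectrum at the requested SNR, optionally denoises it
#' (`"mer"` or `"wa"`), fits the Lorentzian model and returns the
#' estimates. Fully determined by `(snr, method, seed)` and the
#' configuration.
#'
#' @param snr Signal-to-noise ratio of the generated spectrum.
#' @param method `"none"`, `"mer"` or `"wa"`.
#' @param seed Integer seed for the noise realisation.
#' @param peaks,model Ground truth peak set and spectrometer.
#' @param mer_opts [mer_options()] used when `method = "mer"`.
#' @param use_prior Supply the true peak set as the MER prior (the
#'   benchmark protocol; approximate peak knowledge).
#' @param wa_args List of arguments passed on to [wa_denoise()].
#' @param fit_args List of arguments passed on to [fit_brillouin()].
#' @return A one-row `data.frame`: `shift_ghz`, `linewidth_ghz`,
#'   `amplitude`, `me_exists`, `mer_converged`, `fit_success`, `seed`.
#' @export
run_trial <- function(snr, method = c("none", "mer", "wa"), seed,
                      peaks = peak_set(), model = spectrometer_model(),
                      mer_opts = mer_options(), use_prior = TRUE,
                      wa_args = list(),
                      fit_args = list(symmetric_pair = FALSE)) {
  method <- match.arg(method)
  s <- simulate_spectrum(snr, seed, peaks, model)
  me_exists <- NA
  mer_converged <- NA
  if (method == "mer") {
    prior <- if (use_prior) peaks else NULL
    r <- mer_reconstruct(s, model = NULL, prior = prior, options = mer_opts)
    me_exists <- r$exists
    mer_converged <- r$converged
    if (!r$exists) {
      return(data.frame(shift_ghz = NA_real_, linewidth_ghz = NA_real_,
                        amplitude = NA_real_, me_exists = FALSE,
                        mer_converged = FALSE, fit_success = FALSE,
                        seed = seed))
    }
    s <- as_spectrum(r)
  } else if (method == "wa") {
    s <- do.call(wa_denoise, c(list(spectrum = s), wa_args))
  }
  fit <- do.call(fit_brillouin, c(list(spectrum = s), fit_args))
  data.frame(shift_ghz = fit$shift_ghz, linewidth_ghz = fit$linewidth_ghz,
             amplitude = fit$amplitude, me_exists = me_exists,
             mer_converged = mer_converged, fit_success = fit$success,
             seed = seed)
}

#' Monte-Carlo benchmark of denoising methods across SNRs
#'
#' For every `(snr, method)` cell: generate `n_realisations` independent
#' noisy spectra, apply the method, fit, and tabulate the bias and
#' standard deviation of the Brillouin-shift estimate, the fitted
#' linewidth moments, the rate at which no maximum-entropy solution
#' existed, and the Cramer-Rao reference. When
#' `regenerate_on_me_failure = TRUE` (the default), spectra without an ME
#' solution are replaced by fresh realisations until the cell holds
#' `n_realisations` reconstructions, with the failures counted in
#' `me_failure_rate`.
#'
#' Trials are seed-indexed, so results do not depend on execution order,
#' and all methods of a given cell see the same realisations. Fit failures
#' are excluded from the moments and reported in `n_fit_failed`.
#'
#' @param snr_grid Numeric vector of SNRs.
#' @param methods Subset of `c("none", "mer", "wa")`.
#' @param n_realisations Realisations per cell (>= 2).
#' @param seed Base seed for the whole benchmark.
#' @param peaks,model Ground truth.
#' @param regenerate_on_me_failure Replace spectra lacking ME solutions.
#' @param mer_opts,use_prior,wa_args,fit_args Passed to [run_trial()];
#'   `mer_opts = NULL` picks the SNR-dependent default multiplier per
#'   cell.
#' @param progress Print one line per completed cell.
#' @return An object of class `brillouin_benchmark`: a list with `table`
#'   (one row per cell: `snr`, `method`, `bias_ghz`, `bias_pct`,
#'   `std_ghz`, `std_pct`, `linewidth_mean_ghz`, `linewidth_std_ghz`,
#'   `me_failure_rate`, `n_used`, `n_fit_failed`, `crlb_std_ghz`,
#'   `unusable`) and the configuration.
#' @export
run_benchmark <- function(snr_grid, methods = c("none", "mer", "wa"),
                          n_realisations = 500, seed = 1,
                          peaks = peak_set(), model = spectrometer_model(),
                          regenerate_on_me_failure = TRUE,
                          mer_opts = NULL, use_prior = TRUE,
                          wa_args = list(),
                          fit_args = list(symmetric_pair = FALSE),
                          progress = FALSE) {
  stopifnot(length(snr_grid) >= 1L, n_realisations >= 2L)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  trials <- list()
  for (snr in snr_grid) {
    opts <- if (is.null(mer_opts))
      mer_options(lambda = mer_lambda_default(snr)) else mer_opts
    sigma <- peaks$brillouin_amplitude / snr
    crlb <- crlb_shift_std(crlb_params(model, peaks, sigma))
    for (method in methods) {
      got <- 0L
      idx <- 0L
      failures <- 0L
      cell <- vector("list", n_realisations)
      max_idx <- 20L * n_realisations
      while (got < n_realisations && idx < max_idx) {
        idx <- idx + 1L
        tr <- run_trial(snr, method, trial_seed(seed, snr, idx),
                        peaks, model, mer_opts = opts,
                        use_prior = use_prior, wa_args = wa_args,
                        fit_args = fit_args)
        if (method == "mer" && identical(tr$me_exists, FALSE)) {
          failures <- failures + 1L
          if (regenerate_on_me_failure) next
          got <- got + 1L            # keep the failed slot, no estimate
          cell[[got]] <- tr
          next
        }
        got <- got + 1L
        cell[[got]] <- tr
      }
      cell <- do.call(rbind, cell[seq_len(got)])
      ok <- cell$fit_success & is.finite(cell$shift_ghz)
      unusable <- mean(!ok) > 0.95
      est <- cell$shift_ghz[ok]
      lw <- cell$linewidth_ghz[ok]
      omega <- peaks$brillouin_shift_ghz
      rows[[length(rows) + 1L]] <- data.frame(
        snr = snr, method = method,
        bias_ghz = mean(est) - omega,
        bias_pct = (mean(est) - omega) / omega * 100,
        std_ghz = stats::sd(est),
        std_pct = stats::sd(est) / omega * 100,
        linewidth_mean_ghz = mean(lw),
        linewidth_std_ghz = stats::sd(lw),
        me_failure_rate = if (method == "mer")
          failures / max(failures + got, 1L) else NA_real_,
        n_used = sum(ok), n_fit_failed = sum(!ok),
        crlb_std_ghz = crlb, unusable = unusable)
      trials[[paste(snr, method)]] <- cell
      if (progress)
        message(sprintf("snr %.3g %-4s: bias %.3f%% std %.3f%% lw %.2f GHz (n = %d)",
                        snr, method, rows[[length(rows)]]$bias_pct,
                        rows[[length(rows)]]$std_pct,
                        rows[[length(rows)]]$linewidth_mean_ghz, sum(ok)))
    }
  }
  structure(list(table = do.call(rbind, rows), trials = trials,
                 peaks = peaks, model = model, seed = seed,
                 n_realisations = n_realisations),
            class = "brillouin_benchmark")
}

#' @export
print.brillouin_benchmark <- function(x, ...) {
  cat(sprintf("Monte-Carlo benchmark: %d realisations per cell, base seed %d\n",
              x$n_realisations, x$seed))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Long-format series for plotting a benchmark
#'
#' Produces the bias-versus-SNR and log10(standard deviation)-versus-SNR
#' series per method, alongside the Cramer-Rao reference curve.
#'
#' @param benchmark A [run_benchmark()] result.
#' @return A `data.frame` with columns `snr`, `method`, `bias_pct`,
#'   `std_ghz`, `log10_std_ghz`, `crlb_std_ghz`, `log10_crlb_std_ghz`.
#' @export
summarize_benchmark <- function(benchmark) {
  stopifnot(inherits(benchmark, "brillouin_benchmark"))
  t <- benchmark$table
  data.frame(snr = t$snr, method = t$method, bias_pct = t$bias_pct,
             std_ghz = t$std_ghz, log10_std_ghz = log10(t$std_ghz),
             crlb_std_ghz = t$crlb_std_ghz,
             log10_crlb_std_ghz = log10(t$crlb_std_ghz))
}

#' @export
plot.brillouin_benchmark <- function(x, which = c("bias", "std"), ...) {
  which <- match.arg(which)
  t <- x$table
  methods <- unique(t$method)
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(methods)),
                                                "Dark 3")[seq_along(methods)],
                          methods)
  if (which == "bias") {
    graphics::plot(range(t$snr), range(t$bias_pct, na.rm = TRUE),
                   type = "n", xlab = "SNR", ylab = "Bias (% of shift)",
                   ...)
    graphics::abline(h = 0, lty = 3)
    for (m in methods) {
      tm <- t[t$method == m, ]
      graphics::lines(tm$snr, tm$bias_pct, col = cols[m], type = "b")
    }
  } else {
    graphics::plot(range(t$snr),
                   range(log10(c(t$std_ghz, t$crlb_std_ghz)), na.rm = TRUE),
                   type = "n", xlab = "SNR",
                   ylab = "log10 std of shift (GHz)", ...)
    for (m in methods) {
      tm <- t[t$method == m, ]
      graphics::lines(tm$snr, log10(tm$std_ghz), col = cols[m], type = "b")
    }
    tm <- t[t$method == methods[1L], ]
    graphics::lines(tm$snr, log10(tm$crlb_std_ghz), lty = 2)
  }
  graphics::legend("topright", legend = c(methods,
                                          if (which == "std") "CRLB"),
                   col = c(cols[methods], if (which == "std") "black"),
                   lty = c(rep(1, length(methods)),
                           if (which == "std") 2), bty = "n")
  invisible(x)
}

#' Write a benchmark table to CSV and JSON
#'
#' @param benchmark A [run_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "brillouin_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(benchmark$table, file.path(dir, "table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(benchmark$table, file.path(dir, "table.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
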