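# Shared fixtures: the default simulated spectrometer (120 pixels over
# 60 GHz) and water-like three-peak truth used throughout the suite.

default_model <- spectrometer_model()
default_peaks <- peak_set()
default_truth <- synth_truth(default_peaks, default_model)

noisy_spectrum <- function(snr, seed = 1) {
  add_noise(default_truth, snr, seed)
}

# Independent double-loop evaluation of the normalised misfit, used as a
# brute-force oracle against the vectorised implementation.
chi_squared_loops <- function(f, d, sigma, response = NULL, mask = NULL) {
  n <- length(d)
  if (is.null(mask)) mask <- rep(TRUE, n)
  total <- 0
  for (j in seq_len(n)) {
    if (!mask[j]) next
    rf_j <- 0
    for (k in seq_len(n)) {
      r_jk <- if (is.null(response)) as.numeric(j == k) else response[j, k]
      rf_j <- rf_j + r_jk * f[k]
    }
    total <- total + (rf_j - d[j])^2 / sigma[j]^2
  }
  total / sum(mask)
}
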