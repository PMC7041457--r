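# Orthonormal scaling (low-pass) filters. These are the standard published
# Daubechies / least-asymmetric (symlet) coefficients; the high-pass and
# reconstruction filters follow from the quadrature-mirror relations.
.wavelet_filters <- list(
  haar = c(7.07106781186547573e-01, 7.07106781186547573e-01),
  db2 = c(-1.29409522551260370e-01, 2.24143868042013389e-01,
          8.36516303737807942e-01, 4.82962913144534156e-01),
  db4 = c(-1.05974017850690317e-02, 3.28830116668851966e-02,
          3.08413818355607640e-02, -1.87034811719093086e-01,
          -2.79837694168598543e-02, 6.30880767929858921e-01,
          7.14846570552915672e-01, 2.30377813308896506e-01),
  sym8 = c(-3.38241595100612557e-03, -5.42132331791148124e-04,
           3.16950878114929807e-02, 7.60748732491760542e-03,
           -1.43294238350809705e-01, -6.12733590676585241e-02,
           4.81359651258372212e-01, 7.77185751700523508e-01,
           3.64441894835331404e-01, -5.19458381077090373e-02,
           -2.72190299170560028e-02, 4.91371796736075062e-02,
           3.80875201389061510e-03, -1.49522583370482309e-02,
           -3.02920514721366800e-04, 1.88995033275946088e-03)
)

#' Wavelet filter bank
#'
#' Returns the decomposition and reconstruction filters of an orthonormal
#' wavelet. Available families: `haar`, `db2`, `db4`, `sym8`.
#'
#' @param name Wavelet name (default `"sym8"`).
#' @return A list with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and `length`.
#' @export
wavelet_filter <- function(name = "sym8") {
  dec_lo <- .wavelet_filters[[name]]
  if (is.null(dec_lo))
    stop("unknown wavelet '", name, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "))
  n <- length(dec_lo)
  k <- seq_len(n) - 1L
  dec_hi <- (-1)^(k + 1) * rev(dec_lo)
  list(name = name, dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), length = n)
}

# Internal: symmetric (half-point) extension by m samples each side.
symmetric_extend <- function(x, m) {
  n <- length(x)
  idx <- c(rev(seq_len(min(m, n))), seq_len(n), n + 1L - seq_len(min(m, n)))
  while (length(idx) < n + 2 * m) {        # m > n: keep reflecting
    extra <- m - (length(idx) - n) / 2
    idx <- c(rev(idx[seq_len(extra)]), idx, rev(idx)[seq_len(extra)])
  }
  x[idx]
}

# Internal: valid convolution of a with kernel h (kernel is flipped, as in
# a textbook convolution).
conv_valid <- function(a, h) {
  n_out <- length(a) - length(h) + 1L
  out <- numeric(n_out)
  hr <- rev(h)
  for (k in seq_len(n_out))
    out[k] <- sum(a[k:(k + length(h) - 1L)] * hr)
  out
}

#' Single-level discrete wavelet transform
#'
#' One analysis step of the Mallat pyramid with symmetric boundary
#' extension: the signal is extended, convolved with the low- and
#' high-pass decomposition filters and downsampled by two. Output lengths
#' are `floor((N + L - 1)/2)` where `L` is the filter length.
#'
#' @param x Numeric signal.
#' @param filter A [wavelet_filter()] (or a name).
#' @return A list with approximation (`cA`) and detail (`cD`) coefficients.
#' @export
dwt_step <- function(x, filter = wavelet_filter()) {
  if (is.character(filter)) filter <- wavelet_filter(filter)
  L <- filter$length
  ext <- symmetric_extend(x, L - 1L)
  full_lo <- conv_valid(ext, filter$dec_lo)
  full_hi <- conv_valid(ext, filter$dec_hi)
  keep <- seq(2L, length(full_lo), by = 2L)
  list(cA = full_lo[keep], cD = full_hi[keep])
}

#' Single-level inverse discrete wavelet transform
#'
#' @param cA,cD Approximation and detail coefficients (equal length).
#' @param filter A [wavelet_filter()] (or a name).
#' @param out_len Length of the reconstructed signal (defaults to the full
#'   `2*length(cA) - L + 2`).
#' @return The reconstructed signal.
#' @export
idwt_step <- function(cA, cD, filter = wavelet_filter(), out_len = NULL) {
  if (is.character(filter)) filter <- wavelet_filter(filter)
  if (length(cA) != length(cD)) stop("'cA' and 'cD' lengths differ")
  L <- filter$length
  up <- function(c) { u <- numeric(2L * length(c)); u[seq(1L, length(u), 2L)] <- c; u }
  conv_full <- function(a, h) {
    out <- numeric(length(a) + length(h) - 1L)
    for (j in seq_along(h))
      out[j:(j + length(a) - 1L)] <- out[j:(j + length(a) - 1L)] + a * h[j]
    out
  }
  full <- conv_full(up(cA), filter$rec_lo) + conv_full(up(cD), filter$rec_hi)
  n_full <- 2L * length(cA) - L + 2L
  y <- full[(L - 1L):(L - 2L + n_full)]
  if (!is.null(out_len)) {
    if (out_len > length(y)) stop("'out_len' exceeds reconstruction length")
    y <- y[seq_len(out_len)]
  }
  y
}

#' Deepest useful decomposition level
#'
#' Levels beyond this are entirely boundary-dominated for the given filter.
#'
#' @param n Signal length.
#' @param filter_length Length of the wavelet filter.
#' @return The maximum decomposition depth (possibly 0).
#' @export
max_dwt_level <- function(n, filter_length) {
  if (n < filter_length) return(0L)
  as.integer(floor(log2(n / (filter_length - 1))))
}

#' Multi-level discrete wavelet decomposition
#'
#' @param x Numeric signal (or a [brillouin_spectrum()], in which case its
#'   intensities are transformed).
#' @param wavelet Wavelet name (see [wavelet_filter()]).
#' @param levels Decomposition depth; defaults to
#'   `min(4, max_dwt_level(N, L))` and is reduced (with a warning) when the
#'   signal is too short for the request.
#' @return An object of class `wavelet_decomposition`: a list with
#'   `coeffs` (approximation first, then details from coarsest to finest),
#'   `levels`, `wavelet`, `boundary` (`"symmetric"`) and `n` (the original
#'   length).
#' @export
wavedec <- function(x, wavelet = "sym8", levels = NULL) {
  if (inherits(x, "brillouin_spectrum")) x <- x$intensity
  filt <- wavelet_filter(wavelet)
  n <- length(x)
  lmax <- max_dwt_level(n, filt$length)
  if (is.null(levels)) levels <- min(4L, max(lmax, 1L))
  if (levels < 1L) stop("'levels' must be >= 1")
  if (levels > max(lmax, 1L)) {
    warning("signal too short for ", levels, " levels; using ",
            max(lmax, 1L))
    levels <- max(lmax, 1L)
  }
  details <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(cur, filt)
    details[[l]] <- st$cD
    cur <- st$cA
  }
  structure(list(coeffs = c(list(cur), rev(details)), levels = levels,
                 wavelet = wavelet, boundary = "symmetric", n = n),
            class = "wavelet_decomposition")
}

#' Multi-level inverse wavelet transform
#'
#' Perfectly reconstructs the signal from an (unmodified) [wavedec()]
#' decomposition.
#'
#' @param decomp A `wavelet_decomposition`.
#' @return The reconstructed signal of the original length.
#' @export
waverec <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  filt <- wavelet_filter(decomp$wavelet)
  coeffs <- decomp$coeffs
  cur <- coeffs[[1L]]
  for (i in seq(2L, length(coeffs))) {
    cd <- coeffs[[i]]
    if (length(cur) > length(cd)) cur <- cur[seq_along(cd)]
    target <- if (i < length(coeffs)) length(coeffs[[i + 1L]]) else decomp$n
    cur <- idwt_step(cur, cd, filt)
    if (length(cur) > target && i == length(coeffs)) cur <- cur[seq_len(target)]
  }
  cur
}

#' Robust noise-level estimate from the finest wavelet detail
#'
#' `median(|cD_1|) / 0.6745`: for Gaussian white noise the finest detail
#' coefficients are essentially pure noise with the same standard
#' deviation, and the median absolute deviation is insensitive to the few
#' large coefficients carrying sharp signal features.
#'
#' @param decomp A [wavedec()] decomposition.
#' @return Estimated noise standard deviation.
#' @export
estimate_noise <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  finest <- decomp$coeffs[[length(decomp$coeffs)]]
  if (length(finest) == 0L) stop("empty finest detail level")
  stats::median(abs(finest)) / 0.6745
}

#' Universal (level-independent) wavelet threshold
#'
#' The default is the standard universal threshold
#' `T = noise_level * sqrt(2 log N)`, which for white Gaussian noise
#' removes, with probability approaching one, every coefficient that is
#' pure noise. A dimensionally different variant,
#' `T = noise_level * 2 log(N) / N`, circulates in parts of the
#' spectroscopy literature and is available as `dialect = "literal"`.
#'
#' @param noise_level Noise standard deviation `n` (>= 0).
#' @param n_samples Number of samples `N` (>= 1).
#' @param dialect `"standard"` (default) or `"literal"`.
#' @return The threshold (0 when `noise_level = 0` or `N = 1`).
#' @export
universal_threshold <- function(noise_level, n_samples,
                                dialect = c("standard", "literal")) {
  dialect <- match.arg(dialect)
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  if (noise_level < 0) stop("'noise_level' must be >= 0")
  switch(dialect,
         standard = noise_level * sqrt(2 * log(n_samples)),
         literal = noise_level * 2 * log(n_samples) / n_samples)
}

#' Soft (or hard) thresholding of wavelet coefficients
#'
#' Soft thresholding shrinks every coefficient towards zero by the
#' threshold and zeroes those below it: `sign(c) * max(|c| - T, 0)`. Hard
#' thresholding zeroes small coefficients but leaves the rest untouched.
#'
#' @param coeffs Numeric coefficients.
#' @param threshold Threshold `T` (>= 0).
#' @param soft Use soft (default) rather than hard thresholding.
#' @return Thresholded coefficients.
#' @export
soft_threshold <- function(coeffs, threshold, soft = TRUE) {
  if (threshold < 0) stop("'threshold' must be >= 0")
  if (soft) sign(coeffs) * pmax(abs(coeffs) - threshold, 0)
  else coeffs * (abs(coeffs) >= threshold)
}

#' Wavelet-shrinkage denoising of a spectrum
#'
#' Decomposes the spectrum, soft-thresholds all detail levels (the
#' coarse approximation is untouched), and inverts the transform. With the
#' default `"universal"` rule the threshold is level-independent,
#' `sigma_hat * sqrt(2 log N)`, with the noise level estimated from the
#' finest detail via [estimate_noise()] (or taken from `noise_level`).
#' `"universal_per_level"` instead estimates a noise level per detail
#' level, which accommodates intensity-dependent (shot-like) noise;
#' `"manual"` applies a caller-supplied threshold.
#'
#' @param spectrum A [brillouin_spectrum()].
#' @param wavelet Wavelet name (default `"sym8"`).
#' @param levels Decomposition depth (default `min(4, max decomposable)`).
#' @param rule `"universal"`, `"universal_per_level"` or `"manual"`.
#' @param threshold Threshold for `rule = "manual"`.
#' @param noise_level Optional known noise standard deviation; overrides
#'   the MAD estimate for the universal rule.
#' @param soft Soft (default) or hard thresholding.
#' @param dialect Threshold formula dialect (see [universal_threshold()]).
#' @return The denoised [brillouin_spectrum()] (axis, sigma and mask are
#'   copied from the input).
#' @examples
#' s <- simulate_spectrum(snr = 5, seed = 1)
#' d <- wa_denoise(s)
#' @export
wa_denoise <- function(spectrum, wavelet = "sym8", levels = NULL,
                       rule = c("universal", "universal_per_level", "manual"),
                       threshold = NULL, noise_level = NULL, soft = TRUE,
                       dialect = "standard") {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  rule <- match.arg(rule)
  if (rule == "manual" && is.null(threshold))
    stop("rule = 'manual' requires an explicit 'threshold'")
  n <- length(spectrum$intensity)
  decomp <- wavedec(spectrum$intensity, wavelet, levels)
  k <- length(decomp$coeffs)
  if (rule == "universal") {
    sig <- if (is.null(noise_level)) estimate_noise(decomp) else noise_level
    thr <- rep(universal_threshold(sig, n, dialect), k - 1L)
  } else if (rule == "universal_per_level") {
    thr <- vapply(decomp$coeffs[-1L], function(cd) {
      sig <- stats::median(abs(cd)) / 0.6745
      universal_threshold(sig, n, dialect)
    }, numeric(1))
  } else {
    thr <- rep(threshold, k - 1L)
  }
  for (i in seq(2L, k))
    decomp$coeffs[[i]] <- soft_threshold(decomp$coeffs[[i]], thr[i - 1L],
                                         soft = soft)
  out <- spectrum
  out$intensity <- waverec(decomp)
  out$meta$denoised <- "wa"
  out$meta$wa_threshold <- thr
  out
}
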