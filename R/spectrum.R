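#' Construct a Brillouin spectrum object
#'
#' A spectrum is a set of `N` intensity readings on a uniformly spaced
#' frequency axis, expressed in GHz offset from the (elastic) Rayleigh line.
#' Each pixel may carry its own noise standard deviation and a logical mask;
#' masked-out pixels (`mask = FALSE`) are excluded from chi-squared
#' constraints and from fitting, which is how saturated or suppressed
#' Rayleigh regions are handled.
#'
#' @param frequency_ghz Numeric vector of pixel-centre frequencies (GHz),
#'   strictly increasing and uniformly spaced.
#' @param intensity Numeric vector of recorded intensities (counts). Values
#'   may be negative once noise has been added.
#' @param sigma Per-pixel noise standard deviation: a scalar, a vector of
#'   length `N`, or `NULL` when unknown.
#' @param mask Logical vector of length `N`; `TRUE` means the pixel
#'   participates in constraints and fits. Defaults to all `TRUE`.
#' @param meta Free-form list of provenance (seed, SNR, generator
#'   parameters, ...).
#' @return An object of class `brillouin_spectrum`: a list with elements
#'   `frequency_ghz`, `intensity`, `sigma`, `mask`, `meta`.
#' @examples
#' s <- brillouin_spectrum(seq(-29.75, 29.75, by = 0.5), rep(1, 120))
#' s
#' @export
brillouin_spectrum <- function(frequency_ghz, intensity, sigma = NULL,
                               mask = NULL, meta = list()) {
  frequency_ghz <- as.numeric(frequency_ghz)
  intensity <- as.numeric(intensity)
  n <- length(frequency_ghz)
  if (n < 2L) stop("a spectrum needs at least two pixels")
  if (length(intensity) != n)
    stop("'intensity' and 'frequency_ghz' lengths differ")
  d <- diff(frequency_ghz)
  if (any(d <= 0)) stop("'frequency_ghz' must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("'frequency_ghz' must be uniformly spaced")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) == 1L) sigma <- rep(sigma, n)
    if (length(sigma) != n) stop("'sigma' must be scalar or length N")
    if (any(sigma < 0)) stop("'sigma' must be non-negative")
  }
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n || !is.logical(mask))
    stop("'mask' must be a logical vector of length N")
  structure(
    list(frequency_ghz = frequency_ghz, intensity = intensity,
         sigma = sigma, mask = mask, meta = meta),
    class = "brillouin_spectrum"
  )
}

#' @export
print.brillouin_spectrum <- function(x, ...) {
  n <- length(x$intensity)
  cat(sprintf("Brillouin spectrum: %d pixels, %.4g to %.4g GHz (%.4g GHz/pixel)\n",
              n, x$frequency_ghz[1L], x$frequency_ghz[n],
              x$frequency_ghz[2L] - x$frequency_ghz[1L]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$intensity), max(x$intensity)))
  if (!is.null(x$sigma))
    cat(sprintf("  noise sigma: %.4g (mean)\n", mean(x$sigma)))
  if (!all(x$mask))
    cat(sprintf("  masked pixels: %d of %d\n", sum(!x$mask), n))
  if (!is.null(x$meta$snr))
    cat(sprintf("  meta: snr = %s, seed = %s\n",
                format(x$meta$snr), format(x$meta$seed)))
  invisible(x)
}

#' @export
plot.brillouin_spectrum <- function(x, ..., xlab = "Frequency shift (GHz)",
                                    ylab = "Intensity (counts)", type = "l") {
  graphics::plot(x$frequency_ghz, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  if (!all(x$mask))
    graphics::points(x$frequency_ghz[!x$mask], x$intensity[!x$mask],
                     col = "grey", pch = 4)
  invisible(x)
}

#' Mask a frequency range of a spectrum
#'
#' Marks all pixels whose centre frequency lies inside `[from_ghz, to_ghz]`
#' as excluded (`mask = FALSE`). Typically used to drop a saturated or
#' interferometrically suppressed Rayleigh region before reconstruction or
#' fitting.
#'
#' @param spectrum A [brillouin_spectrum()].
#' @param from_ghz,to_ghz Bounds of the range to exclude (GHz, inclusive).
#' @return The spectrum with an updated mask.
#' @export
mask_range <- function(spectrum, from_ghz, to_ghz) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"), from_ghz <= to_ghz)
  sel <- spectrum$frequency_ghz >= from_ghz & spectrum$frequency_ghz <= to_ghz
  spectrum$mask[sel] <- FALSE
  spectrum
}

# Internal: spectra are written with this header so readers can sanity-check
# the dialect.
.spectrum_format_header <- "# brillouin-spectrum v1"

#' Read a spectrum from delimited text
#'
#' The on-disk format is one row per pixel with columns
#' `pixel,frequency_ghz,intensity[,sigma][,mask]`, comma or tab delimited.
#' Lines starting with `#` are comments; an optional header line names the
#' columns. Missing `sigma` columns leave `sigma = NULL` with a warning.
#'
#' @param path Path to a CSV/TSV spectrum file.
#' @return A [brillouin_spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty spectrum: no data rows in ", path)
  delim <- if (grepl("\t", lines[[1L]])) "\t" else ","
  rows <- strsplit(lines, delim, fixed = TRUE)
  header <- NULL
  first <- trimws(rows[[1L]])
  if (any(is.na(suppressWarnings(as.numeric(first))))) {
    header <- tolower(first)
    rows <- rows[-1L]
    line_no <- line_no[-1L]
    if (length(rows) == 0L) stop("empty spectrum: no data rows in ", path)
  }
  ncol <- length(rows[[1L]])
  bad <- which(vapply(rows, length, 1L) != ncol)
  if (length(bad))
    stop("malformed row at line ", line_no[bad[1L]], " of ", path,
         ": expected ", ncol, " fields")
  mat <- matrix(NA_real_, length(rows), ncol)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(trimws(rows[[i]])))
    if (anyNA(v))
      stop("malformed row at line ", line_no[i], " of ", path,
           ": non-numeric field")
    mat[i, ] <- v
  }
  cols <- header
  if (is.null(cols)) {
    cols <- c("pixel", "frequency_ghz", "intensity", "sigma", "mask")[seq_len(ncol)]
  }
  pick <- function(name) {
    j <- match(name, cols)
    if (is.na(j)) NULL else mat[, j]
  }
  freq <- pick("frequency_ghz")
  if (is.null(freq)) freq <- mat[, 2L]
  intens <- pick("intensity")
  if (is.null(intens)) intens <- mat[, 3L]
  sigma <- pick("sigma")
  if (is.null(sigma)) warning("no sigma column in ", path, "; noise level unset")
  mask <- pick("mask")
  if (!is.null(mask)) mask <- mask != 0
  brillouin_spectrum(freq, intens, sigma = sigma, mask = mask,
                     meta = list(source = path))
}

#' Write a spectrum to delimited text
#'
#' @param spectrum A [brillouin_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_spectrum()]
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  n <- length(spectrum$intensity)
  cols <- list(pixel = seq_len(n),
               frequency_ghz = spectrum$frequency_ghz,
               intensity = spectrum$intensity)
  if (!is.null(spectrum$sigma)) cols$sigma <- spectrum$sigma
  cols$mask <- as.integer(spectrum$mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.spectrum_format_header, con)
  writeLines(paste(names(cols), collapse = ","), con)
  body <- do.call(paste, c(lapply(cols, function(v)
    formatC(v, digits = 17, format = "g")), sep = ","))
  writeLines(body, con)
  invisible(path)
}
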