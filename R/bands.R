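#' Nyquist frequency of a sampled BOLD series
#'
#' The highest frequency that can be resolved from a series sampled every
#' `tr_seconds` seconds is `1 / (2 * TR)`; at the common TR of 2 s this is
#' 0.25 Hz, the ceiling of every band table built by [n3l_band_table()].
#'
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @return Frequency in Hz.
#' @export
#' @examples
#' nyquist(2)   # 0.25
nyquist <- function(tr_seconds) {
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("'tr_seconds' must be a single positive number", call. = FALSE)
  }
  1 / (2 * tr_seconds)
}

#' Theoretical limits of a natural-logarithm (N3L) frequency band
#'
#' The N3L partition places band boundaries on a geometric ladder with ratio
#' e, so that the bands form an arithmetic progression on the log-frequency
#' axis. Band "Slow-k" spans `[exp(-(k + 0.5)) * e, exp(-(k - 1.5))]`, i.e.
#' `[exp(-(k - 0.5)), exp(-(k - 1.5))]` Hz: Slow-4 is 0.0302-0.0821 Hz and
#' Slow-5 is 0.0111-0.0302 Hz. These are unclipped values; [n3l_band_table()]
#' clips them to what a given TR and series length can support.
#'
#' @param band_index Integer k >= 2 naming band "Slow-k".
#' @return Named numeric vector `c(f_low = , f_high = )` in Hz.
#' @export
#' @examples
#' round(n3l_band_limits(4), 4)   # 0.0302 0.0821
n3l_band_limits <- function(band_index) {
  k <- band_index
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k != round(k) ||
      k < 2) {
    stop("'band_index' must be an integer >= 2 (band 'Slow-k')",
         call. = FALSE)
  }
  c(f_low = exp(-(k - 0.5)), f_high = exp(-(k - 1.5)))
}

#' Conservative lowest resolvable frequency after zero padding
#'
#' With the series zero padded to `padded_length` points the spectral grid
#' has spacing `1 / (padded_length * TR)`; the lowest frequency treated as
#' resolvable is conservatively taken as twice that spacing,
#' `1 / (padded_length * TR / 2)` (2.44e-04 Hz at TR = 2 s, 4096 points).
#'
#' @param tr_seconds Repetition time in seconds.
#' @param padded_length Length of the zero-padded series.
#' @return Frequency in Hz.
#' @export
conservative_lowest_freq <- function(tr_seconds, padded_length = 4096L) {
  stopifnot(tr_seconds > 0, padded_length >= 2)
  1 / (padded_length * tr_seconds / 2)
}

#' Default minimal reliable frequency (Hz)
#'
#' Frequencies below this are dominated by scanner drift and are excluded
#' from the band table; the default is the conventional 7.32e-04 Hz.
#' @export
MIN_RELIABLE_HZ <- 7.32e-4

#' N3L band table for a given acquisition
#'
#' Builds the ordered table of Slow-k bands supported by a series of
#' `n_timepoints` samples at repetition time `tr_seconds`, zero padded to
#' `padded_length`. Theoretical ladder boundaries ([n3l_band_limits()]) are
#' clipped to `[min_reliable_hz, nyquist]`: the top band's upper edge is cut
#' at the Nyquist frequency, the bottom band's lower edge at the minimal
#' reliable frequency, and bands falling entirely outside that range are
#' dropped. At TR = 2 s this yields seven bands, Slow-8 through Slow-2, with
#' Slow-2 spanning 0.2231-0.25 Hz.
#'
#' @param tr_seconds Repetition time in seconds.
#' @param n_timepoints Number of samples in the (unpadded) series.
#' @param padded_length Zero-padded length used for spectral analysis.
#' @param min_reliable_hz Lowest frequency considered reliable.
#' @return A data.frame with columns `name`, `band_index`, `f_low`, `f_high`,
#'   rows ordered by ascending frequency (slowest band first, Slow-2 last).
#' @export
#' @examples
#' n3l_band_table(2, 142)          # seven bands, Slow-8 ... Slow-2
n3l_band_table <- function(tr_seconds, n_timepoints,
                           padded_length = 4096L,
                           min_reliable_hz = MIN_RELIABLE_HZ) {
  if (padded_length < n_timepoints) {
    stop("'padded_length' must be >= 'n_timepoints'", call. = FALSE)
  }
  ny <- nyquist(tr_seconds)
  if (min_reliable_hz <= 0 || min_reliable_hz >= ny) {
    stop("degenerate frequency range: min_reliable_hz must lie in (0, nyquist)",
         call. = FALSE)
  }
  rows <- list()
  k <- 2L
  repeat {
    lim <- n3l_band_limits(k)
    if (lim[["f_high"]] <= min_reliable_hz) break  # entirely below range
    f_low <- max(lim[["f_low"]], min_reliable_hz)
    f_high <- min(lim[["f_high"]], ny)
    if (f_high > f_low) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("Slow-", k), band_index = k,
        f_low = f_low, f_high = f_high, stringsAsFactors = FALSE)
    }
    k <- k + 1L
  }
  out <- do.call(rbind, rev(rows))
  rownames(out) <- NULL
  out
}

#' Frequency band schemes
#'
#' A scheme is a named, ordered set of frequency bands used to build feature
#' matrices: `"Conventional"` is the single literal 0.01-0.08 Hz band,
#' `"Slow-5"` and `"Slow-4"` are the corresponding N3L bands, and
#' `"Combined"` is Slow-5 followed by Slow-4 (whose joint range approximates
#' the conventional band).
#'
#' @param label One of "Conventional", "Slow-5", "Slow-4", "Combined".
#' @return A list with `label` and `bands`, a data.frame of
#'   `name`, `f_low`, `f_high`.
#' @export
#' @examples
#' band_scheme("Combined")$bands
band_scheme <- function(label = c("Combined", "Conventional",
                                  "Slow-5", "Slow-4")) {
  label <- match.arg(label)
  slow5 <- n3l_band_limits(5)
  slow4 <- n3l_band_limits(4)
  bands <- switch(label,
    "Conventional" = data.frame(name = "Conventional",
                                f_low = 0.01, f_high = 0.08),
    "Slow-5" = data.frame(name = "Slow-5",
                          f_low = slow5[["f_low"]], f_high = slow5[["f_high"]]),
    "Slow-4" = data.frame(name = "Slow-4",
                          f_low = slow4[["f_low"]], f_high = slow4[["f_high"]]),
    "Combined" = data.frame(
      name = c("Slow-5", "Slow-4"),
      f_low = c(slow5[["f_low"]], slow4[["f_low"]]),
      f_high = c(slow5[["f_high"]], slow4[["f_high"]]))
  )
  structure(list(label = label, bands = bands), class = "band_scheme")
}

#' Resolve a band name to its frequency limits
#'
#' Accepts "Slow-k" names (theoretical N3L limits) and "Conventional"
#' (0.01-0.08 Hz).
#' @param band_name Character band name.
#' @return Named numeric `c(f_low, f_high)` in Hz.
#' @export
resolve_band <- function(band_name) {
  if (identical(band_name, "Conventional")) {
    return(c(f_low = 0.01, f_high = 0.08))
  }
  m <- regmatches(band_name, regexec("^Slow-([0-9]+)$", band_name))[[1]]
  if (length(m) != 2L) {
    stop("unresolvable band name: ", band_name, call. = FALSE)
  }
  n3l_band_limits(as.integer(m[2]))
}

## Index of spectral bins kept by the ideal mask for [f_low, f_high).
## Half-open at the top so adjacent bands stay disjoint on the grid, except
## that a band whose upper edge reaches Nyquist is closed there. DC (k = 0)
## is never kept. Returns indices into 0:(padded_length/2) bin numbering.
band_bins <- function(f_low, f_high, tr_seconds, padded_length) {
  ny <- nyquist(tr_seconds)
  df <- 1 / (padded_length * tr_seconds)
  kmax <- floor(padded_length / 2)
  k <- seq_len(kmax)             # skip DC
  f <- k * df
  keep <- f >= f_low & (f < f_high | (f_high >= ny - 1e-12 & f <= ny + 1e-12))
  k[keep]
}

#' Ideal-mask band-pass filter via zero-padded Fourier transform
#'
#' Zero pads the series to `padded_length`, takes the discrete Fourier
#' transform, zeroes every coefficient whose frequency lies outside
#' `[f_low, f_high)` (a rectangular mask, conjugate-symmetric so the output
#' is real; DC is always removed; a band reaching Nyquist keeps the Nyquist
#' bin), inverse transforms and truncates back to the input length. The
#' series mean is removed before padding — once zeros are appended the mean
#' no longer lives solely in the DC bin, and demeaning keeps a constant
#' input mapping to (exactly) zero. No taper is applied, so some edge
#' ringing is expected and analyses sensitive to it should trim edges;
#' at `padded_length = length(x)` the filter is an exact orthogonal
#' projection (idempotent to machine precision).
#'
#' @param x Numeric series.
#' @param f_low,f_high Band limits in Hz.
#' @param tr_seconds Repetition time in seconds.
#' @param padded_length Zero-padded transform length (>= length(x)).
#' @return Filtered numeric series, same length as `x`.
#' @export
bandpass <- function(x, f_low, f_high, tr_seconds, padded_length = 4096L) {
  if (!all(is.finite(x))) stop("non-finite values in input series",
                               call. = FALSE)
  n <- length(x)
  if (padded_length < n) stop("'padded_length' must be >= length(x)",
                              call. = FALSE)
  ny <- nyquist(tr_seconds)
  if (!(f_low >= 0 && f_low < f_high && f_low < ny)) {
    stop("band must satisfy 0 <= f_low < f_high and f_low < nyquist",
         call. = FALSE)
  }
  keep <- band_bins(f_low, f_high, tr_seconds, padded_length)
  if (length(keep) == 0L) {
    stop("band [", f_low, ", ", f_high, ") contains no frequency bins ",
         "at this padding", call. = FALSE)
  }
  xp <- c(x - mean(x), rep(0, padded_length - n))
  X <- stats::fft(xp)
  mask <- rep(0, padded_length)
  mask[keep + 1L] <- 1                      # positive frequencies
  mask[padded_length - keep + 1L] <- 1      # conjugate mirror
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / padded_length
  y[seq_len(n)]
}

#' Spectral decomposition of a zero-padded series
#'
#' Expresses the zero-padded series as
#' `x(t) = sum_k a_k cos(2 pi f_k t) + b_k sin(2 pi f_k t)` on the padded
#' frequency grid `f_k = k / (padded_length * TR)`, k = 0..padded_length/2.
#' The amplitude envelope `sqrt(a_k^2 + b_k^2)` is the quantity summed by
#' [alff()].
#'
#' @inheritParams bandpass
#' @return List of class `spectral_decomposition` with `frequencies`, `a`
#'   (cosine amplitudes), `b` (sine amplitudes), `padded_length`,
#'   `tr_seconds`, `n_original`.
#' @export
spectrum_decomposition <- function(x, tr_seconds, padded_length = 4096L) {
  if (!all(is.finite(x))) stop("non-finite values in input series",
                               call. = FALSE)
  n <- length(x)
  if (padded_length < n) stop("'padded_length' must be >= length(x)",
                              call. = FALSE)
  M <- as.integer(padded_length)
  xp <- c(x, rep(0, M - n))
  X <- stats::fft(xp)
  kmax <- floor(M / 2)
  k <- 0:kmax
  a <- 2 * Re(X[k + 1L]) / M
  b <- -2 * Im(X[k + 1L]) / M
  a[1] <- a[1] / 2                       # DC has no mirror
  if (M %% 2L == 0L) a[kmax + 1L] <- a[kmax + 1L] / 2  # Nyquist bin likewise
  structure(list(frequencies = k / (M * tr_seconds), a = a, b = b,
                 padded_length = M, tr_seconds = tr_seconds, n_original = n),
            class = "spectral_decomposition")
}

#' Write a band table to TSV
#'
#' @param bands Data.frame with `name`, `f_low`, `f_high` (as produced by
#'   [n3l_band_table()] or `band_scheme()$bands`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_band_table <- function(bands, path) {
  utils::write.table(bands[, c("name", "f_low", "f_high")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
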