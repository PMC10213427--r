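# Independent brute-force oracles. Deliberately naive: direct sums, no FFT,
# so they share no code path with the implementation they check.

# O(M*N) discrete Fourier coefficients of x zero-padded to M:
# a_k, b_k such that x(n) = sum_k a_k cos(2 pi k n / M) + b_k sin(...).
dft_oracle <- function(x, M) {
  n <- seq_along(x) - 1L
  kmax <- floor(M / 2)
  a <- b <- numeric(kmax + 1L)
  for (k in 0:kmax) {
    c_ <- sum(x * cos(2 * pi * k * n / M))
    s_ <- sum(x * sin(2 * pi * k * n / M))
    scale <- if (k == 0L || (M %% 2L == 0L && k == kmax)) 1 else 2
    a[k + 1L] <- scale * c_ / M
    b[k + 1L] <- scale * s_ / M
  }
  list(a = a, b = b)
}

# Band-pass oracle: reconstruct from the oracle coefficients, keeping only
# bins with f in [f_low, f_high) (closed at nyquist), DC dropped.
bandpass_oracle <- function(x, f_low, f_high, tr, M) {
  co <- dft_oracle(x, M)
  kmax <- floor(M / 2)
  f <- (0:kmax) / (M * tr)
  ny <- 1 / (2 * tr)
  keep <- f >= f_low & (f < f_high | (f_high >= ny - 1e-12 & f <= ny + 1e-12))
  keep[1] <- FALSE
  n <- seq_along(x) - 1L
  out <- numeric(length(x))
  for (k in which(keep) - 1L) {
    out <- out + co$a[k + 1L] * cos(2 * pi * k * n / M) +
      co$b[k + 1L] * sin(2 * pi * k * n / M)
  }
  out
}

# Per-window Pearson correlation from raw sums (no stats::cor).
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

swc_oracle <- function(x, y, width, step) {
  starts <- seq(1L, length(x) - width + 1L, by = step)
  vapply(starts, function(t0) {
    pearson_oracle(x[t0:(t0 + width - 1L)], y[t0:(t0 + width - 1L)])
  }, numeric(1))
}

# Small cohort used across tests: one fALFF effect and one dFC effect.
tiny_cohort <- function(seed = 11L, noise_sd = 0.3) {
  generate_cohort(cohort_spec(
    n_per_group = 8L, n_rois = 6L, n_timepoints = 100L, tr_seconds = 2,
    falff_effects = list(list(roi = 2L, band = "Slow-4", multiplier = 2.5)),
    dfc_effects = list(list(roi_a = 4L, roi_b = 5L, band = "Slow-5",
                            case_correlation = 0.8,
                            control_correlation = 0.0)),
    noise_sd = noise_sd, seed = seed))
}
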