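# Independent oracles and small builders used across the suite.

# Closed-form Morlet evaluation, coded independently of morlet_wavelet():
# A * exp(-t^2 / (2 sigma^2)) * (cos(2 pi f t) + i sin(2 pi f t)) on the
# same +/- 5 sigma grid.
oracle_wavelet <- function(f, cycles, fs, normalization = "amplitude") {
  sigma <- cycles / (2 * pi * f)
  A <- switch(normalization,
              none = 1,
              amplitude = 1 / (2 * pi * sigma),
              power = 2 / (pi * sigma))
  half <- ceiling(5 * sigma * fs)
  t <- (-half:half) / fs
  A * exp(-t^2 / (2 * sigma^2)) * (cos(2 * pi * f * t) +
                                     1i * sin(2 * pi * f * t))
}

# Direct (time-domain) centre-aligned convolution with every bank wavelet,
# scaled by dt; the independent check on the FFT-based cwt_trace().
direct_cwt <- function(trace, bank) {
  n <- length(trace)
  out <- matrix(0i, length(bank$frequencies), n)
  for (k in seq_along(bank$wavelets)) {
    w <- unclass(bank$wavelets[[k]])
    m <- length(w)
    half <- (m - 1) / 2
    acc <- rep(0i, n)
    for (l in seq_len(m)) {
      idx <- seq_len(n) + half - l + 1
      ok <- idx >= 1 & idx <= n
      acc[ok] <- acc[ok] + w[l] * trace[idx[ok]]
    }
    out[k, ] <- acc / bank$fs
  }
  out
}

# Epochs holding externally supplied traces (trials x channels list of rows).
epochs_from_traces <- function(traces, fs, onset_ms = 0) {
  if (is.numeric(traces)) traces <- list(traces)
  n <- length(traces[[1]])
  data <- array(0, c(length(traces), 1L, n))
  for (i in seq_along(traces)) data[i, 1, ] <- traces[[i]]
  eeg_epochs(data, fs = fs, onset_ms = onset_ms)
}

# Interior sample index range (outside both edge-distorted zones).
interior_of <- function(bank, n) {
  half <- max((lengths(bank$wavelets) - 1L) %/% 2L)
  seq.int(half + 1L, n - half)
}

# Indices selected by a window under the documented rule: endpoints snap to
# the nearest grid point, inclusive.
snap_idx <- function(axis, a, b) {
  seq(which.min(abs(axis - a)), which.min(abs(axis - b)))
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- max(abs(expected))
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
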