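# Complex Morlet wavelet banks.
#
# A Morlet wavelet is a complex sinusoid at centre frequency f enveloped by a
# Gaussian with temporal standard deviation sigma_t = cycles / (2*pi*f).  The
# bank holds one wavelet per analysis frequency, all sharing the same cycle
# count, discretized at the signal sampling rate.

#' Temporal standard deviation of a Morlet wavelet envelope
#'
#' For a complex Morlet wavelet of centre frequency `frequency` whose duration
#' is `cycles` periods of that frequency, the Gaussian envelope has standard
#' deviation `cycles / (2 * pi * frequency)` seconds.
#'
#' @param frequency Centre frequency in Hz (> 0).
#' @param cycles Wavelet duration in cycles of the centre frequency (> 0).
#'   Defaults to 7, the convention of the infant time-frequency literature
#'   this package follows.
#' @return Envelope standard deviation in seconds.
#' @export
#' @examples
#' wavelet_sigma(10)            # 7 / (2 * pi * 10) ~ 0.111 s
wavelet_sigma <- function(frequency, cycles = 7) {
  check_positive(frequency, "frequency")
  check_positive(cycles, "cycles")
  cycles / (2 * pi * frequency)
}

#' Temporal resolution (FWHM) of a Morlet wavelet
#'
#' Full Width at Half Maximum of the Gaussian envelope,
#' `2 * sqrt(2 * log(2)) * sigma_t`.  Plotting this against frequency shows
#' the effective temporal smoothing of the transform and suggests the minimum
#' padding needed before transformation (see [recommend_padding()]).
#'
#' @inheritParams wavelet_sigma
#' @return FWHM in seconds.
#' @seealso [recommend_padding()], [bank_summary()]
#' @export
#' @examples
#' wavelet_fwhm(10)   # ~ 0.262 s
wavelet_fwhm <- function(frequency, cycles = 7) {
  2 * sqrt(2 * log(2)) * wavelet_sigma(frequency, cycles)
}

#' Recommended per-edge signal padding before wavelet transformation
#'
#' Convolution distorts coefficients near segment edges, the more so the lower
#' the frequency (wider the wavelet).  The minimally necessary extra signal at
#' each edge is estimated as `2000 / min_frequency` milliseconds; e.g. for a
#' frequency range starting at 5 Hz, 400 ms of extra signal should be present
#' (or added, see [pad_edges()]) at both edges and chopped after the transform.
#'
#' @param min_frequency Lowest analysis frequency in Hz (> 0).
#' @return Padding per edge in milliseconds.
#' @export
#' @examples
#' recommend_padding(5)    # 400 ms
#' recommend_padding(10)   # 200 ms
recommend_padding <- function(min_frequency) {
  check_positive(min_frequency, "min_frequency")
  2000 / min_frequency
}

# Normalization factor A for a given envelope sd and mode.
#
# amplitude: A = 1 / (2 * pi * sigma_t); power: A = 2 / (pi * sigma_t).
# Both scale as 1/sigma_t, which makes the transform's response to a
# unit-amplitude sinusoid identical at every analysis frequency -- the
# property that permits direct quantitative comparison of frequency content
# across frequencies.  "none" (A = 1) is kept for back-compatibility with
# unnormalized pipelines.
wavelet_norm_factor <- function(sigma_t, normalization) {
  switch(normalization,
    none = 1,
    amplitude = 1 / (2 * pi * sigma_t),
    power = 2 / (pi * sigma_t),
    stop("unknown normalization: ", normalization, call. = FALSE)
  )
}

#' Construct a single complex Morlet wavelet
#'
#' Samples `A * exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * frequency * t)` on
#' a symmetric time grid with spacing `1 / fs`, truncated at `+/- 5 sigma_t`
#' (rounded outward to a whole sample, so the envelope at the edges is below
#' `4e-6` and the truncated wavelet keeps a near-zero sum, preserving the
#' signal's power spectrum).  The grid contains a sample exactly at t = 0, so the length
#' is odd and the value at the centre equals the normalization factor A.
#'
#' @inheritParams wavelet_sigma
#' @param fs Sampling rate in Hz at which the wavelet is discretized; must
#'   match the signal it will be convolved with, and `frequency` must lie
#'   strictly below `fs / 2` (Nyquist).
#' @param normalization One of `"amplitude"` (A = `1 / (2 * pi * sigma_t)`,
#'   for amplitude output), `"power"` (A = `2 / (pi * sigma_t)`, for power
#'   output) or `"none"` (A = 1, unnormalized).
#' @return Complex vector of odd length; attributes `time_s` (the grid),
#'   `sigma_t`, `fwhm` and `norm_factor`.
#' @export
#' @examples
#' w <- morlet_wavelet(10, cycles = 7, fs = 500, normalization = "none")
#' w[(length(w) + 1) / 2]    # 1 + 0i at t = 0
#' Mod(sum(w))               # ~ 0: zero-mean, leaves the power spectrum flat
morlet_wavelet <- function(frequency, cycles = 7, fs,
                           normalization = c("amplitude", "power", "none")) {
  normalization <- match.arg(normalization)
  check_positive(frequency, "frequency")
  check_positive(cycles, "cycles")
  check_positive(fs, "fs")
  if (frequency >= fs / 2) {
    stop(sprintf("`frequency` (%g Hz) must be strictly below Nyquist (fs/2 = %g Hz)",
                 frequency, fs / 2), call. = FALSE)
  }
  sigma_t <- cycles / (2 * pi * frequency)
  A <- wavelet_norm_factor(sigma_t, normalization)
  half <- ceiling(5 * sigma_t * fs)
  t <- seq.int(-half, half) / fs
  w <- A * exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * frequency * t)
  structure(w, time_s = t, sigma_t = sigma_t,
            fwhm = 2 * sqrt(2 * log(2)) * sigma_t, norm_factor = A)
}

#' Build a bank of complex Morlet wavelets
#'
#' One wavelet per analysis frequency, all with the same cycle count and
#' normalization mode, discretized at the signal sampling rate.  The default
#' analysis of this package uses frequencies 10 to 90 Hz in 1 Hz steps with 7
#' cycles and amplitude normalization.
#'
#' @param frequencies Strictly increasing vector of centre frequencies in Hz,
#'   all strictly below `fs / 2`.
#' @inheritParams morlet_wavelet
#' @return A `wavelet_bank` object: list with `frequencies`, `cycles`, `fs`,
#'   `normalization`, `sigma_t` (s), `fwhm` (s) and `wavelets` (list of
#'   complex vectors as returned by [morlet_wavelet()]).
#' @export
#' @examples
#' bank <- wavelet_bank(10:90, cycles = 7, fs = 500)
#' length(bank$wavelets)   # 81
wavelet_bank <- function(frequencies, cycles = 7, fs,
                         normalization = c("amplitude", "power", "none")) {
  normalization <- match.arg(normalization)
  if (length(frequencies) == 0) {
    stop("`frequencies` must contain at least one frequency", call. = FALSE)
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("`frequencies` must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("`frequencies` must be strictly increasing", call. = FALSE)
  }
  wavelets <- lapply(frequencies, morlet_wavelet, cycles = cycles, fs = fs,
                     normalization = normalization)
  structure(
    list(
      frequencies = as.numeric(frequencies),
      cycles = cycles,
      fs = fs,
      normalization = normalization,
      sigma_t = cycles / (2 * pi * as.numeric(frequencies)),
      fwhm = 2 * sqrt(2 * log(2)) * cycles / (2 * pi * as.numeric(frequencies)),
      wavelets = wavelets
    ),
    class = "wavelet_bank"
  )
}

#' Summarize a wavelet bank
#'
#' Per-frequency temporal resolution diagnostics: envelope standard deviation,
#' FWHM and discretized support length.  Useful for choosing padding and for
#' the FWHM-versus-frequency diagnostic plot.
#'
#' @param bank A [wavelet_bank()].
#' @return `data.frame` with columns `frequency_hz`, `sigma_t_s`, `fwhm_ms`,
#'   `length_samples`.
#' @export
bank_summary <- function(bank) {
  stopifnot(inherits(bank, "wavelet_bank"))
  data.frame(
    frequency_hz = bank$frequencies,
    sigma_t_s = bank$sigma_t,
    fwhm_ms = bank$fwhm * 1000,
    length_samples = lengths(bank$wavelets)
  )
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf(
    "<wavelet_bank> %d complex Morlet wavelets, %g-%g Hz, %g cycles, fs = %g Hz, normalization = %s\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$cycles, x$fs, x$normalization))
  invisible(x)
}

#' @export
format.wavelet_bank <- function(x, ...) {
  sprintf("wavelet_bank(%g-%g Hz, %g cycles, fs %g, %s)",
          min(x$frequencies), max(x$frequencies), x$cycles, x$fs,
          x$normalization)
}

# Per-frequency half support length in samples: coefficients closer than this
# to a segment edge are contaminated by the convolution boundary.
bank_half_lengths <- function(bank) {
  (lengths(bank$wavelets) - 1L) %/% 2L
}

#' Edge-distortion extent of a bank
#'
#' Milliseconds at each segment edge whose transform coefficients are
#' contaminated by convolution boundary effects (half the wavelet support of
#' the widest, i.e. lowest-frequency, wavelet).  These samples should be
#' removed with [chop_edges()] or compensated with [pad_edges()].
#'
#' @param bank A [wavelet_bank()].
#' @return Milliseconds per edge (scalar).
#' @export
edge_distortion_ms <- function(bank) {
  max(bank_half_lengths(bank)) / bank$fs * 1000
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
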