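# Continuous wavelet transform of epoched EEG and trial averaging.
#
# Coefficients are the discrete convolution of the DC-removed trace with each
# bank wavelet, centre-aligned so the output shares the input time axis, and
# scaled by dt = 1/fs (Riemann approximation of the continuous convolution, so
# results do not depend on the sampling rate).  Convolution is computed in the
# frequency domain; a direct time-domain implementation serves as the
# independent oracle in the test-suite.

# Precompute zero-padded wavelet spectra for traces of length n.
cwt_plan <- function(bank, n) {
  lens <- lengths(bank$wavelets)
  if (n <= max(lens)) {
    f_bad <- bank$frequencies[which.max(lens)]
    stop(sprintf(
      "signal too short: %d samples, but the %g Hz wavelet spans %d samples",
      n, f_bad, max(lens)), call. = FALSE)
  }
  nfft <- stats::nextn(n + max(lens) - 1L, c(2L, 3L, 5L))
  W <- vapply(bank$wavelets, function(w) {
    stats::fft(c(unclass(w), complex(nfft - length(w))))
  }, complex(nfft))
  list(nfft = nfft, W = W, half = (lens - 1L) %/% 2L, n = n,
       dt = 1 / bank$fs)
}

# Frequency x time complex coefficient matrix for one trace under a plan.
cwt_apply <- function(trace, plan) {
  S <- stats::fft(c(trace, numeric(plan$nfft - plan$n)))
  full <- stats::mvfft(plan$W * S, inverse = TRUE) / plan$nfft
  nf <- ncol(plan$W)
  out <- matrix(0i, nf, plan$n)
  for (j in seq_len(nf)) {
    out[j, ] <- full[plan$half[j] + seq_len(plan$n), j]
  }
  out * plan$dt
}

#' Continuous wavelet transform of a single trace
#'
#' Convolves one signal trace with every wavelet of the bank.  The output is
#' centre-aligned and of the same length as the input, so it shares the input
#' time axis; samples within half a wavelet support of either edge are
#' distorted by the convolution boundary (see [edge_distortion_ms()]) and are
#' expected to be removed by [chop_edges()].
#'
#' @param trace Numeric vector, longer than the longest wavelet of the bank.
#' @param bank A [wavelet_bank()] discretized at the trace's sampling rate.
#' @return Complex matrix, frequencies x time.
#' @export
#' @examples
#' bank <- wavelet_bank(c(10, 20), fs = 250)
#' x <- cos(2 * pi * 10 * seq(0, 2, by = 1 / 250))
#' dim(cwt_trace(x, bank))
cwt_trace <- function(trace, bank) {
  stopifnot(inherits(bank, "wavelet_bank"))
  if (!is.numeric(trace)) stop("`trace` must be numeric", call. = FALSE)
  cwt_apply(trace, cwt_plan(bank, length(trace)))
}

apply_measure <- function(coef, measure) {
  switch(measure,
    complex = coef,
    amplitude = Mod(coef),
    power = Mod(coef)^2,
    stop("unknown measure: ", measure, call. = FALSE))
}

resolve_trials <- function(epochs, trials) {
  nt <- n_trials(epochs)
  if (is.null(trials)) return(seq_len(nt))
  trials <- as.integer(trials)
  if (length(trials) == 0L) {
    stop("`trials` must select at least one trial", call. = FALSE)
  }
  if (anyNA(trials) || any(trials < 1L) || any(trials > nt)) {
    stop(sprintf("`trials` must be indices in 1..%d", nt), call. = FALSE)
  }
  trials
}

new_tf_result <- function(values, measure, bank, epochs, n_avg, sem = NULL) {
  structure(
    list(values = values,
         measure = measure,
         frequencies = bank$frequencies,
         time_ms = epochs$time_ms,
         channels = epochs$channels,
         n_trials_averaged = n_avg,
         baseline = NULL,
         chopped_ms = 0,
         edge_ms = edge_distortion_ms(bank),
         cycles = bank$cycles,
         normalization = bank$normalization,
         condition = epochs$condition,
         subject = epochs$subject,
         sem = sem),
    class = "tf_result")
}

#' Time-frequency transform of epoched EEG
#'
#' The workhorse of the package.  Each selected trial and channel is
#' DC-removed and convolved with every wavelet of the bank; the complex
#' coefficients are turned into the requested measure and averaged over
#' trials:
#'
#' * `mode = "induced"` (total-induced oscillations, the default): the
#'   measure is taken per trial *before* averaging, so activity that is not
#'   phase-locked to stimulus onset is preserved.
#' * `mode = "evoked"`: trials are averaged first (the ERP), the average is
#'   DC-removed and transformed once; non-phase-locked activity cancels in
#'   the ERP and is lost.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param bank A [wavelet_bank()] built at the same sampling rate.
#' @param measure `"amplitude"` (modulus of the complex coefficients, the
#'   default and the measure in signal units), `"power"` (squared modulus) or
#'   `"complex"` (raw coefficients retained, giving direct access to phase;
#'   baseline correction and dB conversion refuse complex results).
#' @param mode `"induced"` or `"evoked"`.
#' @param trials Optional trial index subset (`mode = "induced"` only); a
#'   single index gives single-trial frequency extraction.
#' @param keep_sem If `TRUE` (induced amplitude/power only, > 1 trial), also
#'   store the standard error of the mean across trials as a sibling tensor
#'   `sem` with the same dimensions, backing the SEM-relative-to-baseline
#'   display of [plot_tf()].
#' @return A `tf_result`: channel x frequency x time array `values` plus axes
#'   (`frequencies` Hz, `time_ms`), `measure`, `n_trials_averaged`, baseline
#'   and chopping provenance.
#' @export
#' @examples
#' ep <- simulate_epochs(4, 2, fs = 250, window_ms = c(-200, 800),
#'                       bursts = burst_spec(20, 300), seed = 1)
#' bank <- wavelet_bank(seq(10, 40, 2), fs = 250)
#' res <- tf_transform(ep, bank)
#' dim(res$values)    # 2 channels x 16 frequencies x 251 samples
tf_transform <- function(epochs, bank,
                         measure = c("amplitude", "power", "complex"),
                         mode = c("induced", "evoked"),
                         trials = NULL, keep_sem = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(bank, "wavelet_bank"))
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  if (abs(bank$fs - epochs$fs) > 1e-9) {
    stop(sprintf("bank fs (%g) does not match epochs fs (%g)",
                 bank$fs, epochs$fs), call. = FALSE)
  }
  if (mode == "evoked") {
    if (!is.null(trials)) {
      stop("`trials` subsetting applies to induced mode only", call. = FALSE)
    }
    return(tf_evoked(epochs, bank, measure))
  }
  idx <- resolve_trials(epochs, trials)
  plan <- cwt_plan(bank, n_samples(epochs))
  nc <- n_channels(epochs)
  nf <- length(bank$frequencies)
  nt <- n_samples(epochs)
  cplx <- measure == "complex"
  acc <- array(if (cplx) 0i else 0, c(nc, nf, nt))
  acc2 <- if (keep_sem && !cplx && length(idx) > 1L) array(0, c(nc, nf, nt))
  dc <- remove_dc(epochs)
  for (tr in idx) {
    for (ch in seq_len(nc)) {
      x <- apply_measure(cwt_apply(dc$data[tr, ch, ], plan), measure)
      acc[ch, , ] <- acc[ch, , ] + x
      if (!is.null(acc2)) acc2[ch, , ] <- acc2[ch, , ] + x^2
    }
  }
  nn <- length(idx)
  values <- acc / nn
  sem <- NULL
  if (!is.null(acc2)) {
    v <- pmax(acc2 / nn - (acc / nn)^2, 0) * nn / (nn - 1)
    sem <- sqrt(v / nn)
  }
  new_tf_result(values, measure, bank, epochs, nn, sem)
}

tf_evoked <- function(epochs, bank, measure) {
  plan <- cwt_plan(bank, n_samples(epochs))
  nc <- n_channels(epochs)
  erp <- colMeans(epochs$data, dims = 1)     # channels x samples
  values <- array(if (measure == "complex") 0i else 0,
                  c(nc, length(bank$frequencies), n_samples(epochs)))
  for (ch in seq_len(nc)) {
    trace <- erp[ch, ] - mean(erp[ch, ])
    values[ch, , ] <- apply_measure(cwt_apply(trace, plan), measure)
  }
  new_tf_result(values, measure, bank, epochs, n_trials(epochs))
}

#' @export
print.tf_result <- function(x, ...) {
  d <- dim(x$values)
  bl <- if (is.null(x$baseline)) "none" else x$baseline$mode
  cat(sprintf(
    "<tf_result> %d channels x %d frequencies x %d samples (%s)\n",
    d[1], d[2], d[3], x$measure))
  cat(sprintf("  %g-%g Hz, %g..%g ms, %d trial(s) averaged, baseline %s, chopped %g ms/edge\n",
              min(x$frequencies), max(x$frequencies),
              x$time_ms[1], x$time_ms[d[3]], x$n_trials_averaged, bl,
              x$chopped_ms))
  cat(sprintf("  %s / %s\n", x$subject, x$condition))
  invisible(x)
}

tf_fs <- function(result) {
  if (length(result$time_ms) < 2L) stop("degenerate time axis", call. = FALSE)
  1000 / (result$time_ms[2] - result$time_ms[1])
}
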