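# Post-transform adjustments: edge chopping, baseline correction, dB
# conversion and channel-subset averaging.

snap_index <- function(axis, value) {
  i <- which.min(abs(axis - value))
  i[1]
}

snap_window <- function(axis, window, what) {
  if (length(window) != 2L || !is.numeric(window) || any(!is.finite(window))) {
    stop(sprintf("`%s` must be a numeric vector c(start, end)", what),
         call. = FALSE)
  }
  if (window[1] >= window[2]) {
    stop(sprintf("`%s` start must be below its end", what), call. = FALSE)
  }
  lo <- min(axis); hi <- max(axis)
  if (window[2] < lo || window[1] > hi) {
    stop(sprintf("`%s` [%g, %g] lies outside the axis range [%g, %g]",
                 what, window[1], window[2], lo, hi), call. = FALSE)
  }
  i <- snap_index(axis, window[1])
  j <- snap_index(axis, window[2])
  if (j < i) { k <- i; i <- j; j <- k }
  seq.int(i, j)
}

#' Baseline specification
#'
#' @param mode `"none"`, `"subtractive"` (per channel and frequency, subtract
#'   the mean over the baseline window from the whole time course — the
#'   default analysis of this package, analogous to ERP baseline correction),
#'   `"subtractive_normalized"` (relative change `(value - b) / b`) or
#'   `"divisive"` (`value / b`, the multiplicative model used by several
#'   other time-frequency pipelines).
#' @param window Baseline window `c(start_ms, end_ms)`; endpoints snap to the
#'   nearest sample and are inclusive.  `NULL` (default) means the full
#'   pre-stimulus portion of the time axis.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(mode = c("subtractive", "subtractive_normalized",
                                   "divisive", "none"),
                          window = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, window = window), class = "baseline_spec")
}

#' Chop convolution-distorted edges from a time-frequency result
#'
#' Removes `per_edge_ms` from each end of the time axis (rounded to whole
#' samples), discarding the samples distorted by the convolution boundary.
#' E.g. epochs spanning -500..1500 ms chopped by 300 ms per edge leave
#' 1400 ms segments spanning -200..1200 ms.
#'
#' @param result A `tf_result` from [tf_transform()] (chopping an
#'   [eeg_epochs()] object before transformation is also supported).
#' @param per_edge_ms Milliseconds to remove per edge; twice this must be
#'   smaller than the segment duration.
#' @return The input with a shortened time axis; `chopped_ms` (or, for
#'   epochs, the time axis alone) records the removal.
#' @export
chop_edges <- function(result, per_edge_ms) {
  UseMethod("chop_edges")
}

chop_index <- function(time_ms, fs, per_edge_ms) {
  if (!is.numeric(per_edge_ms) || length(per_edge_ms) != 1L ||
      !is.finite(per_edge_ms) || per_edge_ms < 0) {
    stop("`per_edge_ms` must be a single non-negative number", call. = FALSE)
  }
  n <- length(time_ms)
  span <- time_ms[n] - time_ms[1]
  if (2 * per_edge_ms >= span && per_edge_ms > 0) {
    stop(sprintf(
      "cannot chop %g ms per edge from a %g ms segment", per_edge_ms, span),
      call. = FALSE)
  }
  k <- as.integer(round(per_edge_ms * fs / 1000))
  if (k == 0L) seq_len(n) else seq.int(k + 1L, n - k)
}

#' @export
chop_edges.tf_result <- function(result, per_edge_ms) {
  keep <- chop_index(result$time_ms, tf_fs(result), per_edge_ms)
  result$values <- result$values[, , keep, drop = FALSE]
  if (!is.null(result$sem)) result$sem <- result$sem[, , keep, drop = FALSE]
  result$time_ms <- result$time_ms[keep]
  result$chopped_ms <- result$chopped_ms + per_edge_ms
  result
}

#' @export
chop_edges.eeg_epochs <- function(result, per_edge_ms) {
  keep <- chop_index(result$time_ms, result$fs, per_edge_ms)
  result$data <- result$data[, , keep, drop = FALSE]
  result$time_ms <- result$time_ms[keep]
  result
}

#' Baseline-correct a time-frequency result
#'
#' There is no common baseline across frequencies: for every channel and
#' every frequency, the mean `b` over the baseline window is computed from
#' that (channel, frequency) time course alone and applied to the whole
#' course:
#'
#' * subtractive: `value - b` (spectrograms read like baseline-corrected
#'   ERPs; appropriate under an additive signal model),
#' * subtractive_normalized: `(value - b) / b` (relative change),
#' * divisive: `value / b` (multiplicative model).
#'
#' @param result A `tf_result` with measure `"amplitude"` or `"power"`
#'   (complex results are refused — take a measure first).
#' @param spec A [baseline_spec()], or one of its mode strings.
#' @param window Convenience override of the baseline window.
#' @return Corrected `tf_result`; `baseline` records mode and the snapped
#'   window.
#' @export
#' @examples
#' ep <- simulate_epochs(3, 1, fs = 250, window_ms = c(-200, 800),
#'                       bursts = burst_spec(20, 300), seed = 2)
#' res <- tf_transform(ep, wavelet_bank(c(15, 20, 25), fs = 250))
#' res <- chop_edges(res, 100)
#' res <- baseline_correct(res, "subtractive")   # window = full pre-stimulus
baseline_correct <- function(result, spec = baseline_spec(), window = NULL) {
  stopifnot(inherits(result, "tf_result"))
  if (is.character(spec)) spec <- baseline_spec(spec, window)
  if (!is.null(window)) spec$window <- window
  if (spec$mode == "none") return(result)
  if (!result$measure %in% c("amplitude", "power")) {
    stop(sprintf(
      "baseline correction needs an amplitude or power result, not %s",
      result$measure), call. = FALSE)
  }
  win <- spec$window
  if (is.null(win)) {
    if (result$time_ms[1] >= 0) {
      stop("no pre-stimulus interval to use as default baseline window",
           call. = FALSE)
    }
    win <- c(result$time_ms[1], 0)
  }
  idx <- snap_window(result$time_ms, win, "baseline window")
  b <- rowMeans(result$values[, , idx, drop = FALSE], dims = 2)
  if (spec$mode %in% c("divisive", "subtractive_normalized") && any(b == 0)) {
    stop("degenerate baseline: zero baseline mean for at least one (channel, frequency)",
         call. = FALSE)
  }
  bb <- as.vector(b)   # recycles over the time dimension
  result$values <- switch(spec$mode,
    subtractive = result$values - bb,
    subtractive_normalized = (result$values - bb) / bb,
    divisive = result$values / bb)
  result$baseline <- list(mode = spec$mode,
                          window_ms = range(result$time_ms[idx]))
  result
}

#' Convert a time-frequency result to decibels
#'
#' `20 * log10` for amplitude and `10 * log10` for power, so the same
#' underlying signal maps to the same dB value under either measure.  All
#' values must be positive; for baseline-relative dB apply a divisive
#' baseline first.
#'
#' @param result A `tf_result` with measure `"amplitude"` or `"power"`.
#' @return The result with `measure = "dB"` (`db_of` records the source
#'   measure).
#' @export
to_db <- function(result) {
  stopifnot(inherits(result, "tf_result"))
  if (!result$measure %in% c("amplitude", "power")) {
    stop(sprintf("dB conversion needs an amplitude or power result, not %s",
                 result$measure), call. = FALSE)
  }
  if (any(result$values <= 0)) {
    stop(paste("dB conversion needs strictly positive values;",
               "apply a divisive baseline correction first"), call. = FALSE)
  }
  fac <- if (result$measure == "amplitude") 20 else 10
  result$db_of <- result$measure
  result$values <- fac * log10(result$values)
  result$measure <- "dB"
  result
}

#' Average a time-frequency result over a subset of channels
#'
#' Unweighted mean over the named channels, yielding a single-channel result
#' labelled with the subset.  Useful when an effect is expected over a scalp
#' region, e.g. the frontal cluster Fp1/Fpz/Fp2.
#'
#' @param result A `tf_result`.
#' @param channels Non-empty character vector of channel labels, all present
#'   in the result.
#' @return Single-channel `tf_result`; `channel_group` records the members.
#' @export
average_channels <- function(result, channels) {
  stopifnot(inherits(result, "tf_result"))
  if (length(channels) == 0) {
    stop("`channels` must name at least one channel", call. = FALSE)
  }
  idx <- match(channels, result$channels)
  if (anyNA(idx)) {
    stop("unknown channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  d <- dim(result$values)
  avg <- colMeans(result$values[idx, , , drop = FALSE], dims = 1)
  result$values <- array(avg, c(1L, d[2], d[3]))
  if (!is.null(result$sem)) {
    result$sem <- array(colMeans(result$sem[idx, , , drop = FALSE], dims = 1),
                        c(1L, d[2], d[3]))
  }
  result$channel_group <- as.character(channels)
  result$channels <- paste0("avg(", paste(channels, collapse = ","), ")")
  result
}
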