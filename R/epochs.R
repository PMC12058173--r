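# Epoched EEG container: trials x channels x samples, time axis in ms
# anchored at stimulus onset (t = 0 on or bracketed by the grid).

#' Construct an epoched EEG object
#'
#' @param data Numeric array of dimension `trials x channels x samples`, all
#'   values finite.
#' @param fs Sampling rate in Hz.
#' @param time_ms Time axis in milliseconds relative to stimulus onset; length
#'   must equal the sample dimension and spacing must be `1000 / fs`.  If
#'   omitted, built from `onset_ms` (time of the first sample).
#' @param channels Channel labels (default `"Ch1"`, `"Ch2"`, ...).
#' @param condition,subject Labels carried through the pipeline.
#' @param onset_ms Time of the first sample in ms (used only when `time_ms`
#'   is missing).
#' @return An `eeg_epochs` object.
#' @export
#' @examples
#' x <- eeg_epochs(array(rnorm(2 * 3 * 100), c(2, 3, 100)), fs = 100,
#'                 onset_ms = -200)
#' dim(x$data)
eeg_epochs <- function(data, fs, time_ms = NULL, channels = NULL,
                       condition = "cond", subject = "subj",
                       onset_ms = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-dimensional array (trials x channels x samples)",
         call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("`data` must be all finite", call. = FALSE)
  }
  check_positive(fs, "fs")
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L) {
    stop("need at least 1 trial and 1 channel", call. = FALSE)
  }
  if (is.null(time_ms)) {
    if (is.null(onset_ms)) {
      stop("supply either `time_ms` or `onset_ms`", call. = FALSE)
    }
    time_ms <- onset_ms + (seq_len(d[3]) - 1) * 1000 / fs
  }
  if (length(time_ms) != d[3]) {
    stop("`time_ms` length must equal the sample dimension", call. = FALSE)
  }
  if (d[3] > 1L) {
    dt <- diff(time_ms)
    if (max(abs(dt - 1000 / fs)) > 1e-6 * (1000 / fs)) {
      stop("`time_ms` spacing must equal 1000 / fs", call. = FALSE)
    }
  }
  if (is.null(channels)) channels <- paste0("Ch", seq_len(d[2]))
  if (length(channels) != d[2]) {
    stop("`channels` length must equal the channel dimension", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, time_ms = as.numeric(time_ms),
         channels = as.character(channels),
         condition = condition, subject = subject,
         padded_ms = 0),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples, fs = %g Hz, %g..%g ms (%s / %s)\n",
    d[1], d[2], d[3], x$fs, x$time_ms[1], x$time_ms[d[3]],
    x$subject, x$condition))
  invisible(x)
}

n_trials <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

#' Remove the DC component of every trace
#'
#' Subtracts from each (trial, channel) trace its mean over the full epoch
#' extent, so each trace has exactly zero mean before convolution.
#'
#' @param epochs An [eeg_epochs()] object.
#' @return The same object with per-trace means removed.
#' @export
remove_dc <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  m <- rowMeans(epochs$data, dims = 2)
  epochs$data <- epochs$data - as.vector(m)
  epochs
}

#' Pad epochs at both edges before transformation
#'
#' Extends every trace by `per_edge_ms` on each side, either mirroring the
#' signal about the edge sample (default, preserves continuity of value) or
#' filling with zeros.  The padding compensates for the absence of signal
#' beyond segment boundaries during convolution and is meant to be removed
#' after the transform with [chop_edges()] using the same `per_edge_ms`.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param per_edge_ms Milliseconds to add at each edge (>= 0; rounded to whole
#'   samples).
#' @param method `"mirror"` (default) or `"zero"`.
#' @return Padded `eeg_epochs`; the field `padded_ms` records the cumulative
#'   padding so it can be chopped after the transform.
#' @export
pad_edges <- function(epochs, per_edge_ms, method = c("mirror", "zero")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  method <- match.arg(method)
  if (!is.numeric(per_edge_ms) || length(per_edge_ms) != 1L ||
      !is.finite(per_edge_ms) || per_edge_ms < 0) {
    stop("`per_edge_ms` must be a single non-negative number", call. = FALSE)
  }
  k <- as.integer(round(per_edge_ms * epochs$fs / 1000))
  if (k == 0L) return(epochs)
  n <- n_samples(epochs)
  if (method == "mirror" && k >= n) {
    stop("mirror padding longer than the epoch itself is not supported",
         call. = FALSE)
  }
  left <- if (method == "zero") integer(0) else seq.int(k + 1L, 2L)
  right <- if (method == "zero") integer(0) else seq.int(n - 1L, n - k)
  d <- dim(epochs$data)
  out <- array(0, c(d[1], d[2], n + 2L * k))
  out[, , k + seq_len(n)] <- epochs$data
  if (method == "mirror") {
    out[, , seq_len(k)] <- epochs$data[, , left, drop = FALSE]
    out[, , n + k + seq_len(k)] <- epochs$data[, , right, drop = FALSE]
  }
  dtms <- 1000 / epochs$fs
  epochs$data <- out
  epochs$time_ms <- seq(epochs$time_ms[1] - k * dtms, by = dtms,
                        length.out = n + 2L * k)
  epochs$padded_ms <- epochs$padded_ms + k * dtms
  epochs
}
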