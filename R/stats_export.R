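# Window-averaged values and tabulated export for third-party statistics.

#' Mean of a time-frequency result over a time x frequency window
#'
#' Unweighted mean ("double average") over every (frequency, time) grid point
#' inside the two windows, for one channel.  Window endpoints snap to the
#' nearest grid point and are inclusive, the same rule as baseline windows;
#' a degenerate window `c(x, x)` selects a single grid line.
#'
#' @param result A `tf_result`.
#' @param time_window `c(start_ms, end_ms)` within the result's time axis.
#' @param freq_window `c(low_hz, high_hz)` within the frequency axis.
#' @param channel Channel label or index; may be omitted for single-channel
#'   results.
#' @return Scalar mean.
#' @export
#' @examples
#' ## mean gamma-band response 250-350 ms after onset:
#' ## window_mean(result, c(250, 350), c(30, 40), "Fp2")
window_mean <- function(result, time_window, freq_window, channel = NULL) {
  stopifnot(inherits(result, "tf_result"))
  ti <- snap_span(result$time_ms, time_window, "time_window")
  fi <- snap_span(result$frequencies, freq_window, "freq_window")
  ch <- resolve_channel(result, channel)
  mean(result$values[ch, fi, ti])
}

# Like snap_window() but accepting degenerate (single-point) windows.
snap_span <- function(axis, window, what) {
  if (length(window) == 1L) window <- c(window, window)
  if (length(window) != 2L || !is.numeric(window) || any(!is.finite(window))) {
    stop(sprintf("`%s` must be numeric c(start, end)", what), call. = FALSE)
  }
  if (window[1] > window[2]) {
    stop(sprintf("`%s` start must not exceed its end", what), call. = FALSE)
  }
  lo <- min(axis); hi <- max(axis)
  if (window[2] < lo || window[1] > hi) {
    stop(sprintf("`%s` [%g, %g] lies outside the valid range [%g, %g]",
                 what, window[1], window[2], lo, hi), call. = FALSE)
  }
  i <- snap_index(axis, window[1])
  j <- snap_index(axis, window[2])
  seq.int(min(i, j), max(i, j))
}

resolve_channel <- function(result, channel) {
  nch <- dim(result$values)[1]
  if (is.null(channel)) {
    if (nch != 1L) {
      stop("`channel` must be given for a multi-channel result",
           call. = FALSE)
    }
    return(1L)
  }
  if (is.character(channel)) {
    ch <- match(channel, result$channels)
    if (is.na(ch)) {
      stop("unknown channel: ", channel, " (available: ",
           paste(result$channels, collapse = ", "), ")", call. = FALSE)
    }
    ch
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > nch) {
      stop(sprintf("channel index out of range 1..%d", nch), call. = FALSE)
    }
    ch
  }
}

#' Export window-averaged values as a tab-separated table
#'
#' One row per subject, one column per condition x channel combination
#' (condition-major order), each cell the [window_mean()] of that subject's
#' result for the given windows.  The header names columns
#' `<condition>_<channel>`; the first column holds the subject label.
#' Values are written in full double precision so the file parses back
#' exactly, ready for any third-party statistics package.
#'
#' @param results Nested list `results[[subject]][[condition]]` of
#'   `tf_result` objects sharing axes (e.g. from [load_project_results()]).
#' @param time_window,freq_window Windows passed to [window_mean()].
#' @param subjects,conditions,channels Selection; default all subjects and
#'   conditions of `results` and all channels of the first result.
#' @param path Output `.tab` path, or a directory (the file is then named
#'   `tfexport_<t1>-<t2>ms_<f1>-<f2>Hz.tab` inside it, the project's
#'   `Statistics` folder being the intended target).
#' @return The exported table as a `data.frame`, invisibly.
#' @export
export_stats <- function(results, time_window, freq_window,
                         subjects = NULL, conditions = NULL, channels = NULL,
                         path) {
  if (is.null(subjects)) subjects <- names(results)
  if (length(subjects) == 0) {
    stop("`subjects` must select at least one subject", call. = FALSE)
  }
  missing_subj <- setdiff(subjects, names(results))
  if (length(missing_subj)) {
    stop("no results for subject(s): ",
         paste(missing_subj, collapse = ", "), call. = FALSE)
  }
  if (is.null(conditions)) conditions <- names(results[[subjects[1]]])
  if (length(conditions) == 0) {
    stop("`conditions` must select at least one condition", call. = FALSE)
  }
  ref <- NULL
  for (s in subjects) {
    miss <- setdiff(conditions, names(results[[s]]))
    if (length(miss)) {
      stop(sprintf("missing result(s) for subject %s, condition(s) %s", s,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    for (cn in conditions) {
      r <- results[[s]][[cn]]
      if (is.null(ref)) {
        ref <- r
      } else if (!isTRUE(all.equal(ref$frequencies, r$frequencies)) ||
                 !isTRUE(all.equal(ref$time_ms, r$time_ms)) ||
                 !identical(ref$channels, r$channels)) {
        stop(sprintf(
          "incompatible result axes for subject %s, condition %s", s, cn),
          call. = FALSE)
      }
    }
  }
  if (is.null(channels)) channels <- ref$channels
  if (length(channels) == 0) {
    stop("`channels` must select at least one channel", call. = FALSE)
  }
  tab <- data.frame(subject = subjects, stringsAsFactors = FALSE)
  for (cn in conditions) {
    for (ch in channels) {
      col <- vapply(subjects, function(s) {
        window_mean(results[[s]][[cn]], time_window, freq_window, ch)
      }, 0)
      tab[[paste(cn, ch, sep = "_")]] <- unname(col)
    }
  }
  if (dir.exists(path)) {
    path <- file.path(path, sprintf("tfexport_%g-%gms_%g-%gHz.tab",
                                    time_window[1], time_window[2],
                                    freq_window[1], freq_window[2]))
  }
  header <- paste(names(tab), collapse = "\t")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    paste(c(tab$subject[i],
            vapply(tab[i, -1, drop = FALSE], function(v)
              sprintf("%.17g", v), "")), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  attr(tab, "path") <- path
  invisible(tab)
}

#' Read back a table written by [export_stats()]
#'
#' @param path `.tab` file path.
#' @return `data.frame` with the subject column and numeric value columns.
#' @export
read_stats <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
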