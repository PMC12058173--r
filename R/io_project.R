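# Dataset and project I/O: epoched-EEG readers/writers, ERPWAVELAB-compatible
# result containers, and batch processing of multi-subject projects.

#' Read epoched EEG from disk
#'
#' Two dialects are supported:
#'
#' * `"eeglab_set"`: an EEGLAB `.set` dataset (a MAT-v5 file holding the
#'   `EEG` structure, with the sample tensor either embedded in `EEG.data`
#'   or in a sibling `.fdt` file of little-endian float32).  The dataset
#'   must hold epoched data from an event-related design with one single
#'   event per epoch at a common latency; channel labels, sampling rate and
#'   time axis come from the file metadata.
#' * `"plain_matrix"`: this package's own MAT-v5 layout with variables
#'   `data` (trials x channels x samples), `time_ms`, `fs`, `channels`,
#'   `condition`, `subject` — see [write_epochs()].
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.set` vs anything else),
#'   `"eeglab_set"` or `"plain_matrix"`.
#' @return An [eeg_epochs()] object.
#' @export
read_epochs <- function(path, format = c("auto", "eeglab_set",
                                         "plain_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.set$", path, ignore.case = TRUE)) {
      "eeglab_set"
    } else "plain_matrix"
  }
  if (format == "eeglab_set") read_epochs_set(path) else read_epochs_plain(path)
}

read_epochs_plain <- function(path) {
  m <- read_mat(path)
  need <- c("data", "fs", "time_ms")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("malformed plain_matrix file (missing ",
         paste(miss, collapse = ", "), "): ", path, call. = FALSE)
  }
  data <- m$data
  if (is.null(dim(data)) || length(dim(data)) == 2L) {
    data <- array(data, c(1L, if (is.null(dim(data))) 1L else dim(data)[1],
                          length(m$time_ms)))
  }
  eeg_epochs(data, fs = as.numeric(m$fs), time_ms = as.numeric(m$time_ms),
             channels = m$channels,
             condition = if (!is.null(m$condition)) m$condition else "cond",
             subject = if (!is.null(m$subject)) m$subject else "subj")
}

read_epochs_set <- function(path) {
  m <- read_mat(path)
  EEG <- if ("EEG" %in% names(m)) m$EEG else m
  if (is.null(EEG$srate)) {
    stop("malformed .set file: missing sampling rate (srate): ", path,
         call. = FALSE)
  }
  fs <- as.numeric(EEG$srate)
  nbchan <- as.integer(EEG$nbchan)
  pnts <- as.integer(EEG$pnts)
  trials <- as.integer(if (!is.null(EEG$trials)) EEG$trials else 1L)
  raw_data <- EEG$data
  if (is.character(raw_data) || !is.null(EEG$datfile)) {
    fdt <- if (is.character(raw_data)) raw_data else EEG$datfile
    fdt_path <- file.path(dirname(path), basename(fdt))
    if (!file.exists(fdt_path)) {
      stop("missing .fdt data file: ", fdt_path, call. = FALSE)
    }
    v <- readBin(fdt_path, "double", n = nbchan * pnts * trials, size = 4L,
                 endian = "little")
    raw_data <- array(v, c(nbchan, pnts, trials))
  }
  if (length(dim(raw_data)) == 2L) {
    raw_data <- array(raw_data, c(dim(raw_data), 1L))
  }
  check_single_event_design(EEG, dim(raw_data)[3])
  times <- if (!is.null(EEG$times) && length(EEG$times) == pnts) {
    as.numeric(EEG$times)
  } else if (!is.null(EEG$xmin)) {
    as.numeric(EEG$xmin) * 1000 + (seq_len(pnts) - 1) * 1000 / fs
  } else {
    stop("malformed .set file: no time axis (times/xmin): ", path,
         call. = FALSE)
  }
  labels <- if (!is.null(EEG$chanlocs)) {
    cl <- EEG$chanlocs
    if (inherits(cl, "mat_struct_array")) {
      vapply(cl, function(r) as.character(r$labels)[1], "")
    } else as.character(cl$labels)[1]
  } else paste0("Ch", seq_len(dim(raw_data)[1]))
  eeg_epochs(aperm(raw_data, c(3, 1, 2)), fs = fs, time_ms = times,
             channels = labels,
             condition = if (!is.null(EEG$condition)) EEG$condition else "cond",
             subject = if (!is.null(EEG$subject) && nzchar(EEG$subject[1])) {
               EEG$subject
             } else "subj")
}

# Event-related designs must carry exactly one event per epoch; anything else
# makes the onset anchoring ambiguous.
check_single_event_design <- function(EEG, n_epochs) {
  ev <- EEG$event
  if (is.null(ev)) return(invisible())
  epochs_of <- if (inherits(ev, "mat_struct_array")) {
    vapply(ev, function(r) {
      if (is.null(r$epoch)) NA_real_ else as.numeric(r$epoch)[1]
    }, 0)
  } else if (!is.null(ev$epoch)) {
    as.numeric(ev$epoch)[1]
  } else NA_real_
  if (all(is.na(epochs_of))) return(invisible())
  counts <- table(factor(epochs_of, levels = seq_len(n_epochs)))
  if (any(counts > 1L)) {
    stop(sprintf(
      "unsupported design: epoch(s) %s contain more than one event (need one single event per epoch)",
      paste(names(counts)[counts > 1L], collapse = ", ")), call. = FALSE)
  }
  invisible()
}

#' Write epoched EEG to disk
#'
#' `"plain_matrix"` stores the tensor and metadata in a MAT-v5 container
#' (variables `data` trials x channels x samples, `time_ms`, `fs`,
#' `channels`, `condition`, `subject`).  `"eeglab_set"` writes an EEGLAB
#' `.set` dataset (the `EEG` struct with `data` as channels x samples x
#' trials, `srate`, `times`, `xmin`/`xmax`, `chanlocs` and one stimulus-onset
#' event per epoch); with `embed_data = FALSE` the samples go to a sibling
#' `.fdt` float32 file referenced from the `.set`, as EEGLAB does by default.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param path Output path.
#' @param format `"plain_matrix"` or `"eeglab_set"`.
#' @param embed_data For `.set` output: keep the samples inside the `.set`
#'   file (default) or in a sibling `.fdt`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path,
                         format = c("plain_matrix", "eeglab_set"),
                         embed_data = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  format <- match.arg(format)
  if (format == "plain_matrix") {
    return(write_mat(path, list(
      data = epochs$data, time_ms = epochs$time_ms, fs = epochs$fs,
      channels = epochs$channels, condition = epochs$condition,
      subject = epochs$subject)))
  }
  d <- dim(epochs$data)
  mat_data <- aperm(epochs$data, c(2, 3, 1))   # channels x samples x trials
  onset_idx <- snap_index(epochs$time_ms, 0)
  events <- mat_struct_array(lapply(seq_len(d[1]), function(e) {
    list(type = "stim", latency = (e - 1) * d[3] + onset_idx, epoch = e)
  }))
  chanlocs <- mat_struct_array(lapply(epochs$channels,
                                      function(l) list(labels = l)))
  EEG <- list(
    setname = paste(epochs$subject, epochs$condition, sep = "_"),
    nbchan = d[2], pnts = d[3], trials = d[1], srate = epochs$fs,
    xmin = epochs$time_ms[1] / 1000, xmax = epochs$time_ms[d[3]] / 1000,
    times = epochs$time_ms,
    chanlocs = chanlocs, event = events,
    condition = epochs$condition, subject = epochs$subject)
  if (embed_data) {
    EEG$data <- mat_data
  } else {
    fdt <- sub("\\.set$", ".fdt", path, ignore.case = TRUE)
    con <- file(fdt, "wb")
    writeBin(as.vector(mat_data), con, size = 4L, endian = "little")
    close(con)
    EEG$data <- basename(fdt)
    EEG$datfile <- basename(fdt)
  }
  write_mat(path, list(EEG = EEG))
}

#' Write a time-frequency result as an ERPWAVELAB-compatible container
#'
#' The channel x frequency x time tensor is stored as the MATLAB variable
#' `WT`, with the frequency axis `Fa` (Hz), time axis `tim` (ms), sampling
#' rate `Fs`, channel labels `chanlocs`, wavelet description `wavetyp` and
#' trial count `nepochs` alongside.  Provenance that has no ERPWAVELAB
#' counterpart (measure, baseline, chopping, cycles, normalization,
#' condition, subject) is namespaced inside the additional struct `eegtf`.
#'
#' @param result A `tf_result`.
#' @param path Output path (`.mat`).
#' @return `path`, invisibly.
#' @export
write_wt <- function(result, path) {
  stopifnot(inherits(result, "tf_result"))
  meta <- list(
    measure = result$measure,
    n_trials_averaged = result$n_trials_averaged,
    chopped_ms = result$chopped_ms,
    edge_ms = result$edge_ms,
    cycles = result$cycles,
    normalization = result$normalization,
    condition = result$condition,
    subject = result$subject,
    baseline_mode = if (is.null(result$baseline)) "none" else
      result$baseline$mode,
    baseline_window_ms = if (is.null(result$baseline)) numeric(0) else
      result$baseline$window_ms)
  vars <- list(
    WT = result$values,
    Fa = result$frequencies,
    tim = result$time_ms,
    Fs = tf_fs(result),
    chanlocs = mat_struct_array(lapply(result$channels,
                                       function(l) list(labels = l))),
    wavetyp = sprintf("Morlet %g cycles (%s normalization)", result$cycles,
                      result$normalization),
    nepochs = result$n_trials_averaged,
    eegtf = meta)
  if (!is.null(result$sem)) vars$eegtf$sem <- result$sem
  write_mat(path, vars)
}

#' Read an ERPWAVELAB-compatible time-frequency container
#'
#' Inverts [write_wt()].  Files written by other ERPWAVELAB-compatible tools
#' are accepted as long as they carry `WT`, `Fa` and `tim`; missing
#' provenance defaults to an amplitude measure with no baseline.
#'
#' @param path File path.
#' @return A `tf_result`.
#' @export
read_wt <- function(path) {
  m <- read_mat(path)
  if (is.null(m$WT)) {
    stop("malformed WT file (no WT variable): ", path, call. = FALSE)
  }
  if (is.null(m$Fa) || is.null(m$tim)) {
    stop("malformed WT file (missing Fa/tim axes): ", path, call. = FALSE)
  }
  values <- m$WT
  if (length(dim(values)) != 3L) {
    if (is.null(dim(values))) {
      values <- array(values, c(1L, length(m$Fa), length(m$tim)))
    } else stop("WT variable is not a 3D tensor: ", path, call. = FALSE)
  }
  meta <- if (!is.null(m$eegtf)) m$eegtf else list()
  labels <- if (!is.null(m$chanlocs)) {
    cl <- m$chanlocs
    if (inherits(cl, "mat_struct_array")) {
      vapply(cl, function(r) as.character(r$labels)[1], "")
    } else as.character(cl$labels)[1]
  } else paste0("Ch", seq_len(dim(values)[1]))
  structure(
    list(values = values,
         measure = if (!is.null(meta$measure)) meta$measure else "amplitude",
         frequencies = as.numeric(m$Fa),
         time_ms = as.numeric(m$tim),
         channels = labels,
         n_trials_averaged =
           if (!is.null(m$nepochs)) as.numeric(m$nepochs) else NA_real_,
         baseline = if (!is.null(meta$baseline_mode) &&
                        meta$baseline_mode != "none") {
           list(mode = meta$baseline_mode,
                window_ms = as.numeric(meta$baseline_window_ms))
         } else NULL,
         chopped_ms = if (!is.null(meta$chopped_ms)) meta$chopped_ms else 0,
         edge_ms = if (!is.null(meta$edge_ms)) meta$edge_ms else NA_real_,
         cycles = if (!is.null(meta$cycles)) meta$cycles else NA_real_,
         normalization = if (!is.null(meta$normalization)) {
           meta$normalization
         } else NA_character_,
         condition = if (!is.null(meta$condition)) meta$condition else "cond",
         subject = if (!is.null(meta$subject)) meta$subject else "subj",
         sem = meta$sem),
    class = "tf_result")
}

#' Assemble or load a project configuration
#'
#' A project groups subjects x conditions under one root folder with the
#' layout `Import/` (input epoch files named `<subject>_<condition>.mat` or
#' `.set`), `WT/` (result containers + manifest) and `Statistics/` (export
#' tables).  Analysis parameters mirror the function arguments of the
#' pipeline and are validated before any run.
#'
#' @param root Project root directory.
#' @param subjects,conditions Unique label vectors.
#' @param fmin,fmax,fstep Analysis frequency range and step in Hz.
#' @param cycles,normalization,measure,mode Transform parameters (see
#'   [wavelet_bank()] and [tf_transform()]).
#' @param chop_ms Per-edge chop after the transform, ms.
#' @param baseline,baseline_window Baseline mode and window (see
#'   [baseline_correct()]; `NULL` window = full pre-stimulus interval).
#' @return A `project_config` list.
#' @export
project_config <- function(root, subjects, conditions,
                           fmin = 10, fmax = 90, fstep = 1, cycles = 7,
                           normalization = "amplitude",
                           measure = "amplitude", mode = "induced",
                           chop_ms = 300, baseline = "subtractive",
                           baseline_window = NULL) {
  if (anyDuplicated(subjects)) stop("duplicate subject labels", call. = FALSE)
  if (anyDuplicated(conditions)) {
    stop("duplicate condition labels", call. = FALSE)
  }
  check_positive(fstep, "fstep")
  check_positive(cycles, "cycles")
  if (fmin <= 0 || fmax < fmin) stop("need 0 < fmin <= fmax", call. = FALSE)
  measure <- match.arg(measure, c("amplitude", "power", "complex"))
  mode <- match.arg(mode, c("induced", "evoked"))
  normalization <- match.arg(normalization, c("amplitude", "power", "none"))
  baseline <- match.arg(baseline, c("subtractive", "subtractive_normalized",
                                    "divisive", "none"))
  if (measure == "complex" && baseline != "none") {
    stop("complex measure cannot be baseline-corrected; set baseline = \"none\"",
         call. = FALSE)
  }
  structure(list(root = root, subjects = as.character(subjects),
                 conditions = as.character(conditions),
                 fmin = fmin, fmax = fmax, fstep = fstep, cycles = cycles,
                 normalization = normalization, measure = measure,
                 mode = mode, chop_ms = chop_ms, baseline = baseline,
                 baseline_window = baseline_window),
            class = "project_config")
}

#' Load a project configuration from YAML or JSON
#'
#' @param path `.yml`/`.yaml` or `.json` file whose keys match the arguments
#'   of [project_config()].
#' @return A validated `project_config`.
#' @export
read_project_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(raw$root)) raw$root <- dirname(normalizePath(path))
  do.call(project_config, raw)
}

project_paths <- function(config) {
  list(import = file.path(config$root, "Import"),
       wt = file.path(config$root, "WT"),
       stats = file.path(config$root, "Statistics"),
       manifest = file.path(config$root, "WT", "manifest.json"))
}

project_param_string <- function(config) {
  paste(config$fmin, config$fmax, config$fstep, config$cycles,
        config$normalization, config$measure, config$mode, config$chop_ms,
        config$baseline,
        paste(config$baseline_window, collapse = ","), sep = "|")
}

find_input <- function(import_dir, subject, condition) {
  for (ext in c("mat", "set")) {
    p <- file.path(import_dir, sprintf("%s_%s.%s", subject, condition, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Run the analysis over all subjects and conditions of a project
#'
#' For every subject x condition the input epochs are read from `Import/`,
#' transformed with the configured wavelet bank, chopped, baseline-corrected
#' and written to `WT/<subject>_<condition>.mat` ([write_wt()] containers).
#' A JSON manifest logs, per output, the input file checksum and the
#' parameters used; re-running skips outputs whose manifest entry still
#' matches (unless `force = TRUE`).  Per-item failures are reported and the
#' run continues.
#'
#' @param config A [project_config()].
#' @param force Recompute even when an up-to-date output exists.
#' @return A `project_run` summary: data.frame `items` (subject, condition,
#'   status `computed`/`skipped`/`failed`, message) plus `n_failed`.
#' @export
run_project <- function(config, force = FALSE) {
  stopifnot(inherits(config, "project_config"))
  paths <- project_paths(config)
  for (p in paths[c("wt", "stats")]) {
    dir.create(p, recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- if (file.exists(paths$manifest)) {
    jsonlite::fromJSON(paths$manifest, simplifyVector = FALSE)
  } else list()
  params <- project_param_string(config)
  bank <- NULL
  items <- list()
  for (subject in config$subjects) {
    for (condition in config$conditions) {
      key <- paste(subject, condition, sep = "_")
      out_path <- file.path(paths$wt, paste0(key, ".mat"))
      status <- "computed"; msg <- ""
      input <- find_input(paths$import, subject, condition)
      if (is.null(input)) {
        status <- "failed"
        msg <- sprintf("missing input for %s / %s under %s", subject,
                       condition, paths$import)
      } else {
        md5 <- unname(tools::md5sum(input))
        entry <- manifest[[key]]
        if (!force && !is.null(entry) && identical(entry$input_md5, md5) &&
            identical(entry$params, params) && file.exists(out_path)) {
          status <- "skipped"
        } else {
          res <- tryCatch({
            ep <- read_epochs(input)
            if (is.null(bank) || abs(bank$fs - ep$fs) > 1e-9) {
              bank <- wavelet_bank(seq(config$fmin, config$fmax,
                                       by = config$fstep),
                                   cycles = config$cycles, fs = ep$fs,
                                   normalization = config$normalization)
            }
            tf <- tf_transform(ep, bank, measure = config$measure,
                               mode = config$mode)
            if (config$chop_ms > 0) tf <- chop_edges(tf, config$chop_ms)
            if (config$baseline != "none") {
              tf <- baseline_correct(tf, config$baseline,
                                     window = config$baseline_window)
            }
            write_wt(tf, out_path)
            manifest[[key]] <- list(input = basename(input), input_md5 = md5,
                                    params = params,
                                    output = basename(out_path),
                                    written = format(Sys.time(),
                                                     "%Y-%m-%dT%H:%M:%S"))
            NULL
          }, error = function(e) conditionMessage(e))
          if (!is.null(res)) { status <- "failed"; msg <- res }
        }
      }
      items[[key]] <- data.frame(subject = subject, condition = condition,
                                 status = status, message = msg,
                                 stringsAsFactors = FALSE)
    }
  }
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  items <- do.call(rbind, items)
  rownames(items) <- NULL
  structure(list(items = items, n_failed = sum(items$status == "failed"),
                 manifest_path = paths$manifest),
            class = "project_run")
}

#' @export
print.project_run <- function(x, ...) {
  tab <- table(x$items$status)
  cat("<project_run> ", paste(sprintf("%s: %d", names(tab), tab),
                              collapse = ", "), "\n", sep = "")
  failed <- x$items[x$items$status == "failed", , drop = FALSE]
  for (i in seq_len(nrow(failed))) {
    cat(sprintf("  FAILED %s/%s: %s\n", failed$subject[i],
                failed$condition[i], failed$message[i]))
  }
  invisible(x)
}

#' Load the per-subject/condition results of a project
#'
#' @param config A [project_config()].
#' @return Nested list `results[[subject]][[condition]]` of `tf_result`
#'   objects (missing outputs are errors).
#' @export
load_project_results <- function(config) {
  paths <- project_paths(config)
  out <- list()
  for (subject in config$subjects) {
    out[[subject]] <- list()
    for (condition in config$conditions) {
      p <- file.path(paths$wt, sprintf("%s_%s.mat", subject, condition))
      if (!file.exists(p)) {
        stop("missing project result: ", p, call. = FALSE)
      }
      out[[subject]][[condition]] <- read_wt(p)
    }
  }
  out
}
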