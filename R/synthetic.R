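# Synthetic epoched EEG with known oscillatory content.
#
# The generator emulates event-locked epochs as a sum of oscillatory bursts
# (controllable frequency, latency, width, amplitude and per-trial phase
# policy) plus broadband noise, so the whole analysis chain is testable with
# ground truth and without any recorded data.

#' Describe an oscillatory burst
#'
#' @param frequency Burst oscillation frequency in Hz.
#' @param center_ms Burst centre latency in ms relative to stimulus onset.
#' @param duration_ms Burst width in ms.  For the default Gaussian envelope
#'   this is the envelope FWHM (aligning burst width with the wavelet
#'   resolution vocabulary); for `"boxcar"` it is the full width.
#' @param amplitude Peak amplitude in signal units (>= 0).
#' @param phase `"locked"` (same phase every trial, phase-locked to onset,
#'   surviving trial averaging) or `"jittered"` (uniform random phase per
#'   trial, averaged out of the evoked response).
#' @param phase0 Phase at the burst centre for `"locked"` bursts, radians.
#' @param envelope `"gaussian"` (default) or `"boxcar"`.
#' @param channels Channel indices or labels receiving the burst
#'   (default: all channels).
#' @return A `burst_spec` list.
#' @export
burst_spec <- function(frequency, center_ms, duration_ms = 100, amplitude = 1,
                       phase = c("locked", "jittered"), phase0 = 0,
                       envelope = c("gaussian", "boxcar"), channels = NULL) {
  phase <- match.arg(phase)
  envelope <- match.arg(envelope)
  check_positive(frequency, "frequency")
  check_positive(duration_ms, "duration_ms")
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("`amplitude` must be >= 0", call. = FALSE)
  }
  structure(list(frequency = frequency, center_ms = center_ms,
                 duration_ms = duration_ms, amplitude = amplitude,
                 phase = phase, phase0 = phase0, envelope = envelope,
                 channels = channels),
            class = "burst_spec")
}

# Evaluate a burst on a time axis (ms) for one trial, given its phase.
burst_trace <- function(b, time_ms, phi) {
  trel <- (time_ms - b$center_ms) / 1000
  env <- if (b$envelope == "gaussian") {
    sd_s <- (b$duration_ms / 1000) / (2 * sqrt(2 * log(2)))
    exp(-trel^2 / (2 * sd_s^2))
  } else {
    as.numeric(abs(trel) <= (b$duration_ms / 1000) / 2)
  }
  b$amplitude * env * cos(2 * pi * b$frequency * trel + phi)
}

# Run code with a private, restored RNG state seeded deterministically.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# White or spectrally shaped (1/f^alpha in power) Gaussian noise, unit sd.
noise_trace <- function(n, alpha) {
  x <- stats::rnorm(n)
  if (alpha == 0) return(x)
  f <- c(1, seq_len(n - 1))                    # avoid the DC bin
  f <- pmin(f, n - f + 1)                      # two-sided frequency index
  shaped <- Re(stats::fft(stats::fft(x) * f^(-alpha / 2), inverse = TRUE)) / n
  shaped <- shaped - mean(shaped)
  s <- stats::sd(shaped)
  if (s > 0) shaped / s else shaped
}

#' Simulate epoched EEG with oscillatory bursts plus noise
#'
#' Every trace is the sum of the requested bursts (evaluated on the epoch
#' time axis, with per-trial random phase for `"jittered"` bursts) and
#' broadband Gaussian noise.  The seed fully determines the output: identical
#' seeds give bitwise-identical data, and the caller's RNG state is left
#' untouched.
#'
#' @param n_trials,n_channels Numbers of trials and channels.
#' @param fs Sampling rate in Hz.
#' @param window_ms Epoch extent `c(start, end)` in ms; must bracket 0
#'   (stimulus onset).
#' @param bursts A [burst_spec()] or list of them.
#' @param noise_sd Standard deviation of the additive noise, signal units.
#' @param noise_alpha Spectral exponent of the noise (0 = white; `alpha` > 0
#'   gives 1/f^alpha-shaped power via spectral shaping).
#' @param channels,condition,subject Metadata for the resulting epochs.
#' @param seed Integer seed (required; determinism is part of the contract).
#' @return An [eeg_epochs()] object.
#' @export
#' @examples
#' ep <- simulate_epochs(5, 2, fs = 250, window_ms = c(-200, 800),
#'                       bursts = burst_spec(20, 300), noise_sd = 1, seed = 1)
simulate_epochs <- function(n_trials, n_channels, fs = 500,
                            window_ms = c(-500, 1500), bursts = list(),
                            noise_sd = 1, noise_alpha = 0,
                            channels = NULL, condition = "cond",
                            subject = "S01", seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (inherits(bursts, "burst_spec")) bursts <- list(bursts)
  if (length(window_ms) != 2L || window_ms[1] >= window_ms[2] ||
      window_ms[1] > 0 || window_ms[2] < 0) {
    stop("`window_ms` must be c(start, end) bracketing 0", call. = FALSE)
  }
  for (b in bursts) {
    if (b$frequency >= fs / 2) {
      stop(sprintf("burst frequency %g Hz is at or above Nyquist (%g Hz)",
                   b$frequency, fs / 2), call. = FALSE)
    }
  }
  n <- as.integer(round((window_ms[2] - window_ms[1]) * fs / 1000)) + 1L
  time_ms <- window_ms[1] + (seq_len(n) - 1) * 1000 / fs
  if (is.null(channels)) channels <- paste0("Ch", seq_len(n_channels))
  chan_index <- function(sel) {
    if (is.null(sel)) return(seq_len(n_channels))
    if (is.character(sel)) {
      idx <- match(sel, channels)
      if (anyNA(idx)) {
        stop("unknown burst channel(s): ",
             paste(sel[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      idx
    } else as.integer(sel)
  }
  data <- with_seed(seed, {
    out <- array(0, c(n_trials, n_channels, n))
    for (b in bursts) {
      idx <- chan_index(b$channels)
      phis <- if (b$phase == "jittered") {
        stats::runif(n_trials, 0, 2 * pi)
      } else rep(b$phase0, n_trials)
      for (tr in seq_len(n_trials)) {
        tb <- burst_trace(b, time_ms, phis[tr])
        for (ch in idx) out[tr, ch, ] <- out[tr, ch, ] + tb
      }
    }
    if (noise_sd > 0) {
      for (tr in seq_len(n_trials)) {
        for (ch in seq_len(n_channels)) {
          out[tr, ch, ] <- out[tr, ch, ] + noise_sd * noise_trace(n, noise_alpha)
        }
      }
    }
    out
  })
  eeg_epochs(data, fs = fs, time_ms = time_ms, channels = channels,
             condition = condition, subject = subject)
}

# 19-channel 10-20 montage labels used by the bundled fixtures.
fixture_channels_19 <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "Oz")
}

#' Write self-contained synthetic fixture datasets
#'
#' Generates and writes small epoched-EEG datasets with known content:
#'
#' * `"tiny"`: one subject, one condition, 5 trials x 4 channels at 250 Hz
#'   (-200..800 ms) with a single phase-locked 20 Hz burst; written both as a
#'   plain-matrix container and as an EEGLAB `.set` file.
#' * `"tutorial"`: a multi-subject, four-condition design emulating an infant
#'   gamma-band experiment: conditions `DG`, `AG`, `IDS`, `ADS`, 12 trials x
#'   19 channels at 500 Hz, epochs -500..1500 ms.  `DG` carries a
#'   phase-locked 35 Hz burst centred at 300 ms on the frontal channels
#'   (Fp1, Fpz, Fp2) that the other conditions lack; `IDS` carries a
#'   10 Hz jittered burst at 400 ms.  One plain-matrix file per
#'   subject x condition.
#'
#' @param kind `"tiny"` or `"tutorial"`.
#' @param out_dir Writable output directory (created if missing).
#' @param seed Integer seed; offsets per subject/condition are derived from it.
#' @param subjects Subject labels for `"tutorial"` (default `S01`..`S03`).
#' @param n_trials Trials per condition for `"tutorial"` (default 12).
#' @return Invisibly, a character vector of the written file paths.
#' @export
make_fixture_set <- function(kind = c("tiny", "tutorial"), out_dir,
                             seed = 1, subjects = c("S01", "S02", "S03"),
                             n_trials = 12) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- character(0)
  if (kind == "tiny") {
    ep <- simulate_epochs(5, 4, fs = 250, window_ms = c(-200, 800),
                          bursts = burst_spec(20, 300, amplitude = 2),
                          noise_sd = 0.5, channels = paste0("Ch", 1:4),
                          condition = "cond1", subject = "S01", seed = seed)
    p1 <- file.path(out_dir, "tiny_S01_cond1.mat")
    p2 <- file.path(out_dir, "tiny_S01_cond1.set")
    write_epochs(ep, p1, format = "plain_matrix")
    write_epochs(ep, p2, format = "eeglab_set")
    paths <- c(p1, p2)
  } else {
    conds <- tutorial_condition_specs()
    for (si in seq_along(subjects)) {
      for (ci in seq_along(names(conds))) {
        cond <- names(conds)[ci]
        ep <- simulate_epochs(
          n_trials, 19, fs = 500, window_ms = c(-500, 1500),
          bursts = conds[[cond]], noise_sd = 1,
          channels = fixture_channels_19(),
          condition = cond, subject = subjects[si],
          seed = seed + 1000L * si + ci)
        p <- file.path(out_dir, sprintf("%s_%s.mat", subjects[si], cond))
        write_epochs(ep, p, format = "plain_matrix")
        paths <- c(paths, p)
      }
    }
  }
  invisible(paths)
}

# Burst content of the four tutorial-like conditions.  DG carries the frontal
# phase-locked gamma burst (35 Hz at 300 ms) whose DG - AG difference the
# analysis should localize in the 250-350 ms x 30-40 Hz window; amplitude 3
# over unit noise gives SNR 3.
tutorial_condition_specs <- function() {
  frontal <- c("Fp1", "Fpz", "Fp2")
  list(
    DG = list(burst_spec(35, 300, duration_ms = 100, amplitude = 3,
                         phase = "locked", channels = frontal)),
    AG = list(),
    IDS = list(burst_spec(10, 400, duration_ms = 200, amplitude = 2,
                          phase = "jittered", channels = frontal)),
    ADS = list()
  )
}
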