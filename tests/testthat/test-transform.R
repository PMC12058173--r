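test_that("DC removal zeroes every trace mean and keeps shape", {
  n <- 250                                           # 8 Hz x 1 s: whole cycles
  data <- array(0, c(2, 2, n))
  data[1, 1, ] <- 5                                  # constant
  data[1, 2, ] <- sin(2 * pi * 8 * (0:(n - 1)) / 250)  # zero-mean sinusoid
  data[2, 1, ] <- data[1, 2, ] + 3                   # sinusoid + offset
  data[2, 2, ] <- rnorm(n)
  ep <- eeg_epochs(data, fs = 250, onset_ms = -100)
  out <- remove_dc(ep)
  expect_identical(dim(out$data), dim(data))
  expect_true(all(abs(apply(out$data, c(1, 2), mean)) < 1e-12))
  expect_true(all(abs(out$data[1, 1, ]) < 1e-12))
  expect_lt(max(abs(out$data[1, 2, ] - data[1, 2, ])), 1e-12)
  expect_lt(max(abs(out$data[2, 1, ] - data[1, 2, ])), 1e-12)
})

test_that("FFT-based convolution agrees with the direct time-domain oracle", {
  set.seed(42)
  bank <- wavelet_bank(c(10, 23, 50), cycles = 7, fs = 250)
  interior <- interior_of(bank, 500)
  for (i in 1:5) {
    x <- rnorm(500)
    fftc <- cwt_trace(x, bank)
    direct <- direct_cwt(x, bank)
    expect_rel_equal(fftc[, interior], direct[, interior], 1e-8)
  }
})

test_that("cwt basics: zeros, linearity, alignment, short-trace error", {
  bank <- wavelet_bank(c(10, 20), cycles = 7, fs = 250)
  n <- 600
  expect_true(all(cwt_trace(numeric(n), bank) == 0))
  set.seed(7)
  x <- rnorm(n)
  expect_lt(max(Mod(cwt_trace(2 * x, bank) - 2 * cwt_trace(x, bank))), 1e-10)
  expect_identical(dim(cwt_trace(x, bank)), c(2L, as.integer(n)))
  # the 10 Hz wavelet spans 2*ceiling(5*sigma*fs)+1 = 281 samples at 250 Hz
  err <- tryCatch(cwt_trace(numeric(100), bank), error = conditionMessage)
  expect_match(err, "too short")
  expect_match(err, "10 Hz")
})

test_that("amplitude response to a matched unit sinusoid is time-flat and frequency-flat", {
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  freqs <- seq(10, 90, 10)
  peaks <- vapply(freqs, function(f) {
    bank <- wavelet_bank(f, cycles = 7, fs = fs)
    co <- Mod(cwt_trace(cos(2 * pi * f * t), bank))
    interior <- interior_of(bank, length(t))
    expect_lt(diff(range(co[1, interior])) / mean(co[1, interior]), 0.01)
    max(co[1, interior])
  }, 0)
  expect_lt((max(peaks) - min(peaks)) / min(peaks), 0.01)
})

test_that("measure consistency: power equals amplitude squared", {
  ep <- simulate_epochs(3, 2, fs = 250, window_ms = c(-200, 800),
                        bursts = burst_spec(20, 300), noise_sd = 0.5,
                        seed = 11)
  bank <- wavelet_bank(c(15, 20, 25), fs = 250)
  amp <- tf_transform(ep, bank, measure = "amplitude", trials = 1)
  pow <- tf_transform(ep, bank, measure = "power", trials = 1)
  cpl <- tf_transform(ep, bank, measure = "complex", trials = 1)
  expect_rel_equal(pow$values, amp$values^2, 1e-10)
  expect_rel_equal(Mod(cpl$values), amp$values, 1e-12)
})

test_that("trial subsetting: single-trial extraction and averaging identities", {
  ep <- simulate_epochs(4, 1, fs = 250, window_ms = c(-200, 800),
                        bursts = burst_spec(20, 300), noise_sd = 1, seed = 3)
  bank <- wavelet_bank(c(18, 20, 22), fs = 250)
  single <- tf_transform(ep, bank, trials = 2)
  expect_identical(single$n_trials_averaged, 1L)
  dc <- remove_dc(ep)
  expect_rel_equal(single$values[1, , ],
                   Mod(cwt_trace(dc$data[2, 1, ], bank)), 1e-12)
  # N identical trials average to the single-trial result
  same <- ep
  for (tr in 2:4) same$data[tr, , ] <- same$data[1, , ]
  all4 <- tf_transform(same, bank)
  one <- tf_transform(same, bank, trials = 1)
  expect_lt(max(abs(all4$values - one$values)), 1e-12)
  expect_error(tf_transform(ep, bank, trials = integer(0)), "at least one")
  expect_error(tf_transform(ep, bank, trials = 9), "1..4")
})

test_that("evoked equals induced for identical trials and single trials", {
  ep <- simulate_epochs(6, 2, fs = 250, window_ms = c(-200, 800),
                        bursts = burst_spec(20, 300, amplitude = 2),
                        noise_sd = 0, seed = 5)      # locked, noiseless
  bank <- wavelet_bank(seq(14, 26, 2), fs = 250)
  ind <- tf_transform(ep, bank, mode = "induced")
  evo <- tf_transform(ep, bank, mode = "evoked")
  expect_lt(max(abs(ind$values - evo$values)), 1e-12)
  one <- simulate_epochs(1, 1, fs = 250, window_ms = c(-200, 800),
                         bursts = list(), noise_sd = 1, seed = 6)
  expect_lt(max(abs(tf_transform(one, bank)$values -
                    tf_transform(one, bank, mode = "evoked")$values)), 1e-12)
})

test_that("phase-jittered activity survives induced averaging but cancels in evoked", {
  ep <- simulate_epochs(100, 1, fs = 250, window_ms = c(-200, 800),
                        bursts = burst_spec(20, 300, amplitude = 1,
                                            phase = "jittered"),
                        noise_sd = 0, seed = 8)
  bank <- wavelet_bank(20, fs = 250)
  ind <- tf_transform(ep, bank)
  evo <- tf_transform(ep, bank, mode = "evoked")
  locus <- which.min(abs(ep$time_ms - 300))
  # induced amplitude stays within 10% of the phase-aligned case
  aligned <- simulate_epochs(1, 1, fs = 250, window_ms = c(-200, 800),
                             bursts = burst_spec(20, 300, amplitude = 1),
                             noise_sd = 0, seed = 1)
  ref <- tf_transform(aligned, bank)$values[1, 1, locus]
  expect_lt(abs(ind$values[1, 1, locus] - ref) / ref, 0.10)
  expect_lt(evo$values[1, 1, locus], 0.2 * ind$values[1, 1, locus])
})

test_that("burst parameter recovery at SNR 3 across seeded replicates", {
  bank <- wavelet_bank(seq(10, 60, 2), cycles = 7, fs = 250)
  sig_ms <- wavelet_sigma(40) * 1000
  for (seed in 1:8) {
    ep <- simulate_epochs(12, 1, fs = 250, window_ms = c(-300, 900),
                          bursts = burst_spec(40, 400, duration_ms = 100,
                                              amplitude = 3),
                          noise_sd = 1, seed = seed)
    r <- baseline_correct(chop_edges(tf_transform(ep, bank), 200),
                          "subtractive")
    ix <- which(r$values[1, , ] == max(r$values[1, , ]), arr.ind = TRUE)
    expect_lte(abs(r$frequencies[ix[1]] - 40), 2)   # one 2 Hz grid step
    expect_lte(abs(r$time_ms[ix[2]] - 400), sig_ms)
  }
})

test_that("standard error of the mean across trials backs the SEM tensor", {
  ep <- simulate_epochs(8, 1, fs = 250, window_ms = c(-200, 800),
                        bursts = list(), noise_sd = 1, seed = 13)
  bank <- wavelet_bank(c(20, 30), fs = 250)
  r <- tf_transform(ep, bank, keep_sem = TRUE)
  dc <- remove_dc(ep)
  per_trial <- vapply(1:8, function(tr) Mod(cwt_trace(dc$data[tr, 1, ], bank)),
                      matrix(0, 2, dim(ep$data)[3]))
  manual <- apply(per_trial, c(1, 2), stats::sd) / sqrt(8)
  expect_rel_equal(r$sem[1, , ], manual, 1e-8)
})

test_that("mismatched sampling rates and bad modes are rejected", {
  ep <- simulate_epochs(2, 1, fs = 250, window_ms = c(-200, 800),
                        bursts = list(), seed = 1)
  expect_error(tf_transform(ep, wavelet_bank(20, fs = 500)), "does not match")
  expect_error(tf_transform(ep, wavelet_bank(20, fs = 250),
                            mode = "evoked", trials = 1), "induced")
})
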