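# Shared small result for adjustment tests.
make_result <- function(seed = 21, n_ch = 3, fs = 250) {
  ep <- simulate_epochs(4, n_ch, fs = fs, window_ms = c(-500, 1500),
                        bursts = burst_spec(20, 300, amplitude = 2),
                        noise_sd = 0.5, seed = seed,
                        channels = c("Fp1", "Fpz", "Fp2")[seq_len(n_ch)])
  tf_transform(ep, wavelet_bank(seq(14, 30, 4), fs = fs))
}

test_that("chopping arithmetic matches the worked segment bounds", {
  r <- make_result()
  expect_equal(range(r$time_ms), c(-500, 1500))
  ch <- chop_edges(r, 300)
  expect_equal(range(ch$time_ms), c(-200, 1200))
  expect_equal(max(ch$time_ms) - min(ch$time_ms), 1400)
  expect_equal(ch$chopped_ms, 300)
  # identity at zero, over-chop rejected
  expect_equal(chop_edges(r, 0)$time_ms, r$time_ms)
  short <- r
  keep <- which(r$time_ms >= 0 & r$time_ms <= 1000)
  short$values <- short$values[, , keep, drop = FALSE]
  short$time_ms <- short$time_ms[keep]
  expect_error(chop_edges(short, 600), "cannot chop")
})

test_that("padding: identity at zero, sample counts, pad-then-chop round trip", {
  ep <- simulate_epochs(2, 1, fs = 500, window_ms = c(-200, 800),
                        bursts = burst_spec(20, 300), noise_sd = 1, seed = 2)
  expect_identical(pad_edges(ep, 0)$data, ep$data)
  padded <- pad_edges(ep, 200)
  expect_identical(dim(padded$data)[3], dim(ep$data)[3] + 200L)  # 100/side
  expect_equal(padded$time_ms[1], -400)
  bank <- wavelet_bank(c(15, 20, 25), fs = 500)
  r <- chop_edges(tf_transform(padded, bank), 200)
  expect_equal(r$time_ms, ep$time_ms)
  # mirror continuity: padded trace continuous at the seam
  expect_equal(padded$data[1, 1, 101], ep$data[1, 1, 1])
  expect_equal(padded$data[1, 1, 100], ep$data[1, 1, 2])
  expect_error(pad_edges(ep, -5), "non-negative")
})

test_that("mirror padding reduces the low-frequency edge error below the unpadded distortion", {
  fs <- 250
  t_full <- seq(-1.2, 1.8, by = 1 / fs) * 1000
  f0 <- 10
  trace_of <- function(tms) cos(2 * pi * f0 * tms / 1000 + 0.7)
  bank <- wavelet_bank(10, cycles = 7, fs = fs)
  # ground truth: transform of the longer signal, cut to the short window
  long_ep <- epochs_from_traces(trace_of(t_full), fs, onset_ms = -1200)
  truth <- tf_transform(long_ep, bank)
  keep <- which(t_full >= -400 & t_full <= 1000 + 1e-9)
  truth_vals <- truth$values[1, 1, keep]
  t_short <- t_full[keep]
  short_ep <- epochs_from_traces(trace_of(t_short), fs, onset_ms = -400)
  unpadded <- tf_transform(short_ep, bank)$values[1, 1, ]
  padded <- chop_edges(
    tf_transform(pad_edges(short_ep, recommend_padding(f0)), bank),
    recommend_padding(f0))$values[1, 1, ]
  edge <- 1:25   # first 100 ms at each edge
  n <- length(t_short)
  err_unpadded <- max(abs(unpadded[c(edge, n + 1 - edge)] -
                          truth_vals[c(edge, n + 1 - edge)]))
  err_padded <- max(abs(padded[c(edge, n + 1 - edge)] -
                        truth_vals[c(edge, n + 1 - edge)]))
  expect_lt(err_padded, err_unpadded)
})

test_that("baseline modes: window mean zero, flat surfaces, degenerate errors", {
  r <- chop_edges(make_result(), 300)
  sub <- baseline_correct(r, "subtractive")   # default: full pre-stimulus
  idx <- which(sub$time_ms >= -200 & sub$time_ms <= 0)
  bl_means <- apply(sub$values[, , idx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl_means)), 1e-12)
  expect_equal(sub$baseline$mode, "subtractive")
  # flat surface: divisive -> 1, subtractive-normalized -> 0
  flat <- r
  flat$values[] <- 4.2
  expect_true(all(abs(baseline_correct(flat, "divisive",
                                       window = c(-200, 0))$values - 1) < 1e-12))
  expect_true(all(abs(baseline_correct(flat, "subtractive_normalized",
                                       window = c(-200, 0))$values) < 1e-12))
  zero <- r
  zero$values[] <- 0
  expect_error(baseline_correct(zero, "divisive", window = c(-200, 0)),
               "degenerate")
  cx <- tf_transform(simulate_epochs(2, 1, fs = 250,
                                     window_ms = c(-200, 800),
                                     bursts = list(), seed = 1),
                     wavelet_bank(20, fs = 250), measure = "complex")
  expect_error(baseline_correct(cx, "subtractive", window = c(-100, 0)),
               "amplitude or power")
  expect_error(baseline_correct(r, "subtractive", window = c(5000, 6000)),
               "outside")
})

test_that("baseline idempotence and equivariance under rescaling", {
  r <- chop_edges(make_result(), 300)
  once <- baseline_correct(r, "subtractive", window = c(-200, 0))
  twice <- baseline_correct(once, "subtractive", window = c(-200, 0))
  expect_lt(max(abs(once$values - twice$values)), 1e-12)
  # divisive is invariant to global rescaling; subtractive scales with it
  scaled <- r
  scaled$values <- r$values * 3.7
  expect_rel_equal(
    baseline_correct(scaled, "divisive", window = c(-200, 0))$values,
    baseline_correct(r, "divisive", window = c(-200, 0))$values, 1e-12)
  expect_rel_equal(
    baseline_correct(scaled, "subtractive", window = c(-200, 0))$values,
    3.7 * baseline_correct(r, "subtractive", window = c(-200, 0))$values,
    1e-12)
})

test_that("dB conversion is measure-consistent", {
  r <- make_result()
  p <- r
  p$values <- r$values^2
  p$measure <- "power"
  db_a <- to_db(r)
  db_p <- to_db(p)
  expect_lt(max(abs(db_a$values - db_p$values)), 1e-10)
  expect_identical(db_a$measure, "dB")
  one <- r; one$values[] <- 1; one$measure <- "power"
  expect_true(all(to_db(one)$values == 0))
  ten <- r; ten$values[] <- 10
  expect_true(all(abs(to_db(ten)$values - 20) < 1e-12))
  neg <- baseline_correct(chop_edges(r, 300), "subtractive")
  expect_error(to_db(neg), "divisive")
})

test_that("channel averaging: oracle mean, identities, commutation with baseline", {
  r <- chop_edges(make_result(), 300)
  avg <- average_channels(r, c("Fp1", "Fpz", "Fp2"))
  brute <- (r$values[1, , ] + r$values[2, , ] + r$values[3, , ]) / 3
  expect_lt(max(abs(avg$values[1, , ] - brute)), 1e-13)
  one <- average_channels(r, "Fpz")
  expect_equal(one$values[1, , ], r$values[2, , ])
  opp <- r
  opp$values[2, , ] <- -opp$values[1, , ]
  expect_lt(max(abs(average_channels(opp, c("Fp1", "Fpz"))$values)), 1e-13)
  expect_error(average_channels(r, character(0)), "at least one")
  expect_error(average_channels(r, c("Fp1", "Nope")), "Nope")
  # averaging and subtractive baseline commute (both linear)
  a <- baseline_correct(average_channels(r, c("Fp1", "Fp2")),
                        "subtractive", window = c(-200, 0))
  b <- average_channels(baseline_correct(r, "subtractive",
                                         window = c(-200, 0)),
                        c("Fp1", "Fp2"))
  expect_lt(max(abs(a$values - b$values)), 1e-12)
})
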