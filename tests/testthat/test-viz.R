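viz_result <- function(seed = 41, condition = "DG") {
  ep <- simulate_epochs(4, 3, fs = 250, window_ms = c(-500, 1500),
                        bursts = burst_spec(35, 300, amplitude = 3,
                                            channels = c("Fp1", "Fp2")),
                        noise_sd = 0.3, channels = c("Fp1", "Fpz", "Fp2"),
                        condition = condition, seed = seed)
  chop_edges(tf_transform(ep, wavelet_bank(seq(20, 50, 2), fs = 250)), 300)
}

test_that("condition differences: zero self-difference, inverse, brute-force match", {
  a <- viz_result(41, "DG")
  b <- viz_result(42, "AG")
  expect_true(all(diff_conditions(a, a)$values == 0))
  d <- diff_conditions(a, b)
  expect_identical(d$condition, "DG - AG")
  expect_lt(max(abs((d$values + b$values) - a$values)), 1e-15)
  expect_lt(max(abs(d$values - (a$values - b$values))), 1e-15)
  mismatch <- chop_edges(b, 100)
  expect_error(diff_conditions(a, mismatch), "incompatible")
  pw <- a; pw$measure <- "power"
  expect_error(diff_conditions(a, pw), "measures differ")
})

test_that("time-frequency raster peaks at the injected burst locus", {
  r <- baseline_correct(viz_result(), "subtractive", window = c(-200, 0))
  p <- plot_tf(r, "Fp2")
  expect_s3_class(p, "ggplot")
  df <- p$data
  peak <- df[which.max(df$value), ]
  expect_lt(abs(peak$frequency - 35), 3)
  expect_lt(abs(peak$time - 300), wavelet_sigma(35) * 1000 + 20)
  # self-difference renders a uniformly zero raster
  z <- plot_tf(diff_conditions(r, r), "Fp2")
  expect_true(all(z$data$value == 0))
})

test_that("plot range and scale validation", {
  r <- viz_result()
  expect_error(plot_tf(r, "Fp2", zlim = c(3, 1)), "min < max")
  expect_error(plot_tf(r, "Fp2", time_range = c(5000, 6000)), "outside")
  expect_error(plot_tf(r, "Fp2", freq_range = c(100, 200)), "outside")
  expect_error(plot_tf(r, "Nope"), "unknown channel")
  cx <- viz_result()
  cx$measure <- "complex"
  expect_error(plot_tf(cx, "Fp2"), "complex")
  r$sem <- NULL
  expect_error(plot_tf(r, "Fp2", show_sem = TRUE), "keep_sem")
})

test_that("SEM contour plots build when the sibling tensor exists", {
  ep <- simulate_epochs(6, 1, fs = 250, window_ms = c(-500, 1500),
                        bursts = burst_spec(35, 300, amplitude = 3),
                        noise_sd = 0.5, seed = 44)
  r <- chop_edges(tf_transform(ep, wavelet_bank(seq(25, 45, 5), fs = 250),
                               keep_sem = TRUE), 300)
  expect_identical(dim(r$sem), dim(r$values))
  p <- plot_tf(r, 1, show_sem = TRUE)
  expect_s3_class(p, "ggplot")
})

test_that("electrode layouts parse from .ced, .sfp and .elp dialects", {
  td <- withr::local_tempdir()
  ced <- file.path(td, "m.ced")
  writeLines(c("Number\tlabels\ttheta\tradius",
               "1\tCz\t0\t0",
               "2\tFpz\t0\t0.4",
               "3\tT8\t90\t0.4"), ced)
  lay <- read_layout(ced)
  expect_s3_class(lay, "electrode_layout")
  expect_equal(lay$x[lay$label == "Cz"], 0)
  expect_equal(lay$y[lay$label == "Fpz"], 0.8, tolerance = 1e-12)  # nose = +y
  expect_equal(lay$x[lay$label == "T8"], 0.8, tolerance = 1e-12)   # right ear = +x
  sfp <- file.path(td, "m.sfp")
  writeLines(c("fidnz\t0.9\t0\t-0.1",
               "Cz\t0\t0\t1",
               "Fpz\t0.95\t0\t0.31",
               "C3\t0\t0.95\t0.31"), sfp)
  lay2 <- read_layout(sfp)
  expect_identical(lay2$label, c("Cz", "Fpz", "C3"))   # fiducial dropped
  expect_equal(lay2$y[2], 0.8, tolerance = 0.01)        # frontal -> nose side
  expect_lt(lay2$x[3], 0)                               # left hemisphere -> -x
  elp <- file.path(td, "m.elp")
  writeLines(c("EEG\tCz\t0\t0", "EEG\tFpz\t72\t0", "EEG\tOz\t-72\t0"), elp)
  lay3 <- read_layout(elp)
  expect_equal(lay3$y[2], 0.8, tolerance = 1e-12)
  expect_equal(lay3$y[3], -0.8, tolerance = 1e-12)
  expect_error(read_layout(file.path(td, "m.xyz")), "unsupported")
  expect_warning(electrode_layout("X", 2, 0), "outside the unit disc")
})

test_that("scalp maps: field equals window_mean, constants map to constants", {
  r <- baseline_correct(viz_result(), "subtractive", window = c(-200, 0))
  lay <- layout_1020()
  lay <- lay[lay$label %in% r$channels, ]
  class(lay) <- c("electrode_layout", "data.frame")
  p <- plot_topo2d(r, lay, time_window = c(250, 350), freq_window = c(30, 40))
  fld <- attr(p, "field")
  manual <- vapply(seq_along(r$channels), function(ch) {
    window_mean(r, c(250, 350), c(30, 40), ch)
  }, 0)
  expect_equal(fld$values, manual, tolerance = 1e-12)
  # single-point selection equals the raw tensor entry per channel
  ti <- which.min(abs(r$time_ms - 300))
  fi <- which.min(abs(r$frequencies - 36))
  p2 <- plot_topo2d(r, lay, time = r$time_ms[ti],
                    frequency = r$frequencies[fi])
  expect_equal(attr(p2, "field")$values, r$values[, fi, ti],
               tolerance = 1e-12)
  # constant per-channel values interpolate to that constant inside the disc
  flat <- r
  flat$values[] <- 2.5
  p3 <- plot_topo2d(flat, lay, time_window = c(250, 350),
                    freq_window = c(30, 40))
  grid <- attr(p3, "field")$grid
  expect_lt(max(abs(grid[!is.na(grid)] - 2.5)), 1e-6)
  expect_error(plot_topo2d(r, lay[-1, ], time = 300, frequency = 35),
               "missing from the layout")
  expect_error(plot_topo2d(r, lay), "time")
})

test_that("scalp-map series produce one panel per requested point", {
  r <- viz_result()
  lay <- layout_1020()
  lay <- lay[lay$label %in% r$channels, ]
  class(lay) <- c("electrode_layout", "data.frame")
  p <- plot_topo2d(r, lay, frequency = 35, times = c(250, 300, 350))
  fld <- attr(p, "field")
  expect_length(fld, 3)
  expect_identical(fld[[2]]$tag, "300 ms")
  ti <- which.min(abs(r$time_ms - 300))
  fi <- which.min(abs(r$frequencies - 35))
  expect_equal(fld[[2]]$values, r$values[, fi, ti], tolerance = 1e-12)
})
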