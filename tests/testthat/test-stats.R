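make_tf <- function(seed, condition = "DG", subject = "S01") {
  ep <- simulate_epochs(3, 2, fs = 250, window_ms = c(-500, 1500),
                        bursts = burst_spec(35, 300, amplitude = 2),
                        noise_sd = 0.5, channels = c("Fp1", "Fp2"),
                        condition = condition, subject = subject, seed = seed)
  chop_edges(tf_transform(ep, wavelet_bank(seq(25, 45, 5), fs = 250)), 300)
}

test_that("window_mean equals the brute-force double-loop mean", {
  r <- make_tf(31)
  wm <- window_mean(r, c(250, 350), c(30, 40), "Fp2")
  fi <- snap_idx(r$frequencies, 30, 40)
  ti <- snap_idx(r$time_ms, 250, 350)
  acc <- 0
  for (f in fi) for (t in ti) acc <- acc + r$values[2, f, t]
  expect_equal(wm, acc / (length(fi) * length(ti)), tolerance = 1e-14)
})

test_that("window_mean handles constants, single points and bad windows", {
  r <- make_tf(32)
  flat <- r
  flat$values[] <- 3.25
  expect_identical(window_mean(flat, c(-100, 1100), c(25, 45), "Fp1"), 3.25)
  expect_identical(window_mean(flat, c(0, 0), c(30, 30), 1), 3.25)
  # single-point windows pick the exact grid entry
  ti <- which.min(abs(r$time_ms - 300))
  fi <- which.min(abs(r$frequencies - 35))
  expect_identical(window_mean(r, c(300, 300), c(35, 35), "Fp1"),
                   r$values[1, fi, ti])
  expect_error(window_mean(r, c(2000, 2100), c(30, 40), 1), "valid range")
  expect_error(window_mean(r, c(250, 350), c(100, 200), 1), "valid range")
  expect_error(window_mean(r, c(250, 350), c(30, 40), "Pz"), "unknown channel")
  expect_error(window_mean(r, c(250, 350), c(30, 40)), "multi-channel")
})

make_results <- function() {
  out <- list()
  seed <- 0
  for (s in c("S01", "S02", "S03")) {
    out[[s]] <- list()
    for (cn in c("DG", "AG")) {
      seed <- seed + 1
      out[[s]][[cn]] <- make_tf(seed, condition = cn, subject = s)
    }
  }
  out
}

test_that("export table shape, ordering and full-precision parse-back", {
  res <- make_results()
  td <- withr::local_tempdir()
  tab <- export_stats(res, c(250, 350), c(30, 40),
                      path = file.path(td, "out.tab"))
  expect_identical(dim(tab), c(3L, 5L))    # 3 subjects x (1 + 2 cond * 2 chan)
  expect_identical(names(tab),
                   c("subject", "DG_Fp1", "DG_Fp2", "AG_Fp1", "AG_Fp2"))
  back <- read_stats(file.path(td, "out.tab"))
  expect_identical(names(back), names(tab))
  for (col in names(tab)[-1]) {
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
    recomputed <- vapply(c("S01", "S02", "S03"), function(s) {
      cn <- sub("_.*", "", col); ch <- sub(".*_", "", col)
      window_mean(res[[s]][[cn]], c(250, 350), c(30, 40), ch)
    }, 0)
    expect_equal(back[[col]], unname(recomputed), tolerance = 1e-12)
  }
})

test_that("export selections and error contracts", {
  res <- make_results()
  td <- withr::local_tempdir()
  tab <- export_stats(res, c(250, 350), c(30, 40), subjects = c("S02"),
                      conditions = "DG", channels = "Fp2",
                      path = file.path(td, "one.tab"))
  expect_identical(dim(tab), c(1L, 2L))
  expect_error(export_stats(res, c(250, 350), c(30, 40),
                            subjects = character(0), path = td),
               "at least one")
  expect_error(export_stats(res, c(250, 350), c(30, 40),
                            subjects = c("S01", "S99"), path = td), "S99")
  broken <- res
  broken$S02$AG <- chop_edges(broken$S02$AG, 100)
  expect_error(export_stats(broken, c(250, 350), c(30, 40), path = td),
               "incompatible.*S02")
  missing_cell <- res
  missing_cell$S03$AG <- NULL
  expect_error(export_stats(missing_cell, c(250, 350), c(30, 40), path = td),
               "missing result")
  # directory target lands in that folder (the Statistics subfolder use-case)
  stats_dir <- file.path(td, "Statistics")
  dir.create(stats_dir)
  t2 <- export_stats(res, c(250, 350), c(30, 40), path = stats_dir)
  expect_true(startsWith(attr(t2, "path"), stats_dir))
  expect_true(file.exists(attr(t2, "path")))
})

test_that("window-mean linearity: export of a difference equals difference of exports", {
  res <- make_results()
  td <- withr::local_tempdir()
  diffres <- list()
  for (s in names(res)) {
    diffres[[s]] <- list(D = diff_conditions(res[[s]]$DG, res[[s]]$AG))
  }
  td_tab <- export_stats(diffres, c(250, 350), c(30, 40),
                         path = file.path(td, "d.tab"))
  full <- export_stats(res, c(250, 350), c(30, 40),
                       path = file.path(td, "f.tab"))
  expect_equal(td_tab$D_Fp1, full$DG_Fp1 - full$AG_Fp1, tolerance = 1e-12)
  expect_equal(td_tab$D_Fp2, full$DG_Fp2 - full$AG_Fp2, tolerance = 1e-12)
})
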