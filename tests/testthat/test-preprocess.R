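test_that("common median reference subtracts the per-sample median", {
  ch3 <- data.frame(name = c("a", "b", "c"), region = "X", white_matter = FALSE)
  rec <- pain_recording(matrix(c(1, 2, 3), 3, 1), 1000, ch3)
  out <- common_median_reference(rec)
  expect_equal(as.vector(out$samples), c(-1, 0, 1))

  rec2 <- pain_recording(matrix(5, 3, 10), 1000, ch3)
  expect_true(all(common_median_reference(rec2)$samples == 0))

  # odd channel count: per-sample median of the output is exactly zero
  set.seed(3)
  ch5 <- data.frame(name = paste0("c", 1:5), region = "X", white_matter = FALSE)
  rec5 <- pain_recording(matrix(rnorm(5000), 5, 1000), 1000, ch5)
  ref <- common_median_reference(rec5)
  expect_equal(max(abs(apply(ref$samples, 2, median))), 0)
  # idempotent
  ref2 <- common_median_reference(ref)
  expect_lt(max(abs(ref2$samples - ref$samples)), 1e-9)
  # single channel refuses
  rec1 <- pain_recording(matrix(0, 1, 10), 1000,
                         data.frame(name = "a", region = "X",
                                    white_matter = FALSE))
  expect_error(common_median_reference(rec1), ">= 2 channels")
})

test_that("epoch extraction slices exactly and drops incomplete trials", {
  set.seed(4)
  ch <- data.frame(name = c("a", "b"), region = "X", white_matter = FALSE)
  n <- 120000
  rec <- pain_recording(matrix(rnorm(2 * n), 2, n), 1000, ch)
  tt <- data.frame(patient_id = "P1", trial_id = 1:3, temperature = 45,
                   hand_on = c(500L, 20000L, 60000L),
                   hand_off = c(10500L, 30000L, 70000L),
                   binary_response = c(0, 1, 1), vas = c(0, 2, 3))
  expect_message(ep <- extract_epochs(rec, tt, "hand_on"), "dropping 1")
  expect_equal(dim(ep$data), c(2, 2, 4000))        # trial at 500 dropped
  expect_equal(ep$dropped_trials, 1L)
  # epoch values equal the recording slice exactly (0-based indices)
  expect_identical(ep$data[1, 1, ], rec$samples[1, (20000 - 3000 + 1):(20000 + 1000)])
  expect_equal(range(ep$t_axis), c(-3000, 1000 - 1))
})

test_that("threshold rules flag each artifact class with its reason code", {
  fs <- 1000; n <- 4000
  set.seed(9)
  base <- painhfa:::synth_background(n, fs)
  flat <- rep(0, n)
  satu <- base; satu[2000:2100] <- 6553
  step <- base; step[2500] <- step[2500] + 400     # 400 uV/ms at 1 kHz
  line <- base + 30 * sin(2 * pi * 60 * seq_len(n) / fs)
  ep <- make_epochs(array(c(rbind(base, flat, satu, step, line)),
                          c(5, 1, n))[ , , , drop = FALSE], fs)
  # oracle for the slope rule
  expect_gt(max(abs(diff(step))) * fs / 1000, 300)
  expect_lt(max(abs(diff(base))) * fs / 1000, 300)
  ep <- detect_artifacts(ep)
  expect_false(ep$reject[1, 1])                               # clean
  expect_match(ep$reject_reason[2, 1], "flat")
  expect_match(ep$reject_reason[3, 1], "saturation")
  expect_match(ep$reject_reason[4, 1], "transient")
  expect_match(ep$reject_reason[5, 1], "line_noise")
})

test_that("MAD outlier rule matches a brute-force oracle", {
  set.seed(10)
  n_tr <- 12; n <- 1000
  dat <- array(rnorm(n_tr * n), c(n_tr, 1, n))
  dat[4, 1, 500] <- 50
  ep <- make_epochs(dat, 500)
  out <- mad_outlier_flag(ep, k = 3)
  # brute force: pooled channel median/MAD, flag epochs containing exceedances
  pool <- as.vector(dat[, 1, ])
  flags <- vapply(seq_len(n_tr), function(i)
    any(abs(dat[i, 1, ] - median(pool)) > 3 * mad(pool)), logical(1))
  expect_equal(out$reject[, 1], flags)
  expect_true(out$reject[4, 1])
  expect_match(out$reject_reason[4, 1], "spike_outlier")

  # identical epochs everywhere: degenerate MAD, nothing flagged
  same <- make_epochs(array(7, c(5, 1, 100)), 500)
  expect_false(any(mad_outlier_flag(same, k = 3)$reject))
  # infinite k disables the rule
  expect_false(any(mad_outlier_flag(ep, k = Inf)$reject))
})

test_that("downsampling halves the sample count and preserves the passband", {
  fs <- 1000; n <- 4000
  tt <- (seq_len(n) - 1) / fs             # sample i sits at (i-1)/fs, like t_axis
  dat <- array(NA_real_, c(2, 1, n))
  dat[1, 1, ] <- 3.7                      # DC
  dat[2, 1, ] <- sin(2 * pi * 40 * tt)    # well inside the passband
  ep <- make_epochs(dat, fs)
  ds <- downsample(ep, 500)
  expect_equal(dim(ds$data)[3], 2000)
  expect_equal(ds$fs, 500)
  interior <- 200:1800
  expect_lt(max(abs(ds$data[1, 1, interior] - 3.7)), 3.7 * 0.01)
  truth <- sin(2 * pi * 40 * (ds$t_axis + 3000) / 1000)
  expect_lt(max(abs(ds$data[2, 1, interior] - truth[interior])), 0.01)
  expect_error(downsample(ep, 400), "integer")
})

test_that("the stage contract rejects out-of-order operations", {
  ep <- make_epochs(array(rnorm(2000), c(1, 1, 2000)), 500)
  env <- bandpass_hilbert_amplitude(ep)
  expect_error(detect_artifacts(env), "raw uV")
  expect_error(mad_outlier_flag(env), "raw uV")
})

test_that("rejection masks export as a tidy table", {
  ep <- make_epochs(array(0, c(2, 1, 1000)), 500)
  ep <- detect_artifacts(ep)
  tab <- rejection_table(ep)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$reason == "flat"))
})
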