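test_that("identical seeds give bit-identical studies", {
  args <- list(n_patients = 2,
               regions = data.frame(region = "Amyg", n_patients = 2),
               n_trials = 5, seed = 42)
  s1 <- do.call(simulate_study, args)
  s2 <- do.call(simulate_study, args)
  expect_identical(s1$recordings$P01$samples, s2$recordings$P01$samples)
  expect_identical(s1$recordings$P02$samples, s2$recordings$P02$samples)
  expect_identical(as.data.frame(s1$trials), as.data.frame(s2$trials))
})

test_that("session timing bookkeeping is exact", {
  s <- simulate_study(n_patients = 1,
                      regions = data.frame(region = "Amyg", n_patients = 1),
                      n_trials = 6, seed = 1)
  cfg <- s$config
  expected <- (cfg$lead_in_s + 6 * (cfg$hand_on_s + cfg$iti_s) + cfg$tail_s) *
    cfg$fs
  expect_equal(ncol(s$recordings$P01$samples), expected)
  tt <- s$trials
  expect_true(all(tt$hand_off - tt$hand_on == cfg$hand_on_s * cfg$fs))
  expect_true(all(diff(tt$hand_on) == (cfg$hand_on_s + cfg$iti_s) * cfg$fs))
  # baseline window of each trial is clear of the previous stimulation
  expect_true(all(tt$hand_on[-1] - 3 * cfg$fs >= tt$hand_off[-6]))
})

test_that("the ground-truth effect map covers every region, zeros included", {
  s <- simulate_study(n_patients = 3,
                      regions = data.frame(region = c("Amyg", "Hipp", "OFC"),
                                           n_patients = c(3, 3, 3)),
                      n_trials = 4, seed = 2,
                      effects = data.frame(region = "Amyg", event = "hand_on",
                                           effect = 1))
  em <- s$truth$effect_map
  expect_setequal(unique(em$region), c("Amyg", "Hipp", "OFC"))
  expect_equal(nrow(em), 6)                                  # 3 regions x 2 events
  expect_equal(em$effect[em$region == "Amyg" & em$event == "hand_on"], 1)
  expect_true(all(em$effect[em$region != "Amyg"] == 0))
  expect_error(
    simulate_study(n_patients = 3,
                   regions = data.frame(region = "Amyg", n_patients = 3),
                   n_trials = 4, seed = 2,
                   effects = data.frame(region = "Nope", event = "hand_on",
                                        effect = 1)),
    "unknown regions")
})

test_that("injected artifacts exceed their thresholds and are all logged", {
  kinds <- c("line_noise", "transient", "flat", "saturation", "spike_outlier")
  s <- simulate_study(n_patients = 2,
                      regions = data.frame(region = c("Amyg", "Hipp"),
                                           n_patients = c(2, 2)),
                      n_trials = 8, seed = 31, artifact_kinds = kinds)
  log <- s$truth$artifact_log
  expect_equal(nrow(log), 2 * length(kinds))          # one set per patient
  expect_setequal(unique(log$kind), kinds)
  expect_true(all(c("patient_id", "trial_id", "event", "channel") %in%
                    names(log)))
  # verify amplitudes directly in the raw recordings
  for (i in seq_len(nrow(log))) {
    rec <- s$recordings[[log$patient_id[i]]]
    tt <- s$trials[s$trials$patient_id == log$patient_id[i], ]
    tr <- tt[tt$trial_id == log$trial_id[i], ]
    ev <- if (log$event[i] == "hand_on") tr$hand_on else tr$hand_off
    j <- match(log$channel[i], rec$channels$name)
    x <- rec$samples[j, (ev - 3000 + 1):(ev + 1000)]
    switch(log$kind[i],
      saturation = expect_true(any(x == 6553)),
      flat = expect_lt(var(x), 1),
      transient = expect_gt(max(abs(diff(x))), 300),
      line_noise = {
        pw <- painhfa:::welch_psd(x, rec$fs)
        expect_gt(pw$psd[which.min(abs(pw$freq - 60))], 100)
      },
      spike_outlier = expect_gt(max(abs(x - median(x))), 3 * mad(x)))
  }
  expect_error(inject_artifacts(s$recordings$P01, s$trials, "drift"),
               "unknown artifact kind")
})

test_that("null data shows no yes/no envelope difference in the effect window", {
  fx <- small_proc()
  # Hipp carries no injected effect in the shared fixture
  f0 <- build_features(fx$proc, "Hipp", "hand_on", c(0, 500))
  d <- abs(mean(f0$A[f0$y_binary == 1]) - mean(f0$A[f0$y_binary == 0]))
  se <- sd(f0$A) * sqrt(1 / sum(f0$y_binary == 1) + 1 / sum(f0$y_binary == 0))
  expect_lt(d, 3 * se)
  # Amyg carries a 1.5 z-unit effect: the difference is visible
  f1 <- build_features(fx$proc, "Amyg", "hand_on", c(0, 500))
  expect_gt(mean(f1$A[f1$y_binary == 1]), mean(f1$A[f1$y_binary == 0]))
})

test_that("VAS ratings stay on scale and concentrate at the low end", {
  s <- simulate_study(n_patients = 8,
                      regions = data.frame(region = "Amyg", n_patients = 3),
                      n_trials = 20, seed = 77)
  v <- s$trials$vas
  expect_true(all(v >= 0 & v <= 10))
  expect_true(all(v == round(v)))
  expect_gt(mean(v <= 4), 0.7)          # most ratings between 0 and 4
})
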