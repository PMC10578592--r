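# shared fixtures, built in code at test time

# minimal epoch container for unit tests that bypass extraction
make_epochs <- function(data, fs, t0_ms = -3000, event = "hand_on",
                        channels = NULL, ref = NULL) {
  if (length(dim(data)) == 2) data <- array(data, c(1, dim(data)))
  d <- dim(data)
  if (is.null(channels))
    channels <- data.frame(name = paste0("ch", seq_len(d[2])),
                           atlas_label = NA_character_, region = "X",
                           white_matter = FALSE, stringsAsFactors = FALSE)
  structure(list(data = data, fs = fs,
                 t_axis = t0_ms + (seq_len(d[3]) - 1) / fs * 1000,
                 event = event,
                 trials = data.frame(trial_id = seq_len(d[1])),
                 channels = channels,
                 reject = matrix(FALSE, d[1], d[2]),
                 reject_reason = matrix("", d[1], d[2]),
                 ref = ref, dropped_trials = integer(0),
                 units = "uV", envelope = FALSE, smoothed = FALSE,
                 zscored = FALSE),
            class = "pain_epochs")
}

# channel table mirroring the reference cohort's per-region counts
table_fixture_channels <- function(tbl = region_table()) {
  rows <- list()
  for (i in seq_len(nrow(tbl))) {
    n_pat <- tbl$n_patients[i]
    n_con <- tbl$n_contacts[i]
    # spread contacts over patients as evenly as the totals allow
    per <- rep(n_con %/% n_pat, n_pat)
    extra <- n_con - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
    for (p in seq_len(n_pat)) {
      if (per[p] == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("%s_P%02d_%d", tbl$region[i], p, seq_len(per[p])),
        atlas_label = sprintf("%s_L_1_%d", tbl$region[i], seq_len(per[p])),
        region = tbl$region[i], white_matter = FALSE,
        patient_id = sprintf("P%02d", p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# small processed study shared by several test files (built once per run)
local_proc_cache <- new.env(parent = emptyenv())
small_proc <- function() {
  if (is.null(local_proc_cache$proc)) {
    study <- simulate_study(
      n_patients = 4,
      regions = data.frame(region = c("Amyg", "Hipp"), n_patients = c(4, 4)),
      n_trials = 12, channels_per_region = 2, wm_channels = 1, seed = 2024,
      effects = data.frame(region = "Amyg", event = "hand_on", effect = 1.5))
    local_proc_cache$study <- study
    local_proc_cache$proc <- process_study(study, events = "hand_on")
  }
  list(study = local_proc_cache$study, proc = local_proc_cache$proc)
}

# feature table with known structure for model-level tests
synth_features <- function(n_pat = 8, n_tr = 20, beta = 0, seed = 1,
                           binary = TRUE) {
  set.seed(seed)
  df <- data.frame(
    patient_id = rep(sprintf("P%02d", seq_len(n_pat)), each = n_tr),
    trial_id = rep(seq_len(n_tr), n_pat),
    temperature = sample(seq(43, 47, by = 1), n_pat * n_tr, replace = TRUE),
    A = rnorm(n_pat * n_tr))
  eta <- beta * df$A
  df$y_binary <- rbinom(nrow(df), 1, plogis(eta))
  df$y_vas <- pmin(10, pmax(0, 2 + beta * df$A + rnorm(nrow(df))))
  class(df) <- c("pain_features", "data.frame")
  df
}
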