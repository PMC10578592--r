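#' Broadband high-frequency amplitude via filter-Hilbert
#'
#' Band-passes each trial-by-channel epoch with the zero-phase (squared-
#' magnitude) response of the designed Butterworth filter, applied
#' spectrally, and takes the magnitude of the analytic signal; both steps
#' share one FFT pair per epoch. Filtering operates on the full epoch
#' (including the baseline span), so the -1000..1000 ms analysis window sits
#' far from the boundary; the outer 100 ms of the epoch is excluded from any
#' downstream statistic.
#'
#' @param ep `pain_epochs` (microvolts; typically after downsampling).
#' @param band passband in Hz.
#' @param order filter order of the bandpass (zero-phase application doubles
#'   the effective attenuation).
#' @return `pain_epochs` whose `data` holds the HFA envelope (amplitude
#'   units, non-negative), flagged `envelope = TRUE`.
#' @export
bandpass_hilbert_amplitude <- function(ep, band = c(70, 150), order = 4) {
  stopifnot(inherits(ep, "pain_epochs"))
  if (band[2] >= ep$fs / 2)
    stop("band upper edge (", band[2], " Hz) must be below Nyquist (",
         ep$fs / 2, " Hz)")
  bf <- signal::butter(max(1L, order %/% 2L), band / (ep$fs / 2), type = "pass")
  d <- dim(ep$data)
  n <- d[3]
  H2 <- zero_phase_mag2(bf, n, ep$fs)
  hmask <- numeric(n)                      # analytic-signal doubling mask
  if (n %% 2 == 0) { hmask[c(1, n / 2 + 1)] <- 1; hmask[2:(n / 2)] <- 2 }
  else { hmask[1] <- 1; hmask[2:((n + 1) / 2)] <- 2 }
  G <- H2 * hmask
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      ep$data[i, j, ] <-
        Mod(stats::fft(stats::fft(ep$data[i, j, ]) * G, inverse = TRUE)) / n
  ep$envelope <- TRUE
  ep$band <- band
  ep$units <- "amplitude"
  ep
}

#' Smooth the HFA envelope with a moving average
#'
#' Centered moving-average filter; edges are handled by shrinking the window
#' to the available samples.
#'
#' @param ep envelope `pain_epochs`.
#' @param window window length in ms (300 ms at 500 Hz = 150 samples).
#' @return smoothed `pain_epochs`.
#' @export
smooth_envelope <- function(ep, window = 300) {
  stopifnot(inherits(ep, "pain_epochs"), ep$envelope)
  if (window <= 0) stop("smoothing window must be positive")
  w <- ms_to_samples(window, ep$fs)
  d <- dim(ep$data)
  if (w >= d[3]) stop("smoothing window must be shorter than the epoch")
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      ep$data[i, j, ] <- moving_average(ep$data[i, j, ], w)
  ep$smoothed <- TRUE
  ep$smoothing_window <- window
  ep
}

#' Baseline z-scoring of the HFA envelope
#'
#' Normalises each trial-by-channel epoch by the mean and standard deviation
#' of its own baseline segment (-3 to -2 s relative to the event by default,
#' trimmed by `edge_trim` ms where it touches the epoch edge). A zero
#' baseline SD flags the entry as rejected (`zero_baseline_sd`) instead of
#' producing infinities.
#'
#' @param ep smoothed envelope `pain_epochs`.
#' @param baseline baseline window in ms relative to the event.
#' @param edge_trim ms excluded where the baseline abuts the epoch edge
#'   (filter edge transients).
#' @return z-scored `pain_epochs` (`zscored = TRUE`), with per-trial,
#'   per-channel `baseline_mu` and `baseline_sd` matrices attached.
#' @export
zscore_baseline <- function(ep, baseline = c(-3000, -2000), edge_trim = 100) {
  stopifnot(inherits(ep, "pain_epochs"), ep$envelope)
  lo <- max(baseline[1], ep$t_axis[1] + edge_trim)
  sel <- ep$t_axis >= lo & ep$t_axis < baseline[2]
  if (!any(sel)) stop("baseline segment not contained in the epoch")
  d <- dim(ep$data)
  mu <- sd_ <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      b <- ep$data[i, j, sel]
      mu[i, j] <- mean(b)
      sd_[i, j] <- stats::sd(b)
      if (sd_[i, j] == 0) {
        ep <- add_reason(ep, i, j, "zero_baseline_sd")
      } else {
        ep$data[i, j, ] <- (ep$data[i, j, ] - mu[i, j]) / sd_[i, j]
      }
    }
  }
  ep$baseline_mu <- mu
  ep$baseline_sd <- sd_
  ep$baseline_window <- c(lo, baseline[2])
  ep$zscored <- TRUE
  ep$units <- "z"
  ep
}

#' Run the full preprocessing + HFA chain on a study
#'
#' For each patient and event: common-median reference, epoch extraction,
#' threshold artifact detection (amplifier units, native rate), MAD outlier
#' flagging, downsampling, filter-Hilbert envelope, smoothing and baseline
#' z-scoring. Region inclusion (white-matter and minimum-patient rules) is
#' evaluated on the pooled channel table.
#'
#' @param study `pain_study` (or a list with `recordings` and `trials`).
#' @param events events to epoch.
#' @param span epoch span in ms.
#' @param target_fs analysis sampling rate.
#' @param band HFA passband (Hz).
#' @param smooth_ms envelope smoothing window (ms).
#' @param baseline baseline window (ms).
#' @param min_patients region inclusion threshold.
#' @param mad_k MAD outlier threshold.
#' @param regions optional restriction: only channels in these regions are
#'   epoched and analysed (the common-median reference always uses every
#'   channel). Default: all regions passing the inclusion filter.
#' @return object of class `pain_hfa_study`: per-patient, per-event z-scored
#'   envelope epochs (analysis channels only) plus the pooled channel table
#'   and inclusion mask.
#' @export
process_study <- function(study, events = c("hand_on", "hand_off"),
                          span = c(-3000, 1000), target_fs = 500,
                          band = c(70, 150), smooth_ms = 300,
                          baseline = c(-3000, -2000), min_patients = 3,
                          mad_k = 3, regions = NULL) {
  chans <- study_channels(study)
  incl <- filter_regions(chans, chans$patient_id, min_patients = min_patients)
  use_regions <- regions %||% incl$regions
  patients <- list()
  for (pid in names(study$recordings)) {
    tt0 <- study$trials[study$trials$patient_id == pid, , drop = FALSE]
    rec <- reference_spans(study$recordings[[pid]], tt0, events, span)
    pid_rows <- chans$patient_id == pid
    keep <- incl$mask[pid_rows] & rec$channels$region %in% use_regions
    if (!any(keep)) next
    rec$samples <- rec$samples[keep, , drop = FALSE]
    rec$channels <- rec$channels[keep, , drop = FALSE]
    tt <- study$trials[study$trials$patient_id == pid, , drop = FALSE]
    per_event <- list()
    for (ev in events) {
      ep <- extract_epochs(rec, tt, ev, span)
      ep <- detect_artifacts(ep)
      ep <- mad_outlier_flag(ep, k = mad_k)
      ep <- downsample(ep, target_fs)
      ep <- bandpass_hilbert_amplitude(ep, band)
      ep <- smooth_envelope(ep, smooth_ms)
      ep <- zscore_baseline(ep, baseline)
      per_event[[ev]] <- ep
    }
    patients[[pid]] <- per_event
  }
  structure(list(patients = patients, channels = chans, inclusion = incl,
                 trials = study$trials,
                 config = list(events = events, span = span,
                               target_fs = target_fs, band = band,
                               smooth_ms = smooth_ms, baseline = baseline,
                               min_patients = min_patients)),
            class = "pain_hfa_study")
}

#' @export
print.pain_hfa_study <- function(x, ...) {
  cat("<pain_hfa_study>", length(x$patients), "patients;",
      length(x$inclusion$regions), "included regions:",
      paste(x$inclusion$regions, collapse = " "), "\n")
  invisible(x)
}
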