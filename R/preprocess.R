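#' Common median reference
#'
#' Subtracts, at every time sample, the median across channels from each
#' channel. More robust than the common average to large-amplitude transients
#' on single contacts. The subtracted median trace is stored with the
#' recording so downstream artifact rules that are defined in amplifier units
#' (saturation voltage, flat channels) can be evaluated on the de-referenced
#' values. Idempotent: re-applying changes nothing (the per-sample median of
#' the referenced data is exactly zero for odd channel counts).
#'
#' @param rec `pain_recording` with at least two channels.
#' @return referenced `pain_recording` with a `ref_trace` element.
#' @export
common_median_reference <- function(rec) {
  stopifnot(inherits(rec, "pain_recording"))
  if (nrow(rec$samples) < 2) stop("common median reference needs >= 2 channels")
  med <- col_medians(rec$samples)
  rec$samples <- rec$samples - rep(med, each = nrow(rec$samples))
  rec$ref_trace <- if (is.null(rec$ref_trace)) med else rec$ref_trace + med
  rec$referenced <- TRUE
  rec
}

# Common-median referencing restricted to the samples that will be epoched.
# The reference is per time sample, so referencing only the columns inside
# the epoch spans is exact for everything downstream of extract_epochs;
# samples outside any span keep their raw values (and a zero reference).
reference_spans <- function(rec, trials, events, span) {
  if (nrow(rec$samples) < 2) stop("common median reference needs >= 2 channels")
  fs <- rec$fs
  n <- ncol(rec$samples)
  len <- ms_to_samples(span[2] - span[1], fs)
  idx <- integer(0)
  for (ev in events) {
    lo <- trials[[ev]] + ms_to_samples(span[1], fs)
    for (l in lo) if (l >= 0 && l + len <= n) idx <- c(idx, (l + 1L):(l + len))
  }
  idx <- unique(idx)
  med <- numeric(n)
  med[idx] <- col_medians(rec$samples[, idx, drop = FALSE])
  rec$samples <- rec$samples - rep(med, each = nrow(rec$samples))
  rec$ref_trace <- med
  rec$referenced <- TRUE
  rec
}

#' Extract event-aligned epochs
#'
#' Slices the recording around each trial's event sample. Epochs span
#' `span[1]` to `span[2]` ms (half-open, 0-based event samples), wide enough
#' to carry both the -3..-2 s baseline and the -1000..1000 ms analysis
#' window. Trials whose span exceeds the recording bounds are dropped and
#' logged. No filtering occurs at this stage: epoch values equal the
#' recording slice exactly.
#'
#' @param rec `pain_recording` (normally referenced).
#' @param trials trial-table rows for this patient.
#' @param event `"hand_on"` or `"hand_off"`.
#' @param span epoch window in ms relative to the event.
#' @return object of class `pain_epochs`: `data` (trials x channels x time,
#'   microvolts), `fs`, `t_axis` (ms), `event`, `trials`, `channels`,
#'   `reject`/`reject_reason` masks, and `ref` (trials x time slices of the
#'   subtracted reference trace, when available).
#' @export
extract_epochs <- function(rec, trials, event = c("hand_on", "hand_off"),
                           span = c(-3000, 1000)) {
  stopifnot(inherits(rec, "pain_recording"))
  event <- match.arg(event)
  fs <- rec$fs
  n <- ncol(rec$samples)
  ev <- trials[[event]]
  lo <- ev + ms_to_samples(span[1], fs)      # 0-based first sample
  len <- ms_to_samples(span[2] - span[1], fs)
  ok <- lo >= 0 & (lo + len) <= n
  dropped <- trials$trial_id[!ok]
  if (length(dropped))
    message("dropping ", length(dropped), " trial(s) with incomplete span: ",
            paste(dropped, collapse = ", "))
  trials <- trials[ok, , drop = FALSE]
  lo <- lo[ok]
  nt <- nrow(trials); nc <- nrow(rec$samples)
  data <- array(NA_real_, c(nt, nc, len))
  ref <- if (!is.null(rec$ref_trace)) matrix(NA_real_, nt, len) else NULL
  for (i in seq_len(nt)) {
    idx <- (lo[i] + 1L):(lo[i] + len)        # to 1-based
    data[i, , ] <- rec$samples[, idx]
    if (!is.null(ref)) ref[i, ] <- rec$ref_trace[idx]
  }
  t_axis <- span[1] + (seq_len(len) - 1L) / fs * 1000
  structure(list(data = data, fs = fs, t_axis = t_axis, event = event,
                 trials = trials, channels = rec$channels,
                 reject = matrix(FALSE, nt, nc),
                 reject_reason = matrix("", nt, nc),
                 ref = ref, dropped_trials = dropped,
                 units = "uV", envelope = FALSE, smoothed = FALSE,
                 zscored = FALSE),
            class = "pain_epochs")
}

#' @export
print.pain_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<pain_epochs>", x$event, ":", d[1], "trials x", d[2], "channels x",
      d[3], "samples @", x$fs, "Hz;",
      sum(x$reject), "rejected;",
      if (x$zscored) "z-scored HFA" else if (x$envelope) "HFA envelope"
      else "raw uV", "\n")
  invisible(x)
}

add_reason <- function(ep, i, j, reason) {
  ep$reject[i, j] <- TRUE
  cur <- ep$reject_reason[i, j]
  if (!grepl(reason, cur, fixed = TRUE))
    ep$reject_reason[i, j] <- if (nzchar(cur)) paste(cur, reason, sep = ",")
                              else reason
  ep
}

#' Threshold-based artifact detection
#'
#' Flags any trial-by-channel epoch where (a) the Welch PSD at 60 Hz exceeds
#' `psd_thresh` (reason `line_noise`), (b) the maximum absolute one-sample
#' slope exceeds `slope_thresh` uV/ms (reason `transient`), (c) the variance
#' is below `var_thresh` uV^2 (reason `flat`), or (d) any sample reaches the
#' amplifier saturation voltage (reason `saturation`). Rules are evaluated on
#' amplifier-unit values: when the epochs carry a reference trace, the
#' subtracted median is added back first, so exact-value rules (saturation,
#' flat channels) see the raw voltages.
#'
#' @param ep `pain_epochs` in microvolts, native sampling rate.
#' @param psd_thresh 60 Hz PSD threshold, uV^2/Hz.
#' @param slope_thresh slope threshold, uV/ms.
#' @param var_thresh variance floor, uV^2.
#' @param sat_volt amplifier saturation voltage, uV.
#' @return `pain_epochs` with updated `reject` and `reject_reason`.
#' @export
detect_artifacts <- function(ep, psd_thresh = 100, slope_thresh = 300,
                             var_thresh = 1, sat_volt = 6553) {
  stopifnot(inherits(ep, "pain_epochs"))
  if (ep$envelope) stop("artifact detection must run on raw uV epochs")
  fs <- ep$fs
  d <- dim(ep$data)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- ep$data[i, j, ]
      if (!is.null(ep$ref)) x <- x + ep$ref[i, ]
      pw <- welch_psd(x, fs)
      p60 <- pw$psd[which.min(abs(pw$freq - 60))]
      if (p60 > psd_thresh) ep <- add_reason(ep, i, j, "line_noise")
      slope <- max(abs(diff(x))) * fs / 1000
      if (slope > slope_thresh) ep <- add_reason(ep, i, j, "transient")
      if (stats::var(x) < var_thresh) ep <- add_reason(ep, i, j, "flat")
      if (any(abs(x) >= sat_volt)) ep <- add_reason(ep, i, j, "saturation")
    }
  }
  ep
}

#' MAD-based outlier flagging
#'
#' For each channel, the median and MAD (scaled, consistent for the normal
#' distribution) are computed over all of that channel's retained epoch
#' samples; any epoch containing a value more than `k` MADs from the median
#' is flagged (reason `spike_outlier`). When the MAD is zero the channel is
#' degenerate: any value different from the median flags the epoch, unless
#' all epochs are identical.
#'
#' Like the threshold rules, the statistics are computed in amplifier units
#' (the subtracted reference trace is added back when present): with few
#' channels the common-median trace equals each channel a sizeable fraction
#' of the time, putting an atom at zero in the referenced marginal that
#' deflates the MAD.
#'
#' @param ep `pain_epochs` in microvolts.
#' @param k outlier threshold in MAD units.
#' @return `pain_epochs` with updated masks.
#' @export
mad_outlier_flag <- function(ep, k = 3) {
  stopifnot(inherits(ep, "pain_epochs"))
  if (ep$envelope) stop("MAD outlier flagging must run on raw uV epochs")
  if (!is.finite(k)) return(ep)
  d <- dim(ep$data)
  for (j in seq_len(d[2])) {
    keep <- which(!ep$reject[, j])
    if (!length(keep)) next
    raw <- matrix(ep$data[keep, j, ], nrow = length(keep))
    if (!is.null(ep$ref)) raw <- raw + ep$ref[keep, , drop = FALSE]
    med <- stats::median(raw)
    madv <- stats::mad(raw)
    for (ii in seq_along(keep)) {
      x <- raw[ii, ]
      hit <- if (madv > 0) any(abs(x - med) > k * madv) else any(x != med)
      if (hit) ep <- add_reason(ep, keep[ii], j, "spike_outlier")
    }
  }
  ep
}

#' Downsample epochs or a recording
#'
#' Zero-phase Butterworth low-pass (cutoff below the target Nyquist) followed
#' by integer decimation. The sampling-rate ratio must be an integer.
#'
#' @param x `pain_epochs` or `pain_recording`.
#' @param target_fs target sampling rate (Hz).
#' @return same class as `x`, at `target_fs`.
#' @export
downsample <- function(x, target_fs = 500) UseMethod("downsample")

decim_filter <- function(fs, target_fs) {
  if (fs %% target_fs != 0)
    stop("sampling-rate ratio must be an integer (", fs, " -> ", target_fs, ")")
  signal::butter(6, 0.8 * (target_fs / 2) / (fs / 2), type = "low")
}

#' @rdname downsample
#' @export
downsample.pain_epochs <- function(x, target_fs = 500) {
  if (x$fs == target_fs) return(x)
  bf <- decim_filter(x$fs, target_fs)
  r <- as.integer(x$fs / target_fs)
  d <- dim(x$data)
  H2 <- zero_phase_mag2(bf, d[3], x$fs)
  pick <- seq(1L, d[3], by = r)
  out <- array(NA_real_, c(d[1], d[2], length(pick)))
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j, ] <- spectral_filter(x$data[i, j, ], H2)[pick]
  x$data <- out
  if (!is.null(x$ref)) {
    ref <- matrix(NA_real_, d[1], length(pick))
    for (i in seq_len(d[1])) ref[i, ] <- spectral_filter(x$ref[i, ], H2)[pick]
    x$ref <- ref
  }
  x$t_axis <- x$t_axis[pick]
  x$fs <- target_fs
  x
}

#' @rdname downsample
#' @export
downsample.pain_recording <- function(x, target_fs = 500) {
  if (x$fs == target_fs) return(x)
  bf <- decim_filter(x$fs, target_fs)
  r <- as.integer(x$fs / target_fs)
  n <- ncol(x$samples)
  H2 <- zero_phase_mag2(bf, n, x$fs)
  pick <- seq(1L, n, by = r)
  out <- matrix(NA_real_, nrow(x$samples), length(pick))
  for (j in seq_len(nrow(x$samples)))
    out[j, ] <- spectral_filter(x$samples[j, ], H2)[pick]
  x$samples <- out
  if (!is.null(x$ref_trace)) x$ref_trace <- spectral_filter(x$ref_trace, H2)[pick]
  x$fs <- target_fs
  x
}

#' Export the rejection mask as a tidy table
#'
#' @param ep `pain_epochs`.
#' @return data.frame with one row per rejected (trial, channel): `trial_id`,
#'   `channel`, `reason`.
#' @export
rejection_table <- function(ep) {
  idx <- which(ep$reject, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(trial_id = integer(), channel = character(),
                      reason = character()))
  data.frame(trial_id = ep$trials$trial_id[idx[, 1]],
             channel = ep$channels$name[idx[, 2]],
             reason = ep$reject_reason[idx],
             stringsAsFactors = FALSE)
}
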