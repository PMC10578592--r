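#' Synthetic background LFP for one channel
#'
#' Band-limited (0.3-250 Hz) approximately 1/f^1.5 core (white noise shaped
#' by a pole-zero shelving cascade), soft-compressed with a tanh at `clip`
#' standard deviations so that artifact-free epochs have bounded excursions
#' (heavy-tailed events are modeled explicitly as injected artifacts, not as
#' background), plus a slow-amplitude-modulated rhythmic component and a
#' mains line component.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param rms_core RMS of the 1/f core, microvolts.
#' @param clip soft-clipping point in core SD units.
#' @param osc_amp,osc_freq amplitude (uV) and frequency (Hz) of the rhythm.
#' @param line_amp,line_freq amplitude (uV) and frequency (Hz) of mains.
#' @param am_freq slow amplitude-modulation frequency of the rhythm (Hz).
#' @param sos optional precomputed shaping cascade ([noise_shaping_sos()]).
#' @return numeric vector of length `n` (microvolts).
#' @keywords internal
synth_background <- function(n, fs, rms_core = 25, clip = 2.2,
                             osc_amp = 15, osc_freq = 10,
                             line_amp = 4, line_freq = 60, am_freq = 0.1,
                             sos = NULL) {
  if (is.null(sos)) sos <- noise_shaping_sos(fs)
  as.vector(background_channel(as.integer(n), sos, fs, rms_core, clip,
                               osc_amp, osc_freq, line_amp, line_freq,
                               am_freq))
}

#' First-order IIR cascade approximating band-limited 1/f^alpha noise
#'
#' Designs, by bilinear transform, a cascade of first-order sections that
#' shapes white noise into an approximately 1/f^alpha power spectrum between
#' `band[1]` and `band[2]`: a high-pass at the lower edge, pole-zero shelves
#' whose falling segments tile the band (average amplitude slope
#' f^(-alpha/2), ripple about +/-1.5 dB), and two low-pass sections at the
#' upper edge.
#'
#' @param fs sampling rate (Hz).
#' @param alpha spectral exponent of the power spectrum.
#' @param band frequency support in Hz.
#' @param n_shelf number of shelving sections.
#' @return numeric matrix with rows (b0, b1, a1), a0 = 1.
#' @keywords internal
noise_shaping_sos <- function(fs, alpha = 1.5, band = c(0.3, 250),
                              n_shelf = 8) {
  K <- 2 * fs
  blt <- function(wz, wp) {   # analog (1 + s/wz) / (1 + s/wp)
    a0 <- 1 + K / wp
    c((1 + K / wz) / a0, (1 - K / wz) / a0, (1 - K / wp) / a0)
  }
  hp <- function(wc) {        # s / (s + wc)
    a0 <- K + wc
    c(K / a0, -K / a0, (wc - K) / a0)
  }
  lp <- function(wc) {        # wc / (s + wc)
    a0 <- K + wc
    c(wc / a0, wc / a0, (wc - K) / a0)
  }
  decades <- log10(band[2] / band[1])
  f_pole <- band[1] * 10^(seq(0, decades, length.out = n_shelf + 1))[1:n_shelf]
  # each shelf drops power by 20*log10(ratio) dB; tile the band so the
  # total drop is 10 * alpha * decades dB (average slope f^-alpha)
  ratio <- 10^((alpha / 2) * decades / n_shelf)
  rows <- list(hp(2 * pi * band[1]))
  for (fp in f_pole)
    rows[[length(rows) + 1]] <- blt(2 * pi * fp * ratio, 2 * pi * fp)
  rows[[length(rows) + 1]] <- lp(2 * pi * band[2])
  rows[[length(rows) + 1]] <- lp(2 * pi * band[2])
  do.call(rbind, rows)
}

# Estimate the channel's baseline envelope statistics (mean envelope and SD of
# the 300 ms smoothed envelope) in the HFA band, by running the filter-Hilbert
# chain on a stretch of background. Used to express injected burst amplitudes
# in baseline z units.
estimate_env_scale <- function(bg, fs, band = c(70, 150), smooth_ms = 300) {
  n <- min(length(bg), as.integer(6 * fs))
  x <- bg[seq_len(n)]
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- spectral_filter(x, zero_phase_mag2(bf, n, fs))
  env <- hilbert_amplitude(xf)
  sm <- moving_average(env, ms_to_samples(smooth_ms, fs))
  keep <- seq(ms_to_samples(500, fs), n - ms_to_samples(500, fs))
  list(mu = mean(env[keep]), sd_smooth = stats::sd(sm[keep]))
}

# Additive narrowband burst whose envelope increment, averaged over the burst
# window, equals delta_peak: the raised-cosine taper is normalised to unit
# mean, and the carrier amplitude producing an expected envelope increment
# delta(t) over an incoherent background with mean envelope mu is
# sqrt((mu + delta)^2 - mu^2).
burst_waveform <- function(n_win, fs, delta_peak, mu_env, f_carrier, phase) {
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n_win) / (n_win + 1)))  # raised cosine
  w <- w / mean(w)
  delta <- pmax(0, delta_peak) * w
  a <- sqrt(pmax(0, (mu_env + delta)^2 - mu_env^2))
  a * cos(2 * pi * f_carrier * seq_len(n_win) / fs + phase)
}

#' Inject labelled artifacts into a recording
#'
#' Each artifact is placed in the epoch window of a randomly chosen
#' (trial, event, channel) slot and sized to exceed the corresponding
#' rejection threshold by a comfortable margin:
#' \describe{
#'   \item{line_noise}{60 Hz sinusoid, 30 uV (PSD at 60 Hz about 300 uV^2/Hz
#'     against the 100 uV^2/Hz threshold).}
#'   \item{transient}{single-sample 450 uV excursion (450 uV/ms at 1 kHz
#'     against the 300 uV/ms threshold).}
#'   \item{flat}{signal replaced by a constant over the epoch span
#'     (variance 0 against the < 1 uV^2 rule).}
#'   \item{saturation}{plateau at exactly +6553 uV (amplifier saturation),
#'     entered and left by slow ramps so only the saturation rule trips.}
#'   \item{spike_outlier}{smooth triangular 250 uV deflection over 120 ms;
#'     large against the 3-MAD outlier rule but too slow for the slope rule.}
#' }
#'
#' @param rec `pain_recording` (raw, unreferenced).
#' @param trials trial-table rows for this patient (gives epoch locations).
#' @param kinds character vector of artifact kinds to inject (with
#'   repetition allowed); each entry places one artifact.
#' @param span epoch span in ms that downstream extraction will use.
#' @param seed optional RNG seed.
#' @return list with the modified `recording` and `log` (data.frame:
#'   patient_id, trial_id, event, channel, kind).
#' @export
inject_artifacts <- function(rec, trials, kinds, span = c(-3000, 1000),
                             seed = NULL) {
  stopifnot(inherits(rec, "pain_recording"))
  allowed <- c("line_noise", "transient", "flat", "saturation", "spike_outlier")
  bad <- setdiff(kinds, allowed)
  if (length(bad)) stop("unknown artifact kind: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  fs <- rec$fs
  n <- ncol(rec$samples)
  log <- vector("list", length(kinds))
  used <- character(0)
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    # draw an unused (trial, event, channel) slot
    repeat {
      tr <- trials[sample(nrow(trials), 1), ]
      ev <- sample(c("hand_on", "hand_off"), 1)
      ch <- sample(nrow(rec$samples), 1)
      key <- paste(tr$trial_id, ev, ch)
      if (!key %in% used) { used <- c(used, key); break }
    }
    ev_sample <- if (ev == "hand_on") tr$hand_on else tr$hand_off
    lo <- ev_sample + ms_to_samples(span[1], fs) + 1L  # 1-based
    hi <- ev_sample + ms_to_samples(span[2], fs)
    lo <- max(1L, lo); hi <- min(n, hi)
    idx <- lo:hi
    x <- rec$samples[ch, ]
    if (kind == "line_noise") {
      x[idx] <- x[idx] + 30 * sin(2 * pi * 60 * seq_along(idx) / fs)
    } else if (kind == "transient") {
      at <- sample(idx[seq(200, length(idx) - 200)], 1)
      x[at] <- x[at] + 450
    } else if (kind == "flat") {
      pad <- ms_to_samples(200, fs)
      j <- max(1L, lo - pad):min(n, hi + pad)
      x[j] <- mean(x[j])
    } else if (kind == "saturation") {
      ramp <- ms_to_samples(100, fs)
      plat <- ms_to_samples(200, fs)
      at <- sample(idx[seq(2 * ramp, length(idx) - 2 * ramp - plat)], 1)
      up <- seq(x[at], 6553, length.out = ramp)
      dn <- seq(6553, x[at + ramp + plat + ramp], length.out = ramp)
      x[at:(at + ramp - 1L)] <- up
      x[(at + ramp):(at + ramp + plat - 1L)] <- 6553
      x[(at + ramp + plat):(at + 2L * ramp + plat - 1L)] <- dn
    } else if (kind == "spike_outlier") {
      width <- ms_to_samples(120, fs)
      at <- sample(idx[seq(width, length(idx) - width)], 1)
      tri <- 250 * (1 - abs(seq(-1, 1, length.out = width)))
      x[at:(at + width - 1L)] <- x[at:(at + width - 1L)] + tri
    }
    rec$samples[ch, ] <- x
    log[[i]] <- data.frame(patient_id = rec$patient_id,
                           trial_id = tr$trial_id, event = ev,
                           channel = rec$channels$name[ch], kind = kind,
                           stringsAsFactors = FALSE)
  }
  list(recording = rec, log = do.call(rbind, log))
}

#' Simulate a complete synthetic study
#'
#' Generates, for each simulated patient, an adaptive-staircase behavioural
#' session (temperatures, binary reports, VAS ratings) and a continuous
#' multichannel recording whose 70-150 Hz envelope around the hand-on and
#' hand-off events is modulated by region-specific effect sizes, plus
#' optional labelled artifacts. Ground truth (observer parameters, effect
#' map, latent drives, artifact log) is returned for parameter-recovery and
#' rejection-rule testing.
#'
#' Trial timing: `lead_in_s` of baseline, then `n_trials` cycles of
#' `hand_on_s` stimulation + `iti_s` inter-trial interval, then `tail_s`.
#' The inter-trial interval default keeps the -3..-2 s baseline window of
#' each trial clear of the previous trial's stimulation.
#'
#' @param n_patients number of simulated patients.
#' @param regions data.frame with `region` and `n_patients` columns (how many
#'   patients carry electrodes in each region); defaults to [region_table()].
#'   Counts are clipped to `n_patients`. An optional `channels` column
#'   overrides `channels_per_region` per region.
#' @param n_trials trials per patient (task design requires at least 20).
#' @param channels_per_region electrode contacts per carried region.
#' @param effects NULL for a null dataset, or data.frame with columns
#'   `region`, `event` ("hand_on"/"hand_off") and `effect`: envelope change in
#'   baseline z units per unit latent pain, applied over `burst_window`.
#' @param burst_base event-locked envelope response (z units) common to all
#'   trials, so even null data has an evoked component.
#' @param burst_window support of the evoked burst in ms relative to the event.
#' @param fs sampling rate (Hz).
#' @param hand_on_s,iti_s,lead_in_s,tail_s session timing in seconds.
#' @param grid staircase temperature grid (degC).
#' @param observer_pop population parameters for per-patient observers:
#'   `threshold_mean`, `threshold_sd`, `slope`, `vas_gain`, `vas_noise_sd`,
#'   `lapse`.
#' @param artifact_kinds character vector of artifacts to inject per patient
#'   (NULL for none).
#' @param wm_channels white-matter channels to add per patient (excluded by
#'   the region filter downstream).
#' @param background parameters passed to the background generator.
#' @param seed RNG seed; identical seeds give bit-identical studies.
#' @return object of class `pain_study`: list with `recordings` (named list of
#'   `pain_recording`), `trials` (pooled `trial_table`), `truth` (ground
#'   truth), and `config`.
#' @export
simulate_study <- function(n_patients = 20,
                           regions = region_table(),
                           n_trials = 20,
                           channels_per_region = 2,
                           effects = NULL,
                           burst_base = 0.5,
                           burst_window = c(0, 500),
                           fs = 1000,
                           hand_on_s = 10, iti_s = 5,
                           lead_in_s = 4, tail_s = 2,
                           grid = seq(40, 48, by = 1),
                           observer_pop = list(threshold_mean = 45,
                                               threshold_sd = 1.5,
                                               slope = 1.2, vas_gain = 2,
                                               vas_noise_sd = 0.8,
                                               lapse = 0.02),
                           artifact_kinds = NULL,
                           wm_channels = 1,
                           background = list(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- as.data.frame(regions)
  stopifnot(all(c("region", "n_patients") %in% names(regions)))
  if (!is.null(effects)) {
    stopifnot(all(c("region", "event", "effect") %in% names(effects)))
    unknown <- setdiff(effects$region, regions$region)
    if (length(unknown)) stop("effect map names unknown regions: ",
                              paste(unknown, collapse = ", "))
  }
  pids <- sprintf("P%02d", seq_len(n_patients))
  # which patients carry which region
  carriers <- lapply(seq_len(nrow(regions)), function(i) {
    k <- min(n_patients, regions$n_patients[i])
    sort(sample(n_patients, k))
  })
  names(carriers) <- regions$region

  effect_of <- function(region, event) {
    if (is.null(effects)) return(0)
    hit <- effects$region == region & effects$event == event
    if (any(hit)) effects$effect[which(hit)[1]] else 0
  }

  n_total <- as.integer((lead_in_s + n_trials * (hand_on_s + iti_s) + tail_s) * fs)
  hand_on_samples <- as.integer(lead_in_s * fs +
                                  (seq_len(n_trials) - 1L) * (hand_on_s + iti_s) * fs)
  hand_off_samples <- hand_on_samples + as.integer(hand_on_s * fs)
  burst_lo <- ms_to_samples(burst_window[1], fs)
  n_win <- ms_to_samples(burst_window[2] - burst_window[1], fs)

  recordings <- list()
  trial_rows <- list()
  observers <- list()
  art_logs <- list()

  bg_args <- c(list(n = n_total, fs = fs), background,
               list(sos = noise_shaping_sos(fs)))
  # channels are statistically exchangeable: estimate the baseline envelope
  # scale once from a reference background realisation
  sc_env <- estimate_env_scale(do.call(synth_background, bg_args), fs)

  for (p in seq_len(n_patients)) {
    pid <- pids[p]
    thr <- observer_pop$threshold_mean +
      stats::rnorm(1, 0, observer_pop$threshold_sd)
    thr <- min(max(thr, min(grid) + 1), max(grid) - 1)
    obs <- observer_model(threshold_temp = thr, slope = observer_pop$slope,
                          vas_gain = observer_pop$vas_gain,
                          vas_noise_sd = observer_pop$vas_noise_sd,
                          lapse_rate = observer_pop$lapse)
    observers[[pid]] <- obs
    sc <- run_staircase(obs, n_trials, quest_init(grid = grid,
                                                  slope = observer_pop$slope,
                                                  lapse = observer_pop$lapse))
    beh <- sc$trials
    trial_rows[[pid]] <- data.frame(patient_id = pid,
                                    trial_id = seq_len(n_trials),
                                    temperature = beh$temperature,
                                    hand_on = hand_on_samples,
                                    hand_off = hand_off_samples,
                                    binary_response = beh$binary,
                                    vas = beh$vas,
                                    latent = beh$latent,
                                    stringsAsFactors = FALSE)

    my_regions <- regions$region[vapply(carriers, function(cc) p %in% cc,
                                        logical(1))]
    ch_meta <- list(); ch_data <- list(); k <- 0L
    for (r in my_regions) {
      n_ch <- if (!is.null(regions$channels))
        regions$channels[match(r, regions$region)] else channels_per_region
      for (cc in seq_len(n_ch)) {
        k <- k + 1L
        x <- do.call(synth_background, bg_args)
        for (ev in c("hand_on", "hand_off")) {
          eff <- effect_of(r, ev)
          ev_samples <- if (ev == "hand_on") hand_on_samples else hand_off_samples
          for (i in seq_len(n_trials)) {
            delta <- (burst_base + eff * beh$latent[i]) * sc_env$sd_smooth
            if (delta <= 0) next
            at <- ev_samples[i] + burst_lo
            idx <- (at + 1L):(at + n_win)
            x[idx] <- x[idx] + burst_waveform(n_win, fs, delta, sc_env$mu,
                                              stats::runif(1, 90, 130),
                                              stats::runif(1, 0, 2 * pi))
          }
        }
        hemi <- sample(c("L", "R"), 1)
        ch_meta[[k]] <- data.frame(
          name = sprintf("%s_%s_%d", pid, r, cc),
          atlas_label = sprintf("%s_%s_%d_%d", r, hemi, sample(7, 1), cc),
          region = r, white_matter = FALSE, stringsAsFactors = FALSE)
        ch_data[[k]] <- x
      }
    }
    # patients without any carried region still get a white-matter contact so
    # every recording holds at least one trace
    n_wm <- if (k == 0L) max(1L, wm_channels) else wm_channels
    wm_pool <- if (length(my_regions)) my_regions else regions$region
    for (wm in seq_len(n_wm)) {
      k <- k + 1L
      r <- wm_pool[sample.int(length(wm_pool), 1)]
      ch_meta[[k]] <- data.frame(
        name = sprintf("%s_wm_%d", pid, wm),
        atlas_label = sprintf("%s_%s_%d_%d", r, sample(c("L", "R"), 1), 1L, wm),
        region = r, white_matter = TRUE, stringsAsFactors = FALSE)
      ch_data[[k]] <- do.call(synth_background, bg_args)
    }
    rec <- pain_recording(do.call(rbind, ch_data), fs,
                          do.call(rbind, ch_meta), pid)
    if (!is.null(artifact_kinds) && length(artifact_kinds)) {
      inj <- inject_artifacts(rec, trial_rows[[pid]], artifact_kinds)
      rec <- inj$recording
      art_logs[[pid]] <- inj$log
    }
    recordings[[pid]] <- rec
  }

  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  # full effect map over all simulated regions (zeros included)
  full_map <- expand.grid(region = regions$region,
                          event = c("hand_on", "hand_off"),
                          stringsAsFactors = FALSE)
  full_map$effect <- mapply(effect_of, full_map$region, full_map$event)
  truth <- list(observers = observers,
                effect_map = full_map,
                burst_base = burst_base,
                burst_window = burst_window,
                artifact_log = if (length(art_logs)) do.call(rbind, art_logs)
                               else NULL,
                carriers = carriers)
  structure(list(recordings = recordings,
                 trials = trial_table(trials, fs = fs),
                 truth = truth,
                 config = list(n_patients = n_patients, n_trials = n_trials,
                               fs = fs, hand_on_s = hand_on_s, iti_s = iti_s,
                               lead_in_s = lead_in_s, tail_s = tail_s,
                               grid = grid, burst_window = burst_window)),
            class = "pain_study")
}

#' @export
print.pain_study <- function(x, ...) {
  cat("<pain_study>", length(x$recordings), "patients,",
      nrow(x$trials), "trials total @", x$config$fs, "Hz\n")
  nch <- sum(vapply(x$recordings, function(r) nrow(r$samples), integer(1)))
  cat("  ", nch, "channels;",
      if (is.null(x$truth$artifact_log)) "no injected artifacts" else
        paste(nrow(x$truth$artifact_log), "injected artifacts"), "\n")
  invisible(x)
}

#' Pooled channel metadata for a study
#'
#' @param study `pain_study`.
#' @return data.frame of all channels with a `patient_id` column.
#' @export
study_channels <- function(study) {
  out <- lapply(study$recordings, function(r)
    cbind(r$channels, patient_id = r$patient_id, stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
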