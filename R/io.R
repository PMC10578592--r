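#' Construct a continuous multichannel recording
#'
#' Container for a single patient's continuous intracranial recording: a
#' channels-by-time matrix of voltages (microvolts) plus per-channel metadata.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels data.frame with one row per channel: `name`,
#'   `atlas_label` (Brainnetome-style, may be NA), `region` (collapsed label;
#'   filled from `atlas_label` when missing), `white_matter` (logical).
#' @param patient_id scalar identifier.
#' @return object of class `pain_recording`.
#' @export
pain_recording <- function(samples, fs, channels, patient_id = "P01") {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), fs > 0)
  if (anyNA(samples)) stop("recording contains NA samples")
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (nrow(channels) != nrow(samples))
    stop("channel metadata rows (", nrow(channels),
         ") do not match channel count (", nrow(samples), ")")
  if (is.null(channels$white_matter)) channels$white_matter <- FALSE
  if (is.null(channels$region)) {
    channels$region <- collapse_label(channels$atlas_label)
  } else {
    has_lab <- !is.na(channels$atlas_label) & nzchar(channels$atlas_label)
    if (any(has_lab)) {
      bad <- channels$region[has_lab] != collapse_label(channels$atlas_label[has_lab])
      if (any(bad)) stop("region does not match collapsed atlas label for: ",
                         paste(channels$name[has_lab][bad], collapse = ", "))
    }
  }
  structure(list(samples = samples, fs = fs, channels = channels,
                 patient_id = patient_id, referenced = FALSE),
            class = "pain_recording")
}

#' @export
print.pain_recording <- function(x, ...) {
  cat("<pain_recording> patient", x$patient_id, "-",
      nrow(x$samples), "channels x", ncol(x$samples), "samples @",
      x$fs, "Hz", if (x$referenced) "(common-median referenced)", "\n")
  cat("  regions:", paste(sort(unique(x$channels$region)), collapse = " "), "\n")
  invisible(x)
}

#' Collapse a Brainnetome-style atlas label to its gyral region
#'
#' Keeps the token before the first underscore, dropping hemisphere and
#' subdivision (e.g. `"Amyg_L_2_1"` becomes `"Amyg"`). Labels without an
#' underscore are returned unchanged, so the operation is idempotent.
#'
#' @param atlas_label character vector of atlas labels.
#' @return character vector of collapsed region names.
#' @export
#' @examples
#' collapse_label(c("Amyg_L_2_1", "MFG_R_7_3", "Hipp"))
collapse_label <- function(atlas_label) {
  if (any(is.na(atlas_label)) || any(!nzchar(atlas_label)))
    stop("empty atlas label")
  sub("_.*$", "", atlas_label)
}

#' Region inclusion filter
#'
#' Excludes white-matter channels, then excludes regions represented by fewer
#' than `min_patients` unique patients among the remaining channels.
#'
#' @param channels data.frame of channel metadata with columns `region` and
#'   `white_matter`.
#' @param patient_of_channel vector (same length as `nrow(channels)`) giving
#'   the patient each channel belongs to.
#' @param min_patients minimum number of unique patients per region.
#' @return list with `regions` (character vector of retained regions) and
#'   `mask` (logical vector aligned to the channel rows; TRUE = retained).
#' @export
filter_regions <- function(channels, patient_of_channel, min_patients = 3) {
  stopifnot(length(patient_of_channel) == nrow(channels))
  gm <- !channels$white_matter
  pat_per_region <- tapply(patient_of_channel[gm], channels$region[gm],
                           function(p) length(unique(p)))
  keep_regions <- names(pat_per_region)[pat_per_region >= min_patients]
  mask <- gm & channels$region %in% keep_regions
  list(regions = sort(keep_regions), mask = mask)
}

#' Per-region sampling summary
#'
#' Summarises, for each region, the number of unique patients, the number of
#' unique contacts, and the mean and standard deviation of contacts per
#' contributing patient (mean rounded to one decimal, as conventionally
#' tabulated).
#'
#' @inheritParams filter_regions
#' @return data.frame with columns `region`, `unique_patients`,
#'   `unique_contacts`, `mean_contacts`, `sd_contacts`.
#' @export
region_summary <- function(channels, patient_of_channel) {
  stopifnot(length(patient_of_channel) == nrow(channels))
  if (nrow(channels) == 0)
    return(data.frame(region = character(), unique_patients = integer(),
                      unique_contacts = integer(), mean_contacts = numeric(),
                      sd_contacts = numeric()))
  regs <- sort(unique(channels$region))
  out <- lapply(regs, function(r) {
    sel <- channels$region == r
    per_pat <- table(patient_of_channel[sel])
    data.frame(region = r,
               unique_patients = length(per_pat),
               unique_contacts = sum(sel),
               mean_contacts = round(sum(sel) / length(per_pat), 1),
               sd_contacts = if (length(per_pat) > 1) stats::sd(as.numeric(per_pat)) else 0)
  })
  do.call(rbind, out)
}

#' Reference table of sampled brain regions
#'
#' The sixteen collapsed gyral regions used throughout the package, with the
#' number of unique patients and electrode contacts representing each in the
#' motivating twenty-patient cohort. Used as the default region layout of the
#' synthetic-data generator.
#'
#' @return data.frame with columns `region`, `n_patients`, `n_contacts`.
#' @export
region_table <- function() {
  data.frame(
    region = c("Amyg", "CG", "FuG", "Hipp", "IFG", "INS", "ITG", "MFG",
               "MTG", "OFC", "PrG", "SFG", "STG", "Str", "Tha", "pSTS"),
    n_patients = c(11L, 20L, 9L, 18L, 17L, 12L, 6L, 17L,
                   19L, 18L, 3L, 13L, 11L, 10L, 5L, 3L),
    n_contacts = c(44L, 51L, 16L, 115L, 94L, 30L, 19L, 116L,
                   140L, 190L, 15L, 32L, 36L, 41L, 19L, 9L),
    stringsAsFactors = FALSE
  )
}

# ---- trial tables -----------------------------------------------------------

#' Validate a trial table
#'
#' A trial table holds one row per trial: `patient_id`, `trial_id`,
#' `temperature` (degrees C), `hand_on` and `hand_off` (0-based sample
#' indices of stimulus start and end), `binary_response` (0/1) and `vas`
#' (0-10 rating).
#'
#' @param tt data.frame.
#' @param fs sampling rate, used to check the nominal 10 s stimulus length
#'   (skipped when NULL).
#' @return the validated data.frame, invisibly classed `trial_table`.
#' @export
trial_table <- function(tt, fs = NULL) {
  need <- c("patient_id", "trial_id", "temperature", "hand_on", "hand_off",
            "binary_response", "vas")
  miss <- setdiff(need, names(tt))
  if (length(miss)) stop("trial table missing columns: ", paste(miss, collapse = ", "))
  if (any(tt$hand_off <= tt$hand_on)) stop("hand_off must exceed hand_on")
  if (any(tt$vas < 0 | tt$vas > 10, na.rm = TRUE)) stop("vas outside [0, 10]")
  if (!all(tt$binary_response %in% c(0, 1))) stop("binary_response must be 0/1")
  if (!is.null(fs)) {
    dur <- (tt$hand_off - tt$hand_on) / fs
    if (any(abs(dur - 10) > 0.5))
      warning("some trials deviate from the nominal 10 s stimulus duration")
  }
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Read / write trial tables as TSV
#'
#' @param tt trial table data.frame.
#' @param path file path.
#' @return `read_trial_table` returns the validated table.
#' @export
write_trial_table <- function(tt, path) {
  utils::write.table(tt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  trial_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

# ---- recordings: flat binary + JSON sidecar ---------------------------------

#' Persist a recording as flat binary plus JSON sidecar
#'
#' Samples are written channel-major as little-endian float64; the sidecar
#' (`<path>.json`) records dimensions, sampling rate, patient id and channel
#' metadata, so the pair is self-describing.
#'
#' @param rec `pain_recording`.
#' @param path path of the binary file (sidecar gets `.json` appended).
#' @return `read_recording` returns the reconstructed `pain_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pain_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$samples)), con, size = 8, endian = "little")
  meta <- list(fs = rec$fs, patient_id = rec$patient_id,
               n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
               referenced = rec$referenced,
               channels = rec$channels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  samples <- t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels))
  rec <- pain_recording(samples, meta$fs, meta$channels, meta$patient_id)
  rec$referenced <- isTRUE(meta$referenced)
  rec
}
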