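#' Simulated psychophysical observer
#'
#' Parametrises how a simulated participant answers the two probes of the
#' tonic thermal task: the binary "was that painful?" question and the 0-10
#' visual analog scale (VAS) rating.
#'
#' Both reports derive from a single-trial percept drive
#' `d = (T - threshold) * slope + eps`, with `eps` drawn from a standard
#' logistic distribution: the trial is reported painful when `d > 0`, which
#' makes the marginal psychometric function exactly
#' `logistic((T - threshold) * slope)`, while the VAS rating grows with the
#' suprathreshold part of the same drive. Sharing the percept between the
#' binary report, the VAS rating, and (in the LFP generator) the neural
#' response means the reports carry trial-level information beyond
#' temperature - the property the mixed models are designed to detect, since
#' temperature itself enters them as a random effect.
#'
#' @param threshold_temp pain threshold in degrees C.
#' @param slope psychometric steepness, 1/degC (> 0).
#' @param vas_gain VAS units per degC above threshold.
#' @param vas_noise_sd report noise, VAS units.
#' @param lapse_rate probability of an attention lapse (answer by coin flip);
#'   must lie in [0, 0.1].
#' @return object of class `observer_model`.
#' @export
observer_model <- function(threshold_temp = 45, slope = 1.2, vas_gain = 2,
                           vas_noise_sd = 0.8, lapse_rate = 0.02) {
  stopifnot(slope > 0, lapse_rate >= 0, lapse_rate <= 0.1,
            vas_gain >= 0, vas_noise_sd >= 0)
  structure(list(threshold_temp = threshold_temp, slope = slope,
                 vas_gain = vas_gain, vas_noise_sd = vas_noise_sd,
                 lapse_rate = lapse_rate),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model> threshold %.2f degC, slope %.2f /degC, VAS gain %.2f, lapse %.3f\n",
              x$threshold_temp, x$slope, x$vas_gain, x$lapse_rate))
  invisible(x)
}

#' Expected latent pain drive at a given temperature
#'
#' The logistic drive `plogis((T - threshold) * slope)`: the probability the
#' observer calls the stimulus painful (before lapses), and the expected
#' value of the single-trial latent drive returned by [simulate_observer()].
#'
#' @param model `observer_model`.
#' @param temperature degrees C (vectorised).
#' @return numeric in (0, 1).
#' @export
latent_pain <- function(model, temperature) {
  logistic((temperature - model$threshold_temp) * model$slope)
}

#' Simulate one trial's psychophysical reports
#'
#' Draws the percept drive `d = (T - threshold) * slope + Logistic(0, 1)`.
#' The binary report is `d > 0` (so marginally Bernoulli of the logistic
#' psychometric), replaced by a fair coin flip on lapse trials; the VAS is
#' `clamp(gain * max(0, d / slope) + noise, 0, 10)` rounded to integers; the
#' realized latent drive `plogis(d)` is returned for use as the neural
#' modulation. Uses the current RNG state; pass `seed` for a self-contained
#' draw.
#'
#' @inheritParams latent_pain
#' @param seed optional integer seed set before drawing.
#' @return list with `binary` (0/1), `vas` (integer 0-10) and `latent`
#'   (realized drive in (0, 1)).
#' @export
simulate_observer <- function(model, temperature, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- (temperature - model$threshold_temp) * model$slope +
    stats::rlogis(1)
  binary <- as.integer(d > 0)
  if (stats::runif(1) < model$lapse_rate) binary <- stats::rbinom(1, 1, 0.5)
  vas_raw <- model$vas_gain * max(0, d / model$slope) +
    stats::rnorm(1, 0, model$vas_noise_sd)
  vas <- round(min(10, max(0, vas_raw)))
  list(binary = binary, vas = vas, latent = logistic(d))
}
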