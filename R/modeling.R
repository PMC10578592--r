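#' Sliding-window grid
#'
#' Half-open 500 ms windows stepping by 250 ms over the analysis span. The
#' default spans are (-250, 1000) ms around stimulus onset (hand-on) and
#' (-1000, 1000) ms around stimulus offset (hand-off).
#'
#' @param event `"hand_on"` or `"hand_off"`.
#' @param span optional span override, ms.
#' @param width,step window width and step, ms.
#' @return matrix with columns `start`, `end` (ms), one row per window.
#' @export
window_grid <- function(event = c("hand_on", "hand_off"), span = NULL,
                        width = 500, step = 250) {
  event <- match.arg(event)
  span <- span %||% if (event == "hand_on") c(-250, 1000) else c(-1000, 1000)
  if (diff(span) < width) stop("span shorter than the window width")
  starts <- seq(span[1], span[2] - width, by = step)
  cbind(start = starts, end = starts + width)
}

#' Per-trial region features for one window
#'
#' For every trial of every patient carrying the region: the mean z-scored
#' HFA over the window samples of each retained (non-rejected) channel epoch,
#' then averaged over the patient's retained channels in the region. Joined
#' with temperature and both psychophysical responses. Patients left with no
#' retained trials are dropped (recorded in the `dropped_patients` attribute).
#'
#' @param proc `pain_hfa_study` from [process_study()].
#' @param region collapsed region name (must have passed the inclusion
#'   filter).
#' @param event `"hand_on"` or `"hand_off"`.
#' @param window numeric length-2, window in ms (half-open).
#' @return data.frame of class `pain_features`: `patient_id`, `trial_id`,
#'   `temperature`, `A`, `y_binary`, `y_vas`.
#' @export
build_features <- function(proc, region, event, window) {
  stopifnot(inherits(proc, "pain_hfa_study"))
  if (!region %in% proc$inclusion$regions)
    stop("region '", region, "' did not pass the inclusion filter")
  rows <- list(); dropped <- character(0)
  for (pid in names(proc$patients)) {
    ep <- proc$patients[[pid]][[event]]
    if (is.null(ep)) next
    ch_sel <- which(ep$channels$region == region)   # analysis channels only
    if (!length(ch_sel)) next
    tsel <- ep$t_axis >= window[1] & ep$t_axis < window[2]
    if (!any(tsel)) stop("window outside the epoch span")
    tt <- ep$trials
    A <- rep(NA_real_, nrow(tt))
    for (i in seq_len(nrow(tt))) {
      chm <- ch_sel[!ep$reject[i, ch_sel]]
      if (!length(chm)) next
      A[i] <- mean(vapply(chm, function(j) mean(ep$data[i, j, tsel]),
                          numeric(1)))
    }
    ok <- !is.na(A)
    if (!any(ok)) { dropped <- c(dropped, pid); next }
    rows[[pid]] <- data.frame(patient_id = pid,
                              trial_id = tt$trial_id[ok],
                              temperature = tt$temperature[ok],
                              A = A[ok],
                              y_binary = tt$binary_response[ok],
                              y_vas = tt$vas[ok],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(patient_id = character(),
                                      trial_id = integer(),
                                      temperature = numeric(), A = numeric(),
                                      y_binary = integer(), y_vas = numeric())
  rownames(out) <- NULL
  attr(out, "region") <- region
  attr(out, "event") <- event
  attr(out, "window") <- window
  attr(out, "dropped_patients") <- dropped
  class(out) <- c("pain_features", "data.frame")
  out
}

glme_formula <- function(resp) {
  stats::as.formula(paste(resp, "~ A + (A | temp_f) + (A | patient_f)"))
}

glme_frame <- function(features, temp_round = 0.1) {
  df <- as.data.frame(features)
  df$temp_f <- factor(round(df$temperature / temp_round) * temp_round)
  df$patient_f <- factor(df$patient_id)
  df
}

lmer_ctrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore")
}
# bobyqa stopping radius 1e-4 (default 2e-7): beta agrees to ~7 digits at a
# fraction of the iterations; used identically by the real fit and the
# permutation engine so both optimise the same criterion the same way
glmer_optctrl <- list(rhobeg = 2e-2, rhoend = 1e-4)
glmer_ctrl <- function() {
  lme4::glmerControl(calc.derivs = FALSE,
                     check.conv.singular = "ignore",
                     optCtrl = glmer_optctrl)
}

#' Fit the mixed-effects pain model for one region-window
#'
#' Fits `y ~ A + (A | temperature) + (A | patient)`: the mean z-scored HFA in
#' the window is the fixed effect, with random intercepts and slopes grouped
#' by temperature level (temperatures rounded to `temp_round` degC form the
#' levels) and by patient. The binary report uses a binomial family with
#' logit link; the VAS rating uses an identity-link gaussian. Binomial fits
#' use the fast PIRLS-profiled deviance (`nAGQ = 0`), the same criterion the
#' permutation engine optimises, so real and pseudo t statistics are
#' directly comparable.
#'
#' @param features `pain_features` (or data.frame with columns `A`,
#'   `temperature`, `patient_id`, and `y_binary`/`y_vas`).
#' @param family `"binomial"` (binary report) or `"gaussian"` (VAS).
#' @param temp_round rounding (degC) defining temperature levels.
#' @return object of class `pain_glme`: fixed-effect estimate `beta` with
#'   standard error and `t_stat`, the fitted conditional responses (random
#'   effects included), convergence and separation flags, random-effect SDs,
#'   and the underlying `merMod` in `$model`.
#' @export
fit_glme <- function(features, family = c("binomial", "gaussian"),
                     temp_round = 0.1) {
  family <- match.arg(family)
  df <- glme_frame(features, temp_round)
  if (length(unique(df$patient_f)) < 3)
    stop("need at least 3 patients to fit the mixed model")
  resp <- if (family == "binomial") "y_binary" else "y_vas"
  if (family == "binomial" && length(unique(df$y_binary)) < 2)
    stop("binomial model needs both response classes present")
  converged <- TRUE; messages <- character(0)
  fit <- withCallingHandlers(
    if (family == "binomial") {
      lme4::glmer(glme_formula(resp), data = df, family = stats::binomial(),
                  nAGQ = 0L, control = glmer_ctrl())
    } else {
      lme4::lmer(glme_formula(resp), data = df, REML = FALSE,
                 control = lmer_ctrl())
    },
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      if (grepl("converge", conditionMessage(w))) converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  beta <- lme4::fixef(fit)[["A"]]
  se <- sqrt(as.matrix(stats::vcov(fit))["A", "A"])
  vc <- as.data.frame(lme4::VarCorr(fit))
  fitted_cond <- stats::fitted(fit)
  separated <- family == "binomial" &&
    (abs(beta) > 15 || all(fitted_cond < 1e-6 | fitted_cond > 1 - 1e-6))
  structure(list(beta = beta, se = se, t_stat = beta / se,
                 family = family, model = fit,
                 fitted_conditional = fitted_cond,
                 converged = converged, separated = separated,
                 random_effect_sds = vc[is.na(vc$var2),
                                        c("grp", "var1", "sdcor")],
                 n_obs = nrow(df), n_patients = length(unique(df$patient_f)),
                 temp_round = temp_round,
                 features = df, diagnostics = messages,
                 region = attr(features, "region"),
                 event = attr(features, "event"),
                 window = attr(features, "window")),
            class = "pain_glme")
}

#' @export
print.pain_glme <- function(x, ...) {
  lab <- if (!is.null(x$region))
    sprintf(" [%s %s %d..%d ms]", x$region, x$event,
            x$window[1], x$window[2]) else ""
  cat(sprintf("<pain_glme %s>%s\n", x$family, lab))
  cat(sprintf("  HFA fixed effect: beta = %.4f (SE %.4f), t = %.3f\n",
              x$beta, x$se, x$t_stat))
  cat(sprintf("  %d trials, %d patients%s%s\n", x$n_obs, x$n_patients,
              if (!x$converged) "; NOT converged" else "",
              if (x$separated) "; possible complete separation" else ""))
  invisible(x)
}

#' @export
summary.pain_glme <- function(object, ...) {
  print(object)
  cat("  random-effect SDs:\n")
  print(object$random_effect_sds, row.names = FALSE)
  invisible(object)
}

#' @export
coef.pain_glme <- function(object, ...) lme4::fixef(object$model)

#' @export
predict.pain_glme <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) return(stats::fitted(object$model))
  stats::predict(object$model, newdata = newdata, type = type,
                 allow.new.levels = TRUE, ...)
}

#' @export
residuals.pain_glme <- function(object, ...) stats::residuals(object$model, ...)

#' @export
simulate.pain_glme <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$model, nsim = nsim, seed = seed, ...)
}

#' @export
plot.pain_glme <- function(x, ...) {
  y <- x$features[[if (x$family == "binomial") "y_binary" else "y_vas"]]
  graphics::plot(x$fitted_conditional, y,
                 xlab = "fitted conditional response", ylab = "observed",
                 main = sprintf("%s model%s", x$family,
                                if (!is.null(x$region)) paste0(": ", x$region)
                                else ""), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# ---- permutation engine -----------------------------------------------------

# Pseudo-t statistics from refitting the model with the HFA-report pairing
# randomly broken. Uses lme4's modular interface: the parsed model is reused
# and the deviance function rebuilt per permutation, which reproduces a
# fresh lmer/glmer (nAGQ = 0) fit exactly while skipping formula parsing and
# merMod assembly.
#
# Schemes: "feature" (default) shuffles the HFA feature A within patient,
# rewriting its entries in the fixed-effect design and in the random-slope
# columns of Zt (positions located once by a two-parse diff); the
# "response_*" schemes shuffle the response vector within the named strata.
#
# Two subtleties: the relative-covariance factor Lambdat inside reTrms is
# mutated in place by the optimizer (C++ reference semantics), so its slots
# are restored from forced copies before every rebuild; and the devfun
# closure resolves lme4-internal functions through its environment chain, so
# it is anchored in the lme4 namespace.
perm_pseudo_t <- function(fit, n_perm,
                          scheme = c("feature", "response_patient_temperature",
                                     "response_patient", "response_none")) {
  scheme <- match.arg(scheme)
  df <- fit$features
  resp_col <- if (fit$family == "binomial") "y_binary" else "y_vas"
  y <- df[[resp_col]]
  A <- df$A
  cells <- switch(scheme,
                  feature = df$patient_f,
                  response_patient_temperature =
                    interaction(df$patient_f, df$temp_f, drop = TRUE),
                  response_patient = df$patient_f,
                  response_none = factor(rep(1, nrow(df))))
  form <- glme_formula(resp_col)
  parse_model <- function(d) {
    if (fit$family == "gaussian") {
      lme4::lFormula(form, data = d, REML = FALSE, control = lmer_ctrl())
    } else {
      lme4::glFormula(form, data = d, family = stats::binomial(),
                      control = glmer_ctrl())
    }
  }
  pf <- parse_model(df)
  n <- nrow(df)
  if (scheme == "feature") {
    # locate A's slots in Zt once, by re-parsing with a perturbed A
    df2 <- df
    df2$A <- df$A + seq_len(n)
    pf2 <- parse_model(df2)
    zpos <- which(pf$reTrms$Zt@x != pf2$reTrms$Zt@x)
    obs_of <- findInterval(zpos - 0.5, pf$reTrms$Zt@p)
    stopifnot(all(pf$reTrms$Zt@x[zpos] == A[obs_of]))
    a_col <- match("A", colnames(pf$X))
  }
  Lx0 <- pf$reTrms$Lambdat@x + 0   # + 0 forces a copy: the originals are
  th0 <- pf$reTrms$theta + 0       # mutated in place by each optimisation
  pseudo <- rep(NA_real_, n_perm)
  cell_idx <- split(seq_len(n), cells)
  cell_idx <- cell_idx[lengths(cell_idx) > 1L]
  for (b in seq_len(n_perm)) {
    if (scheme == "feature") {
      Ap <- A
      for (sel in cell_idx) Ap[sel] <- A[sel][sample.int(length(sel))]
      X <- pf$X
      X[, a_col] <- Ap
      pf$X <- X
      Zt <- pf$reTrms$Zt
      Zt@x[zpos] <- Ap[obs_of]
      pf$reTrms$Zt <- Zt
    } else {
      yp <- y
      for (sel in cell_idx) yp[sel] <- y[sel][sample.int(length(sel))]
      pf$fr[[1L]] <- yp
    }
    Lt <- pf$reTrms$Lambdat
    Lt@x <- Lx0 + 0                   # fresh copies: the previous fit mutated
    pf$reTrms$Lambdat <- Lt           # these slots in place, and this fit
    pf$reTrms$theta <- th0 + 0        # will do so again

    t_b <- tryCatch(suppressWarnings({
      if (fit$family == "gaussian") {
        devf <- do.call(lme4::mkLmerDevfun, pf)
        parent.env(environment(devf)) <- asNamespace("lme4")
        # mirror lmer()'s optimizer call (restart_edge, no derivative
        # computation) so the pseudo-t is the same statistic as the real fit
        opt <- lme4::optimizeLmer(devf, restart_edge = TRUE,
                                  boundary.tol = 1e-5, calc.derivs = FALSE)
        rho <- environment(devf)
        beta <- rho$pp$beta(1)
        RXi <- solve(rho$pp$RX())
        sig2 <- (rho$resp$wrss() + rho$pp$sqrL(1)) / n
        beta[2] / sqrt(sig2 * sum(RXi[2, ]^2))
      } else {
        devf <- do.call(lme4::mkGlmerDevfun, pf)
        parent.env(environment(devf)) <- asNamespace("lme4")
        opt <- lme4::optimizeGlmer(devf, calc.derivs = FALSE,
                                   control = glmer_optctrl)
        rho <- environment(devf)
        beta <- rho$pp$beta(1)
        RXi <- solve(rho$pp$RX())
        beta[2] / sqrt(sum(RXi[2, ]^2))
      }
    }), error = function(e) NA_real_)
    pseudo[b] <- t_b
  }
  pseudo
}

#' Permutation significance test for the HFA fixed effect
#'
#' Re-evaluates the mixed model `n_perm` times with the HFA-report pairing
#' randomly broken, collects the pseudo t-statistics, and compares the real
#' t-statistic with their 2.5th and 97.5th percentiles. The model is
#' significant when the real t falls outside those bounds; the p-value
#' counts pseudo-t values more extreme than the real t in the tail matching
#' its sign, floored at one count, doubled for two-sidedness, and divided by
#' the number of converged permutations.
#'
#' A permutation test of an association is exact when the shuffled margin is
#' exchangeable under the null. Here the reports are *not* exchangeable —
#' they carry the staircase's temperature structure — while the null HFA
#' feature is just baseline-normalised noise, exchangeable within patient.
#' The default scheme therefore shuffles the feature `A` within patient
#' (refitting the model with the neural-report pairing broken), which is
#' both exact under the null and fully powered. Response-shuffling schemes
#' are available for comparison: within patient-by-temperature cells (exact
#' but weak for binary responses, whose extreme cells are constant and
#' shuffle to themselves), within patient, or unrestricted (both of the
#' latter break the response-temperature association that the temperature
#' random effects absorb, inflating the null rejection rate).
#'
#' @param fit `pain_glme`, or `pain_features` (then `family` is used to fit).
#' @param family model family, used when `fit` is a feature table.
#' @param n_perm number of permutations (at least 40 for 95% bounds).
#' @param seed optional RNG seed.
#' @param scheme `"feature"` (default), `"response_patient_temperature"`,
#'   `"response_patient"`, or `"response_none"`.
#' @return object of class `pain_perm`: `t_real`, `pseudo_t`, `bounds`,
#'   `p_value`, `significant`, `n_perm`, `n_eff` (converged permutations) and
#'   an `unreliable` flag when more than 10% of refits failed.
#' @export
permutation_test <- function(fit, family = c("binomial", "gaussian"),
                             n_perm = 1000, seed = NULL,
                             scheme = "feature") {
  if (n_perm < 40)
    stop("n_perm = ", n_perm, " is below the minimum (40) for 95% bounds")
  if (!inherits(fit, "pain_glme")) fit <- fit_glme(fit, match.arg(family))
  if (!is.null(seed)) set.seed(seed)
  pseudo <- perm_pseudo_t(fit, n_perm, scheme)
  ok <- is.finite(pseudo)
  n_eff <- sum(ok)
  pseudo <- pseudo[ok]
  bounds <- stats::quantile(pseudo, c(0.025, 0.975), names = FALSE)
  t_real <- fit$t_stat
  significant <- t_real < bounds[1] | t_real > bounds[2]
  count <- if (t_real >= 0) sum(pseudo > t_real) else sum(pseudo < t_real)
  p <- pvalue_from_counts(count, n_eff)
  structure(list(t_real = t_real, pseudo_t = pseudo, bounds = bounds,
                 p_value = p, significant = significant,
                 n_perm = n_perm, n_eff = n_eff,
                 unreliable = (n_perm - n_eff) / n_perm > 0.1,
                 family = fit$family, region = fit$region,
                 event = fit$event, window = fit$window),
            class = "pain_perm")
}

#' @export
print.pain_perm <- function(x, ...) {
  lab <- if (!is.null(x$region))
    sprintf(" [%s %s %d..%d ms]", x$region, x$event,
            x$window[1], x$window[2]) else ""
  cat(sprintf("<pain_perm %s>%s t = %.3f, null 95%% bounds [%.3f, %.3f]\n",
              x$family, lab, x$t_real, x$bounds[1], x$bounds[2]))
  cat(sprintf("  p = %.4g (%s), %d/%d permutations converged%s\n",
              x$p_value,
              if (x$significant) "significant" else "not significant",
              x$n_eff, x$n_perm,
              if (x$unreliable) "; UNRELIABLE (>10% refit failures)" else ""))
  invisible(x)
}

#' @export
plot.pain_perm <- function(x, ...) {
  graphics::hist(x$pseudo_t, breaks = 30, main = "pseudo-t null distribution",
                 xlab = "pseudo t", ...)
  graphics::abline(v = x$t_real, col = "red", lwd = 2)
  graphics::abline(v = x$bounds, lty = 2)
  invisible(x)
}

#' Two-sided permutation p-value from a tail count
#'
#' `p = 2 * max(count, 1) / n_perm`, capped at 1: the number of pseudo
#' statistics more extreme than the real one in its tail, floored at one
#' count (so the smallest attainable p with 1000 permutations is 0.002),
#' doubled for two-sidedness.
#'
#' @param count_more_extreme integer tail count, between 0 and `n_perm`.
#' @param n_perm number of permutations.
#' @return p-value in (0, 1].
#' @export
pvalue_from_counts <- function(count_more_extreme, n_perm = 1000) {
  if (count_more_extreme < 0 || count_more_extreme > n_perm)
    stop("count must be between 0 and n_perm")
  min(1, 2 * max(count_more_extreme, 1) / n_perm)
}

#' Sliding-window permutation scan over regions
#'
#' Builds features and runs the mixed model + permutation test for every
#' (region, event, window, family) combination, mirroring the heatmap
#' analyses.
#'
#' @param proc `pain_hfa_study`.
#' @param regions regions to scan (default: all included regions).
#' @param events events to scan.
#' @param families model families to run.
#' @param n_perm permutations per test.
#' @param seed RNG seed for the permutation stream.
#' @param windows optional window matrix override (else [window_grid()] per
#'   event).
#' @return data.frame of class `pain_scan`: one row per test with `region`,
#'   `event`, `win_start`, `win_end`, `family`, `beta`, `t_real`, `p_value`,
#'   `significant`, `n_eff_perm`, `n_trials`.
#' @export
scan_windows <- function(proc, regions = NULL,
                         events = c("hand_on", "hand_off"),
                         families = c("binomial", "gaussian"),
                         n_perm = 1000, seed = NULL, windows = NULL) {
  stopifnot(inherits(proc, "pain_hfa_study"))
  regions <- regions %||% proc$inclusion$regions
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); k <- 0L
  for (region in regions) {
    for (ev in events) {
      wg <- windows %||% window_grid(ev)
      for (w in seq_len(nrow(wg))) {
        feats <- build_features(proc, region, ev, wg[w, ])
        for (fam in families) {
          k <- k + 1L
          res <- tryCatch({
            fit <- fit_glme(feats, fam)
            pt <- permutation_test(fit, n_perm = n_perm)
            data.frame(region = region, event = ev,
                       win_start = wg[w, 1], win_end = wg[w, 2],
                       family = fam, beta = fit$beta, t_real = pt$t_real,
                       p_value = pt$p_value, significant = pt$significant,
                       n_eff_perm = pt$n_eff, n_trials = fit$n_obs,
                       stringsAsFactors = FALSE)
          }, error = function(e)
            data.frame(region = region, event = ev,
                       win_start = wg[w, 1], win_end = wg[w, 2],
                       family = fam, beta = NA_real_, t_real = NA_real_,
                       p_value = NA_real_, significant = NA,
                       n_eff_perm = NA_integer_, n_trials = NA_integer_,
                       stringsAsFactors = FALSE))
          rows[[k]] <- res
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pain_scan", "data.frame")
  out
}
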