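#' Initialise an adaptive threshold staircase
#'
#' Grid-based Bayesian threshold estimation in the spirit of QUEST: a prior
#' probability mass over candidate thresholds on a fixed temperature grid is
#' updated after every trial with a logistic psychometric likelihood, and the
#' next stimulus is the posterior-mean threshold quantised to the grid.
#'
#' @param grid ordered vector of candidate threshold temperatures (degC);
#'   also the set of proposable stimulus temperatures.
#' @param prior optional prior mass over `grid` (uniform when NULL).
#' @param slope assumed psychometric slope (1/degC) of the update likelihood.
#' @param lapse assumed lapse rate mixed into the likelihood for robustness.
#' @return object of class `quest_state`.
#' @export
quest_init <- function(grid = seq(40, 48, by = 1), prior = NULL,
                       slope = 1.2, lapse = 0.02) {
  if (length(grid) == 0) stop("empty temperature grid")
  stopifnot(!is.unsorted(grid), slope > 0)
  prior <- prior %||% rep(1 / length(grid), length(grid))
  stopifnot(length(prior) == length(grid), all(prior >= 0))
  prior <- prior / sum(prior)
  structure(list(grid = grid, posterior = prior, slope = slope, lapse = lapse,
                 history = data.frame(temperature = numeric(),
                                      response = integer())),
            class = "quest_state")
}

#' Propose the next stimulus temperature
#'
#' Posterior-mean threshold, snapped to the nearest grid value (ties resolve
#' to the lower temperature). Deterministic given the state.
#'
#' @param state `quest_state`.
#' @return temperature in degC, always an element of the grid.
#' @export
quest_propose <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  if (length(state$grid) == 0) stop("empty temperature grid")
  m <- sum(state$grid * state$posterior)
  state$grid[which.min(abs(state$grid - m))]
}

#' Bayes-update the staircase with one trial's outcome
#'
#' Multiplies the posterior by the logistic likelihood of the observed
#' response at the delivered temperature and renormalises; the trial is
#' appended to the history.
#'
#' @param state `quest_state`.
#' @param temperature delivered temperature; must lie on the grid.
#' @param response binary report (0/1 or logical).
#' @return updated `quest_state`.
#' @export
quest_update <- function(state, temperature, response) {
  stopifnot(inherits(state, "quest_state"))
  if (!any(abs(state$grid - temperature) < 1e-9))
    stop("temperature not on the staircase grid")
  if (is.logical(response)) response <- as.integer(response)
  if (!length(response) == 1 || !response %in% c(0L, 1L))
    stop("response must be a single 0/1 value")
  p_yes <- state$lapse / 2 +
    (1 - state$lapse) * logistic((temperature - state$grid) * state$slope)
  lik <- if (response == 1L) p_yes else 1 - p_yes
  post <- state$posterior * lik
  s <- sum(post)
  if (s <= 0) stop("degenerate posterior after update")
  state$posterior <- post / s
  state$history <- rbind(state$history,
                         data.frame(temperature = temperature,
                                    response = response))
  state
}

#' Posterior-mean threshold estimate
#'
#' @param state `quest_state`.
#' @return numeric threshold estimate in degC.
#' @export
quest_estimate <- function(state) {
  sum(state$grid * state$posterior)
}

#' Run a full adaptive staircase against a simulated observer
#'
#' Alternates propose / simulate / update for `n_trials` trials. Uses the
#' current RNG state.
#'
#' @param model `observer_model` answering the trials.
#' @param n_trials number of trials (the task requires at least 20).
#' @param state optional initial `quest_state`.
#' @return list with the final `state` and a data.frame `trials`
#'   (temperature, binary, vas, latent drive).
#' @export
run_staircase <- function(model, n_trials = 20, state = quest_init()) {
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    temp <- quest_propose(state)
    resp <- simulate_observer(model, temp)
    state <- quest_update(state, temp, resp$binary)
    out[[i]] <- data.frame(temperature = temp, binary = resp$binary,
                           vas = resp$vas, latent = resp$latent)
  }
  list(state = state, trials = do.call(rbind, out))
}
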