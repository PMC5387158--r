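#' Initialise a 2-up-1-down staircase track
#'
#' One adaptive track per condition. The rule named "2-up-1-down" in the
#' adaptive-psychophysics tradition used here makes the task harder after two
#' consecutive correct responses and easier after every error, converging on
#' sqrt(1/2) = 70.7% correct. "Harder" means a smaller mean angle for the
#' `mu` track and a larger direction SD for the `sigma` track.
#'
#' @param condition `"mu"` or `"sigma"`.
#' @param config A [session_config()] supplying start level, step and bounds.
#' @return A list of class `staircase_state` with fields `condition`,
#'   `level`, `consecutive_correct`, `step_size`, `n_reversals`,
#'   `level_bounds` and `last_direction`.
#' @export
staircase_init <- function(condition = c("mu", "sigma"),
                           config = session_config()) {
  condition <- match.arg(condition)
  if (condition == "mu") {
    level <- config$mu_start; step <- config$mu_step; bounds <- config$mu_bounds
  } else {
    level <- config$sigma_start; step <- config$sigma_step
    bounds <- config$sigma_bounds
  }
  structure(
    list(condition = condition, level = level, consecutive_correct = 0L,
         step_size = step, n_reversals = 0L, level_bounds = bounds,
         last_direction = 0L),
    class = "staircase_state"
  )
}

#' Update a staircase after one response
#'
#' An incorrect response makes the next trial easier by one step immediately;
#' two consecutive correct responses make it harder by one step and reset the
#' counter. Levels are clamped to `level_bounds`; a flip of the step
#' direction increments `n_reversals`.
#'
#' @param state A `staircase_state`.
#' @param correct Logical: was the response correct?
#' @return The updated `staircase_state`.
#' @examples
#' st <- staircase_init("mu")
#' st$level
#' staircase_update(st, correct = FALSE)$level # easier: larger mean angle
#' @export
staircase_update <- function(state, correct) {
  if (!inherits(state, "staircase_state")) abort("`state` must be a staircase_state.")
  if (!is.logical(correct) || length(correct) != 1L || is.na(correct)) {
    abort("`correct` must be TRUE or FALSE.")
  }
  # direction: +1 when the level increases, -1 when it decreases
  easier_dir <- if (state$condition == "mu") +1L else -1L
  move <- 0L
  if (!correct) {
    move <- easier_dir
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      move <- -easier_dir
      state$consecutive_correct <- 0L
    }
  }
  if (move != 0L) {
    state$level <- clamp(state$level + move * state$step_size,
                         state$level_bounds[1], state$level_bounds[2])
    if (state$last_direction != 0L && move != state$last_direction) {
      state$n_reversals <- state$n_reversals + 1L
    }
    state$last_direction <- move
  }
  state
}

#' Run a single staircase track in isolation
#'
#' Convenience driver used for convergence checks: repeatedly draws a
#' stimulus at the current level (random side), obtains the observer's
#' response, and updates the track.
#'
#' @param condition `"mu"` or `"sigma"`.
#' @param n_trials Number of trials.
#' @param params An [observer_params()].
#' @param config A [session_config()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: `trial_index`, `level`,
#'   `true_side`, `response`, `correct`.
#' @export
simulate_staircase_track <- function(condition = c("mu", "sigma"),
                                     n_trials = 2500L,
                                     params = observer_params(),
                                     config = session_config(),
                                     seed = NULL) {
  condition <- match.arg(condition)
  with_seed(seed, {
    st <- staircase_init(condition, config)
    level <- numeric(n_trials)
    side <- character(n_trials)
    resp <- character(n_trials)
    corr <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      level[i] <- st$level
      side[i] <- if (runif(1L) < 0.5) "left" else "right"
      stim <- make_stimulus(condition, st$level, side[i], config)
      ans <- observer_respond(stim, params)
      resp[i] <- ans$response
      corr[i] <- identical(ans$response, side[i])
      st <- staircase_update(st, corr[i])
    }
    tibble(trial_index = seq_len(n_trials), level = level, true_side = side,
           response = resp, correct = corr)
  })
}
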