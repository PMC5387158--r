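#' Session configuration for the global-motion confidence task
#'
#' Bundles the stimulus and session constants of the dual-staircase
#' global-motion discrimination task: a central array of dots whose
#' directions are drawn from a Gaussian around a mean angle measured from
#' vertical. One condition adapts the mean angle at a fixed 30 degree
#' direction SD (`mu` staircase), the other adapts the SD at a fixed
#' 15 degree mean (`sigma` staircase).
#'
#' @param n_main_trials Total main trials, split evenly between the two
#'   staircase conditions. Must be even and divisible by `n_blocks`.
#' @param n_blocks Number of blocks; conditions are interleaved randomly
#'   within each block with equal per-block counts.
#' @param n_practice_trials Practice trials (accuracy feedback, no
#'   confidence ratings) run before the main session.
#' @param fixed_mean_angle Mean motion angle (degrees from vertical) used in
#'   the sigma-staircase condition.
#' @param fixed_sd Direction SD (degrees) used in the mu-staircase condition.
#' @param n_dots Number of dots per stimulus.
#' @param aperture_radius Aperture radius, degrees visual angle (metadata).
#' @param stimulus_duration_ms,response_window_ms Display timings (metadata).
#' @param max_dot_lifetime_fraction Maximum dot lifetime as a fraction of
#'   stimulus duration (metadata; dot lifetime does not alter the direction
#'   statistics the simulation models).
#' @param mu_start,mu_step,mu_bounds Starting level, step size and bounds
#'   (degrees) of the adaptive mean-angle staircase.
#' @param sigma_start,sigma_step,sigma_bounds Same for the adaptive-SD
#'   staircase.
#'
#' @return A list of class `session_config`.
#' @examples
#' cfg <- session_config()
#' cfg$n_main_trials
#' @export
session_config <- function(n_main_trials = 320L,
                           n_blocks = 8L,
                           n_practice_trials = 56L,
                           fixed_mean_angle = 15,
                           fixed_sd = 30,
                           n_dots = 1100L,
                           aperture_radius = 9.5,
                           stimulus_duration_ms = 250,
                           response_window_ms = 800,
                           max_dot_lifetime_fraction = 0.93,
                           mu_start = 15,
                           mu_step = 1,
                           mu_bounds = c(0.5, 45),
                           sigma_start = 30,
                           sigma_step = 2,
                           sigma_bounds = c(5, 90)) {
  n_main_trials <- as.integer(n_main_trials)
  n_blocks <- as.integer(n_blocks)
  if (n_main_trials %% 2L != 0L) {
    abort("`n_main_trials` must be even (equal split across conditions).")
  }
  if (n_main_trials %% n_blocks != 0L) {
    abort("`n_main_trials` must be divisible by `n_blocks`.")
  }
  if ((n_main_trials / n_blocks) %% 2L != 0L) {
    abort("Each block must hold an even number of trials (condition balance).")
  }
  for (nm in c("fixed_mean_angle", "fixed_sd", "stimulus_duration_ms",
               "response_window_ms", "mu_start", "mu_step",
               "sigma_start", "sigma_step")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  structure(
    list(
      n_main_trials = n_main_trials,
      n_blocks = n_blocks,
      n_practice_trials = as.integer(n_practice_trials),
      fixed_mean_angle = fixed_mean_angle,
      fixed_sd = fixed_sd,
      n_dots = as.integer(n_dots),
      aperture_radius = aperture_radius,
      stimulus_duration_ms = stimulus_duration_ms,
      response_window_ms = response_window_ms,
      max_dot_lifetime_fraction = max_dot_lifetime_fraction,
      mu_start = mu_start, mu_step = mu_step, mu_bounds = mu_bounds,
      sigma_start = sigma_start, sigma_step = sigma_step,
      sigma_bounds = sigma_bounds
    ),
    class = "session_config"
  )
}

#' Parameters of a simulated confidence observer
#'
#' The observer estimates the mean motion direction by averaging a limited
#' subsample of the dots and adding Gaussian sensory noise, chooses
#' left/right by the sign of the estimate, and reports confidence as a noisy
#' affine function of the absolute decision evidence, additively biased by
#' the trial's stimulus SD.
#'
#' Limited-sample averaging (`n_effective_dots`) is what gives the stimulus
#' SD leverage over accuracy: an ideal averager of 1100 dots would see a
#' standard error below one degree even at SD 90 and the SD staircase could
#' never bring performance down to its 71% target.
#'
#' @param sensory_noise SD (degrees) of internal noise added to the direction
#'   estimate. Must be > 0.
#' @param n_effective_dots Number of dots effectively averaged.
#' @param metacognitive_noise SD (standardised-evidence units) of noise
#'   corrupting the confidence channel relative to the decision evidence;
#'   0 gives perfect insight, large values push AROC to 0.5.
#' @param confidence_gain,confidence_offset Affine map from (biased, noisy)
#'   evidence to the 0-100 confidence scale; output is clamped to \[0, 100\].
#' @param variance_bias_weight Additive weight of the trial stimulus SD on
#'   confidence (confidence units per degree of SD): the generative analogue
#'   of the variance-induced confidence bias.
#' @param rt_base_ms Minimum reaction time (ms).
#' @param rt_noise_ms Mean of the positive gamma-distributed RT noise (ms).
#'
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(sensory_noise = 10,
                            n_effective_dots = 4L,
                            metacognitive_noise = 0.5,
                            confidence_gain = 18,
                            confidence_offset = 70,
                            variance_bias_weight = -0.5,
                            rt_base_ms = 300,
                            rt_noise_ms = 110) {
  stopifnot_scalar_number(sensory_noise, "sensory_noise", positive = TRUE)
  stopifnot_scalar_number(confidence_gain, "confidence_gain", positive = TRUE)
  if (metacognitive_noise < 0) abort("`metacognitive_noise` must be >= 0.")
  if (n_effective_dots < 1) abort("`n_effective_dots` must be >= 1.")
  structure(
    list(
      sensory_noise = sensory_noise,
      n_effective_dots = as.integer(n_effective_dots),
      metacognitive_noise = metacognitive_noise,
      confidence_gain = confidence_gain,
      confidence_offset = confidence_offset,
      variance_bias_weight = variance_bias_weight,
      rt_base_ms = rt_base_ms,
      rt_noise_ms = rt_noise_ms
    ),
    class = "observer_params"
  )
}
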