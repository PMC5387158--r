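#' Draw the dot-direction sample for one trial
#'
#' Directions (degrees from vertical, negative = leftward) are constructed as
#' `sign(true_side) * mean_angle + Normal(0, sd_angle)`: the staircase level
#' sets the mean angle in the `mu` condition (SD fixed at
#' `config$fixed_sd`) and the SD in the `sigma` condition (mean fixed at
#' `config$fixed_mean_angle`).
#'
#' @param condition `"mu"` or `"sigma"`.
#' @param level Current staircase level (degrees); mean angle for `mu`,
#'   direction SD for `sigma`. Must be > 0.
#' @param true_side `"left"` or `"right"`.
#' @param config A [session_config()].
#'
#' @return A list with `directions` (length `config$n_dots`), `mean_angle`
#'   and `sd_angle`.
#' @examples
#' set.seed(1)
#' stim <- make_stimulus("mu", level = 6.46, true_side = "right")
#' mean(stim$directions) # close to +6.46
#' @export
make_stimulus <- function(condition = c("mu", "sigma"), level, true_side,
                          config = session_config()) {
  condition <- match.arg(condition)
  true_side <- match.arg(true_side, c("left", "right"))
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0) {
    abort("Invalid staircase state: `level` must be a single positive number.")
  }
  if (condition == "mu") {
    mean_angle <- level
    sd_angle <- config$fixed_sd
  } else {
    mean_angle <- config$fixed_mean_angle
    sd_angle <- level
  }
  if (sd_angle <= 0) abort("Invalid staircase state: non-positive stimulus SD.")
  sgn <- if (true_side == "right") 1 else -1
  list(
    directions = sgn * mean_angle + rnorm(config$n_dots, 0, sd_angle),
    mean_angle = mean_angle,
    sd_angle = sd_angle
  )
}

# mean and SD of |X| for X ~ N(mu, sigma^2) (folded normal)
folded_normal_moments <- function(mu, sigma) {
  delta <- mu / sigma
  m1 <- sigma * sqrt(2 / pi) * exp(-delta^2 / 2) +
    mu * (1 - 2 * pnorm(-delta))
  s1 <- sqrt(mu^2 + sigma^2 - m1^2)
  c(mean = m1, sd = s1)
}

#' Simulate one observer response with confidence
#'
#' The internal direction estimate `e` is the mean of `n_effective_dots`
#' randomly subsampled dot directions plus Gaussian sensory noise; the
#' response is its sign. The confidence channel standardises the decision
#' evidence `|e|` against its trial-conditional (folded-normal)
#' distribution, corrupts it with metacognitive noise, shifts it by
#' `variance_bias_weight * sd_angle`, and affinely maps and clamps it to the
#' 0-100 scale. The standardisation means stimulus parameters influence
#' confidence *only* through the explicit bias weight, giving the
#' bias-regression stage a clean generative target. RT is `rt_base_ms` plus
#' gamma-distributed positive noise.
#'
#' @param stimulus A stimulus as returned by [make_stimulus()].
#' @param params An [observer_params()].
#'
#' @return A list with `response` (`"left"`/`"right"`), `rt_ms`,
#'   `confidence_raw` and the internal `evidence`.
#' @export
observer_respond <- function(stimulus, params = observer_params()) {
  dirs <- stimulus$directions
  if (length(dirs) == 0L) abort("Empty dot-direction sample.")
  m <- min(params$n_effective_dots, length(dirs))
  sub <- if (m == length(dirs)) dirs else dirs[sample.int(length(dirs), m)]
  e <- mean(sub) + rnorm(1L, 0, params$sensory_noise)
  response <- if (e > 0) "right" else "left"
  sigma_eff <- sqrt(params$sensory_noise^2 +
                      stimulus$sd_angle^2 / params$n_effective_dots)
  fm <- folded_normal_moments(stimulus$mean_angle, sigma_eff)
  v <- (abs(e) - fm[["mean"]]) / fm[["sd"]]
  if (params$metacognitive_noise > 0) {
    v <- v + rnorm(1L, 0, params$metacognitive_noise)
  }
  conf <- clamp(params$confidence_gain * v + params$confidence_offset +
                  params$variance_bias_weight * stimulus$sd_angle, 0, 100)
  rt <- params$rt_base_ms + rgamma(1L, shape = 2, scale = params$rt_noise_ms / 2)
  list(response = response, rt_ms = rt, confidence_raw = conf, evidence = e)
}
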