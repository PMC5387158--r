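#' Type-I signal-detection statistics: sensitivity d' and criterion c
#'
#' Treats rightward stimuli as "signal": the hit rate is
#' `H = P(respond right | right)` and the false-alarm rate
#' `F = P(respond right | left)`. Then `d' = z(H) - z(F)` and
#' `c = -(z(H) + z(F)) / 2` with `z` the standard-normal quantile. Extreme
#' rates of 0 or 1 are adjusted by the 1/(2N) rule (0 -> 1/(2N),
#' 1 -> 1 - 1/(2N), N the number of trials of that stimulus class) so both
#' statistics stay finite.
#'
#' @param trials A trial tibble with `true_side` and `response`.
#' @return A one-row tibble with `d_prime`, `criterion`, `hit_rate`,
#'   `fa_rate`, `n_right`, `n_left`.
#' @examples
#' tr <- tibble::tibble(
#'   true_side = rep(c("right", "left"), each = 10),
#'   response  = c(rep("right", 8), rep("left", 2),
#'                 rep("right", 3), rep("left", 7))
#' )
#' compute_sdt(tr) # d' ~ 1.366, c ~ -0.159
#' @export
compute_sdt <- function(trials) {
  right <- trials$true_side == "right"
  n_r <- sum(right)
  n_l <- sum(!right)
  if (n_r == 0L || n_l == 0L) {
    abort("Both stimulus classes (left and right) must be present.")
  }
  adjust <- function(p, n) {
    if (p <= 0) 1 / (2 * n) else if (p >= 1) 1 - 1 / (2 * n) else p
  }
  H <- adjust(mean(trials$response[right] == "right"), n_r)
  F <- adjust(mean(trials$response[!right] == "right"), n_l)
  tibble(
    d_prime = qnorm(H) - qnorm(F),
    criterion = -(qnorm(H) + qnorm(F)) / 2,
    hit_rate = H, fa_rate = F, n_right = n_r, n_left = n_l
  )
}
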