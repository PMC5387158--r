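#' Filter trials before behavioural analysis
#'
#' Applies, in order and in a single pass: (1) drop the first block
#' (staircase stabilisation); (2) drop non-responses; (3) drop trials with
#' RT below `rt_min_ms`; (4) drop trials whose RT deviates from the mean by
#' more than `rt_sd_mult` SDs, where mean and SD are computed once on the
#' post-(1-3) set. The rule is deliberately single-pass: re-applying it to
#' its own output can drop further trials because the mean/SD are
#' re-estimated.
#'
#' @param trials A trial tibble (one subject) with `block`, `response`,
#'   `rt_ms`.
#' @param rt_min_ms Fast-guess threshold in ms (default 100).
#' @param rt_sd_mult Outlier threshold in SDs of the retained-set mean
#'   (default 3).
#' @return A list with `trials` (the retained rows) and `report`, a one-row
#'   tibble with `n_input`, `n_dropped_first_block`, `n_dropped_no_response`,
#'   `n_dropped_rt_fast`, `n_dropped_rt_outlier`, `n_retained`.
#' @export
filter_trials <- function(trials, rt_min_ms = 100, rt_sd_mult = 3) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    abort("`trials` must be a non-empty data frame.")
  }
  n_input <- nrow(trials)
  first_block <- min(trials$block)
  keep <- trials$block != first_block
  n_block <- sum(!keep)
  t1 <- trials[keep, , drop = FALSE]

  responded <- !is.na(t1$response) & t1$response != "none"
  n_none <- sum(!responded)
  t2 <- t1[responded, , drop = FALSE]

  fast <- t2$rt_ms < rt_min_ms
  n_fast <- sum(fast)
  t3 <- t2[!fast, , drop = FALSE]

  m <- mean(t3$rt_ms)
  s <- sd(t3$rt_ms)
  outlier <- if (is.na(s) || s == 0) rep(FALSE, nrow(t3)) else
    abs(t3$rt_ms - m) > rt_sd_mult * s
  n_out <- sum(outlier)
  t4 <- t3[!outlier, , drop = FALSE]

  report <- tibble(
    n_input = n_input,
    n_dropped_first_block = n_block,
    n_dropped_no_response = n_none,
    n_dropped_rt_fast = n_fast,
    n_dropped_rt_outlier = n_out,
    n_retained = nrow(t4)
  )
  stopifnot(report$n_retained ==
              n_input - n_block - n_none - n_fast - n_out)
  list(trials = as_tibble(t4), report = report)
}

#' Assign confidence quartile bins (1-4) within subject
#'
#' Rank-based assignment of the raw 0-100 confidence ratings into 4 bins of
#' (near-)equal size; ties are broken by ascending trial index so the
#' assignment is deterministic, and bin sizes differ by at most one.
#' Because the binning is purely rank-based, any strictly monotone transform
#' of the raw confidence yields the identical assignment (and hence an
#' identical AROC).
#'
#' @param trials A trial tibble with `confidence_raw` and `trial_index`.
#' @param n_bins Number of bins (default 4).
#' @return `trials` with `confidence_bin` filled (integer 1 = lowest
#'   confidence quartile .. `n_bins` = highest).
#' @export
bin_confidence_quartiles <- function(trials, n_bins = 4L) {
  n <- nrow(trials)
  if (n < n_bins) {
    abort(sprintf("Need at least %d trials with confidence to bin.", n_bins))
  }
  if (anyNA(trials$confidence_raw)) {
    abort("`confidence_raw` contains missing values; filter trials first.")
  }
  ord <- order(trials$confidence_raw, trials$trial_index)
  bin <- integer(n)
  bin[ord] <- chunk_ranks(n, n_bins)
  trials$confidence_bin <- bin
  trials
}
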