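#' Type-II ROC and AROC: metacognitive sensitivity from binned confidence
#'
#' Builds the cumulative type-II ROC from the 4 confidence bins: for each
#' interior criterion k = 2..4, the type-II hit rate is
#' `H_k = P(confidence >= k | correct)` and the type-II false-alarm rate
#' `F_k = P(confidence >= k | incorrect)`. Anchoring with (0,0) and (1,1),
#' the AROC is the area under the piecewise-linear ROC through these points
#' (trapezoid rule). 0.5 means confidence carries no information about
#' accuracy; 1 means perfect separation of correct from incorrect trials.
#' Because performance is held near-constant by the staircases, AROC indexes
#' the sensitivity of confidence relative to actual performance.
#'
#' @param trials A trial tibble with logical `correct` and integer
#'   `confidence_bin` (see [bin_confidence_quartiles()]).
#' @param n_bins Number of confidence bins (default 4).
#' @return An object of class `type2_roc`: a list with `bin_counts_correct`,
#'   `bin_counts_incorrect` (counts per bin 1..n_bins), `cumulative_hit`,
#'   `cumulative_fa` (rates at criteria 2..n_bins, decreasing in k) and
#'   `aroc`.
#' @examples
#' tr <- tibble::tibble(
#'   correct = rep(c(TRUE, FALSE), c(20, 15)),
#'   confidence_bin = c(rep(1:4, c(2, 3, 5, 10)), rep(1:4, c(6, 5, 3, 1)))
#' )
#' compute_aroc(tr)$aroc
#' @export
compute_aroc <- function(trials, n_bins = 4L) {
  if (anyNA(trials$confidence_bin)) {
    abort("`confidence_bin` is unset; call bin_confidence_quartiles() first.")
  }
  cc <- tabulate(trials$confidence_bin[trials$correct], nbins = n_bins)
  ci <- tabulate(trials$confidence_bin[!trials$correct], nbins = n_bins)
  aroc_from_counts(cc, ci, n_bins)
}

# Core computation from per-bin counts; exported for count-table input.

#' @rdname compute_aroc
#' @param bin_counts_correct,bin_counts_incorrect Integer vectors of trial
#'   counts per confidence bin (low to high) for correct and incorrect
#'   trials.
#' @export
aroc_from_counts <- function(bin_counts_correct, bin_counts_incorrect,
                             n_bins = length(bin_counts_correct)) {
  cc <- as.numeric(bin_counts_correct)
  ci <- as.numeric(bin_counts_incorrect)
  if (sum(cc) == 0) abort("AROC undefined: no correct trials.")
  if (sum(ci) == 0) abort("AROC undefined: no incorrect trials.")
  # P(confidence >= k | class) for k = n_bins .. 2, then points low->high FA
  ks <- seq(n_bins, 2L)
  H <- vapply(ks, function(k) sum(cc[k:n_bins]) / sum(cc), numeric(1))
  F <- vapply(ks, function(k) sum(ci[k:n_bins]) / sum(ci), numeric(1))
  x <- c(0, F, 1)
  y <- c(0, H, 1)
  aroc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  structure(
    list(bin_counts_correct = cc, bin_counts_incorrect = ci,
         cumulative_hit = H, cumulative_fa = F, aroc = aroc),
    class = "type2_roc"
  )
}

#' @export
print.type2_roc <- function(x, ...) {
  cat(sprintf("<type2_roc> AROC = %.4f (%d correct, %d incorrect trials)\n",
              x$aroc, sum(x$bin_counts_correct), sum(x$bin_counts_incorrect)))
  invisible(x)
}

#' Tidy a type-II ROC: one row per ROC point
#'
#' @param x A `type2_roc` object.
#' @param ... Unused.
#' @return A tibble with `criterion`, `fa`, `hit` (anchors included) and the
#'   `aroc` value.
#' @export
#' @method tidy type2_roc
tidy.type2_roc <- function(x, ...) {
  tibble(
    criterion = c(NA_integer_, rev(seq_along(x$cumulative_fa)) + 1L,
                  NA_integer_),
    fa = c(0, x$cumulative_fa, 1),
    hit = c(0, x$cumulative_hit, 1),
    aroc = x$aroc
  )
}

#' Plot a type-II ROC curve
#'
#' @param object A `type2_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot type2_roc
autoplot.type2_roc <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fa, y = .data$hit)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "P(confidence ≥ k | incorrect)",
      y = "P(confidence ≥ k | correct)",
      title = sprintf("Type-II ROC, AROC = %.3f", object$aroc)
    ) +
    ggplot2::theme_minimal()
}
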