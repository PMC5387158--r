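#' Staircase-stability repeated-measures ANOVA
#'
#' Checks that performance is stable over the session: each subject's
#' retained trials are re-binned, within each staircase condition, into
#' `n_bins` consecutive equal-count bins (sizes differ by at most one);
#' per-bin accuracy is then analysed with a two-way fully within-subject
#' ANOVA (factors: bin and condition, subject as the random factor).
#' Uncorrected and Greenhouse-Geisser-adjusted p-values are reported side by
#' side for every within-subject effect.
#'
#' @param trials A filtered multi-subject trial tibble with `subject_id`,
#'   `condition`, `trial_index`, `correct`.
#' @param n_bins Number of time bins per condition (default 8).
#' @return A tibble with one row per effect (`bin`, `condition`,
#'   `bin:condition`): `df1`, `df2`, `statistic` (F), `p.value`,
#'   `gg_epsilon`, `p.value_gg`. The per-cell accuracies are attached as
#'   attribute `"cells"`.
#' @export
staircase_stability_anova <- function(trials, n_bins = 8L) {
  if (!"subject_id" %in% names(trials)) {
    trials$subject_id <- "S001"
  }
  cells <- trials |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < n_bins) {
        abort(sprintf(
          "Subject %s has only %d retained %s-condition trials; cannot form %d bins.",
          key$subject_id, nrow(d), key$condition, n_bins))
      }
      d <- dplyr::arrange(d, .data$trial_index)
      tibble(bin = chunk_ranks(nrow(d), n_bins), correct = d$correct) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
    }) |>
    dplyr::ungroup()

  rm_anova_2way(cells, id = "subject_id", a = "bin", b = "condition",
                value = "accuracy")
}

# Balanced two-way fully within-subject ANOVA with one observation per
# subject x cell, classical sums-of-squares partition; each within effect is
# tested against its interaction with subject. Greenhouse-Geisser epsilon is
# computed per effect from the covariance of the subject-level contrast
# scores.
rm_anova_2way <- function(cells, id, a, b, value) {
  cells[[a]] <- factor(cells[[a]])
  cells[[b]] <- factor(cells[[b]])
  cells[[id]] <- factor(cells[[id]])
  na <- nlevels(cells[[a]])
  nb <- nlevels(cells[[b]])
  ns <- nlevels(cells[[id]])
  if (nrow(cells) != na * nb * ns) {
    abort("Design is not balanced: expected one observation per subject x cell.")
  }
  # data cube subjects x a x b
  Y <- array(NA_real_, dim = c(ns, na, nb))
  Y[cbind(as.integer(cells[[id]]), as.integer(cells[[a]]),
          as.integer(cells[[b]]))] <- cells[[value]]

  G <- mean(Y)
  m_s <- apply(Y, 1L, mean)
  m_a <- apply(Y, 2L, mean)
  m_b <- apply(Y, 3L, mean)
  m_ab <- apply(Y, c(2L, 3L), mean)
  m_as <- apply(Y, c(1L, 2L), mean)
  m_bs <- apply(Y, c(1L, 3L), mean)

  ss_a <- ns * nb * sum((m_a - G)^2)
  ss_b <- ns * na * sum((m_b - G)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + G)^2)
  ss_as <- nb * sum((m_as - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + G)^2)
  ss_bs <- na * sum((m_bs - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + G)^2)
  resid <- Y
  for (s in seq_len(ns)) for (i in seq_len(na)) for (j in seq_len(nb)) {
    resid[s, i, j] <- Y[s, i, j] - m_as[s, i] - m_bs[s, j] - m_ab[i, j] +
      m_s[s] + m_a[i] + m_b[j] - G
  }
  ss_abs <- sum(resid^2)

  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_eff < 1e-12) return(0)
    (ss_eff / df_eff) / (ss_err / df_err)
  }

  # Greenhouse-Geisser epsilon from subject-level contrast scores
  gg_eps <- function(scores) {
    df <- ncol(scores)
    if (df <= 1L) return(1)
    S <- cov(scores)
    tr <- sum(diag(S))
    if (tr < 1e-14) return(1)
    tr^2 / (df * sum(S * S))
  }
  ortho <- function(k) {
    C <- stats::contr.helmert(k)
    sweep(C, 2L, sqrt(colSums(C^2)), "/")
  }
  Ca <- ortho(na)
  Cb <- ortho(nb)
  eps_a <- gg_eps(m_as %*% Ca)
  eps_b <- gg_eps(m_bs %*% Cb)
  # interaction scores: subject x (a-contrast x b-contrast)
  Yab <- matrix(aperm(Y, c(1L, 2L, 3L)), nrow = ns) # subjects x (a*b), a fastest
  Cab <- kronecker(Cb, Ca)
  eps_ab <- gg_eps(Yab %*% Cab)

  eff <- tibble(
    term = c("bin", "condition", "bin:condition"),
    df1 = c(na - 1L, nb - 1L, (na - 1L) * (nb - 1L)),
    df2 = c((na - 1L) * (ns - 1L), (nb - 1L) * (ns - 1L),
            (na - 1L) * (nb - 1L) * (ns - 1L)),
    statistic = c(f_of(ss_a, na - 1L, ss_as, (na - 1L) * (ns - 1L)),
                  f_of(ss_b, nb - 1L, ss_bs, (nb - 1L) * (ns - 1L)),
                  f_of(ss_ab, (na - 1L) * (nb - 1L), ss_abs,
                       (na - 1L) * (nb - 1L) * (ns - 1L))),
    gg_epsilon = c(eps_a, eps_b, eps_ab)
  )
  eff$p.value <- pf(eff$statistic, eff$df1, eff$df2, lower.tail = FALSE)
  eff$p.value_gg <- pf(eff$statistic, eff$df1 * eff$gg_epsilon,
                       eff$df2 * eff$gg_epsilon, lower.tail = FALSE)
  eff <- eff[, c("term", "df1", "df2", "statistic", "p.value",
                 "gg_epsilon", "p.value_gg")]
  attr(eff, "cells") <- cells
  eff
}
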