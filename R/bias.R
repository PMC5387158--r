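#' Within-subject confidence-bias regression
#'
#' Ordinary least squares of raw confidence on the trial-wise stimulus mean
#' angle, stimulus SD, accuracy and RT (plus an intercept), with all
#' predictors standardised within subject. The `sd_angle` weight is the
#' variance-induced confidence bias: the degree to which a subject's
#' confidence tracks stimulus variability over and above its association
#' with the other modelled factors.
#'
#' Predictors that are constant within the subject (zero variance) are
#' dropped from the model and flagged with `dropped = TRUE` and `NA`
#' estimates.
#'
#' @param trials A filtered trial tibble (>= 20 rows) with `confidence_raw`,
#'   `mean_angle`, `sd_angle`, `correct`, `rt_ms`.
#' @return A tibble with one row per term (`intercept`, `mean_angle`,
#'   `sd_angle`, `correct`, `rt_ms`): `estimate`, `se`, `statistic`,
#'   `dropped`.
#' @export
confidence_bias_betas <- function(trials) {
  if (nrow(trials) < 20L) {
    abort("Need at least 20 retained trials for the bias regression.")
  }
  preds <- c("mean_angle", "sd_angle", "correct", "rt_ms")
  Xraw <- cbind(trials$mean_angle, trials$sd_angle,
                as.numeric(trials$correct), trials$rt_ms)
  colnames(Xraw) <- preds
  sds <- apply(Xraw, 2L, sd)
  keep <- is.finite(sds) & sds > 0
  if (!all(keep)) {
    warn(sprintf("Dropping constant predictor(s): %s",
                 paste(preds[!keep], collapse = ", ")))
  }
  Xs <- scale(Xraw[, keep, drop = FALSE])
  X <- cbind(intercept = 1, Xs)
  y <- trials$confidence_raw
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  p <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)

  terms <- c("intercept", preds)
  out <- tibble(term = terms, estimate = NA_real_, se = NA_real_,
                statistic = NA_real_, dropped = c(FALSE, !keep))
  est <- setNames(fit$coefficients, colnames(X))
  ses <- setNames(se, colnames(X))
  hit <- match(c("intercept", preds[keep]), out$term)
  out$estimate[hit] <- est
  out$se[hit] <- ses
  out$statistic[hit] <- est / ses
  out
}
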