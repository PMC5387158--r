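#' Build the group-level design matrix for the voxelwise regression
#'
#' Columns: intercept; average AROC (the effect of interest, kept on its
#' native scale — the t statistic is scale-invariant); behavioural
#' covariates (average d', average confidence, criterion, the
#' variance-induced confidence-bias beta, the staircase mean-signal
#' difference); and demographic nuisance covariates (age, gender, total
#' intracranial volume). Continuous covariates are z-scored; gender is
#' mean-centred. Constant columns are dropped with a warning; any remaining
#' rank deficiency is an error naming the collinear columns.
#'
#' @param subject_summaries Output of [summarise_cohort()] (one row per
#'   subject; columns `aroc`, `d_prime`, `mean_confidence_100`, `criterion`,
#'   `variance_bias_beta`, `staircase_mean_signal_diff`, `age`, `gender`,
#'   `tiv`).
#' @return A list of class `vbq_design`: `X` (n x p numeric matrix),
#'   `effect` (name of the AROC column), `dropped` (names of dropped
#'   constant columns), `subject_ids`.
#' @export
build_design <- function(subject_summaries) {
  s <- subject_summaries
  need <- c("aroc", "d_prime", "mean_confidence_100", "criterion",
            "variance_bias_beta", "staircase_mean_signal_diff",
            "age", "gender", "tiv")
  miss <- setdiff(need, names(s))
  if (length(miss) > 0L) {
    abort(sprintf("Missing covariates: %s.", paste(miss, collapse = ", ")))
  }
  if (any(!complete.cases(s[, need]))) {
    abort("Missing values in covariates.")
  }
  z <- function(x) (x - mean(x)) / sd(x)
  cols <- list(
    intercept = rep(1, nrow(s)),
    aroc = s$aroc,
    d_prime = z(s$d_prime),
    mean_confidence = z(s$mean_confidence_100),
    criterion = z(s$criterion),
    variance_bias = z(s$variance_bias_beta),
    signal_diff = z(s$staircase_mean_signal_diff),
    age = z(s$age),
    gender = s$gender - mean(s$gender),
    tiv = z(s$tiv)
  )
  const <- vapply(cols, function(x) !all(is.finite(x)) ||
                    length(unique(x)) == 1L, logical(1))
  const["intercept"] <- FALSE
  if (any(const)) {
    warn(sprintf("Dropping constant covariate(s): %s",
                 paste(names(cols)[const], collapse = ", ")))
    cols <- cols[!const]
  }
  X <- do.call(cbind, cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(sprintf("Design is rank deficient; collinear column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  structure(
    list(X = X, effect = "aroc", dropped = names(const)[const],
         subject_ids = s$subject_id %||% rownames(X)),
    class = "vbq_design"
  )
}

#' @export
print.vbq_design <- function(x, ...) {
  cat(sprintf("<vbq_design> %d subjects x %d columns (%s)\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}
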