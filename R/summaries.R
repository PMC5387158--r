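#' Summarise one subject's behaviour
#'
#' Computes the per-condition and across-condition summary statistics that
#' feed the group-level voxelwise design: accuracy, mean RT, mean confidence
#' on both the 0-100 and binned 1-4 scales, d', criterion, AROC and the
#' median adaptive level, plus the within-subject confidence-bias weights
#' and the staircase mean-signal difference (median adaptive mean angle in
#' the mu condition minus the fixed mean angle of the sigma condition).
#'
#' Filtering and quartile binning are applied here if not already done
#' (binning is per subject across conditions; AROC is computed separately
#' per condition and averaged).
#'
#' @param trials One subject's trial tibble.
#' @param covariates Optional one-row data frame / list with `age`, `gender`,
#'   `tiv` to carry into the summary.
#' @param fixed_mean_angle The sigma-condition fixed mean angle (degrees)
#'   used for the mean-signal difference (default 15).
#' @param already_filtered Set `TRUE` if `trials` has been passed through
#'   [filter_trials()] already.
#' @return A one-row tibble with columns `accuracy`, `mean_rt_ms`,
#'   `mean_confidence_100`, `mean_confidence_binned`, `d_prime`, `criterion`,
#'   `aroc` (per-condition variants suffixed `_mu` / `_sigma`, the average
#'   unsuffixed), `median_level_mu`, `median_level_sigma`,
#'   `variance_bias_beta`, `staircase_mean_signal_diff`, `n_trials`, and any
#'   covariates supplied.
#' @export
summarise_subject <- function(trials, covariates = NULL,
                              fixed_mean_angle = 15,
                              already_filtered = FALSE) {
  if (!already_filtered) {
    trials <- filter_trials(trials)$trials
  }
  if (!all(c("mu", "sigma") %in% trials$condition)) {
    abort("Both staircase conditions must be present to summarise a subject.")
  }
  if (anyNA(trials$confidence_bin)) {
    trials <- bin_confidence_quartiles(trials)
  }

  per_cond <- function(d) {
    sdt <- compute_sdt(d)
    tibble(
      accuracy = mean(d$correct),
      mean_rt_ms = mean(d$rt_ms),
      mean_confidence_100 = mean(d$confidence_raw),
      mean_confidence_binned = mean(d$confidence_bin),
      d_prime = sdt$d_prime,
      criterion = sdt$criterion,
      aroc = compute_aroc(d)$aroc
    )
  }
  mu_d <- trials[trials$condition == "mu", ]
  sg_d <- trials[trials$condition == "sigma", ]
  s_mu <- per_cond(mu_d)
  s_sg <- per_cond(sg_d)
  avg <- (s_mu + s_sg) / 2

  betas <- confidence_bias_betas(trials)
  out <- dplyr::bind_cols(
    avg,
    dplyr::rename_with(s_mu, ~ paste0(.x, "_mu")),
    dplyr::rename_with(s_sg, ~ paste0(.x, "_sigma"))
  )
  out$median_level_mu <- median(mu_d$mean_angle)
  out$median_level_sigma <- median(sg_d$sd_angle)
  out$variance_bias_beta <-
    betas$estimate[betas$term == "sd_angle"]
  out$staircase_mean_signal_diff <- out$median_level_mu - fixed_mean_angle
  out$n_trials <- nrow(trials)
  if (!is.null(covariates)) {
    out <- dplyr::bind_cols(out, as_tibble(as.list(covariates)))
  }
  out
}

#' Summarise every subject of a behavioural cohort
#'
#' Maps [filter_trials()], [bin_confidence_quartiles()] and
#' [summarise_subject()] over the cohort and joins the demographic
#' covariates. The result is the subject-level table consumed by
#' [build_design()].
#'
#' @param cohort A `behaviour_cohort` from [simulate_cohort()], or a trial
#'   tibble with a `subject_id` column plus a `subjects` covariate table.
#' @param subjects Covariate table when `cohort` is a plain tibble.
#' @return A tibble with one row per subject (see [summarise_subject()]),
#'   including `age`, `gender`, `tiv`. Filter reports are attached as
#'   attribute `"filter_reports"`.
#' @export
summarise_cohort <- function(cohort, subjects = NULL) {
  if (inherits(cohort, "behaviour_cohort")) {
    trials <- cohort$trials
    subjects <- cohort$subjects
  } else {
    trials <- cohort
  }
  fixed_mean <- if (inherits(cohort, "behaviour_cohort")) {
    cohort$config$fixed_mean_angle
  } else 15

  ids <- unique(trials$subject_id)
  reports <- list()
  rows <- purrr::map(ids, function(sid) {
    d <- trials[trials$subject_id == sid, ]
    f <- filter_trials(d)
    reports[[sid]] <<- f$report
    cov <- NULL
    if (!is.null(subjects)) {
      cov <- subjects[subjects$subject_id == sid,
                      intersect(c("age", "gender", "tiv"), names(subjects))]
    }
    s <- summarise_subject(f$trials, covariates = cov,
                           fixed_mean_angle = fixed_mean,
                           already_filtered = TRUE)
    dplyr::mutate(s, subject_id = sid, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "filter_reports") <-
    dplyr::bind_rows(reports, .id = "subject_id")
  out
}

#' Write / read trial tables as CSV
#'
#' Plain-text round-trip of the trial-table column contract
#' (`subject_id` optional, then `trial_index`, `block`, `condition`,
#' `true_side`, `mean_angle`, `sd_angle`, `response`, `correct`, `rt_ms`,
#' `confidence_raw`, `confidence_bin`).
#'
#' @param trials A trial tibble.
#' @param path Output CSV path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   tibble.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      trial_index = readr::col_integer(),
      block = readr::col_integer(),
      condition = readr::col_character(),
      true_side = readr::col_character(),
      response = readr::col_character(),
      correct = readr::col_logical(),
      confidence_bin = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
}
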