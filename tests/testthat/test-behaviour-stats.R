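make_trials <- function(rt, block = NULL, response = "right",
                        true_side = "right", confidence = 50) {
  n <- length(rt)
  tibble::tibble(
    trial_index = seq_len(n),
    block = block %||% rep(1:2, length.out = n),
    condition = rep(c("mu", "sigma"), length.out = n),
    true_side = rep(true_side, length.out = n),
    mean_angle = 10, sd_angle = 30,
    response = rep(response, length.out = n),
    correct = rep(response, length.out = n) == rep(true_side, length.out = n),
    rt_ms = rt,
    confidence_raw = rep(confidence, length.out = n),
    confidence_bin = NA_integer_
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("trial filter drops first block, fast RTs and 3-SD outliers in one pass", {
  # zero-variance RTs: only the first block goes
  tr <- make_trials(rep(400, 320), block = rep(1:8, each = 40))
  f <- filter_trials(tr)
  expect_equal(f$report$n_dropped_first_block, 40L)
  expect_equal(f$report$n_dropped_rt_fast, 0L)
  expect_equal(f$report$n_dropped_rt_outlier, 0L)
  expect_equal(f$report$n_retained, 280L)

  # a 50 ms trial is counted as a fast guess
  rts <- rep(400, 80); rts[41] <- 50
  f2 <- filter_trials(make_trials(rts, block = rep(1:2, each = 40)))
  expect_equal(f2$report$n_dropped_rt_fast, 1L)

  # hand-computed 3 SD rule on a 12-trial toy (block 0 padding dropped first)
  rt12 <- c(400, 410, 390, 405, 395, 400, 410, 390, 2000, 405, 395, 400)
  toy <- make_trials(c(300, rt12), block = c(0, rep(1, 12)))
  m <- mean(rt12); s <- sd(rt12)
  expected_drop <- which(abs(rt12 - m) > 3 * s)
  f3 <- filter_trials(toy)
  expect_equal(f3$report$n_dropped_rt_outlier, length(expected_drop))
  expect_false(2000 %in% f3$trials$rt_ms)

  # single pass: outlier mean/SD are not re-estimated after removal
  # (re-applying the rule to the output can drop more - documented behaviour)
  f4 <- filter_trials(dplyr::mutate(f3$trials, block = block + 1L))
  expect_true(f4$report$n_retained <= f3$report$n_retained)

  # non-responses are dropped and counted
  tr5 <- make_trials(rep(400, 60), block = rep(1:2, each = 30))
  tr5$response[35] <- "none"
  f5 <- filter_trials(tr5)
  expect_equal(f5$report$n_dropped_no_response, 1L)

  # counts always reconcile
  for (f in list(f, f2, f3, f5)) {
    expect_equal(f$report$n_retained,
                 f$report$n_input - f$report$n_dropped_first_block -
                   f$report$n_dropped_no_response - f$report$n_dropped_rt_fast -
                   f$report$n_dropped_rt_outlier)
  }
  expect_error(filter_trials(tibble::tibble()), "non-empty")
})

test_that("confidence quartile binning is rank-based, deterministic and balanced", {
  tr <- make_trials(rep(400, 8))
  tr$confidence_raw <- c(10, 80, 35, 60, 5, 95, 50, 20)
  b <- bin_confidence_quartiles(tr)
  expect_equal(unname(table(b$confidence_bin)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(b$confidence_bin[tr$confidence_raw == 5], 1L)
  expect_equal(b$confidence_bin[tr$confidence_raw == 95], 4L)

  # total tie: split deterministically by trial order, sizes differ by <= 1
  tr2 <- make_trials(rep(400, 10), confidence = 50)
  b2 <- bin_confidence_quartiles(tr2)
  expect_equal(b2$confidence_bin, c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L))

  # rank invariance: strictly monotone transform gives identical bins
  set.seed(5)
  tr3 <- make_trials(rep(400, 100))
  tr3$confidence_raw <- runif(100, 0, 100)
  b3 <- bin_confidence_quartiles(tr3)
  tr4 <- tr3
  tr4$confidence_raw <- 100 * plogis(tr3$confidence_raw / 10 - 4)
  b4 <- bin_confidence_quartiles(tr4)
  expect_identical(b3$confidence_bin, b4$confidence_bin)

  expect_error(bin_confidence_quartiles(make_trials(rep(400, 3))), "at least")
})

test_that("d-prime and criterion match the closed-form quantile solution", {
  # H = F -> d' = 0
  tr <- tibble::tibble(
    true_side = rep(c("right", "left"), each = 10),
    response = rep(c("right", "left"), 10)
  )
  s <- compute_sdt(tr)
  expect_equal(s$d_prime, 0)

  # H = 0.8, F = 0.3
  tr2 <- tibble::tibble(
    true_side = rep(c("right", "left"), each = 10),
    response = c(rep("right", 8), rep("left", 2),
                 rep("right", 3), rep("left", 7))
  )
  s2 <- compute_sdt(tr2)
  expect_equal(s2$d_prime, qnorm(0.8) - qnorm(0.3), tolerance = 1e-12)
  expect_equal(s2$d_prime, 1.3660217, tolerance = 1e-6)
  expect_equal(s2$criterion, -0.1586104, tolerance = 1e-6)

  # extreme rates stay finite via the 1/(2N) rule
  tr3 <- tibble::tibble(true_side = rep(c("right", "left"), each = 10),
                        response = rep(c("right", "left"), each = 10))
  s3 <- compute_sdt(tr3)
  expect_true(is.finite(s3$d_prime))
  expect_equal(s3$hit_rate, 1 - 1 / 20)

  expect_error(compute_sdt(tibble::tibble(true_side = rep("right", 5),
                                          response = rep("right", 5))),
               "Both stimulus classes")
})

test_that("AROC equals the brute-force trapezoid oracle and hits its limits", {
  # frozen worked example
  r <- aroc_from_counts(c(2, 3, 5, 10), c(6, 5, 3, 1))
  expect_equal(r$aroc, brute_aroc(c(2, 3, 5, 10), c(6, 5, 3, 1)),
               tolerance = 1e-12)
  expect_equal(r$aroc, 239 / 300, tolerance = 1e-12)
  expect_true(all(diff(r$cumulative_hit) >= 0))  # stored k = 4..2 ascending

  # confidence independent of correctness -> 0.5; perfect separation -> 1
  expect_equal(aroc_from_counts(c(5, 5, 5, 5), c(3, 3, 3, 3))$aroc, 0.5)
  expect_equal(aroc_from_counts(c(0, 0, 0, 9), c(7, 0, 0, 0))$aroc, 1.0)

  # random count tables: exact agreement with the oracle
  set.seed(77)
  for (i in seq_len(300)) {
    cc <- rmultinom(1, sample(8:60, 1), runif(4, .1, 1))[, 1]
    ci <- rmultinom(1, sample(8:60, 1), runif(4, .1, 1))[, 1]
    if (sum(cc) == 0 || sum(ci) == 0) next
    expect_equal(aroc_from_counts(cc, ci)$aroc, brute_aroc(cc, ci),
                 tolerance = 1e-12)
  }

  expect_error(aroc_from_counts(c(1, 2, 3, 4), c(0, 0, 0, 0)), "incorrect")
  tr <- make_trials(rep(400, 8))
  expect_error(compute_aroc(tr), "unset")
})

test_that("bias regression matches the normal-equations oracle and flags constants", {
  set.seed(8)
  n <- 24
  tr <- tibble::tibble(
    trial_index = 1:n, block = 2L, condition = "mu",
    true_side = "right", response = "right",
    mean_angle = runif(n, 2, 15), sd_angle = runif(n, 25, 60),
    correct = runif(n) < 0.7, rt_ms = runif(n, 300, 600),
    confidence_raw = runif(n, 10, 90), confidence_bin = NA_integer_
  )
  b <- confidence_bias_betas(tr)
  X <- cbind(1, scale(cbind(tr$mean_angle, tr$sd_angle, as.numeric(tr$correct),
                            tr$rt_ms)))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% tr$confidence_raw)
  expect_equal(b$estimate, as.numeric(beta_oracle), tolerance = 1e-10)

  # constant predictor dropped and flagged
  tr2 <- tr
  tr2$sd_angle <- 30
  expect_warning(b2 <- confidence_bias_betas(tr2), "sd_angle")
  expect_true(b2$dropped[b2$term == "sd_angle"])
  expect_true(is.na(b2$estimate[b2$term == "sd_angle"]))

  expect_error(confidence_bias_betas(tr[1:10, ]), "at least 20")
})

test_that("stability ANOVA: zero-variance cells give F = 0, oracle matches aov", {
  # identical accuracies -> all F = 0
  cells <- expand.grid(subject_id = sprintf("S%d", 1:5), bin = 1:4,
                       condition = c("mu", "sigma"))
  cells$accuracy <- 0.75
  flat <- metavbq:::rm_anova_2way(cells, "subject_id", "bin", "condition",
                                  "accuracy")
  expect_equal(flat$statistic, c(0, 0, 0))

  # random balanced table: F and p match the aov() Error-strata oracle
  set.seed(21)
  cells$accuracy <- runif(nrow(cells), 0.6, 0.9) +
    0.05 * (cells$condition == "sigma")
  ours <- metavbq:::rm_anova_2way(cells, "subject_id", "bin", "condition",
                                  "accuracy")
  fit <- stats::aov(accuracy ~ bin * condition +
                      Error(subject_id / (bin * condition)),
                    data = transform(cells, bin = factor(bin),
                                     condition = factor(condition),
                                     subject_id = factor(subject_id)))
  sm <- summary(fit)
  f_aov <- c(sm[["Error: subject_id:bin"]][[1]]["bin", "F value"],
             sm[["Error: subject_id:condition"]][[1]]["condition", "F value"],
             sm[["Error: subject_id:bin:condition"]][[1]]["bin:condition",
                                                          "F value"])
  expect_equal(ours$statistic, unname(f_aov), tolerance = 1e-8)

  # pure condition offset: F_condition from the classical partition by hand
  cells2 <- expand.grid(subject_id = sprintf("S%d", 1:4), bin = 1:2,
                        condition = c("mu", "sigma"))
  base <- c(S1 = 0.70, S2 = 0.72, S3 = 0.74, S4 = 0.76)
  cells2$accuracy <- base[as.character(cells2$subject_id)] +
    0.04 * (cells2$condition == "sigma")
  ours2 <- metavbq:::rm_anova_2way(cells2, "subject_id", "bin", "condition",
                                   "accuracy")
  # no subject x condition variability: the effect is infinite-F; our
  # implementation returns Inf there (SS_err = 0, SS_eff > 0)
  expect_true(is.infinite(ours2$statistic[2]) || ours2$statistic[2] > 1e10)
  expect_equal(ours2$statistic[1], 0)  # no bin effect

  # end-to-end: re-binning errors name the subject when infeasible
  sparse <- tibble::tibble(subject_id = "S9", condition = "mu",
                           trial_index = 1:5, correct = TRUE)
  expect_error(staircase_stability_anova(sparse, n_bins = 8), "S9")
})

test_that("stability ANOVA p-values are calibrated under a stationary null", {
  set.seed(99)
  rejections <- replicate(150, {
    cells <- expand.grid(subject_id = sprintf("S%d", 1:12), bin = 1:8,
                         condition = c("mu", "sigma"))
    cells$accuracy <- rbinom(nrow(cells), 20, 0.71) / 20
    a <- metavbq:::rm_anova_2way(cells, "subject_id", "bin", "condition",
                                 "accuracy")
    a$p.value[a$term == "bin"] < 0.05
  })
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.11)
})

test_that("subject summaries carry the full Table-style column set", {
  co <- simulate_cohort(4, seed = 77)
  s <- summarise_cohort(co)
  expect_equal(nrow(s), 4L)
  need <- c("subject_id", "accuracy", "mean_rt_ms", "mean_confidence_100",
            "mean_confidence_binned", "d_prime", "criterion", "aroc",
            "accuracy_mu", "accuracy_sigma", "aroc_mu", "aroc_sigma",
            "median_level_mu", "median_level_sigma", "variance_bias_beta",
            "staircase_mean_signal_diff", "age", "gender", "tiv")
  expect_true(all(need %in% names(s)))
  expect_true(all(s$aroc >= 0 & s$aroc <= 1))
  expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
  # averaged stats are the mean of the two condition-wise stats
  expect_equal(s$aroc, (s$aroc_mu + s$aroc_sigma) / 2)
  rep <- attr(s, "filter_reports")
  expect_equal(nrow(rep), 4L)

  # degenerate all-correct input propagates the AROC error
  tr <- co$trials[co$trials$subject_id == "S001", ]
  tr$correct <- TRUE
  tr$response <- tr$true_side
  expect_error(summarise_subject(tr), "incorrect")

  # missing condition is an error
  expect_error(summarise_subject(tr[tr$condition == "mu", ]),
               "Both staircase conditions")
})

test_that("trial tables round-trip through CSV", {
  tr <- run_session(seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, f)
  tr2 <- read_trials(f)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
})
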