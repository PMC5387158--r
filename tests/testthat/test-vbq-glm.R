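test_that("design matrix has the full covariate set and guards against collinearity", {
  s <- make_summaries(48, seed = 1)
  d <- build_design(s)
  expect_equal(dim(d$X), c(48L, 10L))
  expect_equal(colnames(d$X),
               c("intercept", "aroc", "d_prime", "mean_confidence",
                 "criterion", "variance_bias", "signal_diff", "age",
                 "gender", "tiv"))
  # continuous nuisance covariates are z-scored, AROC stays native
  expect_equal(unname(colMeans(d$X[, 3:10])), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(d$X[, c(3:8, 10)], 2, sd)), rep(1, 7),
               tolerance = 1e-12)
  expect_equal(d$X[, "aroc"], s$aroc)

  # constant gender column is dropped with a warning
  s2 <- s; s2$gender <- 1L
  expect_warning(d2 <- build_design(s2), "gender")
  expect_false("gender" %in% colnames(d2$X))

  # duplicated information is a rank error naming the column
  s3 <- s; s3$variance_bias_beta <- s3$d_prime
  expect_error(build_design(s3), "rank deficient")

  s4 <- s[, setdiff(names(s), "tiv")]
  expect_error(build_design(s4), "tiv")
})

test_that("voxelwise t-statistics match the per-voxel lm oracle", {
  set.seed(2)
  n <- 12
  s <- make_summaries(n, seed = 3)
  mask <- array(FALSE, c(3, 2, 2))
  mask[1:3] <- TRUE
  g <- grid_spec(shape = c(3L, 2L, 2L), voxel_size_mm = 2, gm_mask = mask)
  Y <- matrix(rnorm(n * 3, mean = 1), n, 3)
  Y[, 2] <- Y[, 2] + 2 * s$aroc
  mc <- manual_cohort(Y, g)
  # 12 subjects cannot support 10 columns + intercept-only margin? p = 10, ok
  d <- build_design(s)
  tm <- fit_voxelwise(mc, d, "MT")
  oracle <- vapply(1:3, function(v) {
    summary(stats::lm(Y[, v] ~ d$X - 1))$coefficients["d$Xaroc", "t value"]
  }, numeric(1))
  expect_equal(tm$t, oracle, tolerance = 1e-10)
  expect_equal(tm$df, n - 10L)

  # contrast antisymmetry
  tneg <- fit_voxelwise(mc, d, "MT", contrast = "neg")
  expect_equal(tneg$t, -tm$t, tolerance = 1e-12)

  # fewer subjects than columns is an error
  d9 <- d
  d9$X <- d$X[1:9, ]
  mc9 <- manual_cohort(Y[1:9, ], g)
  expect_error(fit_voxelwise(mc9, d9, "MT"), "Fewer subjects")
})

test_that("null-cohort t-maps follow the Student t reference distribution", {
  n <- 24
  s <- make_summaries(n, seed = 5)
  g <- grid_spec(shape = c(14L, 14L, 10L), voxel_size_mm = 6,
                 origin_mm = c(-39, -41, -23),
                 gm_mask = array(TRUE, c(14, 14, 10)))
  p <- map_params(noise_fwhm_mm = 0)   # independent voxels for the KS check
  mc <- generate_cohort_maps(s, default_effect_sites()[0, ], g, p,
                             map_types = "MT", seed = 6)
  tm <- fit_voxelwise(mc, build_design(s), "MT")
  ks <- stats::ks.test(tm$t, "pt", df = tm$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("VOI sphere masks match analytic sphere volumes and unions", {
  # fine grid: discretised 5 mm sphere within 10% of (4/3) pi r^3
  g1 <- grid_spec(shape = c(31L, 31L, 31L), voxel_size_mm = 1,
                  origin_mm = c(-15, -15, -15),
                  gm_mask = array(TRUE, c(31, 31, 31)))
  ctr <- tibble::tibble(x = 0.4, y = -0.3, z = 0.7)
  m1 <- make_voi_mask(ctr, g1, radius_mm = 5)
  expect_gt(length(m1), 4 / 3 * pi * 125 * 0.9)
  expect_lt(length(m1), 4 / 3 * pi * 125 * 1.1)

  # two nearby centres: union is smaller than the sum (overlap)
  two <- tibble::tibble(x = c(1, 0), y = c(0, 0), z = c(2, 0))
  m2 <- make_voi_mask(two, g1, radius_mm = 5)
  expect_lt(length(m2), 2 * length(m1) * 1.05)
  expect_lt(length(m2), length(make_voi_mask(two[1, ], g1, 5)) +
              length(make_voi_mask(two[2, ], g1, 5)))

  # radius 0 keeps exactly the centre voxels
  m3 <- make_voi_mask(tibble::tibble(x = 0, y = 0, z = 0), g1, radius_mm = 0)
  expect_equal(length(m3), 1L)
  expect_equal(voxel_to_world(g1, arrayInd(m3, g1$shape)),
               matrix(c(0, 0, 0), 1))

  # centre outside the grid errors
  expect_error(make_voi_mask(tibble::tibble(x = 90, y = 0, z = 0), g1, 5),
               "outside the grid")

  # default VOI set intersects the default grey-matter mask
  g <- grid_spec()
  voi <- make_voi_mask(grid = g)
  expect_gt(length(voi), 100L)
  expect_true(all(g$gm_mask[voi]))
})

test_that("26-connectivity labelling agrees with a brute-force flood fill", {
  set.seed(7)
  for (i in 1:5) {
    vol <- array(runif(14 * 10 * 8) < 0.25, dim = c(14, 10, 8))
    vox <- which(vol)
    ours <- metavbq:::label_clusters(vox, dim(vol))
    brute <- brute_label(vol)
    # same partition: co-membership matrices agree
    expect_equal(length(ours), length(brute))
    expect_true(all(tapply(brute, ours, function(x) length(unique(x))) == 1))
    expect_true(all(tapply(ours, brute, function(x) length(unique(x))) == 1))
    expect_equal(metavbq:::max_cluster_extent(vox, dim(vol)),
                 max(tabulate(brute)))
  }
  expect_equal(metavbq:::max_cluster_extent(integer(0), c(5, 5, 5)), 0L)
})

test_that("permutation p-values respect the 1/n_perm floor with the identity first", {
  n <- 16
  s <- make_summaries(n, seed = 8)
  g <- grid_spec(shape = c(6L, 6L, 4L), voxel_size_mm = 6,
                 origin_mm = c(-15, -15, -9),
                 gm_mask = array(TRUE, c(6, 6, 4)))
  set.seed(9)
  Y <- matrix(rnorm(n * 144, sd = 0.1), n, 144)
  Y[, 50] <- Y[, 50] + 5 * s$aroc   # overwhelming effect at one voxel
  mc <- manual_cohort(Y, g)
  d <- build_design(s)
  res <- suppressWarnings(
    permutation_fwe(mc, d, "MT", "pos", "peak", n_perm = 10, seed = 10))
  expect_equal(min(res$peaks$p_fwe_peak), 1 / 10)
  expect_equal(res$peaks$voxel_index[1], mc$mask_index[50])
  expect_warning(
    permutation_fwe(mc, d, "MT", "pos", "peak", n_perm = 5, seed = 1),
    "cannot resolve")
})

test_that("permutation inference matches a brute-force Freedman-Lane reference", {
  n <- 14
  s <- make_summaries(n, seed = 11)
  g <- grid_spec(shape = c(4L, 4L, 3L), voxel_size_mm = 6,
                 origin_mm = c(-9, -9, -6), gm_mask = array(TRUE, c(4, 4, 3)))
  set.seed(12)
  Y <- matrix(rnorm(n * 48), n, 48)
  mc <- manual_cohort(Y, g)
  d <- build_design(s)
  res <- suppressWarnings(
    permutation_fwe(mc, d, "MT", "pos", "peak", n_perm = 6, seed = 13))
  X <- d$X
  a <- match("aroc", colnames(X))
  Z <- X[, -a]
  Rz <- diag(n) - Z %*% solve(crossprod(Z)) %*% t(Z)
  W <- Rz %*% Y
  t_full <- function(M) {
    vapply(seq_len(ncol(M)), function(v) {
      summary(stats::lm(M[, v] ~ X - 1))$coefficients["Xaroc", "t value"]
    }, numeric(1))
  }
  expect_equal(res$tmap$t, t_full(Y), tolerance = 1e-10)
  set.seed(13)
  mx <- c(max(t_full(Y)),
          vapply(1:5, function(b) {
            p <- sample.int(n)
            max(t_full(W[order(p), ]))
          }, numeric(1)))
  expect_equal(res$null_max_t, mx, tolerance = 1e-10)
})

test_that("report tables round-trip and handle empty results", {
  empty <- report_tables(list())
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(empty, f)
  back <- read_report(f)
  expect_equal(nrow(back), 0L)
  expect_true(all(c("map", "contrast", "k", "p_fwe", "t") %in% names(back)))

  n <- 16
  s <- make_summaries(n, seed = 14)
  g <- grid_spec(shape = c(8L, 8L, 6L), voxel_size_mm = 6,
                 origin_mm = c(-21, -21, -15),
                 gm_mask = array(TRUE, c(8, 8, 6)))
  set.seed(15)
  Y <- matrix(rnorm(n * 384, sd = 0.05), n, 384)
  Y[, 100] <- Y[, 100] + 4 * s$aroc
  mc <- manual_cohort(Y, g)
  res <- permutation_fwe(mc, build_design(s), "MT", "pos", "cluster",
                         cluster_p = 0.001, n_perm = 40, seed = 16)
  rep <- report_tables(res, alpha = 1)
  write_report(rep, f)
  back2 <- read_report(f)
  expect_equal(as.data.frame(back2), as.data.frame(rep), tolerance = 1e-12)
})
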