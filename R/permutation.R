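#' Permutation-based familywise-error-corrected voxelwise inference
#'
#' Fits the voxelwise regression and corrects for multiple comparisons by
#' permutation, using Freedman-Lane residual permutation under the nuisance
#' model: the outcome maps are residualised against all covariates except
#' AROC, the residual rows are permuted, the nuisance fit is re-added
#' implicitly, and the full model is refit to each permuted dataset. The
#' identity permutation is always the first of `n_perm`, so p-values are
#' bounded below by `1 / n_perm` and exact under exchangeability.
#'
#' * `mode = "peak"`: the max-t null distribution over the mask gives an
#'   FWE-corrected peak p-value per voxel (use a volume-of-interest mask via
#'   `mask_index` for small-volume correction).
#' * `mode = "cluster"`: suprathreshold clusters (26-connectivity, one-tailed
#'   per contrast) at the `cluster_p` cluster-forming threshold are scored
#'   against the max-cluster-extent null.
#'
#' @param cohort A `qmap_cohort`.
#' @param design A [build_design()] result.
#' @param map_type `"MT"`, `"R1"` or `"R2star"`.
#' @param contrast `"pos"` or `"neg"` (direction of the AROC effect).
#' @param mode `"peak"` or `"cluster"`.
#' @param mask_index Linear voxel indices restricting the analysis (e.g.
#'   from [make_voi_mask()]); default: the cohort's whole grey-matter mask.
#' @param cluster_p Cluster-forming (uncorrected, one-tailed) p threshold;
#'   0.001 by default, 0.005 for exploratory analyses.
#' @param n_perm Total number of permutations including the identity.
#'   Use >= 500 for reported results; small values are fine for calibration
#'   experiments.
#' @param seed Optional integer seed for the permutation stream.
#' @param alpha Reporting threshold stored in the result (default 0.05).
#' @return An object of class `vbq_result`: list with `tmap` (the observed
#'   [fit_voxelwise()] result restricted to the mask), `peaks` and
#'   `clusters` tibbles (world coordinates, t, corrected and uncorrected
#'   p-values; cluster rows carry extent `k`), and `settings`.
#' @export
permutation_fwe <- function(cohort, design, map_type = "MT",
                            contrast = c("pos", "neg"),
                            mode = c("peak", "cluster"),
                            mask_index = NULL,
                            cluster_p = 0.001,
                            n_perm = 1000L,
                            seed = NULL,
                            alpha = 0.05) {
  contrast <- match.arg(contrast)
  mode <- match.arg(mode)
  n_perm <- as.integer(n_perm)
  if (n_perm < 2L) abort("`n_perm` must be >= 2 (identity plus permutations).")
  if (1 / n_perm > alpha) {
    warn(sprintf(
      "n_perm = %d cannot resolve p-values below %.3f (alpha = %.3f).",
      n_perm, 1 / n_perm, alpha))
  }
  X <- design$X
  n <- nrow(X)
  a <- match(design$effect, colnames(X))
  Z <- X[, -a, drop = FALSE]

  vox <- mask_index %||% cohort$mask_index
  cols <- match(vox, cohort$mask_index)
  if (anyNA(cols)) abort("`mask_index` must be a subset of the cohort mask.")
  if (length(cols) == 0L) abort("Empty analysis mask.")
  Y <- cohort$maps[[map_type]][, cols, drop = FALSE]
  if (is.null(Y)) abort(sprintf("Map type `%s` not present.", map_type))

  # Frisch-Waugh: residualise regressor and data against the nuisance block
  ZtZinv <- chol2inv(chol(crossprod(Z)))
  rz <- function(M) M - Z %*% (ZtZinv %*% crossprod(Z, M))
  xr <- as.numeric(rz(X[, a, drop = FALSE]))
  xr2 <- sum(xr^2)
  W <- rz(Y)                    # n x V residualised maps
  W2 <- colSums(W^2)
  ZX <- cbind(Z, xr)
  nz <- ncol(Z)
  df <- n - ncol(X)
  sgn <- if (contrast == "pos") 1 else -1

  # Full-model t for the AROC column when the rows of W are permuted by
  # `p` (Freedman-Lane; the nuisance-fit component H_z Y drops out of the
  # partialled statistic). Expanding the residualisation of the permuted
  # data keeps everything in one n x V crossprod:
  #   C = Z' P W, num = xr' P W, SSE = ||W||^2 - C' (Z'Z)^-1 C - num^2/xr2
  t_of <- function(p) {
    CC <- crossprod(ZX[p, , drop = FALSE], W)      # (nz+1) x V
    Cz <- CC[seq_len(nz), , drop = FALSE]
    num <- CC[nz + 1L, ]
    sse <- W2 - colSums(Cz * (ZtZinv %*% Cz)) - num^2 / xr2
    sgn * num / sqrt(xr2 * sse / df)
  }

  obs_t <- t_of(seq_len(n))
  thr <- qt(1 - cluster_p, df)
  shape <- cohort$grid$shape

  with_seed(seed, {
    null_max_t <- numeric(n_perm)
    null_max_k <- integer(n_perm)
    null_max_t[1L] <- max(obs_t)
    null_max_k[1L] <- max_cluster_extent(vox[obs_t >= thr], shape)
    for (b in seq_len(n_perm - 1L)) {
      tb <- t_of(sample.int(n))
      null_max_t[b + 1L] <- max(tb)
      if (mode == "cluster") {
        null_max_k[b + 1L] <- max_cluster_extent(vox[tb >= thr], shape)
      }
    }

    p_unc <- pt(obs_t, df, lower.tail = FALSE)
    peaks <- tibble()
    clusters <- tibble()
    if (mode == "peak") {
      p_fwe <- vapply(obs_t, function(t0) mean(null_max_t >= t0), numeric(1))
      keep <- which(p_fwe <= alpha)
      if (length(keep) == 0L) keep <- which.max(obs_t) # always report the max
      w <- voxel_to_world(cohort$grid, arrayInd(vox[keep], shape))
      peaks <- tibble(
        x = w[, 1L], y = w[, 2L], z = w[, 3L],
        t = obs_t[keep], p_fwe_peak = p_fwe[keep],
        p_uncorrected = p_unc[keep], voxel_index = vox[keep]
      ) |> dplyr::arrange(.data$p_fwe_peak, dplyr::desc(.data$t))
    } else {
      supra <- which(obs_t >= thr)
      if (length(supra) > 0L) {
        lab <- label_clusters(vox[supra], shape)
        clusters <- purrr::map_dfr(seq_len(max(lab)), function(cl) {
          members <- supra[lab == cl]
          k <- length(members)
          pk <- members[which.max(obs_t[members])]
          w <- voxel_to_world(cohort$grid, arrayInd(vox[pk], shape))
          tibble(
            k = k,
            p_fwe_cluster = mean(null_max_k >= k),
            p_uncorrected = p_unc[pk],
            t = obs_t[pk],
            x = w[1L], y = w[2L], z = w[3L],
            voxel_index = vox[pk]
          )
        }) |> dplyr::arrange(.data$p_fwe_cluster, dplyr::desc(.data$k))
      }
    }

    structure(
      list(
        tmap = structure(
          list(t = obs_t, voxel_index = vox, df = df, map_type = map_type,
               contrast = contrast, grid = cohort$grid),
          class = "vbq_tmap"),
        peaks = peaks, clusters = clusters,
        null_max_t = null_max_t,
        null_max_k = if (mode == "cluster") null_max_k else NULL,
        settings = tibble(map_type = map_type, contrast = contrast,
                          mode = mode, cluster_forming_p = cluster_p,
                          t_threshold = thr, n_perm = n_perm, df = df,
                          n_voxels = length(vox), alpha = alpha,
                          seed = seed %||% NA_integer_)
      ),
      class = "vbq_result"
    )
  })
}

#' @export
print.vbq_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<vbq_result> %s/%s %s-level, %d perms, %d voxels\n",
              s$map_type, s$contrast, s$mode, s$n_perm, s$n_voxels))
  if (s$mode == "peak") {
    cat(sprintf("  %d peak(s) at p_FWE <= %.3g (best p = %.4f)\n",
                sum(x$peaks$p_fwe_peak <= s$alpha), s$alpha,
                min(x$peaks$p_fwe_peak)))
  } else if (nrow(x$clusters) > 0L) {
    cat(sprintf("  %d cluster(s), best: k = %d, p_FWE = %.4f\n",
                nrow(x$clusters), x$clusters$k[1L],
                x$clusters$p_fwe_cluster[1L]))
  } else {
    cat("  no suprathreshold clusters\n")
  }
  invisible(x)
}

#' Tidy a permutation inference result
#'
#' @param x A `vbq_result`.
#' @param ... Unused.
#' @return The peak table (`mode = "peak"`) or cluster table
#'   (`mode = "cluster"`) with map type and contrast columns prepended.
#' @export
#' @method tidy vbq_result
tidy.vbq_result <- function(x, ...) {
  tab <- if (x$settings$mode == "peak") x$peaks else x$clusters
  dplyr::bind_cols(
    tibble(map = x$settings$map_type, contrast = x$settings$contrast),
    tab
  )
}

#' @rdname tidy.vbq_result
#' @export
#' @method glance vbq_result
glance.vbq_result <- function(x, ...) {
  x$settings
}
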