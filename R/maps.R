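# Separable 3D Gaussian smoothing by banded matrix products along each axis.
# Kernels are renormalised at the volume edges (truncated-kernel weights sum
# to 1 everywhere), so the smoothed field has no edge fall-off in the mean.
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  half <- max(1L, ceiling(3 * sigma))
  taps <- stats::dnorm(seq(-half, half), sd = sigma)
  dims <- dim(vol)
  smooth_axis <- function(v, ax) {
    n <- dims[ax]
    K <- matrix(0, n, n)
    for (o in seq(-half, half)) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1L & j <= n
      K[cbind(i[ok], j[ok])] <- taps[o + half + 1L]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    vp <- aperm(v, perm)
    m <- K %*% matrix(vp, nrow = n)
    aperm(array(m, dims[perm]), order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

# Empirical FWHM (mm) of a smooth random field from the lag-1 autocorrelation
# implied by the variance of neighbouring-voxel differences. For white noise
# smoothed with a Gaussian kernel of SD s, the field ACF is exp(-d^2/(4 s^2)).
#' Estimate the smoothness (FWHM, mm) of a 3D random field
#'
#' @param vol A 3D array (mean-zero random field).
#' @param voxel_size_mm Voxel size in mm.
#' @return Estimated FWHM in mm (average over the three axes).
#' @export
estimate_fwhm <- function(vol, voxel_size_mm) {
  est_axis <- function(ax) {
    d <- dim(vol)
    n <- d[ax]
    idx1 <- slice.index(vol, ax) <= n - 1L
    idx2 <- slice.index(vol, ax) >= 2L
    dif <- vol[idx2] - vol[idx1]
    rho <- 1 - var(dif) / (2 * var(as.vector(vol)))
    if (rho <= 0) return(NA_real_)
    s <- voxel_size_mm / (2 * sqrt(-log(rho)))
    2 * sqrt(2 * log(2)) * s
  }
  mean(vapply(1:3, est_axis, numeric(1)), na.rm = TRUE)
}

#' Generate a cohort of synthetic quantitative maps with planted effects
#'
#' Each subject's map of a given type is built as
#' `baseline + planted site effects + covariate confounds + smooth noise`,
#' evaluated over the grey-matter mask:
#' * every effect site adds `slope * (predictor - cohort mean)` scaled by a
#'   Gaussian spatial kernel (SD = `spatial_extent_mm / 2`) around its
#'   coordinate;
#' * age, gender and TIV add uniform in-mask confound fields with the
#'   [map_params()] slopes;
#' * the noise field is white Gaussian noise smoothed to
#'   `noise_fwhm_mm` FWHM and rescaled to the target in-mask SD.
#'
#' @param subject_summaries Subject-level tibble (one row per subject) with
#'   every predictor referenced by `sites`, plus `age`, `gender`, `tiv`.
#' @param sites Effect-site tibble ([default_effect_sites()]); pass a
#'   zero-row tibble for a null cohort.
#' @param grid A [grid_spec()].
#' @param params A [map_params()].
#' @param map_types Which map types to generate.
#' @param seed Optional integer seed.
#' @return A `qmap_cohort`: list with `subject_ids`, `grid`, `maps` (named
#'   list of subjects x in-mask-voxels matrices), `mask_index` (linear voxel
#'   indices of the in-mask columns), `truth` (the `sites` table with voxel
#'   indices), and `params`.
#' @export
generate_cohort_maps <- function(subject_summaries,
                                 sites = default_effect_sites(),
                                 grid = grid_spec(),
                                 params = map_params(),
                                 map_types = c("MT", "R1", "R2star"),
                                 seed = NULL) {
  n <- nrow(subject_summaries)
  if (n < 10L) {
    warn("Fewer than 10 subjects: voxelwise regression will be fragile.")
  }
  for (p in unique(sites$predictor)) {
    if (!p %in% names(subject_summaries)) {
      abort(sprintf("Site predictor `%s` missing from subject summaries.", p))
    }
  }
  mask_index <- which(grid$gm_mask)
  wcoords <- voxel_world_coords(grid)[mask_index, , drop = FALSE]

  if (nrow(sites) > 0L) {
    ijk <- world_to_voxel(grid, as.matrix(sites[, c("x", "y", "z")]))
    lin <- ijk[, 1L] + grid$shape[1L] * (ijk[, 2L] - 1L) +
      prod(grid$shape[1:2]) * (ijk[, 3L] - 1L)
    bad <- !in_grid(grid, ijk) | !(lin %in% mask_index)
    if (any(bad)) {
      abort(sprintf("Effect site outside the grey-matter mask: (%s)",
                    paste(apply(sites[bad, c("x", "y", "z")], 1L, paste,
                                collapse = ", "), collapse = "; ")))
    }
    sites$voxel_index <- lin
  } else {
    sites$voxel_index <- integer(0)
  }

  with_seed(seed, {
    maps <- list()
    for (mt in map_types) {
      M <- matrix(params$baseline[[mt]], n, length(mask_index))
      # planted effects
      for (s in which(sites$map == mt)) {
        site <- sites[s, ]
        d2 <- rowSums(sweep(wcoords, 2L,
                            as.numeric(site[, c("x", "y", "z")]))^2)
        kern <- exp(-d2 / (2 * (site$spatial_extent_mm / 2)^2))
        kern[kern < 0.01] <- 0
        pred <- subject_summaries[[site$predictor]]
        M <- M + (site$slope * (pred - mean(pred))) %o% kern
      }
      # uniform covariate confound fields
      for (cv in c("age", "gender", "tiv")) {
        sl <- params[[paste0(cv, "_slope")]][[mt]]
        if (!is.null(subject_summaries[[cv]]) && sl != 0) {
          x <- subject_summaries[[cv]]
          M <- M + (sl * (x - mean(x))) %o% rep(1, length(mask_index))
        }
      }
      # smooth noise, rescaled to the target in-mask SD
      if (params$noise_sd[[mt]] > 0) {
        for (i in seq_len(n)) {
          noise <- array(rnorm(prod(grid$shape)), dim = grid$shape)
          noise <- gaussian_smooth_3d(noise, params$noise_fwhm_mm,
                                      grid$voxel_size_mm)
          nm <- noise[mask_index]
          M[i, ] <- M[i, ] + nm / sd(nm) * params$noise_sd[[mt]]
        }
      }
      maps[[mt]] <- M
    }
    structure(
      list(subject_ids = subject_summaries$subject_id %||%
             sprintf("S%03d", seq_len(n)),
           grid = grid, maps = maps, mask_index = mask_index,
           truth = sites, params = params),
      class = "qmap_cohort"
    )
  })
}

#' @export
print.qmap_cohort <- function(x, ...) {
  cat(sprintf("<qmap_cohort> %d subjects, maps: %s, %d in-mask voxels\n",
              length(x$subject_ids), paste(names(x$maps), collapse = "/"),
              length(x$mask_index)))
  invisible(x)
}

# expand an in-mask vector to a full 3D volume (0 outside mask)
mask_to_volume <- function(values, cohort_or_grid, mask_index = NULL) {
  grid <- if (inherits(cohort_or_grid, "qmap_cohort")) cohort_or_grid$grid
  else cohort_or_grid
  mi <- mask_index %||% cohort_or_grid$mask_index
  vol <- array(0, dim = grid$shape)
  vol[mi] <- values
  vol
}
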