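#' Mass-univariate voxelwise regression t-map
#'
#' Per in-mask voxel, ordinary least squares of map values on the full
#' design; returns the t statistic for the AROC coefficient with `n - p`
#' degrees of freedom. The `"neg"` contrast is the sign-flipped map.
#'
#' @param cohort A `qmap_cohort`.
#' @param design A [build_design()] result.
#' @param map_type `"MT"`, `"R1"` or `"R2star"`.
#' @param contrast `"pos"` (AROC-positive) or `"neg"`.
#' @param mask_index Optional restriction: linear voxel indices (subset of
#'   `cohort$mask_index`) to analyse.
#' @return A list of class `vbq_tmap`: `t` (vector over analysed voxels),
#'   `voxel_index` (linear indices), `df`, `beta` (AROC slope per voxel),
#'   `map_type`, `contrast`, `grid`.
#' @export
fit_voxelwise <- function(cohort, design, map_type = "MT",
                          contrast = c("pos", "neg"), mask_index = NULL) {
  contrast <- match.arg(contrast)
  X <- design$X
  Y <- cohort$maps[[map_type]]
  if (is.null(Y)) abort(sprintf("Map type `%s` not present.", map_type))
  if (nrow(Y) != nrow(X)) {
    abort("Design rows do not match the number of subjects in the cohort.")
  }
  if (nrow(X) <= ncol(X)) {
    abort("Fewer subjects than design columns: model is not estimable.")
  }
  cols <- seq_len(ncol(Y))
  vox <- cohort$mask_index
  if (!is.null(mask_index)) {
    cols <- match(mask_index, cohort$mask_index)
    if (anyNA(cols)) abort("`mask_index` must be a subset of the cohort mask.")
    vox <- mask_index
    Y <- Y[, cols, drop = FALSE]
  }
  a <- match(design$effect, colnames(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)              # p x V
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  tval <- B[a, ] / sqrt(XtXinv[a, a] * sigma2)
  if (contrast == "neg") tval <- -tval
  structure(
    list(t = as.numeric(tval), voxel_index = vox, df = df,
         beta = as.numeric(B[a, ]) * (if (contrast == "neg") -1 else 1),
         map_type = map_type, contrast = contrast, grid = cohort$grid),
    class = "vbq_tmap"
  )
}

#' @export
print.vbq_tmap <- function(x, ...) {
  cat(sprintf("<vbq_tmap> %s/%s: %d voxels, df = %d, max t = %.2f\n",
              x$map_type, x$contrast, length(x$t), x$df, max(x$t)))
  invisible(x)
}

#' Default volume-of-interest sphere centres (MNI mm)
#'
#' The a-priori frontal and parietal coordinates used for small-volume
#' correction: left and right anterior prefrontal cortex, right dorsolateral
#' prefrontal cortex and precuneus peaks from earlier volumetric studies of
#' metacognitive ability.
#'
#' @return A tibble with `region`, `x`, `y`, `z`.
#' @export
default_voi_centers <- function() {
  tibble(
    region = c("L aPFC", "L aPFC", "R aPFC", "R aPFC", "R aPFC",
               "R DLPFC", "Precuneus", "Precuneus"),
    x = c(-20, -12, 24, 33, 32, 36, 6, 8),
    y = c(53, 54, 65, 50, 50, 39, -57, -64),
    z = c(12, 16, 18, 9, 7, 21, 18, 24)
  )
}

#' Build a spherical volume-of-interest mask
#'
#' A voxel is included iff its centre lies within `radius_mm` of any sphere
#' centre; the union is intersected with the grid's grey-matter mask.
#'
#' @param centers Tibble with `x`, `y`, `z` (mm); default
#'   [default_voi_centers()].
#' @param grid A [grid_spec()].
#' @param radius_mm Sphere radius in mm (default 5).
#' @return Sorted vector of linear voxel indices, with a `provenance`
#'   attribute (tibble: voxel index, nearest sphere id).
#' @export
make_voi_mask <- function(centers = default_voi_centers(),
                          grid = grid_spec(), radius_mm = 5) {
  ijk <- world_to_voxel(grid, as.matrix(centers[, c("x", "y", "z")]))
  if (!in_grid(grid, ijk)) {
    bad <- which(apply(ijk, 1L, function(r) any(r < 1L | r > grid$shape)))
    abort(sprintf("VOI centre outside the grid: (%s)",
                  paste(apply(centers[bad, c("x", "y", "z")], 1L, paste,
                              collapse = ", "), collapse = "; ")))
  }
  w <- voxel_world_coords(grid)
  gm <- as.vector(grid$gm_mask)
  hits <- integer(0)
  prov <- list()
  for (s in seq_len(nrow(centers))) {
    d2 <- (w[, 1L] - centers$x[s])^2 + (w[, 2L] - centers$y[s])^2 +
      (w[, 3L] - centers$z[s])^2
    v <- which(d2 <= radius_mm^2 & gm)
    hits <- c(hits, v)
    prov[[s]] <- tibble(voxel_index = v, sphere = s)
  }
  out <- sort(unique(hits))
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}
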