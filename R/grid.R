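#' Analysis grid for synthetic quantitative maps
#'
#' A reduced MNI-like grid: axial-aligned affine with isotropic voxels,
#' positioned so that every published coordinate used by the default effect
#' sites and volume-of-interest centres falls inside the volume. The default
#' 2 mm grid spans x in \[-59, 59\], y in \[-75, 71\], z in \[-24, 40\] mm.
#' The grey-matter mask is a superellipsoid (exponent 4) that keeps all
#' those coordinates while trimming the corners of the box.
#'
#' @param shape Integer vector of voxels per axis.
#' @param voxel_size_mm Isotropic voxel size in mm (>= 0.8).
#' @param origin_mm World coordinates (mm) of the centre of the first voxel.
#' @param gm_mask Optional logical array of dimension `shape`; defaults to
#'   the superellipsoid mask.
#' @return A list of class `qmap_grid` with `shape`, `voxel_size_mm`,
#'   `affine` (4x4 voxel-to-world, 0-based indices) and `gm_mask`.
#' @examples
#' g <- grid_spec()
#' g$shape; sum(g$gm_mask)
#' @export
grid_spec <- function(shape = c(60L, 74L, 33L),
                      voxel_size_mm = 2,
                      origin_mm = NULL,
                      gm_mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) {
    abort("`shape` must be three integers >= 2.")
  }
  if (voxel_size_mm < 0.8) abort("`voxel_size_mm` must be >= 0.8.")
  if (is.null(origin_mm)) {
    # centre the default extents of the 2 mm reference grid
    extent <- (shape - 1L) * voxel_size_mm
    centre <- c(0, -2, 8)
    origin_mm <- centre - extent / 2
  }
  affine <- diag(c(rep(voxel_size_mm, 3L), 1))
  affine[1:3, 4L] <- origin_mm
  grid <- structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm, affine = affine,
         gm_mask = NULL),
    class = "qmap_grid"
  )
  grid$gm_mask <- gm_mask %||% default_gm_mask(grid)
  if (!identical(dim(grid$gm_mask), as.integer(shape))) {
    abort("`gm_mask` dimensions must match `shape`.")
  }
  grid
}

# Superellipsoid pseudo grey-matter mask: boxier than an ellipsoid so
# frontal-pole and occipital printed coordinates stay inside.
default_gm_mask <- function(grid) {
  w <- voxel_world_coords(grid)
  extent <- (grid$shape - 1L) * grid$voxel_size_mm
  centre <- grid$affine[1:3, 4L] + extent / 2
  semi <- extent / 2 * c(0.97, 0.99, 0.99)
  v <- ((w[, 1L] - centre[1L]) / semi[1L])^4 +
    ((w[, 2L] - centre[2L]) / semi[2L])^4 +
    ((w[, 3L] - centre[3L]) / semi[3L])^4
  array(v <= 1, dim = grid$shape)
}

# world coordinates (V x 3) of every voxel centre, column-major voxel order
voxel_world_coords <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  sweep(sweep(idx - 1, 2L, diag(grid$affine)[1:3], "*"), 2L,
        grid$affine[1:3, 4L], "+")
}

#' Convert world (mm) coordinates to voxel indices and back
#'
#' @param grid A `qmap_grid`.
#' @param xyz Numeric matrix (n x 3) or vector of world coordinates in mm.
#' @return `world_to_voxel()`: integer matrix of 1-based voxel indices
#'   (nearest voxel); `voxel_to_world()`: numeric matrix of mm coordinates.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  vx <- sweep(xyz, 2L, grid$affine[1:3, 4L]) / grid$voxel_size_mm
  out <- round(vx) + 1L
  storage.mode(out) <- "integer"
  out
}

#' @rdname world_to_voxel
#' @param ijk Matrix/vector of 1-based voxel indices.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  sweep((ijk - 1) * grid$voxel_size_mm, 2L, grid$affine[1:3, 4L], "+")
}

in_grid <- function(grid, ijk) {
  all(ijk >= 1L) && all(ijk <= matrix(grid$shape, nrow(ijk), 3L, byrow = TRUE))
}

#' @export
print.qmap_grid <- function(x, ...) {
  lo <- voxel_to_world(x, c(1, 1, 1))
  hi <- voxel_to_world(x, x$shape)
  cat(sprintf(
    "<qmap_grid> %s voxels @ %g mm; x[%g,%g] y[%g,%g] z[%g,%g] mm; %d in mask\n",
    paste(x$shape, collapse = "x"), x$voxel_size_mm,
    lo[1], hi[1], lo[2], hi[2], lo[3], hi[3], sum(x$gm_mask)))
  invisible(x)
}
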