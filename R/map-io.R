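#' Write / read a synthetic map cohort as NIfTI volumes
#'
#' One uncompressed NIfTI-1 file per subject per map type
#' (`<subject>_<map>.nii`, float64, world coordinates in the qform affine),
#' plus `gm_mask.nii`, and a JSON sidecar `cohort.json` carrying subject
#' ids, grid metadata, noise/baseline parameters and the planted-effect
#' truth table. The round-trip is lossless.
#'
#' @param cohort A `qmap_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns the vector of files written (invisibly);
#'   `read_cohort()` returns the reconstructed `qmap_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- cohort$grid
  aff <- structure(grid$affine, code = 2L)
  files <- character(0)
  write_vol <- function(vol, path) {
    attr(vol, "pixdim") <- rep(grid$voxel_size_mm, 3L)
    im <- RNifti::asNifti(vol, datatype = "double")
    RNifti::qform(im) <- aff
    RNifti::writeNifti(im, path, datatype = "double")
    path
  }
  for (mt in names(cohort$maps)) {
    for (i in seq_along(cohort$subject_ids)) {
      f <- file.path(dir, sprintf("%s_%s.nii", cohort$subject_ids[i], mt))
      files <- c(files, write_vol(
        mask_to_volume(cohort$maps[[mt]][i, ], cohort), f))
    }
  }
  files <- c(files, write_vol(grid$gm_mask * 1, file.path(dir, "gm_mask.nii")))
  meta <- list(
    subject_ids = cohort$subject_ids,
    map_types = names(cohort$maps),
    shape = grid$shape,
    voxel_size_mm = grid$voxel_size_mm,
    affine = grid$affine,
    noise_fwhm_mm = cohort$params$noise_fwhm_mm,
    truth = cohort$truth
  )
  jf <- file.path(dir, "cohort.json")
  jsonlite::write_json(meta, jf, digits = NA, auto_unbox = TRUE)
  invisible(c(files, jf))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  mask_im <- RNifti::readNifti(file.path(dir, "gm_mask.nii"))
  affine <- matrix(unlist(meta$affine), 4L, 4L)
  grid <- grid_spec(shape = shape, voxel_size_mm = meta$voxel_size_mm,
                    origin_mm = affine[1:3, 4L],
                    gm_mask = array(as.array(mask_im) > 0, dim = shape))
  mask_index <- which(grid$gm_mask)
  maps <- list()
  for (mt in meta$map_types) {
    M <- matrix(NA_real_, length(meta$subject_ids), length(mask_index))
    for (i in seq_along(meta$subject_ids)) {
      f <- file.path(dir, sprintf("%s_%s.nii", meta$subject_ids[i], mt))
      im <- RNifti::readNifti(f)
      if (!identical(dim(im), shape)) {
        abort(sprintf("Grid mismatch in %s: expected %s, found %s.", f,
                      paste(shape, collapse = "x"),
                      paste(dim(im), collapse = "x")))
      }
      vs <- RNifti::pixdim(im)[1:3]
      if (max(abs(vs - grid$voxel_size_mm)) > 1e-6) {
        abort(sprintf("Voxel-size mismatch in %s.", f))
      }
      M[i, ] <- as.array(im)[mask_index]
    }
    maps[[mt]] <- M
  }
  truth <- as_tibble(meta$truth)
  structure(
    list(subject_ids = meta$subject_ids, grid = grid, maps = maps,
         mask_index = mask_index, truth = truth,
         params = map_params(noise_fwhm_mm = meta$noise_fwhm_mm)),
    class = "qmap_cohort"
  )
}
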