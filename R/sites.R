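#' Planted effect sites for synthetic map cohorts
#'
#' Each site plants a linear voxelwise effect of a subject-level predictor
#' on one map type, with a Gaussian spatial profile of scale
#' `spatial_extent_mm` (kernel SD = extent / 2) centred at an MNI-style
#' coordinate. The default set mirrors the regions where metacognitive
#' ability has been related to grey-matter microstructure: positive MT and
#' R1 effects in right anterior prefrontal cortex, a negative MT effect in
#' the left hippocampus, a positive R2* effect in the precuneus and left
#' middle temporal gyrus, and a negative R2* effect in primary visual
#' cortex.
#'
#' Default slopes are scaled so that, with the default noise SDs and a
#' cohort AROC SD of ~0.04, the planted peak t-values land in the 4-6 range
#' typical of this literature; the default 12 mm spatial extent mirrors the
#' several-hundred-voxel cluster sizes such studies report, so planted
#' effects form clusters that whole-brain cluster-level inference can
#' reliably resolve.
#'
#' @param x,y,z World coordinates in mm.
#' @param map `"MT"`, `"R1"` or `"R2star"`.
#' @param predictor Name of a column of the subject summary table.
#' @param slope Effect in map units per predictor unit (sign = direction).
#' @param spatial_extent_mm Spatial scale (radius) of the planted effect.
#' @return A one-row tibble; `default_effect_sites()` returns one row per
#'   default site.
#' @export
effect_site <- function(x, y, z, map = c("MT", "R1", "R2star"),
                        predictor = "aroc", slope = 1,
                        spatial_extent_mm = 12) {
  map <- match.arg(map)
  tibble(x = x, y = y, z = z, map = map, predictor = predictor,
         slope = slope, spatial_extent_mm = spatial_extent_mm)
}

#' @rdname effect_site
#' @export
default_effect_sites <- function() {
  dplyr::bind_rows(
    effect_site(37, 41, 22, "MT", "aroc", slope = 0.8),      # R aPFC
    effect_site(37, 42, 22, "R1", "aroc", slope = 0.6),      # R aPFC
    effect_site(-31, -25, -14, "MT", "aroc", slope = -0.8),  # L hippocampus
    effect_site(9, -64, 24, "R2star", "aroc", slope = 24),   # R precuneus
    effect_site(1, -69, 11, "R2star", "aroc", slope = -24),  # L & R V1
    effect_site(-51, -48, 2, "R2star", "aroc", slope = 24)   # L MTG
  )
}

#' Noise, baseline and confound parameters of the synthetic maps
#'
#' Baselines are plausible grey-matter values: MT saturation in percent
#' units, R1 and R2* in 1/s. `noise_sd` is the between-subject SD of the
#' spatially smooth noise field after smoothing. Small uniform confound
#' slopes for age (per year), gender (female vs male) and total intracranial
#' volume (per ml) make the nuisance regression non-trivial; age effects are
#' on by default for all maps since age is a strong determinant of brain
#' microstructure.
#'
#' @param baseline,noise_sd,age_slope,gender_slope,tiv_slope Named numeric
#'   vectors over `MT`, `R1`, `R2star`.
#' @param noise_fwhm_mm FWHM (mm) of the Gaussian spatial smoothing of the
#'   noise fields; 0 disables smoothing.
#' @return A list of class `map_params`.
#' @export
map_params <- function(baseline = c(MT = 0.9, R1 = 0.62, R2star = 16),
                       noise_sd = c(MT = 0.04, R1 = 0.025, R2star = 1.2),
                       age_slope = c(MT = -0.003, R1 = -0.002, R2star = 0.06),
                       gender_slope = c(MT = -0.005, R1 = -0.003, R2star = -0.1),
                       tiv_slope = c(MT = 2e-5, R1 = 1e-5, R2star = 1e-3),
                       noise_fwhm_mm = 4) {
  structure(
    list(baseline = baseline, noise_sd = noise_sd, age_slope = age_slope,
         gender_slope = gender_slope, tiv_slope = tiv_slope,
         noise_fwhm_mm = noise_fwhm_mm),
    class = "map_params"
  )
}
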