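#' Configuration for the end-to-end pipeline
#'
#' Collects every stage's settings plus a master seed. Each stage receives a
#' deterministic child seed derived by hashing the master seed with the
#' stage name, so stages are reproducible independently of execution order.
#'
#' @param seed Master integer seed.
#' @param n_subjects Cohort size.
#' @param session A [session_config()].
#' @param cohort A [cohort_params()].
#' @param grid A [grid_spec()].
#' @param sites Effect-site tibble ([default_effect_sites()]).
#' @param map A [map_params()].
#' @param voi_centers VOI centre tibble ([default_voi_centers()]).
#' @param voi_radius_mm VOI sphere radius.
#' @param cluster_p Cluster-forming threshold.
#' @param n_perm Permutations per analysis (including identity).
#' @param map_types Map types to analyse.
#' @param output_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_subjects = 48L,
                            session = session_config(),
                            cohort = cohort_params(),
                            grid = grid_spec(),
                            sites = default_effect_sites(),
                            map = map_params(),
                            voi_centers = default_voi_centers(),
                            voi_radius_mm = 5,
                            cluster_p = 0.001,
                            n_perm = 500L,
                            map_types = c("MT", "R1", "R2star"),
                            output_dir = "metavbq-output") {
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         session = session, cohort = cohort, grid = grid, sites = sites,
         map = map, voi_centers = voi_centers,
         voi_radius_mm = voi_radius_mm, cluster_p = cluster_p,
         n_perm = as.integer(n_perm), map_types = map_types,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full simulate-analyse pipeline
#'
#' Executes, with per-stage derived seeds: behaviour simulation ->
#' behavioural analysis (filtering, binning, summaries, stability ANOVA) ->
#' synthetic map generation -> voxelwise inference (every map type, both
#' contrasts, VOI peak-level and whole-mask cluster-level) -> report. All
#' artefacts are written under `config$output_dir` and listed, with MD5
#' checksums, in the returned manifest (also saved as `manifest.csv`).
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A tibble manifest with `file` and `md5` columns (paths relative
#'   to `output_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) abort(sprintf("Cannot create output dir `%s`.", out))
  say <- function(...) if (verbose) message(sprintf(...))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  say("[1/5] simulate-behaviour (n = %d)", config$n_subjects)
  beh <- step("simulate-behaviour", simulate_cohort(
    config$n_subjects, config$cohort, config$session,
    seed = derive_seed(config$seed, "simulate-behaviour")))
  write_trials(beh$trials, file.path(out, "trials.csv"))
  readr::write_csv(beh$subjects, file.path(out, "subjects.csv"))

  say("[2/5] analyse-behaviour")
  summaries <- step("analyse-behaviour", summarise_cohort(beh))
  readr::write_csv(summaries, file.path(out, "subject_summaries.csv"))
  readr::write_csv(attr(summaries, "filter_reports"),
                   file.path(out, "filter_reports.csv"))
  filtered <- dplyr::bind_rows(lapply(
    split(beh$trials, beh$trials$subject_id),
    function(d) filter_trials(d)$trials))
  anova_tab <- step("stability-anova", staircase_stability_anova(filtered))
  readr::write_csv(anova_tab, file.path(out, "stability_anova.csv"))

  say("[3/5] simulate-maps (%s voxels)",
      paste(config$grid$shape, collapse = "x"))
  cohort <- step("simulate-maps", generate_cohort_maps(
    summaries, config$sites, config$grid, config$map,
    map_types = config$map_types,
    seed = derive_seed(config$seed, "simulate-maps")))
  map_dir <- file.path(out, "maps")
  write_cohort(cohort, map_dir)

  say("[4/5] run-vbq (%d permutations)", config$n_perm)
  design <- step("build-design", build_design(summaries))
  voi <- make_voi_mask(config$voi_centers, config$grid,
                       config$voi_radius_mm)
  results <- list()
  for (mt in config$map_types) {
    for (ctr in c("pos", "neg")) {
      for (mode in c("peak", "cluster")) {
        key <- sprintf("%s_%s_%s", mt, ctr, mode)
        results[[key]] <- step(paste0("run-vbq:", key), permutation_fwe(
          cohort, design, map_type = mt, contrast = ctr, mode = mode,
          mask_index = if (mode == "peak") voi else NULL,
          cluster_p = config$cluster_p, n_perm = config$n_perm,
          seed = derive_seed(config$seed, paste0("vbq-", key))))
      }
    }
  }

  say("[5/5] report")
  report <- report_tables(results, alpha = 1)
  write_report(report, file.path(out, "report.csv"))
  write_report(report_tables(results, alpha = 0.05),
               file.path(out, "report_significant.csv"))
  jsonlite::write_json(
    list(seed = config$seed, n_subjects = config$n_subjects,
         n_perm = config$n_perm, cluster_p = config$cluster_p,
         voi_radius_mm = config$voi_radius_mm,
         map_types = config$map_types),
    file.path(out, "config.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(out, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.csv")
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files)))
  )
  readr::write_csv(manifest, file.path(out, "manifest.csv"))
  manifest
}
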