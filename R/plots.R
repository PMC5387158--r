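#' Plot staircase trajectories of a session
#'
#' Adaptive level (mean angle for the mu staircase, direction SD for the
#' sigma staircase) against trial number, one panel per condition.
#'
#' @param trials A trial tibble from [run_session()].
#' @return A ggplot.
#' @export
plot_staircase <- function(trials) {
  d <- trials |>
    dplyr::mutate(level = ifelse(.data$condition == "mu",
                                 .data$mean_angle, .data$sd_angle))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial_index, y = .data$level,
                                  colour = .data$correct)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ condition, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          mu = "mu staircase (mean angle, deg)",
                          sigma = "sigma staircase (direction SD, deg)"))) +
    ggplot2::labs(x = "Trial", y = "Adaptive level (deg)",
                  colour = "Correct") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a voxelwise t-map
#'
#' @param object A `vbq_tmap` (from [fit_voxelwise()] or inside a
#'   `vbq_result`).
#' @param z_mm Axial slice position in mm (default: slice of the maximum t).
#' @param ... Unused.
#' @return A ggplot raster of the slice with the grey-matter outline.
#' @export
#' @method autoplot vbq_tmap
autoplot.vbq_tmap <- function(object, z_mm = NULL, ...) {
  grid <- object$grid
  ijk <- arrayInd(object$voxel_index, grid$shape)
  w <- voxel_to_world(grid, ijk)
  if (is.null(z_mm)) z_mm <- w[which.max(object$t), 3L]
  k <- which.min(abs(unique(w[, 3L]) - z_mm))
  zsel <- abs(w[, 3L] - z_mm) < grid$voxel_size_mm / 2
  d <- tibble(x = w[zsel, 1L], y = w[zsel, 2L], t = object$t[zsel])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s / %s t-map, z = %g mm",
                                  object$map_type, object$contrast, z_mm),
                  x = "x (mm)", y = "y (mm)", fill = "t") +
    ggplot2::theme_minimal()
}

#' Cohort-level behavioural summary plot
#'
#' AROC against discrimination sensitivity (d') across subjects, the
#' standard check that metacognitive ability varies independently of task
#' performance under the staircases.
#'
#' @param summaries Output of [summarise_cohort()].
#' @return A ggplot.
#' @export
plot_cohort_aroc <- function(summaries) {
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$d_prime,
                                          y = .data$aroc)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey50", linewidth = 0.5) +
    ggplot2::labs(x = "d' (average)", y = "AROC (average)",
                  title = "Metacognitive ability vs discrimination sensitivity") +
    ggplot2::theme_minimal()
}
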