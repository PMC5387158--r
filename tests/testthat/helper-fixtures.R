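# Shared fixtures and independent oracles for the test suite.

# Independent brute-force type-II ROC area: build the five ROC points
# explicitly from cumulative tail probabilities and accumulate trapezoids in
# a plain loop. Deliberately kept free of any package internals.
brute_aroc <- function(counts_correct, counts_incorrect) {
  nc <- sum(counts_correct)
  ni <- sum(counts_incorrect)
  stopifnot(nc > 0, ni > 0)
  nb <- length(counts_correct)
  pts <- matrix(c(0, 0), ncol = 2)
  for (k in nb:2) {
    hit <- sum(counts_correct[k:nb]) / nc
    fa <- sum(counts_incorrect[k:nb]) / ni
    pts <- rbind(pts, c(fa, hit))
  }
  pts <- rbind(pts, c(1, 1))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  area <- 0
  for (i in 2:nrow(pts)) {
    area <- area + (pts[i, 1] - pts[i - 1, 1]) *
      (pts[i, 2] + pts[i - 1, 2]) / 2
  }
  area
}

# Plausible subject-summary table drawn directly (no behavioural simulation);
# used where the maps/GLM stages are tested in isolation.
make_summaries <- function(n, seed = NULL) {
  metavbq:::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      aroc = stats::rnorm(n, 0.65, 0.045),
      d_prime = stats::rnorm(n, 1.16, 0.12),
      mean_confidence_100 = stats::rnorm(n, 51, 12),
      criterion = stats::rnorm(n, 0, 0.15),
      variance_bias_beta = stats::rnorm(n, -2.5, 1.5),
      staircase_mean_signal_diff = stats::rnorm(n, -5, 2),
      age = sample(20:40, n, replace = TRUE),
      gender = stats::rbinom(n, 1, 0.6),
      tiv = round(stats::rnorm(n, 1450, 110), 1)
    )
  })
}

# Assemble a qmap_cohort directly from a subjects x voxels matrix.
manual_cohort <- function(Y, grid, map_type = "MT") {
  structure(
    list(subject_ids = sprintf("S%03d", seq_len(nrow(Y))),
         grid = grid, maps = stats::setNames(list(Y), map_type),
         mask_index = which(grid$gm_mask),
         truth = tibble::tibble(), params = map_params()),
    class = "qmap_cohort"
  )
}

# Coarse (6 mm) variant of the default grid: same world extents, so all
# default coordinates remain inside.
coarse_grid <- function() grid_spec(shape = c(20L, 25L, 11L), voxel_size_mm = 6)

# Brute-force 26-connectivity labelling by breadth-first search over a
# logical volume; returns per-voxel component id for the TRUE voxels (in the
# order of `which(vol)`).
brute_label <- function(vol) {
  shape <- dim(vol)
  vox <- which(vol)
  lab <- rep(NA_integer_, length(vox))
  lookup <- match(seq_len(prod(shape)), vox)
  nxt <- 0L
  for (start in seq_along(vox)) {
    if (!is.na(lab[start])) next
    nxt <- nxt + 1L
    queue <- vox[start]
    lab[start] <- nxt
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      ijk <- arrayInd(v, shape)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        p <- ijk + c(dx, dy, dz)
        if (any(p < 1L) || any(p > shape)) next
        lin <- p[1] + shape[1] * (p[2] - 1L) + shape[1] * shape[2] * (p[3] - 1L)
        j <- lookup[lin]
        if (!is.na(j) && is.na(lab[j])) {
          lab[j] <- nxt
          queue <- c(queue, vox[j])
        }
      }
    }
  }
  lab
}
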