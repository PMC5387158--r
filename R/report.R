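#' Combine inference results into a peak/cluster report table
#'
#' One row per surviving cluster (cluster mode) or per reported peak (peak
#' mode) across a list of results: map type, contrast sign, extent `k`
#' (clusters), corrected and uncorrected p-values, t and peak coordinates.
#' Region names are attached only when a labelling function is supplied;
#' otherwise coordinates speak for themselves.
#'
#' @param results A `vbq_result` or list of them.
#' @param alpha Keep rows with corrected p <= `alpha` (default 0.05); use
#'   `alpha = 1` to keep everything reported.
#' @param labeller Optional `function(x, y, z) -> character` giving region
#'   labels.
#' @return A tibble with columns `map`, `contrast`, `k`, `p_fwe`,
#'   `p_uncorrected`, `t`, `x`, `y`, `z` (and `region` if labelled).
#' @export
report_tables <- function(results, alpha = 0.05, labeller = NULL) {
  if (inherits(results, "vbq_result")) results <- list(results)
  rows <- purrr::map_dfr(results, function(r) {
    d <- tidy(r)
    if (nrow(d) == 0L) return(tibble())
    if (r$settings$mode == "peak") {
      d$k <- NA_integer_
      d$p_fwe <- d$p_fwe_peak
    } else {
      d$p_fwe <- d$p_fwe_cluster
    }
    d[d$p_fwe <= alpha,
      c("map", "contrast", "k", "p_fwe", "p_uncorrected", "t", "x", "y", "z")]
  })
  if (nrow(rows) > 0L && !is.null(labeller)) {
    rows$region <- labeller(rows$x, rows$y, rows$z)
  }
  rows
}

#' Write / read the report table as CSV
#'
#' @param report A tibble from [report_tables()].
#' @param path CSV path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   tibble (empty reports round-trip as header-only files).
#' @export
write_report <- function(report, path) {
  if (nrow(report) == 0L) {
    report <- tibble(map = character(), contrast = character(),
                     k = integer(), p_fwe = double(),
                     p_uncorrected = double(), t = double(),
                     x = double(), y = double(), z = double())
  }
  readr::write_csv(report, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    map = readr::col_character(), contrast = readr::col_character(),
    k = readr::col_integer(), .default = readr::col_double()
  ))
}
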