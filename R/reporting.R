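# Tidy CSV surface. Every writer emits '#' comment lines (units, schema
# version) before the header; readers pass comment = "#". Column names and
# order are part of the package contract and are pinned by tests.
CSV_SCHEMA_VERSION <- "1"

csv_header_lines <- function(kind, units) {
  c(
    sprintf("# slopebench csv schema v%s: %s", CSV_SCHEMA_VERSION, kind),
    sprintf("# units: %s", units)
  )
}

write_csv_with_header <- function(df, path, kind, units) {
  writeLines(csv_header_lines(kind, units), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a sweep result as a tidy CSV
#'
#' One row per condition x statistic: columns `rho` (plus `sd_ratio` for
#' independent sweeps), `statistic`, `value`. Statistics are
#' `expected_slope`, `mean_slope`, `sd_slope`, `mc_se_slope`,
#' `rejection_rate`, `mc_se_rejection`.
#'
#' @param sweep A [run_subtractive_sweep()] or [run_independent_sweep()]
#'   result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  id_cols <- intersect(c("rho", "sd_ratio"), names(sweep))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(sweep),
    cols = -dplyr::all_of(id_cols),
    names_to = "statistic", values_to = "value"
  )
  write_csv_with_header(
    long, path, kind = paste0("sweep-", attr(sweep, "kind")),
    units = "slopes dimensionless; underlying measures in degrees"
  )
}

#' Write shared-error bootstrap slope draws as a tidy CSV
#'
#' Long over relationship x resample: columns `relationship`, `iteration`,
#' `slope`, `population_slope` (the full-population estimate, constant
#' within a relationship).
#'
#' @param study A [run_shared_error_study()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_shared_error_csv <- function(study, path) {
  stopifnot(inherits(study, "bootstrap_slopes"))
  pop <- attr(study, "population_slopes")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(study), cols = -"iteration",
    names_to = "relationship", values_to = "slope"
  )
  long <- dplyr::mutate(
    long, population_slope = unname(pop[.data$relationship])
  )
  long <- dplyr::select(long, "relationship", "iteration", "slope",
                        "population_slope")
  long <- dplyr::arrange(long, .data$relationship, .data$iteration)
  write_csv_with_header(
    long, path, kind = "shared-error-bootstrap",
    units = "slopes dimensionless; model quantities in degrees"
  )
}

#' Write loose-additivity bootstrap draws as a tidy CSV
#'
#' Columns `noise_sd` (degrees), `predicted_slope` (closed-form
#' attenuation, constant within a noise level), `iteration`, `slope`.
#'
#' @param study A [run_loose_additivity_study()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_loose_additivity_csv <- function(study, path) {
  stopifnot(inherits(study, "loose_additivity_result"))
  draws <- attr(study, "draws")
  long <- dplyr::left_join(
    draws,
    dplyr::select(tibble::as_tibble(study), "noise_sd", "predicted_slope"),
    by = "noise_sd"
  )
  long <- dplyr::select(long, "noise_sd", "predicted_slope", "iteration",
                        "slope")
  write_csv_with_header(
    long, path, kind = "loose-additivity",
    units = "noise_sd in degrees; slopes dimensionless"
  )
}

#' Read back a slopebench result CSV
#'
#' @param path A CSV written by one of the `write_*_csv()` functions.
#' @return A tibble; `#` comment lines are skipped.
#' @export
read_result_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("result file not found: %s", path),
                 class = "slopebench_io_error")
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
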