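#' Read a cohort table from CSV
#'
#' Reads and validates the cohort schema: identifier and demographic
#' columns, cochlear measurements in mm, inserted electrode length, an
#' exclusion code and the twelve `score_<measure>_<timepoint>` columns
#' (blank cells are missing scores). A missing `cdl_mm` is computed from
#' `A_mm` and `B_mm` on the fly by downstream stages.
#'
#' @param path Path to the CSV file.
#' @return A cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c(cohort_required_cols, score_columns()),
                          names(cohort))
  # cdl may legitimately be absent (computed from A/B)
  missing_cols <- setdiff(missing_cols, "cdl_mm")
  if (length(missing_cols)) {
    abort(paste0("cohort file `", path, "` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Write an analysis report to disk
#'
#' Emits the analysis as three files under `dir`: `table_geometry.csv`
#' (cohort geometry summary), `table_outcomes.csv` (the partial-correlation
#' family with display rounding: r to 2 decimals, p to 3) and `report.json`
#' (all tables at full precision plus run metadata).
#'
#' @param analysis A `mismatch_analysis` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "mismatch_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(analysis$geometry_summary,
                   file.path(dir, "table_geometry.csv"))
  display <- dplyr::mutate(
    analysis$outcomes,
    r = sprintf("%.2f", .data$r),
    p.value = sprintf("%.3f", .data$p.value)
  )
  readr::write_csv(display, file.path(dir, "table_outcomes.csv"))
  jsonlite::write_json(
    list(
      counts = analysis$counts,
      geometry_summary = analysis$geometry_summary,
      diagnostics = analysis$diagnostics,
      t_tests = analysis$t_tests,
      outcomes = analysis$outcomes,
      mismatch = analysis$mismatch,
      alpha = analysis$alpha, m = analysis$m,
      bonferroni_threshold = analysis$bonferroni_threshold,
      metadata = analysis$metadata
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
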