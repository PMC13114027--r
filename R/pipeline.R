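cohort_required_cols <- c(
  "patient_id", "sex", "side", "age_years", "pta_db",
  "A_mm", "B_mm", "H_mm", "cdl_mm", "inserted_mm", "exclusion_code"
)

score_measures <- c("monosyllable", "consonant", "word", "sentence")
score_timepoints <- c("3m", "6m", "12m")

score_columns <- function() {
  as.vector(outer(score_measures, score_timepoints,
                  function(m, t) paste0("score_", m, "_", t)))
}

#' Apply the eligibility filter
#'
#' Splits a cohort into the three nested analysis sets: the geometry set
#' (all ears with preoperative measurements), the electrode-position set
#' (geometry set minus ears with extracochlear contacts) and the outcome
#' set (electrode set minus second-implant ears), with counts and
#' percentages at each stage.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] or
#'   [read_cohort_csv()]).
#' @return An object of class `eligibility_filter`: list with tibbles
#'   `geometry`, `electrode`, `outcome` and a `counts` tibble
#'   (`stage`, `n`, `pct_of_cohort`).
#' @examples
#' flt <- apply_eligibility_filter(simulate_cohort(seed = 1))
#' flt$counts
#' @export
apply_eligibility_filter <- function(cohort) {
  if (!"exclusion_code" %in% names(cohort)) {
    abort("cohort is missing the `exclusion_code` column")
  }
  known <- c("none", "extracochlear", "second_ci")
  bad <- !cohort$exclusion_code %in% known
  if (any(bad)) {
    abort(paste0("unknown exclusion_code in row(s): ",
                 paste(which(bad), collapse = ", ")))
  }
  geometry <- cohort
  electrode <- dplyr::filter(cohort, .data$exclusion_code != "extracochlear")
  outcome <- dplyr::filter(electrode, .data$exclusion_code != "second_ci")
  n0 <- nrow(geometry)
  counts <- tibble(
    stage = c("geometry", "electrode_position", "outcome"),
    n = c(n0, nrow(electrode), nrow(outcome)),
    pct_of_cohort = round(100 * c(n0, nrow(electrode), nrow(outcome)) / n0, 1)
  )
  if (nrow(outcome) == 0) warn("outcome set is empty after exclusions")
  structure(
    list(geometry = geometry, electrode = electrode, outcome = outcome,
         counts = counts),
    class = "eligibility_filter"
  )
}

#' @export
print.eligibility_filter <- function(x, ...) {
  cat("<eligibility_filter>\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.eligibility_filter <- function(x, ...) x$counts

#' Per-ear mismatch across a cohort
#'
#' Runs the geometry, tonotopy and mismatch layers for every ear of a
#' cohort table: locates the contacts, fits the quartic mismatch profile
#' and extracts the C6 summary. Ears whose duct length column is missing
#' have it computed from A and B.
#'
#' @param cohort A cohort tibble.
#' @param array An [electrode_array()].
#' @param geometry A [geometry_config()].
#' @param greenwood A [greenwood_params()].
#' @param fmap A frequency map from [default_frequency_map()].
#' @return A tibble with one row per ear: `patient_id`, `side`, `aid_deg`,
#'   `coverage_pct`, `mismatch_c6_semitones`, `c6_place_hz`, `c6_centre_hz`,
#'   `c6_in_band`, `insertion_complete`, `n_extracochlear`.
#' @export
compute_cohort_mismatch <- function(cohort,
                                    array = electrode_array(),
                                    geometry = geometry_config(),
                                    greenwood = greenwood_params(),
                                    fmap = default_frequency_map()) {
  cdl <- cohort$cdl_mm
  if (is.null(cdl) || anyNA(cdl)) {
    computed <- eca_cdl(cohort$A_mm, cohort$B_mm, geometry)
    cdl <- if (is.null(cdl)) computed else dplyr::coalesce(cdl, computed)
  }
  n <- nrow(cohort)
  nc <- array$n_contacts
  inserted <- cohort$inserted_mm

  # vectorised equivalent of locate_contacts() + fit_mismatch_profile() per
  # ear; the per-ear path is the reference implementation and the two are
  # held equal by tests
  arc <- outer(inserted, (seq_len(nc) - 1) * array$contact_span / (nc - 1), `-`)
  frac <- arc / cdl
  if (any(frac > 1)) abort("inserted length exceeds the cochlear duct length")
  intra <- frac >= 0
  denom_lw <- 1 - exp(-geometry$b_lateral * deg2rad(geometry$theta_total))
  theta <- matrix(NA_real_, n, nc)
  theta[intra] <- rad2deg(-log(1 - frac[intra] * denom_lw) / geometry$b_lateral)
  place <- matrix(NA_real_, n, nc)
  place[intra] <- place_frequency_at_angle(theta[intra], 1, geometry, greenwood)
  centres <- matrix(fmap$centre_hz, n, nc, byrow = TRUE)
  dev <- abs(12 * log2(place / centres))

  u <- theta / geometry$theta_total
  mis <- rep(NA_real_, n)
  clamped <- logical(n)
  for (i in seq_len(n)) {
    ok <- intra[i, ]
    if (sum(ok) < 5) {
      mis[i] <- if (ok[6]) dev[i, 6] else NA_real_
      next
    }
    cf <- stats::lm.fit(outer(u[i, ok], 0:4, `^`), dev[i, ok])$coefficients
    if (ok[6]) {
      v <- drop(u[i, 6]^(0:4) %*% cf)
      clamped[i] <- v < 0
      mis[i] <- max(v, 0)
    }
  }

  tibble(
    patient_id = cohort$patient_id,
    side = cohort$side,
    aid_deg = theta[, 1],
    coverage_pct = 100 * inserted / cdl,
    mismatch_c6_semitones = mis,
    c6_place_hz = place[, 6],
    c6_centre_hz = fmap$centre_hz[6],
    c6_in_band = !is.na(place[, 6]) & place[, 6] >= 1000 & place[, 6] <= 2000,
    insertion_complete = rowSums(!intra) == 0,
    n_extracochlear = rowSums(!intra)
  )
}

summarise_mean_sd <- function(x) {
  sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
}

#' Run the full mismatch-outcome analysis
#'
#' End-to-end orchestration: eligibility filtering, per-ear mismatch,
#' a cohort geometry summary, Pearson diagnostics (AID-CDL, AID-mismatch,
#' coverage-mismatch, CDL-mismatch on the electrode-position set), sex and
#' side t tests on duct length, and the 4-measure x 3-time-point family of
#' partial correlations between mismatch and speech scores controlling age
#' and preoperative PTA, with per-time-point listwise deletion and
#' Bonferroni control over the family.
#'
#' @param cohort A cohort tibble.
#' @param alpha Family-wise significance level. Default 0.05.
#' @param array,geometry,greenwood,fmap Component configurations.
#' @return An object of class `mismatch_analysis`: list with `counts`,
#'   `mismatch` (per-ear tibble), `geometry_summary`, `diagnostics`,
#'   `t_tests`, `outcomes` (the partial-correlation family tibble),
#'   `alpha`, `m`, `bonferroni_threshold` and `metadata`.
#' @examples
#' fit <- run_full_analysis(simulate_cohort(seed = 1))
#' tidy(fit)
#' @export
run_full_analysis <- function(cohort, alpha = 0.05,
                              array = electrode_array(),
                              geometry = geometry_config(),
                              greenwood = greenwood_params(),
                              fmap = default_frequency_map()) {
  flt <- apply_eligibility_filter(cohort)
  if (nrow(flt$outcome) < 8) abort("outcome set too small (< 8 ears)")

  mm_electrode <- compute_cohort_mismatch(flt$electrode, array, geometry,
                                          greenwood, fmap)

  geo <- flt$geometry
  geometry_summary <- tibble(
    quantity = c("A (mm)", "B (mm)", "H (mm)", "CDL (mm)",
                 "CDL male (mm)", "CDL female (mm)",
                 "AID (deg)", "coverage (%)", "apical place frequency (Hz)"),
    n = c(rep(nrow(geo), 6), rep(nrow(mm_electrode), 3)),
    value = c(
      summarise_mean_sd(geo$A_mm), summarise_mean_sd(geo$B_mm),
      summarise_mean_sd(geo$H_mm), summarise_mean_sd(geo$cdl_mm),
      summarise_mean_sd(geo$cdl_mm[geo$sex == "male"]),
      summarise_mean_sd(geo$cdl_mm[geo$sex == "female"]),
      summarise_mean_sd(mm_electrode$aid_deg),
      summarise_mean_sd(mm_electrode$coverage_pct),
      sprintf("%.1f ± %.1f",
              mean(place_frequency_at_angle(mm_electrode$aid_deg,
                                            flt$electrode$cdl_mm,
                                            geometry, greenwood)),
              sd(place_frequency_at_angle(mm_electrode$aid_deg,
                                          flt$electrode$cdl_mm,
                                          geometry, greenwood)))
    )
  )

  diag_pairs <- list(
    c("aid_deg", "cdl"), c("aid_deg", "mismatch"),
    c("coverage_pct", "mismatch"), c("cdl", "mismatch")
  )
  diag_data <- dplyr::left_join(
    mm_electrode,
    dplyr::select(flt$electrode, "patient_id", cdl = "cdl_mm"),
    by = "patient_id"
  )
  diag_data$mismatch <- diag_data$mismatch_c6_semitones
  diagnostics <- purrr::map_dfr(diag_pairs, function(p) {
    res <- cor_pearson(diag_data[[p[1]]], diag_data[[p[2]]], alpha = alpha)
    dplyr::bind_cols(tibble(pair = paste(p[1], "vs", p[2])), res)
  })

  t_tests <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(comparison = "cdl_by_sex"),
                     t_test_groups(geo$cdl_mm[geo$sex == "male"],
                                   geo$cdl_mm[geo$sex == "female"])),
    dplyr::bind_cols(tibble(comparison = "cdl_by_side"),
                     t_test_groups(geo$cdl_mm[geo$side == "right"],
                                   geo$cdl_mm[geo$side == "left"]))
  )

  outcome <- dplyr::left_join(
    flt$outcome,
    dplyr::select(mm_electrode, "patient_id",
                  "aid_deg", "coverage_pct", "mismatch_c6_semitones"),
    by = "patient_id"
  )
  m <- length(score_measures) * length(score_timepoints)
  cells <- tidyr::expand_grid(measure = score_measures,
                              timepoint = score_timepoints)
  outcomes <- purrr::pmap_dfr(cells, function(measure, timepoint) {
    col <- paste0("score_", measure, "_", timepoint)
    if (!col %in% names(outcome)) {
      abort(paste0("cohort is missing score column `", col, "`"))
    }
    keep <- !is.na(outcome[[col]]) & !is.na(outcome$mismatch_c6_semitones)
    d <- outcome[keep, ]
    base <- tibble(measure = measure, timepoint = timepoint)
    if (nrow(d) < 7) { # n >= k + 4 with margin for a stable estimate
      warn(sprintf("cell %s/%s not estimable (n = %d)", measure, timepoint, nrow(d)))
      return(dplyr::bind_cols(base, tibble(
        r = NA_real_, n = nrow(d), k = 2L, df = NA_integer_,
        statistic = NA_real_, p.value = NA_real_,
        significant_raw = NA, significant_bonferroni = NA
      )))
    }
    res <- cor_partial(d[[col]], d$mismatch_c6_semitones,
                       covariates = cbind(age = d$age_years, pta = d$pta_db),
                       alpha = alpha, m = m)
    dplyr::bind_cols(base, res)
  })

  structure(
    list(
      counts = flt$counts,
      mismatch = mm_electrode,
      geometry_summary = geometry_summary,
      diagnostics = diagnostics,
      t_tests = t_tests,
      outcomes = outcomes,
      alpha = alpha, m = m,
      bonferroni_threshold = bonferroni_threshold(alpha, m),
      metadata = list(
        package_version = as.character(utils::packageVersion("tonomatch")),
        seed = attr(cohort, "seed"),
        config_hash = rlang::hash(list(alpha, array, geometry, greenwood, fmap)),
        n_cohort = nrow(cohort)
      )
    ),
    class = "mismatch_analysis"
  )
}

#' @export
print.mismatch_analysis <- function(x, ...) {
  cat("<mismatch_analysis>\n")
  cat(sprintf("  cohort: %d -> %d -> %d (geometry / electrode / outcome)\n",
              x$counts$n[1], x$counts$n[2], x$counts$n[3]))
  cat(sprintf("  Bonferroni threshold: %.4f (alpha = %.2f, m = %d)\n",
              x$bonferroni_threshold, x$alpha, x$m))
  cat("  partial correlations (mismatch vs score | age, PTA):\n")
  print(as.data.frame(dplyr::mutate(
    x$outcomes,
    r = round(.data$r, 2), p.value = round(.data$p.value, 3)
  )[, c("measure", "timepoint", "n", "r", "p.value", "significant_bonferroni")]),
  row.names = FALSE)
  invisible(x)
}

#' @describeIn run_full_analysis Tidy the partial-correlation family: one
#'   row per measure/time point with `r`, `n`, `df`, `p.value` and
#'   significance flags.
#' @param x A `mismatch_analysis` object.
#' @param ... Unused.
#' @export
tidy.mismatch_analysis <- function(x, ...) x$outcomes

#' @describeIn run_full_analysis One-row run summary: cohort counts, family
#'   size, Bonferroni threshold, number of significant cells.
#' @export
glance.mismatch_analysis <- function(x, ...) {
  tibble(
    n_cohort = x$counts$n[1],
    n_electrode = x$counts$n[2],
    n_outcome = x$counts$n[3],
    m = x$m,
    alpha = x$alpha,
    bonferroni_threshold = x$bonferroni_threshold,
    n_significant_raw = sum(x$outcomes$significant_raw, na.rm = TRUE),
    n_significant_bonferroni = sum(x$outcomes$significant_bonferroni, na.rm = TRUE),
    config_hash = x$metadata$config_hash
  )
}
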