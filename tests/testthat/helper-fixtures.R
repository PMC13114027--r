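# Shared fixtures for the suite. Everything is generated in code; no data
# files are read.

# Numeric ellipse-perimeter oracle: arc-length quadrature, independent of
# the Ramanujan closed form used by the implementation.
ellipse_perimeter_quadrature <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

# Numeric t-density integration oracle for two-sided p-values.
t_pvalue_quadrature <- function(t_stat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-12)$value
}

# Cohort-mean electrode state under default configurations.
mean_electrode_state <- function() {
  locate_contacts(0.748 * 34.0, 34.0)
}

# Partial correlation between a score column and the C6 mismatch for the
# outcome set of a cohort, controlling age and PTA with listwise deletion.
cohort_partial_r <- function(cohort, column) {
  flt <- apply_eligibility_filter(cohort)
  mm <- compute_cohort_mismatch(flt$outcome)
  d <- dplyr::left_join(flt$outcome,
                        mm[, c("patient_id", "mismatch_c6_semitones")],
                        by = "patient_id")
  keep <- !is.na(d[[column]])
  cor_partial(d[[column]][keep], d$mismatch_c6_semitones[keep],
              covariates = cbind(age = d$age_years, pta = d$pta_db)[keep, ])$r
}
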