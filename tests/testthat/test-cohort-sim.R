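test_that("exclusion and attrition counts are exact, not stochastic", {
  for (seed in c(1, 2, 99)) {
    cohort <- simulate_cohort(seed = seed)
    expect_equal(nrow(cohort), 44)
    expect_equal(sum(cohort$exclusion_code == "extracochlear"), 6)
    expect_equal(sum(cohort$exclusion_code == "second_ci"), 3)
    expect_equal(sum(cohort$exclusion_code == "none"), 35)
    expect_equal(sum(!is.na(cohort$score_consonant_3m)), 35)
    expect_equal(sum(!is.na(cohort$score_consonant_6m)), 33)
    expect_equal(sum(!is.na(cohort$score_consonant_12m)), 27)
    # monotone dropout: missing at 6 months implies missing at 12 months
    miss6 <- is.na(cohort$score_word_6m) & cohort$exclusion_code == "none"
    miss12 <- is.na(cohort$score_word_12m) & cohort$exclusion_code == "none"
    expect_true(all(miss12[miss6]))
  }
})

test_that("the sex split is 15/29 at implant stage and 15/20 in the outcome set", {
  cohort <- simulate_cohort(seed = 4)
  expect_equal(sum(cohort$sex == "male"), 15)
  expect_equal(sum(cohort$sex == "female"), 29)
  keep <- cohort$exclusion_code == "none"
  expect_equal(sum(cohort$sex[keep] == "male"), 15)
  expect_equal(sum(cohort$sex[keep] == "female"), 20)
})

test_that("generated records respect demographic and geometric invariants", {
  cohort <- simulate_cohort(seed = 8)
  expect_true(all(cohort$age_years >= 21 & cohort$age_years <= 89))
  expect_true(all(cohort$A_mm > cohort$B_mm))
  expect_true(all(cohort$A_mm > 6 & cohort$A_mm < 12))
  expect_true(all(cohort$inserted_mm < cohort$cdl_mm))
  # cdl consistent with back-solved (A, B) through the duct-length formula
  expect_equal(suppressWarnings(eca_cdl(cohort$A_mm, cohort$B_mm)),
               cohort$cdl_mm, tolerance = 1e-9)
  scores <- as.matrix(cohort[, grep("^score_", names(cohort))])
  expect_true(all(is.na(scores) | (scores >= 0 & scores <= 100)))
})

test_that("generated geometry matches the configured moments at scale", {
  cfg <- cohort_config(n_patients = 4400, n_male = 1500,
                       n_extracochlear = 0, n_second_ci = 0,
                       attrition = c("3m" = 4400, "6m" = 4400, "12m" = 4400))
  cohort <- simulate_cohort(cfg, seed = 15)
  male <- cohort$sex == "male"
  expect_equal(mean(cohort$cdl_mm[male]), 34.6, tolerance = 0.1)
  expect_equal(mean(cohort$cdl_mm[!male]), 33.6, tolerance = 0.1)
  cov <- 100 * cohort$inserted_mm / cohort$cdl_mm
  expect_equal(mean(cov), 74.8, tolerance = 0.5)
  expect_equal(sd(cov), 4.6, tolerance = 0.5)
  expect_equal(mean(cohort$age_years), 66.6, tolerance = 1.5)
  mm <- attr(cohort, "mismatch")
  expect_equal(mean(mm$aid_deg), 511, tolerance = 10)
  expect_lt(mean(mm$aid_deg > 720), 0.01)
})

test_that("a null generator produces near-zero partial correlations", {
  cfg <- cohort_config(
    effect_sizes = dplyr::mutate(default_effect_sizes(), r_target = 0),
    gamma_age = 0, gamma_pta = 0
  )
  est <- vapply(1:60, function(i) {
    cohort <- simulate_cohort(cfg, seed = 200 + i)
    cohort_partial_r(cohort, "score_monosyllable_3m")
  }, 1.0)
  expect_lt(abs(mean(est)), 0.05)
})

test_that("solve_effect_size inverts the latent-model correlation algebra", {
  expect_equal(solve_effect_size(0), 0)
  expect_equal(solve_effect_size(-0.52), -0.52 / sqrt(1 - 0.52^2))
  expect_equal(solve_effect_size(-0.52), -0.6088, tolerance = 1e-4)
  expect_equal(solve_effect_size(0.3, noise_sd = 2), 2 * 0.3 / sqrt(0.91))
  expect_error(solve_effect_size(1), "strictly inside")
  expect_error(solve_effect_size(-1.2), "strictly inside")
  # large-n check: plugging gamma back recovers the target correlation
  set.seed(33)
  n <- 1e5
  z <- rnorm(n)
  g <- solve_effect_size(-0.52)
  y <- g * z + rnorm(n)
  expect_equal(cor(z, y), -0.52, tolerance = 0.01)
})

test_that("cohorts are reproducible under the same seed and differ otherwise", {
  a <- simulate_cohort(seed = 123)
  b <- simulate_cohort(seed = 123)
  c <- simulate_cohort(seed = 124)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("simulate_cohort demands an explicit seed and leaves the RNG alone", {
  expect_error(simulate_cohort(), "seed")
  set.seed(555)
  before <- .Random.seed
  invisible(simulate_cohort(seed = 42))
  expect_identical(.Random.seed, before)
})
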