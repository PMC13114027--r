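#' Default speech-outcome effect sizes
#'
#' Target partial correlations (controlling age and preoperative PTA)
#' between frequency-to-place mismatch and each speech measure at each time
#' point, used as the generator's default effect sizes. Phoneme-level
#' measures carry the strongest negative effects, with consonant perception
#' at 3 months the largest in magnitude.
#'
#' @return A tibble with columns `measure`, `timepoint`, `r_target`.
#' @export
default_effect_sizes <- function() {
  tidyr::expand_grid(
    measure = c("monosyllable", "consonant", "word", "sentence"),
    timepoint = c("3m", "6m", "12m")
  ) |>
    dplyr::mutate(r_target = c(
      -0.41, -0.41, -0.40,
      -0.52, -0.41, -0.50,
      -0.39, -0.39, -0.20,
      -0.35, -0.28, -0.13
    ))
}

#' Synthetic-cohort generator configuration
#'
#' Parameters of the virtual cochlear-implant cohort. Defaults emulate a
#' 44-ear adult cohort: 15 males / 29 females; age truncated normal
#' N(66.6, 16.8) on \[21, 89\]; preoperative pure-tone average N(97.2, 20.2)
#' dB HL; cochlear duct length N(34.6, 0.9) mm in males and N(33.6, 1.5) mm
#' in females; inserted electrode length drawn around the nominal insertion
#' mark with its spread solved so that electrode coverage has mean 74.8%
#' and SD 4.6%; six ears flagged extracochlear (partial insertion with a
#' 10-30% shortfall) and three excluded as second-implant cases, leaving 35
#' analysable; attrition 35 -> 33 -> 27 across 3/6/12 months.
#'
#' Speech scores arise from a linear latent model: standardised age and PTA
#' enter with coefficients `gamma_age` and `gamma_pta`, standardised
#' mismatch with a coefficient solved from the target partial correlation
#' (see [solve_effect_size()]), plus unit normal noise; the latent score is
#' rescaled by `score_scale` around per-measure/time means, sentence scores
#' are softly compressed above `ceiling_start`, and all scores are bounded
#' to \[0, 100\].
#'
#' @param n_patients Cohort size. Default 44.
#' @param n_male Number of males. Default 15.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated
#'   normal.
#' @param pta_mean,pta_sd,pta_range Preoperative pure-tone average (dB HL),
#'   truncated normal.
#' @param cdl_male,cdl_female Mean and SD (mm) of cochlear duct length by
#'   sex.
#' @param coverage_mean,coverage_sd Target electrode-coverage moments (%).
#' @param ba_ratio,ba_jitter_sd Basal-turn width/diameter ratio used to
#'   back-solve A and B from the duct length, and its jitter SD.
#' @param h_mean,h_sd Cochlear height (mm), descriptive only.
#' @param prob_right Probability of a right-side implant. Default 22/35.
#' @param n_extracochlear Ears flagged with extracochlear contacts.
#'   Default 6.
#' @param n_second_ci Ears excluded as second implants. Default 3.
#' @param shortfall_range Relative insertion shortfall for extracochlear
#'   ears. Default `c(0.10, 0.30)`.
#' @param attrition Named analysable counts at 3/6/12 months.
#'   Default `c("3m" = 35, "6m" = 33, "12m" = 27)`; must be non-increasing.
#' @param effect_sizes Tibble of target partial correlations per
#'   measure/time point; see [default_effect_sizes()].
#' @param gamma_age,gamma_pta Standardised covariate effects on the latent
#'   score. Default -0.2 each.
#' @param score_means 4 x 3 matrix of mean scores (rows: monosyllable,
#'   consonant, word, sentence; columns: 3/6/12 months).
#' @param score_scale Score points per latent SD. Default 12.
#' @param ceiling_start,ceiling_factor Sentence ceiling: scores above
#'   `ceiling_start` are compressed towards it by `ceiling_factor`.
#' @param array,geometry,greenwood,fmap Component configurations used when
#'   computing each ear's mismatch.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 44,
                          n_male = 15,
                          age_mean = 66.6, age_sd = 16.8,
                          age_range = c(21, 89),
                          pta_mean = 97.2, pta_sd = 20.2,
                          pta_range = c(40, 130),
                          cdl_male = c(mean = 34.6, sd = 0.9),
                          cdl_female = c(mean = 33.6, sd = 1.5),
                          coverage_mean = 74.8, coverage_sd = 4.6,
                          ba_ratio = 6.5 / 8.7, ba_jitter_sd = 0.01,
                          h_mean = 4.0, h_sd = 0.3,
                          prob_right = 22 / 35,
                          n_extracochlear = 6,
                          n_second_ci = 3,
                          shortfall_range = c(0.10, 0.30),
                          attrition = c("3m" = 35, "6m" = 33, "12m" = 27),
                          effect_sizes = default_effect_sizes(),
                          gamma_age = -0.2, gamma_pta = -0.2,
                          score_means = NULL,
                          score_scale = 12,
                          ceiling_start = 80, ceiling_factor = 0.5,
                          array = electrode_array(),
                          geometry = geometry_config(),
                          greenwood = greenwood_params(),
                          fmap = default_frequency_map()) {
  if (n_male < 0 || n_male > n_patients) abort("invalid sex split")
  n_analysable <- n_patients - n_extracochlear - n_second_ci
  if (any(diff(attrition) > 0)) abort("`attrition` must be non-increasing")
  if (attrition[1] > n_analysable) {
    abort("first attrition count exceeds the analysable cohort")
  }
  if (any(abs(effect_sizes$r_target) >= 1)) abort("target |r| must be < 1")
  if (coverage_sd <= 0 || cdl_male["sd"] <= 0 || cdl_female["sd"] <= 0) {
    abort("all SDs must be positive")
  }
  if (is.null(score_means)) {
    score_means <- matrix(
      c(45, 52, 58,   # monosyllable
        50, 58, 63,   # consonant
        55, 63, 68,   # word
        70, 80, 86),  # sentence (ceiling region at 6-12 months)
      nrow = 4, byrow = TRUE,
      dimnames = list(c("monosyllable", "consonant", "word", "sentence"),
                      c("3m", "6m", "12m"))
    )
  }
  structure(
    list(
      n_patients = n_patients, n_male = n_male,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      pta_mean = pta_mean, pta_sd = pta_sd, pta_range = pta_range,
      cdl_male = cdl_male, cdl_female = cdl_female,
      coverage_mean = coverage_mean, coverage_sd = coverage_sd,
      ba_ratio = ba_ratio, ba_jitter_sd = ba_jitter_sd,
      h_mean = h_mean, h_sd = h_sd,
      prob_right = prob_right,
      n_extracochlear = n_extracochlear, n_second_ci = n_second_ci,
      shortfall_range = shortfall_range,
      attrition = attrition,
      effect_sizes = effect_sizes,
      gamma_age = gamma_age, gamma_pta = gamma_pta,
      score_means = score_means, score_scale = score_scale,
      ceiling_start = ceiling_start, ceiling_factor = ceiling_factor,
      array = array, geometry = geometry, greenwood = greenwood,
      fmap = fmap
    ),
    class = "cohort_config"
  )
}

# Truncated-normal draws via the inverse-CDF method.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(p, mean, sd)
}

#' Solve the mismatch coefficient for a target partial correlation
#'
#' For a latent score built as `gamma * z + e` with standardised predictor
#' `z` and noise SD `noise_sd`, the population (partial) correlation with
#' `z` is `gamma / sqrt(gamma^2 + noise_sd^2)`; inverting gives
#' `gamma = r * noise_sd / sqrt(1 - r^2)`.
#'
#' @param r_target Target partial correlation, strictly inside (-1, 1).
#' @param noise_sd Noise standard deviation. Default 1.
#' @return The coefficient `gamma`.
#' @examples
#' solve_effect_size(-0.52) # ~ -0.609
#' @export
solve_effect_size <- function(r_target, noise_sd = 1) {
  if (any(!is.finite(r_target)) || any(abs(r_target) >= 1)) {
    abort("`r_target` must lie strictly inside (-1, 1)")
  }
  if (any(noise_sd <= 0)) abort("`noise_sd` must be positive")
  r_target * noise_sd / sqrt(1 - r_target^2)
}

# Population CDL moments implied by the sex mixture.
cdl_mixture_moments <- function(config) {
  p <- config$n_male / config$n_patients
  mu <- p * config$cdl_male["mean"] + (1 - p) * config$cdl_female["mean"]
  v <- p * config$cdl_male["sd"]^2 + (1 - p) * config$cdl_female["sd"]^2 +
    p * (config$cdl_male["mean"] - mu)^2 +
    (1 - p) * (config$cdl_female["mean"] - mu)^2
  c(mean = unname(mu), sd = sqrt(unname(v)))
}

# Moments of the inserted-length draw that reproduce the target coverage
# moments (delta method around the population means): the nominal insertion
# mark plus residual depth variability once CDL variation is accounted for.
inserted_length_moments <- function(config) {
  cdl <- cdl_mixture_moments(config)
  mu_L <- config$coverage_mean / 100 * cdl["mean"]
  between <- (config$coverage_mean * cdl["sd"] / cdl["mean"])^2
  resid_var <- config$coverage_sd^2 - between
  if (resid_var <= 0) {
    abort("coverage SD too small for the CDL spread; no feasible insertion-depth variance")
  }
  c(mean = unname(mu_L), sd = unname(cdl["mean"] / 100 * sqrt(resid_var)))
}

#' Generate a synthetic cochlear-implant cohort
#'
#' Draws a full virtual cohort under a [cohort_config()]: demographics,
#' cochlear geometry (duct length by sex, basal-turn A/B back-solved via the
#' elliptic-circular approximation), insertion depth, per-ear
#' frequency-to-place mismatch computed through the geometry, tonotopy and
#' mismatch layers, and longitudinal speech scores with configured effect
#' sizes, a sentence ceiling, exact exclusion counts and exact attrition.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; required so every cohort is reproducible.
#' @return A tibble with one row per patient: `patient_id`, `sex`, `side`,
#'   `age_years`, `pta_db`, `A_mm`, `B_mm`, `H_mm`, `cdl_mm`, `inserted_mm`,
#'   `exclusion_code` (`none`, `extracochlear`, `second_ci`) and
#'   `score_<measure>_<timepoint>` columns (blank = missing). The per-ear
#'   mismatch table used during generation is attached as attribute
#'   `"mismatch"`.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' table(cohort$exclusion_code)
#' @export
simulate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) abort("an explicit `seed` is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  n <- config$n_patients
  sex <- sample(rep(c("male", "female"), c(config$n_male, n - config$n_male)))
  side <- ifelse(runif(n) < config$prob_right, "right", "left")
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  pta <- rtruncnorm(n, config$pta_mean, config$pta_sd,
                    config$pta_range[1], config$pta_range[2])

  cdl <- ifelse(
    sex == "male",
    rnorm(n, config$cdl_male["mean"], config$cdl_male["sd"]),
    rnorm(n, config$cdl_female["mean"], config$cdl_female["sd"])
  )
  # back-solve basal-turn measurements: the Ramanujan perimeter is linear in
  # scale, so A = cdl / (eca_scale * P(1/2, ratio/2))
  ratio <- rnorm(n, config$ba_ratio, config$ba_jitter_sd)
  A <- cdl / (config$geometry$eca_scale * ramanujan_perimeter(0.5, ratio / 2))
  B <- ratio * A
  H <- rnorm(n, config$h_mean, config$h_sd)

  # exclusions drawn from the female majority so the analysable subset keeps
  # the 15 male / 20 female split
  n_excl <- config$n_extracochlear + config$n_second_ci
  females <- which(sex == "female")
  if (length(females) < n_excl) abort("not enough females to host the exclusions")
  excl <- sample(females, n_excl)
  exclusion_code <- rep("none", n)
  exclusion_code[excl[seq_len(config$n_extracochlear)]] <- "extracochlear"
  if (config$n_second_ci > 0) {
    exclusion_code[excl[config$n_extracochlear + seq_len(config$n_second_ci)]] <- "second_ci"
  }

  lm_mom <- inserted_length_moments(config)
  span <- config$array$contact_span
  inserted <- rtruncnorm(n, lm_mom["mean"], lm_mom["sd"],
                         lower = span + 0.2,
                         upper = pmin(config$array$array_length, cdl - 0.1))
  short <- exclusion_code == "extracochlear"
  inserted[short] <- inserted[short] *
    (1 - runif(sum(short), config$shortfall_range[1], config$shortfall_range[2]))

  cohort <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = sex, side = side,
    age_years = age, pta_db = pta,
    A_mm = A, B_mm = B, H_mm = H,
    cdl_mm = cdl, inserted_mm = inserted,
    exclusion_code = exclusion_code
  )

  mm <- compute_cohort_mismatch(cohort, array = config$array,
                                geometry = config$geometry,
                                greenwood = config$greenwood,
                                fmap = config$fmap)

  # latent score model on the analysable subset
  analysable <- which(exclusion_code == "none")
  zs <- function(v) as.numeric(scale(v))
  z_age <- zs(age[analysable])
  z_pta <- zs(pta[analysable])
  z_mm <- zs(mm$mismatch_c6_semitones[analysable])

  measures <- rownames(config$score_means)
  timepoints <- colnames(config$score_means)

  # exact monotone attrition: patients missing at one visit stay missing
  n_a <- length(analysable)
  dropout_order <- sample(analysable)
  missing_at <- lapply(seq_along(timepoints), function(j) {
    n_miss <- n_a - unname(config$attrition[j])
    if (n_miss > 0) dropout_order[seq_len(n_miss)] else integer(0)
  })

  for (i in seq_along(measures)) {
    for (j in seq_along(timepoints)) {
      r_t <- config$effect_sizes$r_target[
        config$effect_sizes$measure == measures[i] &
          config$effect_sizes$timepoint == timepoints[j]
      ]
      gamma_mm <- solve_effect_size(r_t, noise_sd = 1)
      latent <- config$gamma_age * z_age + config$gamma_pta * z_pta +
        gamma_mm * z_mm + rnorm(n_a)
      score <- config$score_means[i, j] + config$score_scale * latent
      if (measures[i] == "sentence") {
        over <- score > config$ceiling_start
        score[over] <- config$ceiling_start +
          (score[over] - config$ceiling_start) * config$ceiling_factor
      }
      score <- pmin(100, pmax(0, score))
      col <- rep(NA_real_, n)
      col[analysable] <- score
      col[missing_at[[j]]] <- NA_real_
      cohort[[paste0("score_", measures[i], "_", timepoints[j])]] <- col
    }
  }

  attr(cohort, "mismatch") <- mm
  attr(cohort, "seed") <- as.integer(seed)
  cohort
}
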