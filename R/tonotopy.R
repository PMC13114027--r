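#' Greenwood frequency-position constants
#'
#' Constants of the Greenwood frequency-position function for the human
#' cochlea, `f = scale_hz * (10^(slope * x) - offset)`, where `x` is the
#' relative distance from the apex along the organ of Corti (`x = 0` at the
#' apex, `x = 1` at the base).
#'
#' @param scale_hz Frequency scale in Hz. Default 165.4.
#' @param slope Dimensionless exponent per unit relative distance.
#'   Default 2.1.
#' @param offset Dimensionless low-frequency offset, in `[0, 1)`.
#'   Default 0.88.
#' @return An object of class `greenwood_params`.
#' @examples
#' greenwood_frequency(c(0, 0.5, 1), greenwood_params())
#' @export
greenwood_params <- function(scale_hz = 165.4, slope = 2.1, offset = 0.88) {
  if (!is.finite(scale_hz) || scale_hz <= 0) abort("`scale_hz` must be positive")
  if (!is.finite(slope) || slope <= 0) abort("`slope` must be positive")
  if (!is.finite(offset) || offset < 0 || offset >= 1) {
    abort("`offset` must lie in [0, 1)")
  }
  structure(list(scale_hz = scale_hz, slope = slope, offset = offset),
            class = "greenwood_params")
}

#' Greenwood place-to-frequency map
#'
#' Characteristic frequency at relative distance `x` from the apex of the
#' organ of Corti. Strictly increasing in `x`: low frequencies at the apex,
#' high at the base.
#'
#' @param x Relative distance(s) from the apex, in `[0, 1]`.
#' @param params A [greenwood_params()].
#' @return Frequency in Hz.
#' @export
greenwood_frequency <- function(x, params = greenwood_params()) {
  stopifnot(inherits(params, "greenwood_params"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("`x` must lie in [0, 1] (relative distance from the apex)")
  }
  params$scale_hz * (10^(params$slope * x) - params$offset)
}

#' Greenwood frequency-to-place map
#'
#' Algebraic inverse of [greenwood_frequency()]: the relative distance from
#' the apex at which the organ of Corti is tuned to frequency `f`.
#'
#' @param f Frequency in Hz; must be at least the apical minimum
#'   `scale_hz * (1 - offset)`.
#' @param params A [greenwood_params()].
#' @return Relative distance(s) from the apex in `[0, 1]`.
#' @export
greenwood_place <- function(f, params = greenwood_params()) {
  stopifnot(inherits(params, "greenwood_params"))
  f_min <- params$scale_hz * (1 - params$offset)
  if (any(!is.finite(f)) || any(f < f_min)) {
    abort(sprintf("`f` must be >= the apical minimum %.3f Hz", f_min))
  }
  log10(f / params$scale_hz + params$offset) / params$slope
}

#' Place frequency at an insertion angle
#'
#' Composes the organ-of-Corti spiral map with the Greenwood function: the
#' angle is converted to a fraction of organ-of-Corti length from the base,
#' the complementary fraction is the Greenwood distance-from-apex, and the
#' characteristic frequency follows. Monotonically decreasing in the angle
#' (deeper contacts sit more apically and see lower frequencies).
#'
#' @param theta_deg Insertion angle(s) in degrees from the round-window
#'   reference.
#' @param cdl_mm Lateral-wall cochlear duct length in mm (sets the
#'   organ-of-Corti length via `config$oc_length_ratio`; the place fraction
#'   itself is scale-free).
#' @param config A [geometry_config()].
#' @param params A [greenwood_params()].
#' @return Place frequency in Hz.
#' @examples
#' place_frequency_at_angle(511.1, 34.0) # ~285 Hz at the cohort-mean AID
#' @export
place_frequency_at_angle <- function(theta_deg, cdl_mm,
                                     config = geometry_config(),
                                     params = greenwood_params()) {
  if (any(!is.finite(cdl_mm)) || any(cdl_mm <= 0)) {
    abort("`cdl_mm` must be finite and positive")
  }
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0) ||
      any(theta_deg > config$theta_total)) {
    abort(sprintf("`theta_deg` must lie in [0, %g] degrees", config$theta_total))
  }
  # the fraction of organ-of-Corti length covered at an angle is scale-free,
  # so the duct length cancels out of the place fraction
  frac_from_base <- spiral_fraction(deg2rad(theta_deg), config$b_oc,
                                    deg2rad(config$theta_total))
  greenwood_frequency(1 - frac_from_base, params)
}
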