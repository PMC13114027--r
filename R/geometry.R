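#' Geometry calibration constants
#'
#' Bundles the calibration constants used by the cochlear geometry layer:
#' the elliptic-circular scaling applied to the Ramanujan ellipse perimeter,
#' the organ-of-Corti/lateral-wall length ratio, and the exponential decay
#' rates of the two spiral arc-length maps.
#'
#' The two decay rates are calibration constants, not measured anatomy:
#' `b_lateral` is set so that an insertion fraction of 0.748 of the cochlear
#' duct length lands at an angular insertion depth near 511 degrees, and
#' `b_oc` so that a 511-degree apical contact maps to a place frequency near
#' 286 Hz. Both can be replaced wholesale when a software-specific
#' angle-length table is available.
#'
#' @param eca_scale Dimensionless factor applied to the Ramanujan perimeter
#'   of the basal-turn ellipse (semi-axes A/2, B/2) to obtain the full
#'   cochlear duct length. Default 1.417.
#' @param oc_length_ratio Organ-of-Corti length as a fraction of the
#'   lateral-wall duct length; must lie in (0.5, 1). Default 0.90.
#' @param b_lateral Exponential decay rate (per radian) of the lateral-wall
#'   cumulative arc-length map. Default 0.1025.
#' @param b_oc Decay rate (per radian) of the organ-of-Corti map.
#'   Default 0.140.
#' @param theta_total Total angular extent of the spiral in degrees
#'   (2.5 turns). Default 900.
#'
#' @return An object of class `geometry_config` (a named list).
#' @examples
#' geometry_config()
#' @export
geometry_config <- function(eca_scale = 1.417,
                            oc_length_ratio = 0.90,
                            b_lateral = 0.1025,
                            b_oc = 0.140,
                            theta_total = 900) {
  vals <- c(eca_scale = eca_scale, oc_length_ratio = oc_length_ratio,
            b_lateral = b_lateral, b_oc = b_oc, theta_total = theta_total)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all geometry_config fields must be finite and positive")
  }
  if (oc_length_ratio <= 0.5 || oc_length_ratio >= 1) {
    abort("`oc_length_ratio` must lie in (0.5, 1)")
  }
  structure(as.list(vals), class = "geometry_config")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Ramanujan's second approximation to the ellipse perimeter; relative error
# is below 0.05% for the axis ratios seen in basal turns (b/a > 0.5).
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Cochlear duct length from basal-turn measurements
#'
#' Estimates the lateral-wall cochlear duct length (CDL) from the basal-turn
#' diameter `A` and width `B` with an elliptic-circular approximation: the
#' basal turn is treated as an ellipse with semi-axes `A/2` and `B/2`, its
#' perimeter computed with Ramanujan's approximation, and the result scaled
#' to full duct length by `config$eca_scale`.
#'
#' @param A Basal-turn diameter in mm (largest distance from the round-window
#'   centre to the contralateral wall). Vectorised.
#' @param B Basal-turn width in mm, perpendicular to the `A` line. Vectorised.
#' @param config A [geometry_config()].
#'
#' @return Cochlear duct length(s) in mm.
#' @examples
#' eca_cdl(8.7, 6.5) # ~34 mm, a typical adult cochlea
#' @export
eca_cdl <- function(A, B, config = geometry_config()) {
  if (any(!is.finite(A)) || any(!is.finite(B)) || any(A <= 0) || any(B <= 0)) {
    abort("`A` and `B` must be finite and positive (mm)")
  }
  if (any(A <= B)) {
    abort("basal-turn diameter `A` must exceed width `B`")
  }
  out_of_band <- A < 6 | A > 12
  if (any(out_of_band)) {
    warn(sprintf("%d `A` value(s) outside the 6-12 mm sanity band", sum(out_of_band)))
  }
  config$eca_scale * ramanujan_perimeter(A / 2, B / 2)
}

#' Spiral arc-length model
#'
#' A closed-form cumulative arc-length map for the cochlear spiral:
#' arc length grows as `1 - exp(-b * theta)` of the angle from the
#' round-window reference, normalised so the full angular extent reaches the
#' total length exactly. Separate decay rates are used for the lateral wall
#' and the organ of Corti, which sit at different radii.
#'
#' @param total_length Total arc length of the spiral in mm (for the lateral
#'   wall this is the CDL).
#' @param level `"lateral_wall"` or `"organ_of_corti"`; selects the decay
#'   rate from `config`.
#' @param config A [geometry_config()].
#'
#' @return An object of class `spiral_model` with fields `theta_total`
#'   (degrees), `b` (per radian), `total_length` (mm) and `level`.
#' @examples
#' sp <- spiral_model(34.0)
#' angle_to_length(511.1, sp)
#' @export
spiral_model <- function(total_length,
                         level = c("lateral_wall", "organ_of_corti"),
                         config = geometry_config()) {
  level <- match.arg(level)
  if (!is.finite(total_length) || total_length <= 0) {
    abort("`total_length` must be finite and positive (mm)")
  }
  b <- if (level == "lateral_wall") config$b_lateral else config$b_oc
  structure(
    list(theta_total = config$theta_total, b = b,
         total_length = total_length, level = level),
    class = "spiral_model"
  )
}

#' @export
print.spiral_model <- function(x, ...) {
  cat(sprintf("<spiral_model: %s, L = %.2f mm, b = %.4f /rad, theta = %g deg>\n",
              x$level, x$total_length, x$b, x$theta_total))
  invisible(x)
}

# Normalised cumulative arc length in [0, 1] at angle theta (radians).
spiral_fraction <- function(theta_rad, b, theta_total_rad) {
  (1 - exp(-b * theta_rad)) / (1 - exp(-b * theta_total_rad))
}

#' Convert insertion angle to arc length
#'
#' Cumulative arc length along the spiral from the round-window reference
#' (0 degrees) to angle `theta_deg`. Strictly increasing and concave in the
#' angle; reaches `model$total_length` exactly at the full angular extent.
#'
#' @param theta_deg Angle(s) in degrees, in `[0, theta_total]`.
#' @param model A [spiral_model()].
#' @return Arc length(s) in mm.
#' @export
angle_to_length <- function(theta_deg, model) {
  stopifnot(inherits(model, "spiral_model"))
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0) ||
      any(theta_deg > model$theta_total)) {
    abort(sprintf("`theta_deg` must lie in [0, %g] degrees", model$theta_total))
  }
  model$total_length *
    spiral_fraction(deg2rad(theta_deg), model$b, deg2rad(model$theta_total))
}

#' Convert arc length to insertion angle
#'
#' Exact closed-form inverse of [angle_to_length()].
#'
#' @param length_mm Arc length(s) in mm, in `[0, total_length]`.
#' @param model A [spiral_model()].
#' @return Angle(s) in degrees.
#' @export
length_to_angle <- function(length_mm, model) {
  stopifnot(inherits(model, "spiral_model"))
  if (any(!is.finite(length_mm)) || any(length_mm < 0) ||
      any(length_mm > model$total_length)) {
    abort(sprintf("`length_mm` must lie in [0, %g] mm", model$total_length))
  }
  u <- length_mm / model$total_length
  denom <- 1 - exp(-model$b * deg2rad(model$theta_total))
  rad2deg(-log(1 - u * denom) / model$b)
}

#' Electrode coverage of the cochlear duct
#'
#' Inserted electrode length as a percentage of the cochlear duct length.
#'
#' @param inserted_mm Inserted electrode length in mm.
#' @param cdl_mm Cochlear duct length in mm.
#' @return Coverage in percent.
#' @examples
#' electrode_coverage(25.43, 34.0)
#' @export
electrode_coverage <- function(inserted_mm, cdl_mm) {
  if (any(!is.finite(inserted_mm)) || any(inserted_mm <= 0)) {
    abort("`inserted_mm` must be finite and positive")
  }
  if (any(!is.finite(cdl_mm)) || any(cdl_mm <= 0)) {
    abort("`cdl_mm` must be finite and positive")
  }
  if (any(inserted_mm > cdl_mm)) {
    abort("inserted length exceeds the cochlear duct length; flag the record for review")
  }
  100 * inserted_mm / cdl_mm
}
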