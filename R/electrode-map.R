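#' Lateral-wall electrode array description
#'
#' Physical description of a straight lateral-wall electrode array. The
#' defaults describe a 28 mm array with 12 equally spaced contacts spanning
#' 23.1 mm, numbered apex-first (C1 apical, C12 basal).
#'
#' @param n_contacts Number of contacts (>= 2). Default 12.
#' @param contact_span Distance from the most apical to the most basal
#'   contact in mm. Default 23.1.
#' @param array_length Overall array length in mm. Default 28.
#' @return An object of class `electrode_array`.
#' @export
electrode_array <- function(n_contacts = 12, contact_span = 23.1,
                            array_length = 28) {
  if (n_contacts < 2 || n_contacts != round(n_contacts)) {
    abort("`n_contacts` must be an integer >= 2")
  }
  if (!is.finite(contact_span) || contact_span <= 0 ||
      contact_span > array_length) {
    abort("need 0 < contact_span <= array_length")
  }
  structure(list(n_contacts = as.integer(n_contacts),
                 contact_span = contact_span,
                 array_length = array_length),
            class = "electrode_array")
}

#' Default logarithmic frequency allocation
#'
#' Builds the default filter bank: `n_channels` bands with geometrically
#' spaced edges between `f_low` and `f_high`, channel centres at the
#' geometric mean of their band edges. Channel 1 (the apical contact C1)
#' receives the lowest band.
#'
#' @param f_low,f_high Frequency range in Hz. Defaults 70 and 8500.
#' @param n_channels Number of channels. Default 12.
#' @return A tibble with columns `channel` (1 = apical), `edge_low_hz`,
#'   `edge_high_hz` and `centre_hz`, ascending in frequency.
#' @examples
#' default_frequency_map()
#' @export
default_frequency_map <- function(f_low = 70, f_high = 8500, n_channels = 12) {
  if (!is.finite(f_low) || !is.finite(f_high) || f_low <= 0 || f_high <= f_low) {
    abort("need 0 < f_low < f_high")
  }
  if (n_channels < 2 || n_channels != round(n_channels)) {
    abort("`n_channels` must be an integer >= 2")
  }
  edges <- f_low * (f_high / f_low)^(seq(0, n_channels) / n_channels)
  tibble(
    channel = seq_len(n_channels),
    edge_low_hz = edges[-length(edges)],
    edge_high_hz = edges[-1],
    centre_hz = sqrt(edges[-length(edges)] * edges[-1])
  )
}

#' Locate electrode contacts along the cochlear spiral
#'
#' Places each contact of a straight array inserted `inserted_mm` into a
#' cochlea of duct length `cdl_mm`: the apical contact C1 sits at arc
#' position `inserted_mm`, successive contacts follow basally at equal
#' spacing. Arc positions are converted to insertion angles with the
#' lateral-wall spiral and to Greenwood place frequencies at the organ of
#' Corti. Contacts whose arc position falls below the round window (arc < 0)
#' are extracochlear and carry `NA` angle and frequency.
#'
#' @param inserted_mm Inserted electrode length in mm.
#' @param cdl_mm Cochlear duct length in mm.
#' @param array An [electrode_array()].
#' @param config A [geometry_config()].
#' @param params A [greenwood_params()].
#' @return A tibble (class `electrode_state`) with one row per contact:
#'   `contact` ("C1".."C12"), `arc_mm`, `angle_deg`, `place_hz`. Attributes:
#'   `aid_deg` (angle of C1), `coverage_pct`, `insertion_complete`,
#'   `n_extracochlear`.
#' @examples
#' st <- locate_contacts(25.43, 34.0)
#' attr(st, "aid_deg")
#' @export
locate_contacts <- function(inserted_mm, cdl_mm,
                            array = electrode_array(),
                            config = geometry_config(),
                            params = greenwood_params()) {
  stopifnot(inherits(array, "electrode_array"))
  cov_pct <- electrode_coverage(inserted_mm, cdl_mm) # validates inputs
  n <- array$n_contacts
  arc <- inserted_mm - (seq_len(n) - 1) * array$contact_span / (n - 1)
  intra <- arc >= 0
  lw <- spiral_model(cdl_mm, "lateral_wall", config)
  angle <- rep(NA_real_, n)
  place <- rep(NA_real_, n)
  angle[intra] <- length_to_angle(arc[intra], lw)
  place[intra] <- place_frequency_at_angle(angle[intra], cdl_mm, config, params)
  out <- tibble(
    contact = paste0("C", seq_len(n)),
    arc_mm = arc,
    angle_deg = angle,
    place_hz = place
  )
  structure(
    out,
    aid_deg = angle[1],
    coverage_pct = cov_pct,
    insertion_complete = all(intra),
    n_extracochlear = sum(!intra),
    class = c("electrode_state", class(out))
  )
}
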