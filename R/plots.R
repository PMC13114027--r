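#' Plot a per-ear mismatch profile
#'
#' Per-contact semitone deviations against insertion angle with the fitted
#' fourth-order polynomial and the C6 summary point.
#'
#' @param object A `mismatch_profile` from [fit_mismatch_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mismatch_profile <- function(object, ...) {
  dat <- dplyr::filter(object$data, !is.na(.data$angle_deg))
  grid <- tibble(angle_deg = seq(min(dat$angle_deg), max(dat$angle_deg),
                                 length.out = 200))
  grid$fit <- if (is.null(object$coefficients)) {
    NA_real_
  } else {
    drop(outer(grid$angle_deg, 0:4, `^`) %*% object$coefficients)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$angle_deg, y = .data$deviation_st)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("point", x = object$c6_angle_deg, y = object$mismatch_c6,
                      colour = "firebrick", size = 3, shape = 17) +
    ggplot2::labs(
      x = "insertion angle (degrees)",
      y = "semitone deviation",
      title = "Frequency-to-place mismatch profile",
      subtitle = sprintf("C6 mismatch: %.1f semitones", object$mismatch_c6)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the partial-correlation family
#'
#' Point estimates of the mismatch-score partial correlations by measure
#' and time point, with Bonferroni-surviving cells highlighted.
#'
#' @param object A `mismatch_analysis` from [run_full_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mismatch_analysis <- function(object, ...) {
  dat <- dplyr::mutate(
    object$outcomes,
    timepoint = factor(.data$timepoint, levels = c("3m", "6m", "12m")),
    measure = factor(.data$measure,
                     levels = c("monosyllable", "consonant", "word", "sentence"))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$timepoint, y = .data$r,
                                    group = .data$measure)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant_bonferroni),
                        size = 3, na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
      name = "Bonferroni\nsignificant"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), nrow = 1) +
    ggplot2::labs(
      x = "time after activation",
      y = "partial correlation (mismatch vs score | age, PTA)",
      title = "Mismatch and speech perception over time"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plots of mismatch diagnostics
#'
#' Angular insertion depth against the C6 mismatch statistic for each ear
#' of the electrode-position set, the cohort-level counterpart of the
#' per-ear profile plot.
#'
#' @param analysis A `mismatch_analysis`.
#' @return A ggplot object.
#' @export
plot_mismatch_vs_aid <- function(analysis) {
  stopifnot(inherits(analysis, "mismatch_analysis"))
  ggplot2::ggplot(analysis$mismatch,
                  ggplot2::aes(x = .data$aid_deg,
                               y = .data$mismatch_c6_semitones)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "angular insertion depth (degrees)",
                  y = "C6 mismatch (semitones)",
                  title = "Deeper insertion, smaller mismatch") +
    ggplot2::theme_minimal()
}
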