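#' Plot co-localization posteriors
#'
#' Bar chart of PP0..PP4 for one or more pairs (faceted by prior `f` when
#' several are present).
#'
#' @param object A `coloc_posterior` tibble (e.g. [coloc_candidates()]
#'   output).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coloc_posterior
#' @export
autoplot.coloc_posterior <- function(object, ...) {
  long <- object |>
    tibble::as_tibble() |>
    dplyr::mutate(pair = if ("eprobe" %in% names(object)) {
      paste(object$eprobe, object$cpg, sep = " / ")
    } else paste0("pair ", dplyr::row_number())) |>
    tidyr::pivot_longer(dplyr::all_of(c("pp0", "pp1", "pp2", "pp3", "pp4")),
                        names_to = "hypothesis", values_to = "posterior")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$hypothesis,
                                          y = .data$posterior,
                                          fill = .data$hypothesis)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if ("f" %in% names(long) && dplyr::n_distinct(long$f) > 1) {
    p <- p + ggplot2::facet_grid(f ~ pair)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the internal empirical calibration curve
#'
#' Posterior versus prior expectation of co-localization across the `f`
#' grid; the selected `f` (smallest discrepancy) is highlighted.
#'
#' @param calib An [empirical_calibration()] result.
#' @return A ggplot object.
#' @export
plot_calibration <- function(calib) {
  stopifnot(inherits(calib, "coloc_calibration"))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(calib),
    dplyr::all_of(c("posterior_expectation", "prior_expectation")),
    names_to = "quantity", values_to = "expected_pairs"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$f, .data$expected_pairs,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(calib, "selected_f"),
                        linetype = "dashed") +
    ggplot2::labs(x = "prior fraction f",
                  y = "expected co-localized pairs") +
    ggplot2::theme_minimal()
}

#' Plot a direction-of-effect summary
#'
#' Fractions of opposite-sign SNP effects and negative E-M correlations
#' per stratum.
#'
#' @param dir A [direction_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_direction_summary <- function(dir) {
  long <- tidyr::pivot_longer(
    dir, dplyr::all_of(c("frac_opposite", "frac_negative_corr")),
    names_to = "measure", values_to = "fraction"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$stratum, .data$fraction,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "fraction of pairs") +
    ggplot2::theme_minimal()
}

#' Plot mediation results across pairs
#'
#' Sobel P (log10) versus mediation proportion, coloured by model.
#'
#' @param results Row-bound [run_both_models()] results.
#' @return A ggplot object.
#' @export
plot_mediation <- function(results) {
  d <- dplyr::filter(results, is.finite(.data$prop_mediated),
                     abs(.data$prop_mediated) <= 3)
  ggplot2::ggplot(d, ggplot2::aes(.data$prop_mediated,
                                  -log10(pmax(.data$p_sobel, 1e-15)),
                                  colour = .data$model)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "mediation proportion",
                  y = expression(-log[10] * "(Sobel P)")) +
    ggplot2::theme_minimal()
}
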