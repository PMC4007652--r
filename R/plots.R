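#' Plotting helpers
#'
#' ggplot2 views of the main result types: the rSASA distribution with
#' the accessibility threshold, the elastic-network eigenvalue spectrum,
#' and per-conformer rSASA traces along normal modes.
#'
#' @name plots
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of site rSASA values
#'
#' @param report a [run_map()] report
#' @param threshold accessibility threshold drawn as a reference line
#' @param width bin width (0.1 rSASA units)
#' @return a ggplot object
#' @export
plot_rsasa_distribution <- function(report, threshold = 0.2, width = 0.1) {
  d <- report[report$status == "matched" & !is.na(report$rsasa), ]
  ggplot2::ggplot(d, ggplot2::aes(x = pmin(.data$rsasa, 1))) +
    ggplot2::geom_histogram(breaks = seq(0, 1, width),
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "octapeptide rSASA", y = "sites",
                  title = "Accessibility of phosphosite octapeptides") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param object a `phospho_enm_modes` object
#' @param ... unused
#' @export
autoplot.phospho_enm_modes <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d[!d$rigid_body, ],
                  ggplot2::aes(x = .data$mode - object$n_zero,
                               y = .data$eigenvalue)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "vibrational mode", y = "eigenvalue (model units)",
                  title = "Elastic-network normal mode spectrum") +
    ggplot2::theme_minimal()
}

#' Per-conformer rSASA along normal modes
#'
#' @param er an [ensemble_rsasa()] result
#' @param threshold accessibility threshold reference line
#' @return a ggplot object
#' @export
plot_conformer_rsasa <- function(er, threshold = 0.2) {
  d <- er[!is.na(er$mode), ]
  input <- er$rsasa[is.na(er$mode)][1]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$amplitude, y = .data$rsasa,
                                  group = .data$mode)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = input, linetype = 3) +
    ggplot2::labs(x = "mode amplitude (Angstrom)",
                  y = "coarse octapeptide rSASA",
                  title = "Site accessibility across the conformer ensemble") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @name tidiers
#' @title Tidy views of fitted objects
#' @description `tidy()` returns per-mode eigenvalues of an elastic
#'   network mode set; `glance()` returns its one-row summary.
#' @param x a fitted object
#' @param ... unused
NULL
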