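#' Plot methods
#'
#' `autoplot()` methods for the package's result types: ranked correlation
#' curves, per-mask mean-density histograms, rotational correlation profiles
#' and FSC curves.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name spt-plots
NULL

#' @rdname spt-plots
#' @export
autoplot.spt_ranked <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank", y = "constrained correlation with reference",
                  title = "Ranked correlation against the hollow reference")
}

#' @rdname spt-plots
#' @export
autoplot.spt_group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$mean_density, fill = .data$group)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 20) +
    ggplot2::labs(x = "mean density under mask", y = "particles",
                  title = sprintf("Mask %s: t = %.2f", object$mask_label,
                                  object$t_score))
}

#' @rdname spt-plots
#' @export
autoplot.spt_rotational_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("cc_c8", "cc_d8"),
                              names_to = "series", values_to = "cc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$azimuth, y = .data$cc,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 315, 45)) +
    ggplot2::labs(x = "azimuth (degrees)", y = "correlation",
                  title = "Rotational correlation (C8 / D8)")
}

#' @rdname spt-plots
#' @param thresholds FSC thresholds drawn as reference lines.
#' @export
autoplot.spt_fsc <- function(object, thresholds = c(0.5, 1 / 3), ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed") +
    ggplot2::labs(x = "spatial frequency (1/A)", y = "FSC",
                  title = "Fourier shell correlation")
}
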