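#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cleveland-style plot of a coverage report
#'
#' Per-amino-acid coverage of the demand profile by the diet, essentials
#' emphasised and the limiting amino acid highlighted; the dashed line marks
#' 100% (perfectly matched supply).
#'
#' @param object A `coverage_report` from [aa_coverage()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(is.finite(.data$coverage))
  df$aa <- factor(df$aa, levels = rev(df$aa[order(df$essential, df$coverage,
                                                  decreasing = TRUE)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coverage, y = .data$aa)) +
    ggplot2::geom_vline(xintercept = 100, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = 100, xend = .data$coverage,
                                       yend = .data$aa), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$limiting,
                                     shape = .data$essential), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = "essential") +
    ggplot2::labs(
      x = "coverage of demand (%)", y = NULL,
      title = sprintf("%s vs %s demand", attr(object, "diet_label"),
                      attr(object, "demand_label")),
      subtitle = sprintf("limiting: %s (%.1f%%), predicted gain %.1f%%",
                         attr(object, "limiting_aa"),
                         attr(object, "limiting_coverage"),
                         attr(object, "predicted_gain"))
    ) +
    ggplot2::theme_minimal()
}

#' Distance histogram of a permutation null
#'
#' Histogram of the Euclidean distances from each permuted profile to the
#' median permuted profile, with dashed lines at each observed profile's
#' distance.
#'
#' @param object A `permutation_null` from [permute_null()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_null <- function(object, bins = 60, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "Euclidean distance to median permuted profile",
                  y = "permutations") +
    ggplot2::theme_minimal()
  if (nrow(object$observed) > 0) {
    p <- p +
      ggplot2::geom_vline(data = object$observed,
                          ggplot2::aes(xintercept = .data$distance,
                                       colour = .data$label),
                          linetype = "dashed") +
      ggplot2::labs(colour = "observed")
  }
  p
}

#' Per-amino-acid box summary of a permutation null
#'
#' Box plots (median, interquartile range, 1.5 IQR fences) of the permuted
#' proportion of each amino acid, essentials left of the divider, with
#' observed profiles overplotted as points.
#'
#' @param null A `permutation_null`.
#' @param observed Optional named list of observed profiles.
#' @param essentials Essential set used to order the x axis.
#' @return A ggplot.
#' @export
plot_null_profiles <- function(null, observed = NULL, essentials = aa_essential()) {
  s <- null_summary(null)
  ord <- c(sort(essentials), sort(setdiff(aa_alphabet(), essentials)))
  s$aa <- factor(s$aa, levels = ord)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$aa)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower_fence,
                                        ymax = .data$upper_fence),
                           width = 0.2, colour = "grey60") +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3),
                           fill = "grey85", width = 0.6, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = length(essentials) + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = NULL, y = "proportion of amino acid") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    observed <- name_if_unnamed(observed, "observed")
    obs <- purrr::imap(observed, function(pr, nm) {
      tibble::tibble(aa = factor(aa_alphabet(), levels = ord),
                     proportion = unname(aa_vector(pr)), label = nm)
    }) |> dplyr::bind_rows()
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(y = .data$proportion,
                                              colour = .data$label), size = 2) +
      ggplot2::labs(colour = "profile")
  }
  p
}

#' Tissue panel plot
#'
#' Limiting-amino-acid coverage per tissue for each diet, the data layout
#' used to judge which diet best meets each tissue's predicted demand.
#'
#' @param panel Output of [tissue_panel()].
#' @return A ggplot.
#' @export
plot_tissue_panel <- function(panel) {
  panel$tissue <- factor(panel$tissue,
                         levels = rev(unique(panel$tissue[order(panel$limiting_coverage)])))
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$limiting_coverage,
                                      y = .data$tissue, colour = .data$diet)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$limiting_aa),
                       vjust = -0.9, size = 3, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 100, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "limiting amino acid coverage (%)", y = NULL) +
    ggplot2::theme_minimal()
}
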