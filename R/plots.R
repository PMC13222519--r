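#' Plot a geometry report against its reference bands
#'
#' Metric values as points over their reference intervals; out-of-band
#' metrics are highlighted. Distances and angles are faceted apart since
#' their scales differ by two orders of magnitude.
#'
#' @param report A [geometry_metrics()] result.
#' @return A ggplot object.
#' @export
plot_geometry_report <- function(report) {
  df <- tibble::as_tibble(report)
  df$kind <- ifelse(grepl("^ang", df$metric), "angle (degrees)",
                    "distance (angstrom)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.25, colour = "grey55"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$value, colour = .data$in_range), size = 2.5
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d7301f"),
      name = "in range"
    ) +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.geometry_report <- function(object, ...) {
  plot_geometry_report(object)
}

#' Plot screening outcomes
#'
#' Bar chart of classification labels from a [screen_batch()] table, filled
#' by acceptance.
#'
#' @param screened A [screen_batch()] tibble.
#' @return A ggplot object.
#' @export
plot_screen_summary <- function(screened) {
  df <- screened
  df$label <- ifelse(is.na(df$label), "rejected", df$label)
  df$label <- factor(df$label,
                     levels = c("alpha", "beta", "gamma", "rejected"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, fill = .data$accepted)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#31a354", `FALSE` = "#bdbdbd"),
      name = "accepted"
    ) +
    ggplot2::labs(x = "backbone class", y = "molecules") +
    ggplot2::theme_minimal()
}

#' Plot similarity hits
#'
#' Ranked bar chart of the hit scores under the ranking coefficient, with
#' exact structural matches highlighted.
#'
#' @param hits A [search_components()] result.
#' @return A ggplot object.
#' @export
plot_similarity_hits <- function(hits) {
  df <- tibble::as_tibble(hits)
  df$component_id <- stats::reorder(df$component_id, -df$rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component_id, y = .data$score,
                                   fill = .data$exact)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#d95f0e", `FALSE` = "#2c7fb8"),
      name = "exact match"
    ) +
    ggplot2::labs(x = NULL,
                  y = paste0(attr(hits, "coefficient"), " similarity")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.similarity_hits <- function(object, ...) {
  plot_similarity_hits(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
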