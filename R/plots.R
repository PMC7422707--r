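#' Plot a phospho-ladder assignment as an annotated stick spectrum
#'
#' @param object A `ladder_assignment` from [assign_phospho_ladder()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ladder_assignment <- function(object, ...) {
  df <- as_tibble(object)
  df$intensity[is.na(df$intensity)] <- 1
  df$label <- if_else(is.na(df$n_phospho), "", paste0(df$n_phospho, "P"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0,
                                       colour = .data$assigned)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "m/z (Da)", y = "intensity",
                  title = sprintf("Phospho-ladder, base MH+ %.1f Da",
                                  attr(object, "base_mass"))) +
    ggplot2::theme_minimal()
}

#' Lollipop plot of a phosphosite map
#'
#' Sites are drawn along the mature-chain coordinate with stem height equal
#' to the aggregated spectral count (region-level MALDI sites, which carry
#' no counts, are shown at baseline height); major sites are filled black.
#'
#' @param object A `site_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_map <- function(object, ...) {
  df <- tidy(object)
  df$height <- ifelse(is.na(df$spectral_count), 1, df$spectral_count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$height)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$source, fill = .data$major),
                        size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`LC-MS/MS` = 21, MALDI = 24, both = 22)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               labels = c(`TRUE` = "major", `FALSE` = "minor")) +
    ggplot2::labs(x = "position (mature numbering)", y = "spectral count",
                  fill = "major site", shape = "evidence") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.site_map
#' @export
autoplot.repro_report <- function(object, ...) {
  autoplot(object$site_map)
}

#' Bar plot of per-site conservation percentages
#'
#' @param conservation Output of [site_conservation()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(conservation) {
  ggplot2::ggplot(conservation,
                  ggplot2::aes(x = factor(.data$position), y = .data$conservation)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "phosphosite (reference numbering)",
                  y = "conservation (% of aligned species)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
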