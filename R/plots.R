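#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stick-spectrum plot of a peak list
#'
#' @param object A [peaklist()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peaklist
#' @export
autoplot.peaklist <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(
      x = "m/z", y = "intensity",
      title = paste0(peaklist_instrument(object), ", ",
                     peaklist_polarity(object), " mode")
    ) +
    ggplot2::theme_minimal()
}

#' Annotated-spectrum plot
#'
#' Stick spectrum with the top-ranked decomposition label on each assigned
#' peak.
#'
#' @param object A `peak_annotation` from [annotate_peaklist()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peak_annotation
#' @export
autoplot.peak_annotation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0,
                                       color = .data$assigned)) +
    ggplot2::geom_text(
      data = df[df$assigned, ],
      ggplot2::aes(label = .data$best), angle = 90, hjust = -0.1, size = 2.6
    ) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black",
                                           `FALSE` = "grey60")) +
    ggplot2::expand_limits(y = max(df$intensity, 1) * 1.35) +
    ggplot2::labs(x = "m/z", y = "intensity", color = "assigned") +
    ggplot2::theme_minimal()
}

#' Released-product bar chart of a digestion census
#'
#' @param object A `product_census` from [digest()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot product_census
#' @export
autoplot.product_census <- function(object, ...) {
  df <- generics::tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$n,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}
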