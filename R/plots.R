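#' Bar plot of a 96-class mutation spectrum
#'
#' @param spectrum A single-scope spectrum tibble from [count_spectrum()].
#' @param title Optional plot title.
#' @return A ggplot with one bar per class, coloured by substitution type,
#'   the conventional signature-plot layout.
#' @export
plot_spectrum <- function(spectrum, title = NULL) {
  d <- as_tibble(spectrum) %>%
    mutate(
      type = paste0(
        substr(.data$class, 2, 2), ">", substr(.data$class, 6, 6)
      ),
      class = factor(.data$class, levels = context_classes())
    )
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$class, y = .data$n, fill = .data$type)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~type, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "Count", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(
        angle = 90, vjust = 0.5, size = 4, family = "mono"
      ),
      legend.position = "none"
    )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
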