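#' Plot a VAF spectrum
#'
#' Bar chart of the 19-bin spectrum; the top bin holds the homoplasmic
#' (VAF ~ 1) mutations.
#'
#' @param spectrum A [vaf_spectrum()] object.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  tb <- spectrum_as_tibble(spectrum)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$vaf_low + 0.025,
                                   y = .data$count)) +
    ggplot2::geom_col(width = 0.045, fill = "steelblue") +
    ggplot2::labs(x = "VAF", y = switch(spectrum$normalization,
                                        raw = "mutation count",
                                        per_cell_mean = "mutations per cell"),
                  title = if (!is.na(spectrum$cell_type)) {
                    spectrum$cell_type
                  } else NULL) +
    ggplot2::theme_minimal()
}

#' Plot marginal posteriors of the bottleneck parameters
#'
#' Histograms of the accepted draws for alpha, Td, Ta and the derived Nb,
#' with posterior means marked.
#'
#' @param posterior An [abc_reject()] result.
#' @return A ggplot object faceted by parameter.
#' @export
plot_posterior <- function(posterior) {
  long <- tibble::as_tibble(posterior)[, c("alpha", "Td", "Ta", "Nb")] |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter",
                        values_to = "value")
  means <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean),
                        color = "firebrick", linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "accepted draws") +
    ggplot2::theme_minimal()
}
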