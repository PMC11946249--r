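#' Forest plot of reporting odds ratios
#'
#' ROR point estimates with 95% Wald intervals on a log scale, one row per
#' event, colored by the combined signal flag. Undefined RORs are dropped.
#'
#' @param results tibble from [disproportionality()].
#' @param max_events show at most this many events (largest `a` first).
#' @return a ggplot object.
#' @export
plot_signal_forest <- function(results, max_events = 30) {
  df <- results %>%
    filter(.data$ror_defined) %>%
    arrange(desc(.data$a)) %>%
    slice_head(n = max_events) %>%
    mutate(event = factor(.data$event, levels = rev(unique(.data$event))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$event,
                                   color = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_low,
                                         xmax = .data$ror_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#c0392b",
                                           `FALSE` = "grey40"),
                                name = "combined signal") +
    ggplot2::labs(x = "ROR (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of cross-drug signal overlap
#'
#' Counts of events signalled in exactly each drug subset (the Venn region
#' counts from [signal_overlap()]); empty regions are dropped.
#'
#' @param overlap tibble from [signal_overlap()].
#' @return a ggplot object.
#' @export
plot_signal_overlap <- function(overlap) {
  df <- overlap %>%
    filter(.data$count > 0) %>%
    arrange(.data$n_drugs, desc(.data$count)) %>%
    mutate(drugs = factor(.data$drugs, levels = unique(.data$drugs)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drugs, y = .data$count,
                                   fill = factor(.data$n_drugs))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "drugs in subset") +
    ggplot2::labs(x = NULL, y = "events signalled in exactly this subset") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
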