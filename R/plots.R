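#' Plots
#'
#' ggplot2 views of the main result types: a genome map of element calls and
#' an IR-pair arc/segment view.
#'
#' @name plots
NULL

#' Genome map of element calls
#'
#' @param calls calls tibble.
#' @param genome_len genome length (nt) for the x scale.
#' @return A ggplot: one horizontal lane per call, copies drawn as segments
#'   coloured by kind.
#' @export
plot_element_map <- function(calls, genome_len = NULL) {
  if (nrow(calls) == 0L) stop("no calls to plot")
  rows <- calls %>% tidyr::unnest("copies")
  rows$lane <- match(rows$call_id, unique(rows$call_id))
  p <- ggplot2::ggplot(rows) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$lane,
                   yend = .data$lane, colour = .data$kind),
      linewidth = 3) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(rows$call_id)),
      labels = unique(rows$call_id)) +
    ggplot2::labs(x = "genome position (nt)", y = NULL, colour = "kind") +
    ggplot2::theme_minimal()
  if (!is.null(genome_len)) p <- p + ggplot2::xlim(0, genome_len)
  p
}

#' Plot inverted-repeat pairs along a sequence
#'
#' @param pairs tibble from [find_inverted_repeats()].
#' @return A ggplot with one lane per pair: arms as solid segments joined by a
#'   dashed spacer.
#' @export
plot_ir_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) stop("no IR pairs to plot")
  pairs$lane <- seq_len(nrow(pairs))
  ggplot2::ggplot(pairs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$left_end, xend = .data$right_start,
                                       y = .data$lane, yend = .data$lane),
                          linetype = "dashed", colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$left_start, xend = .data$left_end,
                                       y = .data$lane, yend = .data$lane,
                                       colour = factor(.data$mismatches)),
                          linewidth = 3) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$right_start, xend = .data$right_end,
                                       y = .data$lane, yend = .data$lane,
                                       colour = factor(.data$mismatches)),
                          linewidth = 3) +
    ggplot2::labs(x = "position (nt)", y = "IR pair", colour = "mismatches") +
    ggplot2::theme_minimal()
}
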