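# ggplot2 visualisations for profiles and domain architectures.

#' Plot a conservation profile
#'
#' Information content per alignment column, with the consensus residue on
#' the x axis.
#'
#' @param object A [build_profile()] object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot pac_profile
#' @export
autoplot.pac_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$ic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$consensus),
                       vjust = -0.3, size = 2.5) +
    ggplot2::labs(x = "alignment column", y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' Plot domain architectures
#'
#' Draws each record as a horizontal track with its PAC span and
#' associated-domain annotations.
#'
#' @param records Protein records.
#' @param matches Match tibble from [scan_strict()].
#' @param annotations Annotation tibble from [annotate_domains()].
#' @return A ggplot object.
#' @export
plot_architecture <- function(records, matches, annotations) {
  records <- as_protein_records(records)
  backbone <- tibble::tibble(record_id = records$id,
                             len = nchar(records$sequence))
  pac <- dplyr::mutate(matches[, c("record_id", "span_start", "span_end")],
                       kind = "pac")
  ann <- dplyr::bind_rows(
    dplyr::rename(annotations[, c("record_id", "kind", "start", "end")],
                  span_start = "start", span_end = "end"),
    pac)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = backbone,
                          ggplot2::aes(x = 1, xend = .data$len,
                                       y = .data$record_id, yend = .data$record_id),
                          linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_segment(data = ann,
                          ggplot2::aes(x = .data$span_start, xend = .data$span_end,
                                       y = .data$record_id, yend = .data$record_id,
                                       colour = .data$kind),
                          linewidth = 4) +
    ggplot2::labs(x = "residue", y = NULL, colour = "domain") +
    ggplot2::theme_minimal()
}
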