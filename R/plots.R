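# Plot methods for result objects not covered next to their classes.

#' Contact-site amino-acid frequency comparison
#'
#' Side-by-side bars of the immunogenic- and nonimmunogenic-class
#' amino-acid frequencies at TCR-contact sites, ordered by their
#' difference, mirroring the exploratory comparison that motivates the
#' frequency-score feature (hydrophobic residues enriched in the
#' immunogenic class, charged D/K in the nonimmunogenic one).
#'
#' @param object A [estimate_contact_frequencies()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.frequency_model <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::arrange(.data$difference) |>
    dplyr::mutate(aa = factor(.data$aa, levels = .data$aa)) |>
    tidyr::pivot_longer(c("f_pos", "f_neg"), names_to = "class",
                        values_to = "frequency") |>
    dplyr::mutate(class = dplyr::recode(.data$class,
                                        f_pos = "immunogenic",
                                        f_neg = "nonimmunogenic"))
  ggplot2::ggplot(d, ggplot2::aes(.data$aa, .data$frequency,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "amino acid (ordered by class difference)",
                  y = "contact-site frequency",
                  title = "Amino-acid usage at TCR-contact sites") +
    ggplot2::theme_minimal()
}

#' Score-band distribution of predictions
#'
#' Histogram of predicted scores colored by reporting category, with the
#' 0.4 and 0.5 band boundaries marked.
#'
#' @param predictions A tibble from [predict.ep_model()].
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_score_bands <- function(predictions, binwidth = 0.02) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(.data$score, fill = .data$category)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(0.4, 0.5), linetype = "dashed") +
    ggplot2::labs(x = "immunogenicity score (fraction of trees)",
                  y = "peptides", title = "Predicted score bands") +
    ggplot2::theme_minimal()
}
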