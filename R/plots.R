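#' Plot the ROC curve of a cross-validation result
#'
#' @param object A `hairpin_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hairpin_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)",
      y = "True positive rate (Sn)",
      title = sprintf("%d-fold cross-validation ROC (AUC = %.4f)",
                      object$folds, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Read-length distribution per library, coloured by category
#'
#' @param summary Output of [length_category_summary()].
#' @param proportions Plot per-library proportions rather than read counts
#'   (default TRUE, which puts libraries of different depth on one scale).
#' @return A ggplot object (faceted by library).
#' @export
plot_length_distribution <- function(summary, proportions = TRUE) {
  y <- if (proportions) "prop_reads" else "reads"
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$length, y = .data[[y]],
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~library) +
    ggplot2::labs(x = "Read length (nt)",
                  y = if (proportions) "Proportion of mapped reads" else "Reads",
                  fill = "Category") +
    ggplot2::theme_minimal()
}

#' Category composition across libraries
#'
#' @param summary Output of [length_category_summary()].
#' @param unique_tags Use unique-tag proportions instead of read
#'   proportions (default FALSE).
#' @return A stacked-bar ggplot object.
#' @export
plot_category_composition <- function(summary, unique_tags = FALSE) {
  val <- if (unique_tags) "prop_unique" else "prop_reads"
  comp <- summary |>
    dplyr::group_by(.data$library, .data$category) |>
    dplyr::summarise(prop = sum(.data[[val]]), .groups = "drop")
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$library, y = .data$prop,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Proportion", fill = "Category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Positionwise nucleotide-preference profile
#'
#' @param prefs Output of [position_preferences()] or
#'   [five_prime_logo_matrix()].
#' @return A stacked-bar ggplot object (one column per position).
#' @export
plot_position_preferences <- function(prefs) {
  long <- tidyr::pivot_longer(prefs, dplyr::all_of(NUC),
                              names_to = "nucleotide", values_to = "freq")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$freq,
                                     fill = .data$nucleotide)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Position (5' to 3')", y = "Frequency",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
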