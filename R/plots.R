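#' @importFrom ggplot2 ggplot aes autoplot geom_col geom_line geom_point
#'   geom_hline facet_wrap labs theme_minimal coord_flip
NULL

#' Plot the top feature importances of a fitted model
#'
#' @param object A `hotspot_model`.
#' @param top_n How many features to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hotspot_model
#' @export
autoplot.hotspot_model <- function(object, top_n = 20, ...) {
  imp <- head(tidy(object), top_n)
  ggplot(imp, aes(x = stats::reorder(.data$feature, .data$importance),
                  y = .data$importance)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "Impurity importance",
         title = sprintf("Top %d features of %d", top_n,
                         nrow(tidy(object)))) +
    theme_minimal()
}

#' Plot a fitted per-amino-acid probability correction
#'
#' @param object A `hotspot_calibration`.
#' @param ... Unused.
#' @return A ggplot of the additive correction per amino acid.
#' @method autoplot hotspot_calibration
#' @export
autoplot.hotspot_calibration <- function(object, ...) {
  ggplot(object, aes(x = .data$amino_acid, y = .data$correction)) +
    geom_col(fill = "darkorange") +
    labs(x = "Amino acid", y = "HS probability correction",
         title = "Per-amino-acid probability correction") +
    theme_minimal()
}

#' Per-chain hot-spot probability profile
#'
#' Line plot of the corrected (or raw) HS probability along each chain, with
#' predicted hot-spots highlighted and the 0.5 decision boundary drawn.
#'
#' @param predictions Prediction tibble with `chain_id`, `position` and
#'   probability/class columns (raw or corrected).
#' @return A ggplot faceted by chain.
#' @export
plot_hs_profile <- function(predictions) {
  prob_col <- if ("corrected_hs_probability" %in% names(predictions)) {
    "corrected_hs_probability"
  } else {
    "raw_hs_probability"
  }
  class_col <- if ("predicted_class" %in% names(predictions)) {
    "predicted_class"
  } else {
    "predicted_class_raw"
  }
  ggplot(predictions, aes(x = .data$position, y = .data[[prob_col]])) +
    geom_line(colour = "grey50") +
    geom_point(aes(colour = .data[[class_col]]), size = 1) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    facet_wrap(~chain_id, scales = "free_x") +
    labs(x = "Residue position", y = "HS probability", colour = "Class") +
    theme_minimal()
}
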