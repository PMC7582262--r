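as_binary_class <- function(x, arg) {
  x <- as.character(x)
  if (any(is.na(x)) || !all(x %in% c("HS", "NS"))) {
    abort(paste0("`", arg, "` must contain only 'HS' and 'NS'"))
  }
  x
}

#' Confusion counts for binary hot-spot predictions
#'
#' HS is the positive class: a true positive is an actual HS predicted HS, a
#' true negative an actual NS predicted NS.
#'
#' @param predicted,actual Character vectors of `"HS"`/`"NS"` of equal length.
#' @return One-row tibble with integer `tp`, `tn`, `fp`, `fn` summing to the
#'   number of residues.
#' @export
#' @examples
#' confusion_counts(c("HS", "NS", "HS"), c("HS", "NS", "NS"))
confusion_counts <- function(predicted, actual) {
  predicted <- as_binary_class(predicted, "predicted")
  actual <- as_binary_class(actual, "actual")
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have the same length")
  }
  tibble(tp = sum(predicted == "HS" & actual == "HS"),
         tn = sum(predicted == "NS" & actual == "NS"),
         fp = sum(predicted == "HS" & actual == "NS"),
         fn = sum(predicted == "NS" & actual == "HS"))
}

#' Scalar metrics from confusion counts
#'
#' Accuracy, precision, recall (true-positive rate), false-positive rate and
#' F1, all HS-positive-centric. A 0/0 cell yields `NA` rather than a silent
#' 0 or 1, so degenerate predictors (e.g. one that never calls HS) are loudly
#' visible instead of corrupting comparisons.
#'
#' @param counts One-row tibble from [confusion_counts()].
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `fpr`, `f1`.
#' @export
scalar_metrics <- function(counts) {
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (any(total == 0)) abort("Confusion counts sum to zero")
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  tibble(accuracy = (tp + tn) / total,
         precision = precision,
         recall = recall,
         fpr = safe_div(fp, fp + tn),
         f1 = ifelse(is.na(precision) | is.na(recall) |
                       (precision + recall) == 0,
                     NA_real_,
                     2 * precision * recall / (precision + recall)))
}

#' Area under the ROC curve
#'
#' Computed as the rank statistic: the probability that a randomly chosen
#' hot-spot receives a higher HS probability than a randomly chosen
#' null-spot, ties counted one half. This equals trapezoidal integration of
#' the ROC curve over all thresholds, and is invariant under any strictly
#' increasing transform of the scores.
#'
#' @param hs_probabilities Numeric scores (higher means more HS-like).
#' @param actual `"HS"`/`"NS"` vector of the same length.
#' @return AUROC in \[0, 1\], or `NA` when only one class is present.
#' @export
auroc <- function(hs_probabilities, actual) {
  actual <- as_binary_class(actual, "actual")
  if (length(hs_probabilities) != length(actual)) {
    abort("`hs_probabilities` and `actual` must have the same length")
  }
  n_pos <- sum(actual == "HS")
  n_neg <- sum(actual == "NS")
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(hs_probabilities, ties.method = "average")
  (sum(r[actual == "HS"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metrics report for a set of predictions
#'
#' @param predictions Tibble with `label` plus prediction columns
#'   (`predicted_class_raw`/`raw_hs_probability` and, when present, the
#'   post-correction `predicted_class`/`corrected_hs_probability`).
#' @return One row per evaluation stage (`original`, and `corrected` when the
#'   corrected columns are present): confusion counts, scalar metrics, AUROC
#'   and the residue count.
#' @export
evaluate_predictions <- function(predictions) {
  stopifnot("label" %in% names(predictions))
  stages <- list(original = c("predicted_class_raw", "raw_hs_probability"))
  if (all(c("predicted_class", "corrected_hs_probability") %in% names(predictions))) {
    stages$corrected <- c("predicted_class", "corrected_hs_probability")
  }
  purrr::imap_dfr(stages, function(cols, nm) {
    counts <- confusion_counts(predictions[[cols[1]]], predictions$label)
    bind_cols(tibble(stage = nm, n = nrow(predictions)),
              counts,
              scalar_metrics(counts),
              tibble(auroc = auroc(predictions[[cols[2]]], predictions$label)))
  })
}

#' Per-amino-acid metrics breakdown
#'
#' One metrics row per amino acid present plus a pooled `"all"` row, for each
#' evaluation stage (before and, when available, after the probability
#' correction). Confusion counts are additive, so the pooled row equals the
#' column sums of the per-amino-acid rows.
#'
#' @inheritParams evaluate_predictions
#' @return Tibble keyed by `amino_acid` and `stage`.
#' @export
per_amino_acid_report <- function(predictions) {
  stopifnot(all(c("amino_acid", "label") %in% names(predictions)))
  if (nrow(predictions) == 0) abort("`predictions` has no rows")
  groups <- c(as.list(sort(unique(predictions$amino_acid))), list("all"))
  purrr::map_dfr(groups, function(aa) {
    rows <- if (identical(aa, "all")) predictions
            else predictions[predictions$amino_acid == aa, ]
    bind_cols(tibble(amino_acid = aa), evaluate_predictions(rows))
  })
}

#' Support-weighted metrics variant
#'
#' Averages each metric over the two classes (each class taken in turn as the
#' positive one), weighted by class support — the aggregation convention many
#' multi-class toolkits print. Offered alongside the HS-centric metrics so
#' both conventions are available when comparing against published tables.
#'
#' @param predicted,actual `"HS"`/`"NS"` vectors of equal length.
#' @return One-row tibble: `precision_weighted`, `recall_weighted`,
#'   `f1_weighted`.
#' @export
weighted_metrics <- function(predicted, actual) {
  predicted <- as_binary_class(predicted, "predicted")
  actual <- as_binary_class(actual, "actual")
  per_class <- purrr::map_dfr(c("HS", "NS"), function(pos) {
    counts <- confusion_counts(ifelse(predicted == pos, "HS", "NS"),
                               ifelse(actual == pos, "HS", "NS"))
    bind_cols(tibble(support = sum(actual == pos)), scalar_metrics(counts))
  })
  w <- per_class$support / sum(per_class$support)
  wavg <- function(v) sum(w * dplyr::coalesce(v, 0))
  tibble(precision_weighted = wavg(per_class$precision),
         recall_weighted = wavg(per_class$recall),
         f1_weighted = wavg(per_class$f1))
}
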