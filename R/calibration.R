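#' Fit the per-amino-acid hot-spot probability correction
#'
#' Class imbalance varies strongly by residue type, so a single 0.5 threshold
#' on the raw HS probability under-calls hot-spots for some amino acids. The
#' correction examined here is fitted on a tuning set, per amino acid: let
#' `mFN` be the maximum raw HS probability among false negatives (actual HS
#' predicted NS) and `mTN` the maximum among true negatives. When false
#' negatives exist and `mFN > mTN`, the amino acid receives the additive
#' correction `0.50 - mFN` (clamped to \[0, 0.5\]); otherwise 0. The `mFN >
#' mTN` guard guarantees that, on the tuning set itself, lifting the highest
#' false negative to the 0.50 boundary cannot push any true negative across
#' it — true positives are gained without creating false positives. An amino
#' acid with false negatives but no true negatives is treated as having
#' `mTN = -Inf`, so the guard passes.
#'
#' @param predictions Tibble with columns `amino_acid`, `raw_hs_probability`
#'   and `label` (`"HS"`/`"NS"`), typically [predict_hs_probability()] output
#'   on the tuning set joined with its labels.
#' @return A `hotspot_calibration` tibble with one row per standard amino
#'   acid: `correction` (0 for residue types absent from the tuning set),
#'   `max_fn_prob`, `max_tn_prob`, `n_fn`, `n_tn`, `n_tuning`.
#' @export
#' @examples
#' preds <- tibble::tibble(amino_acid = "Y",
#'                         raw_hs_probability = c(0.42, 0.30),
#'                         label = c("HS", "NS"))
#' fit_correction(preds)
fit_correction <- function(predictions) {
  need <- c("amino_acid", "raw_hs_probability", "label")
  miss <- setdiff(need, names(predictions))
  if (length(miss) > 0) {
    abort(paste0("`predictions` is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(predictions) == 0) abort("Cannot fit a correction on an empty tuning set")

  per_aa <- predictions |>
    mutate(pred_ns = .data$raw_hs_probability <= 0.5) |>
    group_by(.data$amino_acid) |>
    summarise(
      n_tuning = n(),
      n_fn = sum(.data$pred_ns & .data$label == "HS"),
      n_tn = sum(.data$pred_ns & .data$label == "NS"),
      max_fn_prob = if (any(.data$pred_ns & .data$label == "HS"))
        max(.data$raw_hs_probability[.data$pred_ns & .data$label == "HS"]) else NA_real_,
      max_tn_prob = if (any(.data$pred_ns & .data$label == "NS"))
        max(.data$raw_hs_probability[.data$pred_ns & .data$label == "NS"]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(correction = ifelse(
      .data$n_fn > 0 &
        .data$max_fn_prob > dplyr::coalesce(.data$max_tn_prob, -Inf),
      pmin(0.5, pmax(0, 0.5 - .data$max_fn_prob)),
      0
    ))

  out <- tibble(amino_acid = AA_CODES) |>
    left_join(per_aa, by = "amino_acid") |>
    mutate(correction = dplyr::coalesce(.data$correction, 0),
           n_fn = dplyr::coalesce(.data$n_fn, 0L),
           n_tn = dplyr::coalesce(.data$n_tn, 0L),
           n_tuning = dplyr::coalesce(.data$n_tuning, 0L)) |>
    select("amino_acid", "correction", "max_fn_prob", "max_tn_prob",
           "n_fn", "n_tn", "n_tuning")
  class(out) <- c("hotspot_calibration", class(out))
  out
}

#' Fit the correction from a model and a tuning set
#'
#' Convenience wrapper: predicts raw probabilities on the tuning residues and
#' fits the per-amino-acid correction. Aborts if any tuning residue was seen
#' during training (checked against the model's stored residue keys), since a
#' correction fitted on training data would be meaningless.
#'
#' @param model A `hotspot_model`.
#' @param tuning_data Feature tibble for the tuning set including `label`
#'   (and `chain_id`/`position` for the leakage check).
#' @return A `hotspot_calibration` table.
#' @export
calibrate_hotspot_model <- function(model, tuning_data) {
  stopifnot(inherits(model, "hotspot_model"))
  if (!is.null(model$training_keys) &&
      all(c("chain_id", "position") %in% names(tuning_data))) {
    overlap <- intersect(residue_keys(tuning_data), model$training_keys)
    if (length(overlap) > 0) {
      abort(c("Tuning set overlaps the training set; calibration refused",
              paste0(length(overlap), " shared residue(s), e.g. ",
                     paste(head(overlap, 3), collapse = ", "))))
    }
  }
  pred <- predict_hs_probability(model, tuning_data)
  pred$label <- tuning_data$label
  fit_correction(pred)
}

#' Apply a fitted probability correction
#'
#' Adds each residue's per-amino-acid correction to its raw HS probability
#' (capped at 1) and assigns the final class. Where a positive correction was
#' fitted, the 0.50 boundary is closed (corrected probability >= 0.50 is HS),
#' so the tuning set's highest lifted false negative is recovered; where the
#' correction is zero the raw rule (HS strictly above 0.50) is kept
#' unchanged, making a zero correction the exact identity on classes even
#' for residues sitting on the boundary. Residues already classified HS
#' before correction can only move further into the HS class. Amino acids
#' absent from the calibration table get correction 0; such rows are flagged
#' in `correction_fitted`.
#'
#' @param predictions Tibble with `amino_acid` and `raw_hs_probability`
#'   (e.g. [predict_hs_probability()] output).
#' @param calibration A `hotspot_calibration` from [fit_correction()].
#' @return `predictions` plus `correction`, `corrected_hs_probability`,
#'   `predicted_class` (post-correction) and `correction_fitted`.
#' @export
apply_correction <- function(predictions, calibration) {
  stopifnot(inherits(calibration, "hotspot_calibration"))
  idx <- match(predictions$amino_acid, calibration$amino_acid)
  corr <- dplyr::coalesce(calibration$correction[idx], 0)
  predictions |>
    mutate(correction = corr,
           corrected_hs_probability = pmin(1, .data$raw_hs_probability + corr),
           predicted_class_raw = ifelse(.data$raw_hs_probability > 0.5, "HS", "NS"),
           predicted_class = ifelse(
             ifelse(corr > 0,
                    .data$corrected_hs_probability >= 0.5,
                    .data$raw_hs_probability > 0.5),
             "HS", "NS"),
           correction_fitted = !is.na(idx) &
             calibration$n_tuning[dplyr::coalesce(idx, 1L)] > 0)
}

#' @export
print.hotspot_calibration <- function(x, ...) {
  active <- sum(x$correction > 0)
  cat(sprintf("<hotspot_calibration> %d amino acid(s) with a positive correction\n",
              active))
  NextMethod()
}

#' @rdname hotspot_calibration_broom
#' @method tidy hotspot_calibration
#' @export
tidy.hotspot_calibration <- function(x, ...) as_tibble(x)

#' Broom-style accessors for calibration tables
#'
#' `tidy()` returns the per-amino-acid table; `glance()` summarises it.
#'
#' @param x A `hotspot_calibration`.
#' @param ... Unused.
#' @name hotspot_calibration_broom
#' @method glance hotspot_calibration
#' @export
glance.hotspot_calibration <- function(x, ...) {
  tibble(n_amino_acids_fitted = sum(x$n_tuning > 0),
         n_corrections_active = sum(x$correction > 0),
         max_correction = max(x$correction),
         n_tuning = sum(x$n_tuning))
}

#' Write / read a calibration table as JSON
#'
#' @param calibration A `hotspot_calibration`.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the `hotspot_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "hotspot_calibration"))
  jsonlite::write_json(as.data.frame(calibration), path,
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(paste0("Calibration file not found: ", path))
  out <- as_tibble(jsonlite::fromJSON(path))
  out$n_fn <- as.integer(out$n_fn)
  out$n_tn <- as.integer(out$n_tn)
  out$n_tuning <- as.integer(out$n_tuning)
  out$correction <- as.numeric(out$correction)
  out$max_fn_prob <- as.numeric(out$max_fn_prob)
  out$max_tn_prob <- as.numeric(out$max_tn_prob)
  class(out) <- c("hotspot_calibration", class(out))
  out
}
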