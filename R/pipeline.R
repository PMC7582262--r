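#' Run the full hot-spot prediction pipeline
#'
#' Orchestrates the stages in their canonical order: feature extraction,
#' per-amino-acid stratified splitting, extra-trees training on the train
#' partition, probability-correction fitting on the tuning partition, and
#' final evaluation on the independent partition. Independent-test residues
#' are never visible to training or calibration; this is asserted against the
#' model's stored residue keys and any violation is a hard failure, not a
#' warning. One structured log line per stage (row counts in and out) goes to
#' `stderr`, so the dataset bookkeeping is always auditable.
#'
#' @param chains Chain tibble from [read_chain_fasta()], or a FASTA path.
#' @param labels Labelled-residue tibble (`chain_id`, `position`,
#'   `amino_acid`, `label`), or a CSV path readable by
#'   [read_residue_table()]. Every labelled residue must exist in the chains
#'   with a matching wild-type amino acid.
#' @param seed Integer seed driving the split and the ensemble.
#' @param config A [feature_config()].
#' @param properties Property table.
#' @param n_trees,class_weighting Passed to [train_hotspot_model()].
#' @param out_dir Optional directory; when given, all artifacts are written:
#'   `features.csv`, `split.csv`, `split_report.csv`, `predictions.csv`
#'   (independent set, raw and corrected), `calibration.json`,
#'   `metrics.csv`, `per_amino_acid_metrics.csv` and `manifest.json` (seeds,
#'   checksums, versions, row counts).
#' @param verbose Emit per-stage log lines (default `TRUE`).
#' @return A `hotspot_run` list: `split`, `model`, `calibration`,
#'   `predictions` (independent set), `metrics`, `per_amino_acid`,
#'   `manifest`.
#' @export
run_hotspot_pipeline <- function(chains, labels, seed,
                                 config = feature_config(),
                                 properties = amino_acid_properties(),
                                 n_trees = 500,
                                 class_weighting = "balanced",
                                 out_dir = NULL,
                                 verbose = TRUE) {
  log_stage <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  if (is.character(chains)) chains <- read_chain_fasta(chains)
  if (is.character(labels)) labels <- read_residue_table(labels)
  validate_labels(labels)

  features <- extract_features(chains, config = config, properties = properties)
  log_stage("extract", "%d chains -> %d residues x %d features",
            nrow(chains), nrow(features),
            ncol(features) - 3L)

  data <- inner_join(labels, features,
                     by = c("chain_id", "position", "amino_acid"))
  if (nrow(data) < nrow(labels)) {
    abort(sprintf(paste0("%d labelled residue(s) have no matching chain ",
                         "position/amino acid in the FASTA input"),
                  nrow(labels) - nrow(data)))
  }

  split <- stratified_split(data, seed = seed)
  counts <- table(split$partition)
  log_stage("split", "%d residues -> %d train / %d tuning / %d independent",
            nrow(split), counts[["train"]], counts[["tuning"]],
            counts[["independent"]])

  train_data <- filter(split, .data$partition == "train")
  tuning_data <- filter(split, .data$partition == "tuning")
  indep_data <- filter(split, .data$partition == "independent")
  if (nrow(tuning_data) == 0 || nrow(indep_data) == 0) {
    abort("Split produced an empty tuning or independent partition")
  }

  model <- train_hotspot_model(select(train_data, -"partition"),
                               n_trees = n_trees,
                               class_weighting = class_weighting,
                               seed = seed)
  log_stage("train", "%d residues, %d trees", model$n_train, n_trees)

  calibration <- calibrate_hotspot_model(model, select(tuning_data, -"partition"))
  log_stage("calibrate", "%d tuning residues, %d active correction(s)",
            nrow(tuning_data), sum(calibration$correction > 0))

  # leakage guard: the independent half must be disjoint from everything the
  # model or the calibration ever saw
  seen <- c(model$training_keys, residue_keys(tuning_data))
  overlap <- intersect(residue_keys(indep_data), seen)
  if (length(overlap) > 0) {
    abort(c("Independent-test residues overlap training/tuning data",
            paste0(length(overlap), " shared residue(s)")))
  }

  predictions <- predict_hs_probability(model, select(indep_data, -"partition")) |>
    apply_correction(calibration)
  predictions$label <- indep_data$label
  metrics <- evaluate_predictions(predictions)
  per_aa <- per_amino_acid_report(predictions)
  log_stage("evaluate", "%d independent residues, corrected accuracy %.3f",
            nrow(predictions),
            metrics$accuracy[metrics$stage == "corrected"])

  manifest <- list(
    package_version = as.character(utils::packageVersion("hotspotr")),
    r_version = as.character(getRversion()),
    seed = as.integer(seed),
    windows = config$windows,
    property_checksum = rlang::hash(properties),
    n_chains = nrow(chains),
    n_labelled = nrow(data),
    n_train = unname(counts[["train"]]),
    n_tuning = unname(counts[["tuning"]]),
    n_independent = unname(counts[["independent"]]),
    n_trees = n_trees,
    class_weighting = class_weighting
  )

  run <- structure(list(split = split, model = model,
                        calibration = calibration,
                        predictions = predictions, metrics = metrics,
                        per_amino_acid = per_aa, manifest = manifest),
                   class = "hotspot_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_residue_table(features, file.path(out_dir, "features.csv"))
    write_residue_table(split, file.path(out_dir, "split.csv"))
    readr::write_csv(split_report(split), file.path(out_dir, "split_report.csv"))
    write_residue_table(predictions, file.path(out_dir, "predictions.csv"))
    write_calibration(calibration, file.path(out_dir, "calibration.json"))
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(per_aa, file.path(out_dir, "per_amino_acid_metrics.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("write", "artifacts in %s", out_dir)
  }
  run
}

#' @export
print.hotspot_run <- function(x, ...) {
  cat("<hotspot_run>\n")
  cat(sprintf("  %d train / %d tuning / %d independent residues\n",
              x$manifest$n_train, x$manifest$n_tuning, x$manifest$n_independent))
  print(x$metrics)
  invisible(x)
}

#' @rdname hotspot_run_broom
#' @method tidy hotspot_run
#' @export
tidy.hotspot_run <- function(x, ...) x$per_amino_acid

#' Broom-style accessors for pipeline runs
#'
#' `glance()` returns the corrected independent-test metrics as one row;
#' `tidy()` the per-amino-acid breakdown.
#'
#' @param x A `hotspot_run`.
#' @param ... Unused.
#' @name hotspot_run_broom
#' @method glance hotspot_run
#' @export
glance.hotspot_run <- function(x, ...) {
  filter(x$metrics, .data$stage == "corrected") |>
    select(-"stage")
}
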