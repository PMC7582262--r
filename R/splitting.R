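#' Per-amino-acid stratified train / tuning / independent-test split
#'
#' Splits labelled residues the way the hot-spot pipeline requires: the data
#' are first divided into one subset per (amino acid, class) pair; each subset
#' with both classes represented for that amino acid is split 60:40 into
#' train and test; amino acids present with only one class (in alanine-scanning
#' data typically CYS and MET, which carry only null-spots) go entirely to
#' train, since a test set could never assay them fairly. The pooled 40% is
#' then randomly halved into a tuning half (used to fit the probability
#' correction) and an independent half (touched only by final evaluation).
#'
#' The test count per two-class subset is `round(0.4 * n)` (half up), with a
#' floor of one test residue when `n >= 2`; singleton subsets go to train.
#' When the pooled test set is odd, the tuning half gets the extra residue.
#' All randomness derives from `seed`; per-subset counts are identical across
#' seeds, only membership changes.
#'
#' @param labels Tibble of labelled residues: `chain_id`, `position`,
#'   `amino_acid`, `label` (`"HS"` hot-spot / `"NS"` null-spot), optionally
#'   `ddg` (kcal/mol; rows with `ddg >= 2` must be labelled HS).
#' @param seed Integer seed controlling the random assignment.
#' @return The input tibble with an added `partition` factor
#'   (`train` / `tuning` / `independent`), of class `hotspot_split`.
#' @export
#' @examples
#' labs <- tibble::tibble(chain_id = "c", position = 1:10,
#'                        amino_acid = "Y",
#'                        label = rep(c("HS", "NS"), 5))
#' stratified_split(labs, seed = 1)
stratified_split <- function(labels, seed) {
  validate_labels(labels)
  labels <- as_tibble(labels)
  n_in <- nrow(labels)

  withr::local_seed(as.integer(seed))

  two_class <- labels |>
    group_by(.data$amino_acid) |>
    mutate(.two_class = dplyr::n_distinct(.data$label) == 2) |>
    ungroup()

  idx_test <- two_class |>
    mutate(.row = dplyr::row_number()) |>
    filter(.data$.two_class) |>
    group_by(.data$amino_acid, .data$label) |>
    group_split_test()

  partition <- rep("train", n_in)
  if (length(idx_test) > 0) {
    n_tune <- ceiling(length(idx_test) / 2)
    tune_rows <- sample_exactly(idx_test, n_tune)
    partition[tune_rows] <- "tuning"
    partition[setdiff(idx_test, tune_rows)] <- "independent"
  }

  out <- labels
  out$partition <- factor(partition, levels = c("train", "tuning", "independent"))
  class(out) <- c("hotspot_split", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}

# helper: within each (aa, label) group pick the test rows; returns row indices
group_split_test <- function(grouped) {
  picked <- grouped |>
    summarise(.rows = list({
      rows <- .data$.row
      n <- length(rows)
      n_test <- if (n >= 2) max(1L, floor(0.4 * n + 0.5)) else 0L
      if (n_test > 0) sample_exactly(rows, n_test) else integer(0)
    }), .groups = "drop")
  sort(unlist(picked$.rows))
}

# size-safe sampling without replacement (sample() re-interprets length-1 x)
sample_exactly <- function(x, k) x[sample.int(length(x), k)]

validate_labels <- function(labels) {
  need <- c("chain_id", "position", "amino_acid", "label")
  miss <- setdiff(need, names(labels))
  if (length(miss) > 0) {
    abort(paste0("`labels` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(labels) == 0) abort("`labels` has no rows")
  if (any(is.na(labels$label)) || !all(labels$label %in% c("HS", "NS"))) {
    abort("Every residue must be labelled 'HS' or 'NS'")
  }
  bad_aa <- setdiff(unique(labels$amino_acid), AA_CODES)
  if (length(bad_aa) > 0) {
    abort(paste0("Unknown amino-acid code(s) in labels: ",
                 paste(bad_aa, collapse = ", ")))
  }
  if ("ddg" %in% names(labels)) {
    viol <- !is.na(labels$ddg) & labels$ddg >= 2.0 & labels$label != "HS"
    if (any(viol)) {
      abort(paste0(sum(viol), " residue(s) with ddG >= 2.0 kcal/mol are not ",
                   "labelled HS; the hot-spot definition requires HS"))
    }
  }
  invisible(labels)
}

#' Per-amino-acid composition of a split
#'
#' @param split A `hotspot_split` from [stratified_split()].
#' @return Tibble with one row per amino acid present in the input and the
#'   HS/NS count in each partition
#'   (`train_HS`, `train_NS`, `tuning_HS`, ..., `independent_NS`); row sums
#'   equal the input counts.
#' @export
split_report <- function(split) {
  stopifnot(inherits(split, "hotspot_split"))
  split |>
    count(.data$amino_acid, .data$partition, .data$label) |>
    tidyr::pivot_wider(names_from = c("partition", "label"),
                       names_sep = "_",
                       values_from = "n",
                       values_fill = 0L,
                       names_expand = TRUE) |>
    arrange(.data$amino_acid)
}

#' @export
print.hotspot_split <- function(x, ...) {
  counts <- table(x$partition)
  cat(sprintf("<hotspot_split> %d residues: %d train / %d tuning / %d independent (seed %d)\n",
              nrow(x), counts[["train"]], counts[["tuning"]],
              counts[["independent"]], attr(x, "seed")))
  NextMethod()
}
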