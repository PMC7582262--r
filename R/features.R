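#' Feature-extraction configuration
#'
#' Fixes the settings that determine the per-residue descriptor layout: the
#' sliding-window half-widths, whether the target residue itself enters the
#' window mean, and the amino-acid order of the one-hot block. With the
#' defaults the descriptor has 20 + 1 + 19 + 19 x 7 = 173 values.
#'
#' Windows are symmetric: a window of size `w` at position `i` covers sequence
#' indices `[i - w, i + w]` clipped to the chain, so near the termini the mean
#' is taken over the residues that exist (no padding).
#'
#' @param windows Strictly increasing positive integers; half-widths of the
#'   sliding windows.
#' @param include_target Should the target residue contribute to its own
#'   window means? Default `TRUE`.
#' @param one_hot_order Permutation of the 20 standard codes giving the
#'   column order of the one-hot block.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(windows = DEFAULT_WINDOWS,
                           include_target = TRUE,
                           one_hot_order = aa_codes()) {
  windows <- as.integer(windows)
  if (length(windows) == 0 || any(windows <= 0) || is.unsorted(windows, strictly = TRUE)) {
    abort("`windows` must be strictly increasing positive integers")
  }
  if (!setequal(one_hot_order, AA_CODES) || length(one_hot_order) != 20) {
    abort("`one_hot_order` must be a permutation of the 20 standard codes")
  }
  structure(list(windows = windows,
                 include_target = isTRUE(include_target),
                 one_hot_order = one_hot_order),
            class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat("<feature_config>\n",
      " windows: ", paste(x$windows, collapse = ", "), "\n",
      " include_target: ", x$include_target, "\n", sep = "")
  invisible(x)
}

#' Frozen feature-name order
#'
#' The descriptor layout is one-hot block (`aa_<code>`), relative-position
#' quartile (`position_quartile`), the 19 raw properties, then one window-mean
#' block per window size (`<property>_w<size>`). Models store this order and
#' prediction refuses mismatched matrices, so train- and predict-time columns
#' always align.
#'
#' @inheritParams extract_features
#' @return Character vector (length 173 at the defaults).
#' @export
feature_names <- function(config = feature_config(),
                          properties = amino_acid_properties()) {
  props <- property_names(properties)
  c(paste0("aa_", config$one_hot_order),
    "position_quartile",
    props,
    as.vector(vapply(config$windows,
                     function(w) paste0(props, "_w", w),
                     character(length(props)))))
}

#' One-hot encode an amino acid
#'
#' @param aa Vector of one-letter codes.
#' @param one_hot_order Column order; default alphabetical.
#' @return Numeric 0/1 matrix, one row per element of `aa`, 20 columns named
#'   `aa_<code>`; each row sums to exactly 1.
#' @export
one_hot <- function(aa, one_hot_order = aa_codes()) {
  bad <- setdiff(unique(aa), AA_CODES)
  if (length(bad) > 0) {
    abort(paste0("Unknown amino-acid code(s): ", paste(bad, collapse = ", ")))
  }
  m <- outer(aa, one_hot_order, "==") * 1
  colnames(m) <- paste0("aa_", one_hot_order)
  m
}

#' Relative-position quartile of a residue
#'
#' Marks in which quarter of its chain a residue lies, as an integer 1-4:
#' `min(4, ceiling(4 * position / length))`. The last residue always maps to
#' 4; the first maps to 1 whenever the chain has at least 4 residues (shorter
#' chains use the same formula with no special case, so a lone residue sits
#' in quartile 4).
#'
#' @param position 1-based residue index (vectorised).
#' @param length Chain length (recycled).
#' @return Integer vector with values in 1..4.
#' @export
#' @examples
#' residue_quartile(1:8, 8)
residue_quartile <- function(position, length) {
  if (any(length < 1)) abort("`length` must be >= 1")
  if (any(position < 1 | position > length)) {
    abort("`position` must satisfy 1 <= position <= length")
  }
  pmin(4L, as.integer(ceiling(4 * position / length)))
}

#' Window mean of the 19 properties around one residue
#'
#' Arithmetic mean of each property over the residues at indices
#' `[position - window_size, position + window_size]`, clipped to the chain;
#' the target residue is included unless `include_target = FALSE`.
#'
#' This scalar form exists for inspection and testing; [extract_features()]
#' computes all windows for all residues at once.
#'
#' @param sequence Residue string (standard codes).
#' @param position 1-based index of the target residue.
#' @param window_size Half-width, >= 1.
#' @param properties Property table.
#' @param include_target Include the target residue in the mean?
#' @return Named numeric vector of 19 property means.
#' @export
window_average <- function(sequence, position, window_size,
                           properties = amino_acid_properties(),
                           include_target = TRUE) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  if (position < 1 || position > L) abort("`position` outside the sequence")
  if (window_size < 1) abort("`window_size` must be >= 1")
  idx <- max(1, position - window_size):min(L, position + window_size)
  if (!include_target) idx <- setdiff(idx, position)
  pm <- property_matrix(properties)
  colMeans(pm[res[idx], , drop = FALSE])
}

#' Extract the full per-residue descriptor for one or more chains
#'
#' Computes, for every residue of every chain, the ordered descriptor used by
#' the hot-spot classifier: 20 one-hot identity values, the relative-position
#' quartile, the 19 raw physicochemical properties of the residue, and the
#' window means of those properties over each configured window (19 x 7 = 133
#' at the defaults), 173 values in all. Window means use cumulative sums, so
#' extraction is linear in chain length.
#'
#' @param chains Tibble from [read_chain_fasta()] (columns `chain_id`,
#'   `sequence`), or a path to a FASTA file.
#' @param config A [feature_config()].
#' @param properties Property table; defaults to the bundled one.
#' @return Tibble with `chain_id`, `position`, `amino_acid`, then one column
#'   per feature in [feature_names()] order.
#' @export
#' @examples
#' fa <- system.file("extdata", "6q1g.fasta", package = "hotspotr")
#' feats <- extract_features(fa)
#' dim(feats)
extract_features <- function(chains,
                             config = feature_config(),
                             properties = amino_acid_properties()) {
  if (is.character(chains) && length(chains) == 1) {
    chains <- read_chain_fasta(chains)
  }
  validate_property_table(properties)
  pm <- property_matrix(properties)
  out <- purrr::map2_dfr(chains$chain_id, chains$sequence,
                         extract_chain, config = config, pm = pm)
  stopifnot(identical(setdiff(names(out), c("chain_id", "position", "amino_acid")),
                      feature_names(config, properties)))
  out
}

extract_chain <- function(chain_id, sequence, config, pm) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  M <- pm[res, , drop = FALSE]          # L x 19 per-residue property values

  oh <- one_hot(res, config$one_hot_order)
  quart <- residue_quartile(seq_len(L), L)

  # window means via cumulative sums: mean over rows [lo, hi] of M
  cs <- rbind(0, apply(M, 2, cumsum))   # (L+1) x 19
  win_blocks <- lapply(config$windows, function(w) {
    lo <- pmax(1L, seq_len(L) - w)
    hi <- pmin(L, seq_len(L) + w)
    sums <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
    cnt <- hi - lo + 1L
    if (!config$include_target) {
      sums <- sums - M
      cnt <- cnt - 1L
      if (any(cnt == 0)) abort("Window excludes every residue; enlarge `windows`")
    }
    blk <- sums / cnt
    colnames(blk) <- paste0(colnames(M), "_w", w)
    blk
  })

  bind_cols(
    tibble(chain_id = chain_id, position = seq_len(L), amino_acid = res),
    as_tibble(oh),
    tibble(position_quartile = quart),
    as_tibble(M),
    purrr::map_dfc(win_blocks, as_tibble)
  )
}
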