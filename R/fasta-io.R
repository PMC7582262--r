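#' Read protein chains from a FASTA file
#'
#' Parses a (possibly multi-chain) protein FASTA file into a tibble with one
#' row per chain. Sequence lines belonging to a header are concatenated,
#' surrounding whitespace is stripped, letters are uppercased, blank lines and
#' Windows line endings are tolerated. Every residue must be one of the 20
#' standard one-letter codes; non-standard letters (X, B, Z, U, ...) are
#' rejected because the residue descriptor scheme is only defined for the
#' standard alphabet.
#'
#' @param path Path to a FASTA file.
#' @param nonstandard What to do with a chain containing a letter outside the
#'   20 standard codes: `"error"` (default) aborts naming the chain, position
#'   and offending character; `"skip"` drops the chain with a warning.
#' @return A tibble with columns `chain_id` (header line without the leading
#'   `>`), `sequence` (uppercase residue string) and `length`.
#' @export
#' @examples
#' fa <- system.file("extdata", "6q1g.fasta", package = "hotspotr")
#' read_chain_fasta(fa)
read_chain_fasta <- function(path, nonstandard = c("error", "skip")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Failed to parse FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0) {
    abort(paste0("No FASTA records (no '>' header line) in '", path, "'"))
  }
  ids <- trimws(names(set))
  seqs <- unname(toupper(gsub("[[:space:]]", "", as.character(set))))
  if (any(ids == "")) {
    abort("FASTA header with empty chain identifier")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate chain identifier(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("Chain with empty sequence: ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }

  bad <- !purrr::map_lgl(seqs, seq_is_standard)
  if (any(bad)) {
    msgs <- purrr::map2_chr(ids[bad], seqs[bad], function(id, s) {
      pos <- first_nonstandard(s)
      sprintf("chain '%s': non-standard residue '%s' at position %d",
              id, substr(s, pos, pos), pos)
    })
    if (nonstandard == "error") {
      abort(c("Sequence validation failed", msgs))
    }
    warn(c("Skipping chain(s) with non-standard residues", msgs))
    ids <- ids[!bad]
    seqs <- seqs[!bad]
    if (length(ids) == 0) abort("All chains were skipped; nothing to return")
  }

  tibble(chain_id = ids, sequence = seqs, length = nchar(seqs))
}

seq_is_standard <- function(s) {
  !grepl(paste0("[^", paste(AA_CODES, collapse = ""), "]"), s)
}

first_nonstandard <- function(s) {
  regexpr(paste0("[^", paste(AA_CODES, collapse = ""), "]"), s)[[1]]
}

#' Expand chains to one row per residue
#'
#' @param chains Tibble as returned by [read_chain_fasta()].
#' @return Tibble with `chain_id`, `position` (1-based, contiguous per chain)
#'   and `amino_acid`.
#' @export
chain_residues <- function(chains) {
  stopifnot(all(c("chain_id", "sequence") %in% names(chains)))
  purrr::map2_dfr(chains$chain_id, chains$sequence, function(id, s) {
    tibble(chain_id = id,
           position = seq_len(nchar(s)),
           amino_acid = strsplit(s, "")[[1]])
  })
}

#' Write chains to a FASTA file
#'
#' Inverse of [read_chain_fasta()]; lines are wrapped at 60 characters.
#'
#' @param chains Tibble with `chain_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(chains, path) {
  set <- Biostrings::BStringSet(chains$sequence)
  names(set) <- chains$chain_id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Write / read a per-residue table as CSV
#'
#' Thin wrappers around readr that fix the column conventions used by the
#' pipeline artifacts: comma-delimited, UTF-8, header row, `position` kept as
#' an integer. A written table round-trips losslessly through
#' [read_residue_table()].
#'
#' @param rows A data frame of per-residue records sharing a common column set
#'   (typically `chain_id`, `position`, `amino_acid`, then payload columns).
#' @param path File path.
#' @return `write_residue_table()` returns `path` invisibly;
#'   `read_residue_table()` returns a tibble.
#' @export
write_residue_table <- function(rows, path) {
  readr::write_csv(as_tibble(rows), path)
  invisible(path)
}

#' @rdname write_residue_table
#' @export
read_residue_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("position" %in% names(out)) out$position <- as.integer(out$position)
  out
}
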