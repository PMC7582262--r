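# cache for the bundled table so repeated extraction calls don't re-read disk
the <- new.env(parent = emptyenv())

#' Literature-based amino-acid property table
#'
#' Returns the bundled table of 19 physicochemical properties for each of the
#' 20 standard amino acids: Chou-Fasman helix/sheet/turn propensities, pKa of
#' the alpha-carboxyl and alpha-amine groups and of the side chain (0.0 marks
#' residues without an ionizable side chain), isoelectric point, counts of
#' C/H/N/O/S atoms plus heavy-atom and total-atom counts derived from the
#' free-amino-acid molecular formula, average residue mass (g/mol), maximum
#' accessible surface area (A^2), residue volume (A^3), Kyte-Doolittle
#' hydropathy and Grantham polarity. These values are the raw per-residue
#' features and the inputs to the sliding-window averages.
#'
#' The table is fixed and shipped with the package; [property_sources()]
#' documents the reference behind every column. Users may substitute their own
#' table (same shape: `amino_acid` column plus 19 numeric columns covering all
#' 20 codes) anywhere a `properties` argument is accepted.
#'
#' @return A 20-row tibble: `amino_acid` plus 19 numeric property columns.
#' @export
#' @examples
#' amino_acid_properties()
#' property_names()
amino_acid_properties <- function() {
  if (is.null(the$properties)) {
    path <- system.file("extdata", "amino_acid_properties.csv",
                        package = "hotspotr")
    if (path == "" || !file.exists(path)) {
      abort("Bundled amino-acid property table is missing; reinstall hotspotr")
    }
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    validate_property_table(tab)
    the$properties <- tab
  }
  the$properties
}

validate_property_table <- function(tab) {
  if (!"amino_acid" %in% names(tab) || ncol(tab) != 20) {
    abort("Property table must have an 'amino_acid' column and 19 property columns")
  }
  if (!setequal(tab$amino_acid, AA_CODES) || nrow(tab) != 20) {
    abort("Property table must cover exactly the 20 standard amino acids")
  }
  vals <- as.matrix(tab[setdiff(names(tab), "amino_acid")])
  if (!is.numeric(vals) || !all(is.finite(vals))) {
    abort("Property table contains non-finite or non-numeric values")
  }
  invisible(tab)
}

#' @rdname amino_acid_properties
#' @param properties A property table; defaults to the bundled one.
#' @export
property_names <- function(properties = amino_acid_properties()) {
  setdiff(names(properties), "amino_acid")
}

#' Provenance of the bundled property table
#'
#' @return Tibble with one row per property: `property`, `source`.
#' @export
property_sources <- function() {
  path <- system.file("extdata", "amino_acid_property_sources.csv",
                      package = "hotspotr")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Look up a single property value
#'
#' @param aa One-letter amino-acid code (vectorised).
#' @param name One property name from [property_names()].
#' @param properties Property table.
#' @return Numeric vector of property values.
#' @export
#' @examples
#' get_property("W", "residue_mass")
get_property <- function(aa, name, properties = amino_acid_properties()) {
  if (length(name) != 1 || !name %in% property_names(properties)) {
    abort(paste0("Unknown property name: ", paste(name, collapse = ", ")))
  }
  bad <- setdiff(unique(aa), properties$amino_acid)
  if (length(bad) > 0) {
    abort(paste0("Unknown amino-acid code(s): ", paste(bad, collapse = ", ")))
  }
  properties[[name]][match(aa, properties$amino_acid)]
}

# 20 x 19 numeric matrix keyed by amino-acid code, columns in table order
property_matrix <- function(properties = amino_acid_properties()) {
  m <- as.matrix(properties[setdiff(names(properties), "amino_acid")])
  rownames(m) <- properties$amino_acid
  m
}
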