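# shared helpers for building small inputs in code

write_tmp_fasta <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "chains.fasta")
  writeLines(lines, path)
  path
}

example_fasta <- function() {
  system.file("extdata", "6q1g.fasta", package = "hotspotr")
}

# tiny feature frame with one perfectly separating column plus noise columns,
# for fast model tests that don't need real extraction
separable_frame <- function(n = 120, p_noise = 5, margin = 3, seed = 42) {
  withr::with_seed(seed, {
    label <- rep(c("HS", "NS"), length.out = n)
    signal <- ifelse(label == "HS", margin, -margin) + rnorm(n, sd = 0.3)
    noise <- matrix(rnorm(n * p_noise), n)
    colnames(noise) <- paste0("noise_", seq_len(p_noise))
    dplyr::bind_cols(
      tibble::tibble(chain_id = "c1", position = seq_len(n),
                     amino_acid = sample(aa_codes(), n, replace = TRUE),
                     label = label, signal = signal),
      tibble::as_tibble(noise)
    )
  })
}

# labelled residues with controllable per-aa class counts; positions unique
make_labels <- function(counts) {
  # counts: tibble with amino_acid, n_hs, n_ns
  rows <- purrr::pmap_dfr(counts, function(amino_acid, n_hs, n_ns) {
    tibble::tibble(amino_acid = amino_acid,
                   label = c(rep("HS", n_hs), rep("NS", n_ns)))
  })
  rows$chain_id <- "chain1"
  rows$position <- seq_len(nrow(rows))
  rows[c("chain_id", "position", "amino_acid", "label")]
}
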