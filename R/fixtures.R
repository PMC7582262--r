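#' Default per-amino-acid hot-spot rates for the experiment-like fixture
#'
#' Emulates the class structure of experimental alanine-scanning datasets:
#' alanine itself is absent (it is the mutation target, so it never appears
#' as a scanned wild-type residue), cysteine and methionine occur only as
#' null-spots, tyrosine and tryptophan are hot-spot-enriched, and the overall
#' hot-spot fraction is close to 24% (roughly 1 HS : 3.2 NS).
#'
#' @return Named numeric vector of target HS rates over 19 amino acids.
#' @export
alanine_scan_hs_rates <- function() {
  rates <- setNames(rep(0.25, 19), setdiff(AA_CODES, "A"))
  rates[c("C", "M")] <- 0
  rates["Y"] <- 0.60
  rates["W"] <- 0.35
  rates["R"] <- 0.30
  rates[c("S", "G", "P")] <- 0.15
  rates
}

#' Specification for a synthetic hot-spot dataset
#'
#' Describes the generator used for end-to-end testing. Chains are emitted by
#' a two-state segment process that emulates the patch organisation of
#' protein interfaces (hot-spots cluster in compositionally distinct
#' stretches, the classical O-ring picture): each segment of
#' `segment_length` residues is drawn either from a hot-spot-prone alphabet
#' or from a background alphabet. The hot alphabet weights each amino acid by
#' `hs_rates * exp(tilt * s)` and the background by
#' `(1 - hs_rates) * exp(-tilt * s)`, where `s` is the amino acid's
#' standardized mean over the informative properties, so the two states
#' differ in exactly the physicochemical signal the feature extractor
#' measures.
#'
#' Labels are then drawn so that the HS probability is a logistic function of
#' the window-averaged informative properties: writing `z` for the
#' standardized mean of the informative window means and `t` for the
#' midpoint between the two states' mean `z`, each residue's HS probability
#' is `plogis(effect_size * (z - t))`. `effect_size = Inf` is the
#' deterministic limit (a hard threshold at `t`); `effect_size = 0` makes
#' labels independent of the features. Amino acids with a target rate of
#' exactly 0 (or 1) are forced to NS (HS) regardless of `z`, and label noise
#' never touches forced classes, so single-class constraints such as
#' "CYS/MET null-spot only" hold exactly. The learnable signal lives, by
#' construction, inside the extracted feature space.
#'
#' @param n_chains Number of chains (default 12).
#' @param chain_length Length range, inclusive (default 60..100).
#' @param hs_rates Named per-amino-acid target HS rates; names define the
#'   sequence alphabet. Default [alanine_scan_hs_rates()].
#' @param informative_properties Property names carrying the signal.
#' @param effect_size Steepness of the label logistic per standard deviation
#'   of the informative signal (default 4, at which the realized class
#'   imbalance tracks `hot_fraction`); `Inf` gives deterministic labels.
#' @param label_noise Label flip probability (default 0.05).
#' @param window Half-width of the informative window (default 7, one of the
#'   extraction windows).
#' @param segment_length Length range of the hot/background segments
#'   (default 50..80).
#' @param hot_fraction Prior probability that a segment is hot-spot-prone
#'   (default 0.24, the class imbalance of alanine-scanning data).
#' @param tilt Compositional separation between the two segment states along
#'   the informative properties (default 1.4).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chains = 12,
                         chain_length = c(60, 100),
                         hs_rates = alanine_scan_hs_rates(),
                         informative_properties = c("hydropathy",
                                                    "surface_area",
                                                    "polarity"),
                         effect_size = 4,
                         label_noise = 0.05,
                         window = 7,
                         segment_length = c(50, 80),
                         hot_fraction = 0.24,
                         tilt = 1.4,
                         seed = 1) {
  if (is.null(names(hs_rates)) || !all(names(hs_rates) %in% AA_CODES) ||
      anyDuplicated(names(hs_rates))) {
    abort("`hs_rates` must be named by distinct standard amino-acid codes")
  }
  if (any(hs_rates < 0 | hs_rates > 1)) abort("`hs_rates` must lie in [0, 1]")
  if (all(hs_rates == 0) || all(hs_rates == 1)) {
    abort("`hs_rates` would force a single class for every residue")
  }
  if (effect_size < 0) abort("`effect_size` must be >= 0")
  if (label_noise < 0 || label_noise > 1) abort("`label_noise` must lie in [0, 1]")
  if (hot_fraction <= 0 || hot_fraction >= 1) {
    abort("`hot_fraction` must lie strictly inside (0, 1)")
  }
  if (n_chains < 1 || chain_length[1] < 2) {
    abort("Need at least one chain of length >= 2")
  }
  miss <- setdiff(informative_properties, property_names())
  if (length(miss) > 0) {
    abort(paste0("Unknown informative propert(ies): ", paste(miss, collapse = ", ")))
  }
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 hs_rates = hs_rates,
                 informative_properties = informative_properties,
                 effect_size = effect_size,
                 label_noise = label_noise,
                 window = as.integer(window),
                 segment_length = as.integer(segment_length),
                 hot_fraction = hot_fraction,
                 tilt = tilt,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic labelled hot-spot dataset
#'
#' @param spec A [fixture_spec()].
#' @return List with `chains` (tibble writable by [write_chain_fasta()]) and
#'   `labels` (`chain_id`, `position`, `amino_acid`, `label`), deterministic
#'   under the spec's seed.
#' @export
#' @examples
#' d <- generate_hotspot_dataset(fixture_spec(n_chains = 2, seed = 7))
#' head(d$labels)
generate_hotspot_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::local_seed(spec$seed)
  ab <- names(spec$hs_rates)
  pm <- property_matrix()

  # state alphabets: tilted along the informative-property axis
  s_aa <- rowMeans(scale(pm[ab, spec$informative_properties, drop = FALSE]))
  s_aa <- (s_aa - mean(s_aa)) / sd(s_aa)
  q_hot <- spec$hs_rates * exp(spec$tilt * s_aa)
  q_hot <- q_hot / sum(q_hot)
  q_cold <- (1 - spec$hs_rates) * exp(-spec$tilt * s_aa)
  q_cold <- q_cold / sum(q_cold)

  lens <- sample(seq(spec$chain_length[1], spec$chain_length[2]),
                 spec$n_chains, replace = TRUE)

  # segment skeleton first; the hot-segment count is fixed (not Bernoulli)
  # so the realized class imbalance tracks `hot_fraction` tightly
  skeleton <- purrr::map(lens, function(L) {
    segs <- integer(0)
    while (sum(segs) < L) {
      segs <- c(segs, sample(seq(spec$segment_length[1],
                                 spec$segment_length[2]), 1))
    }
    tibble(seg_len = segs, state = 0L)
  })
  n_seg <- sum(purrr::map_int(skeleton, nrow))
  n_hot <- min(n_seg - 1L, max(1L, round(spec$hot_fraction * n_seg)))
  states <- sample(rep(c(1L, 0L), c(n_hot, n_seg - n_hot)))
  skeleton <- purrr::map(skeleton, function(sk) {
    sk$state <- states[seq_len(nrow(sk))]
    states <<- states[-seq_len(nrow(sk))]
    sk
  })

  chains <- tibble(
    chain_id = sprintf("synth_%02d", seq_len(spec$n_chains)),
    sequence = purrr::map2_chr(skeleton, lens, function(sk, L) {
      res <- unlist(purrr::map2(sk$seg_len, sk$state, function(k, st) {
        sample(ab, k, replace = TRUE, prob = if (st == 1) q_hot else q_cold)
      }))
      paste(res[seq_len(L)], collapse = "")
    })
  )
  chains$length <- nchar(chains$sequence)
  state <- unlist(purrr::map2(skeleton, lens, function(sk, L) {
    rep(sk$state, sk$seg_len)[seq_len(L)]
  }))

  # informative signal: window means of the informative properties, pooled
  # over the whole dataset and standardized globally, so the planted rule is
  # a fixed monotone function of the same window features the extractor emits
  labels <- purrr::map2_dfr(chains$chain_id, chains$sequence, function(id, s) {
    res <- strsplit(s, "")[[1]]
    L <- length(res)
    M <- pm[res, spec$informative_properties, drop = FALSE]
    cs <- rbind(0, apply(M, 2, cumsum))
    lo <- pmax(1L, seq_len(L) - spec$window)
    hi <- pmin(L, seq_len(L) + spec$window)
    W <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
    bind_cols(tibble(chain_id = id, position = seq_len(L), amino_acid = res),
              as_tibble(W))
  })
  wm <- scale(as.matrix(labels[spec$informative_properties]))
  labels <- select(labels, "chain_id", "position", "amino_acid")
  labels$z <- as.numeric(scale(rowMeans(wm)))

  # decision boundary: midpoint between the two states' mean signal
  t_mid <- (mean(labels$z[state == 1]) + mean(labels$z[state == 0])) / 2
  rate <- spec$hs_rates[labels$amino_acid]
  p_hs <- if (is.infinite(spec$effect_size)) {
    as.numeric(labels$z > t_mid)
  } else {
    plogis(spec$effect_size * (labels$z - t_mid))
  }
  p_hs[rate <= 0] <- 0   # forced single-class residue types
  p_hs[rate >= 1] <- 1

  lab <- rbinom(nrow(labels), 1, p_hs)
  # noise never touches forced classes, so structural constraints like
  # "CYS/MET null-spot only" hold exactly
  flip <- rbinom(nrow(labels), 1, spec$label_noise) == 1 &
    rate > 0 & rate < 1
  lab[flip] <- 1 - lab[flip]
  labels$label <- ifelse(lab == 1, "HS", "NS")

  list(chains = chains,
       labels = select(labels, "chain_id", "position", "amino_acid", "label"))
}

#' Write a generated fixture to disk
#'
#' Emits `<prefix>.fasta`, `<prefix>_labels.csv` and `<prefix>_spec.json`
#' (the spec echo, so a run can be reproduced from its artifacts alone).
#'
#' @param spec A [fixture_spec()].
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(spec, prefix) {
  d <- generate_hotspot_dataset(spec)
  paths <- c(fasta = paste0(prefix, ".fasta"),
             labels = paste0(prefix, "_labels.csv"),
             spec = paste0(prefix, "_spec.json"))
  write_chain_fasta(d$chains, paths[["fasta"]])
  write_residue_table(d$labels, paths[["labels"]])
  jsonlite::write_json(unclass(spec), paths[["spec"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
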