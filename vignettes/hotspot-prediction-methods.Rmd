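---
title: "Sequence-only hot-spot prediction: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-only hot-spot prediction: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

## The problem

Protein–protein interfaces concentrate most of their binding free energy in a
small number of *hot-spot* residues: positions whose mutation to alanine
raises the binding free energy (ΔΔG~binding~) by more than 2.0 kcal·mol^-1^.
Residues that fail this threshold are *null-spots* (NS). Experimental alanine
scanning is expensive, and structure-based predictors need a solved complex,
so a predictor that works from sequence alone is useful whenever only the
chain sequence is known.

`hotspotr` implements such a pipeline end to end: per-residue feature
extraction from FASTA input, a stratified dataset split, an extremely
randomized trees classifier, a per-amino-acid probability-threshold
correction, and confusion-matrix evaluation.

## The per-residue descriptor (173 values)

Every residue of a chain is described by four concatenated blocks, in a
frozen column order that travels with any trained model:

1. **One-hot identity (20)** — a single 1 at the residue's position in the
   alphabetical code order.
2. **Relative-position quartile (1)** — `min(4, ceiling(4 * position /
   length))`, an integer 1–4 marking in which quarter of the chain the
   residue lies. The ceiling form assigns remainders to earlier quartiles
   deterministically; chains shorter than four residues use the same formula
   with no special case (a lone residue sits in quartile 4).
3. **Raw physicochemical properties (19)** — looked up in the bundled table
   (below).
4. **Sliding-window means (19 × 7 = 133)** — for each window half-width in
   (2, 5, 7, 10, 25, 50, 75), the arithmetic mean of each property over the
   residues at indices `[i − w, i + w]`, clipped at the chain termini with no
   padding, target residue included.

The window semantics deserve a note, because "a window of size w" is
ambiguous between trailing and centered windows and between total width and
per-side width. We fixed *symmetric, truncated, target-inclusive* windows:
this is the standard convention for residue-context features, and it gives
the descriptor a testable mirror symmetry (reversing a sequence maps residue
*i* to residue *L − i + 1* with quartiles flipped 1↔4, 2↔3), which the test
suite exercises. `feature_config(include_target = FALSE)` switches the
convention off for sensitivity analyses.

## The property table

The 19 properties cover secondary-structure propensity (Chou–Fasman helix,
sheet and turn), acid–base chemistry (pKa of the α-carboxyl and α-amine
groups, side-chain pKa with 0.0 as the documented sentinel for residues
without an ionizable side chain, isoelectric point), composition (C/H/N/O/S
atom counts, heavy-atom and total-atom counts derived from the
free-amino-acid molecular formula), size (average residue mass, maximum
accessible surface area, residue volume) and interaction character
(Kyte–Doolittle hydropathy, Grantham polarity). Each column's literature
source ships with the package (`property_sources()`), the table is immutable
at run time, and every column varies across the 20 amino acids — a constant
column would be an uninformative feature. Users can substitute their own
20 × 19 table anywhere a `properties` argument is accepted; trained model
bundles carry a checksum of the table they were extracted with and refuse to
predict against a different one.

## Dataset splitting

Alanine-scanning datasets are imbalanced overall (roughly 1 HS : 3.2 NS) and
per amino acid: some residue types appear with only one class (commonly CYS
and MET, null-spot only), and alanine itself never appears (it is the
mutation target). A plain random split can therefore starve the test set of
whole residue types. The splitter instead works per (amino acid, class)
subset: each subset whose amino acid has both classes is split 60:40 into
train and test, and single-class amino acids go entirely to train — a test
set could never score them fairly. The pooled 40% is randomly halved into a
*tuning* half (used only to fit the probability correction) and an
*independent* half (used only for final evaluation).

Rounding: the test count per subset is `round(0.4 n)` (half up) with a floor
of one test residue when `n ≥ 2`; singleton subsets go to train. When the
pooled test set is odd, the tuning half receives the extra residue — tuning
benefits most from data. Different seeds permute membership but never the
per-subset counts.

## The classifier

An ensemble of extremely randomized trees: each candidate split draws one
threshold uniformly at random per candidate feature and keeps the best of
those, which decorrelates trees strongly and suits small tabular datasets.
Defaults, frozen for reproducibility: 500 trees, bootstrap replicas per
tree, `floor(sqrt(p))` candidate features per split, unlimited depth,
minimum node size 1. Class imbalance is handled by *balanced* case weights —
each residue weighted inversely to its class frequency — applied alongside
the per-tree bootstrap, so each tree's effective class weighting varies with
its resample. Probabilities are the ensemble average of terminal-leaf class
frequencies. The engine is `ranger` (`splitrule = "extratrees"`,
`num.random.splits = 1`), single-threaded so a fixed seed reproduces the
ensemble exactly.

`tune_hotspot_model()` wraps a grid search with stratified k-fold
cross-validation (default 10 folds) on the training partition only. The
score it maximises is F1 by default — appropriate for the HS-positive,
imbalanced setting — switchable to accuracy or AUROC; degenerate folds in
which a metric is 0/0 score 0 for ranking purposes rather than propagating
an undefined value.

## Per-amino-acid probability correction

Because the HS:NS ratio varies strongly by residue type, a global 0.5
probability threshold systematically under-calls hot-spots for some amino
acids. The correction is fitted per amino acid on the tuning half only: with
`mFN` the maximum raw HS probability among false negatives and `mTN` the
maximum among true negatives, the amino acid receives the additive
correction `0.50 − mFN` exactly when false negatives exist and `mFN > mTN`
(otherwise 0; corrections are clamped to [0, 0.5], and an amino acid with
false negatives but no true negatives passes the guard, `mTN` being taken as
−∞). The guard makes a structural guarantee: on the tuning set itself every
true negative sits at or below `mTN < mFN`, so after adding `0.50 − mFN` it
stays strictly below 0.50 — true positives are gained, false positives are
not created. The test suite asserts this empirically across random tuning
sets, and the pipeline reports the FP/TP deltas.

Boundary conventions matter here. The raw class is HS when the probability
strictly exceeds 0.50. Where a positive correction was fitted, the final
class uses a *closed* boundary (corrected ≥ 0.50), so the lifted maximal
false negative reaches the HS class as intended. Where the correction is
zero, the raw rule is kept: a zero correction is the exact identity on
classes, including for residues sitting exactly on 0.50 — a blanket closed
boundary would silently flip such ties. Amino acids absent from the tuning
set get correction 0 and are flagged (`correction_fitted = FALSE`);
in particular alanine, for which no ground truth exists in
alanine-scanning data, is always predicted with correction 0.

## Metrics

Accuracy, precision, recall, false-positive rate and F1 are computed from
the confusion counts with HS as the positive class; any 0/0 cell yields `NA`
rather than a silent 0 or 1, so degenerate predictors (e.g. one that never
calls HS) are loudly visible. AUROC is the rank statistic — the probability
that a random hot-spot outranks a random null-spot, ties counted ½ — which
equals trapezoidal integration of the ROC curve and is invariant under
strictly increasing transforms of the scores; the tests check it against
exhaustive pair enumeration and against an independent ROC implementation.
Because published tables sometimes aggregate the two classes
support-weighted, `weighted_metrics()` emits that convention as well, so
both are available for comparison without asserting which one a given table
used. Per-amino-acid breakdowns (`per_amino_acid_report()`) are additive:
the pooled row equals the column sums of the per-type rows.

## The synthetic-data generator

Real alanine-scanning data cannot ship with the package, so the generator
builds datasets with the statistical structure the pipeline assumes, and
every stage is tested against them. Chains are produced by a two-state
segment process emulating the patch organisation of interfaces (hot-spots
cluster in compositionally distinct stretches — the classical O-ring
picture): segments of 50–80 residues are drawn either from a
hot-spot-prone alphabet or from a background alphabet. The hot alphabet
weights amino acid *a* by `rate(a) · exp(tilt · s(a))` and the background by
`(1 − rate(a)) · exp(−tilt · s(a))`, where `s(a)` is the amino acid's
standardized mean over the informative properties (default hydropathy,
surface area, polarity) and `rate(a)` the per-amino-acid hot-spot targets.
The default rates emulate experimental alanine-scanning structure: no
alanine in the alphabet, CYS and MET at rate 0 (null-spot only), tyrosine
enriched at 0.60, and an overall hot fraction near 24% (1 HS : 3.2 NS). The
number of hot segments is fixed at `round(hot_fraction · n_segments)` rather
than drawn per segment, so the realized imbalance tracks its target tightly.

Labels are then drawn so that the HS probability is a logistic function of
the planted signal: `z` is the standardized mean of the informative
window-7 means (one of the extraction windows, so the learnable signal lives
inside the 173-feature space by construction), `t` the midpoint between the
two states' mean `z`, and `P(HS) = plogis(effect_size · (z − t))`.
`effect_size = Inf` is the deterministic limit; `effect_size = 0` makes
labels independent of the features. Amino acids with rate exactly 0 or 1 are
forced to their class regardless of `z`, and label noise never touches
forced classes, so single-class constraints hold exactly. Defaults: 12
chains of 60–100 residues (≈950 labelled residues, the scale of the
experimental datasets), tilt 1.4, hot fraction 0.24, logistic steepness 4
(at which the realized imbalance matches the emulated one), label noise
0.05.

Two design notes, recorded because the design was genuinely open. First,
the segment process is what makes the end-to-end recovery property
meaningful: with uniformly random sequences the planted decision boundary
cuts through the dense middle of the window-mean distribution, and the
tuned classifier plateaus around 0.90–0.94 independent-test accuracy even
on noiseless labels and much larger datasets; with patch-structured
sequences the boundary sits in the low-density gap between states and a
strong planted signal is recovered at ≥ 0.95 accuracy robustly across
seeds. Second, what the generator does **not** emulate: real ΔΔG
energetics, structural context, contact networks, sequence redundancy
between chains, or the label sparsity of experimental datasets (it labels
every residue). Passing the recovery tests therefore demonstrates that the
pipeline's plumbing, split hygiene and learning machinery work — not that
real hot-spots are this easy.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated data:
the default fixture (≈950 residues) for the pipeline and structural checks,
a 24-chain fixture (≈1,900 residues) for the noise-free recovery check, ten
default-sized null fixtures for the no-leakage check (independent-test AUROC
stays in [0.35, 0.65] when the effect size is zero), and 100–150-row random
prediction tables for the calibration-guard and metric-oracle checks. A full
pipeline run at these sizes takes a few seconds on one CPU core.

## Known limitations

* The property table is assembled from standard public references by
  category; it is a faithful stand-in, not a byte-level copy of any specific
  deposited table, and substituting a different defensible table will move
  third-decimal feature values.
* The grid-search scoring metric, the split rounding rule and the window
  semantics are fixed, documented conventions; other reasonable conventions
  exist, and results on small datasets can be sensitive to them.
* Published headline figures for this class of predictor depend on the
  specific deposited residue set, its split seed and its exact property
  values; reproducing them requires the external dataset
  (`inst/scripts/reproduce-published.R` is a non-gating helper for that) and
  agreement should be expected only approximately.
* Prediction quality on real proteins is bounded by what sequence-local
  composition can express: long-range structural effects that decide many
  hot-spots are invisible to this feature set.
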