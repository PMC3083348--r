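---
title: "Methods behind oglcnacr: window-encoded SVM site prediction, calibration, and crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind oglcnacr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oglcnacr)
```

## The prediction problem

O-GlcNAcylation attaches a single N-acetylglucosamine to Ser/Thr hydroxyls
of nucleocytoplasmic proteins. It is dynamic and reciprocal with
phosphorylation, but it has no consensus motif, and curated corpora contain
on the order of a few hundred experimentally mapped sites against tens of
thousands of unmodified Ser/Thr in the same sequences — a positive rate
near 1.2%. Any usable predictor therefore has to (i) squeeze signal out of
local sequence context alone and (ii) report its confidence on a scale that
survives this extreme class imbalance. This vignette records how `oglcnacr`
does both, which knobs matter, and which choices were genuinely open.

## Window encoding

A candidate site is its sequence context: `n` residues upstream and `n`
downstream plus the site itself, a window of `2n + 1` symbols. Windows that
overhang a terminal are padded with a dedicated end-of-sequence symbol so
all windows have equal length. Each symbol is one-hot encoded over a
21-letter alphabet (20 amino acids + end-of-sequence), giving a binary
vector of length `21 (2n + 1)` with exactly `2n + 1` ones.

Numerical conventions:

* **Alphabet order.** Only the first two amino-acid slots (Ala, Arg) and the
  last slot (end-of-sequence) are fixed by the encoding convention this
  follows; the full order is not dictated by anything. We order the 20 amino
  acids alphabetically by three-letter code. Any fixed permutation yields an
  identical SVM (the RBF kernel only sees Hamming structure), but a declared
  order makes feature vectors decodable and reproducible; `decode_window()`
  inverts `sparse_encode()` exactly, and the test suite fuzzes this round
  trip.
* **`n` (window half-width).** Default 5 — the value at which this family of
  predictors has been observed to perform best — configurable 1–25.
  Raising `n` grows the feature space linearly (231 features at `n = 5`)
  and mostly adds noise beyond ~10.
* **Nonstandard letters.** B/Z/X/U/O/J/`*` have no slot in the 21-symbol
  alphabet. They are rejected by default; under `permissive = TRUE` they map
  to `X`, which encodes as an all-zero block. That keeps the vector length
  as published conventions expect, at the cost of making `X` windows carry
  slightly less mass (the vector sum drops below `2n + 1`); the block-argmax
  decoder returns `X` for all-zero blocks.
* **Coordinates.** 1-based everywhere a user can see, matching how sites are
  named in the literature (e.g. S473). Internal half-open arithmetic is
  never exposed.

## The classifier and its evaluation

An RBF-kernel C-SVM (libsvm via `e1071`) is trained on all windows: the
annotated sites are positives, every other Ser/Thr in the same sequences is
a negative. We deliberately do **not** resample: the downstream calibration
depends on held-out scores drawn at the natural class balance. Cost-weighted
training is available (`class_weights`) for users who want a sharper
decision boundary rather than a ranking.

`(C, γ)` are selected by grid search over `C ∈ 2^{-5..5}`, `γ ∈ 2^{-10..2}`
in powers of 4 (a standard log-spaced RBF search; nothing in the problem
fixes the grids) under k-fold cross-validation, default `folds = 5`.
Two fold-assignment policies exist because the right one is genuinely
debatable:

* `by_protein` (default): all sites of a protein share a fold. Windows from
  one protein — let alone homologs — are heavily correlated, and site-level
  folding lets near-duplicate windows straddle the train/test split,
  inflating AUC. Protein-grouped folding is the defensible default.
* `by_site`: plain instance-level folding, provided for comparability with
  evaluations that fold at the site level.

Fold draws are seeded; if a draw leaves a training fold single-class it is
redrawn a bounded number of times under `by_protein` and fails immediately
under `by_site` (where the user can do nothing about it by redrawing).

Performance is the area under the ROC curve computed by the Mann–Whitney
rank identity (ties counted 1/2) — the probability that a random positive
outscores a random negative. Both a pooled AUC (all held-out scores ranked
together) and the per-fold mean are reported, since either convention is
found in practice; the grid is ranked on the pooled value, with
deterministic tie-breaking towards smaller `C`, then smaller `γ`. The
implementation is cross-checked in the tests against a brute-force
pair-counting oracle and, for the grid, against an exhaustive loop that
retrains every pair directly.

## From scores to estimated precision and lift

A raw SVM decision value is meaningless to a bench scientist. The
calibration table turns it into an **estimated precision lower bound**:

1. pool the held-out cross-validation scores;
2. cut them into `bins` equal-frequency bins (default 20);
3. for each bin with `x` positives of `m` instances, report the one-sided
   lower Clopper–Pearson limit at `confidence` (default 95%):
   `qbeta(1 - confidence, x, m - x + 1)`, 0 when `x = 0`;
4. enforce monotonicity in score by pooling adjacent violators from low to
   high scores, merging bin counts and recomputing the limit, until the
   sequence of lower bounds is non-decreasing. Empty bins merge with a
   neighbour.

"Estimated lower bound" admits several readings; the exact one-sided
binomial limit plus adjacent-violator pooling was chosen because it is
conservative, closed-form, and testable: on synthetic data where the true
per-bin precision is known, the bound must cover it at least 95% of the
time, and the suite checks this over 30 replicates. The bound never exceeds
the raw bin precision.

**Lift** is estimated precision divided by the corpus base rate, default
0.0123 (the observed positive fraction of curated corpora of this kind,
373/30,270 ≈ 1.23%). Lift 1 means "no better than picking Ser/Thr at
random"; calibrated lifts in the mid-teens are what a corpus of this shape
supports at the top of the ranking. The default report threshold keeps
sites with estimated precision at or above the base rate (lift ≥ 1);
out-of-range scores clamp to the outermost calibration bins rather than
extrapolating. Proteins the caller lists as having secreted forms are
flagged in the report, because a sequence-context predictor cannot know
that a secreted form is topologically unavailable to the cytoplasmic
transferase.

## Yin-Yang crosstalk

Given per-protein O-GlcNAc positions `G` and phospho positions `P`:

* **identical** sites are `G ∩ P`;
* **adjacent** sites are the `p ∈ P` with `1 ≤ |p − g| ≤ k` for some
  `g ∈ G`, default `k = 4`.

Adjacency is judged per `(p, g)` **pair**: a phospho-site identical to one
O-GlcNAc site still counts as adjacent when it lies within `k` of a
*different* O-GlcNAc site. This pair-level rule (rather than excluding all
identical positions from the adjacent set) is required to reproduce curated
compendia in which the same position appears in both columns. Counts are
taken over distinct phospho positions per protein. The bundled
`yin_yang_table1.tsv` transcribes such a compendium (48 proteins) and the
summary over it — 74 adjacent sites, 48 proteins with at least one
relation, 41 identical sites — is pinned in the tests. One published row
lists an "identical" phospho-site with no matching O-GlcNAc position in its
own row, so the reconstructable identical total is 41 where the source
table prints 42; the transcription keeps the row verbatim and the rule is
not bent to absorb the discrepancy.

## Ortholog site transfer

Experimental sites propagate to an ortholog through a global
(end-gap-penalised) pairwise alignment: BLOSUM62 with affine gaps (open 11,
extend 1) by default, since ortholog pairs are near-full-length homologs; a
linear-gap match/mismatch scheme exists for constructed tests and is
verified against an independent dynamic-programming oracle. A site
transfers iff its column pairs it with a non-gap target position whose
residue is Ser or Thr. Two open choices were resolved as follows:

* **S↔T cross-conservation counts.** The biological criterion is a
  conserved hydroxyl acceptor, not letter identity; `conserved_identity`
  records whether the letter matched exactly, so the stricter reading is a
  one-line filter.
* **No identity gate by default.** Ortholog pairing is the caller's claim;
  a `--min-identity` option exists for pipelines that want a guard.

Sites on gap columns are dropped silently but tallied (`skipped`), and
`inferred + skipped = source sites` is a tested invariant, as is identity
transfer under self-alignment.

## Position enrichment (two-sample logo)

For each flank position and residue, the difference between positive-set
and negative-set frequencies with a pooled two-proportion z-test.
End-of-sequence symbols leave the denominators, so positions near terminals
are estimated from real residues only. Position 0 is reported but never
tested (it is Ser/Thr by construction). Default `alpha = 0.05` with no
multiple-testing correction — matching the convention of the familiar
two-sample-logo displays, which show per-cell significance — and Bonferroni
is available by flag. Cells with pooled frequency 0 or 1 get `p = 1`
(no evidence either way). The null false-positive rate at `alpha = 0.05`
is checked by Monte Carlo in the suite.

## The synthetic generator

`generate_corpus()` emulates the statistical shape the predictor assumes:

* ~300 sequences with log-normal lengths (median 1000), drawn i.i.d. from a
  background (uniform 0.05 by default; a Swiss-Prot-like preset is
  included) — chosen so the default corpus carries roughly 30,000 Ser/Thr
  sites, the scale of the motivating corpora;
* each Ser/Thr independently positive with probability 0.0123;
* positive flanks resampled from a motif model, default Pro at −3/−2, Val at
  −1, Thr at +1, Ala at +2, each planted with probability 0.6 — mirroring
  the qualitative "PPV(S/T)TA"-like enrichment seen around real sites, with
  no claim of matching real effect sizes. Flank rewriting never touches a
  position that is itself a selected positive centre; it may create or
  destroy other Ser/Thr, which simply join or leave the negative pool.

Identical seeds give byte-identical FASTA and site tables. What passing
tests on this generator shows — and what it does not: the pipeline recovers
a position-specific first-order signal at realistic imbalance (held-out AUC
≥ 0.85, in practice ≈ 0.98, with calibrated lifts in the teens), and finds
nothing on null corpora (permuted labels give AUC 0.5 ± 0.03 over
replicates). Real O-GlcNAc context is weaker and higher-order, so real-data
AUCs in the mid-0.7s are the realistic regime; synthetic performance is a
correctness check, not a performance claim.

`generate_crosstalk_fixture()` plants exact counts of identical and
adjacent relations, spaced widely enough that planted relations cannot
interact, so the crosstalk module can be held to exact recovery.

## Problem sizes and runtime

The test suite trains on corpora of ~400–4,500 sites (seconds each) and
runs the full ~30,000-site benchmark once: a 5-fold protein-grouped CV at
`C = 1`, `γ = 2^-6` takes under half a minute on one core, the scale used
by `scripts/acceptance.R`. Grid searches in tests use 3×3 grids on small
corpora so they can be compared against exhaustive retraining oracles.

## Known limitations

* Sequence context only: no physicochemical, structural or localisation
  features, hence the secreted-form flag is advisory metadata, not a model
  term.
* Calibration bins inherit the granularity of the held-out score
  distribution; with few positives the upper bins are wide and the bound
  coarse.
* The generator's first-order (per-position independent) motif model cannot
  produce the correlated, compositionally biased context of real substrate
  regions.
* Ortholog transfer trusts the caller's pairing; it will happily map sites
  through a bad alignment of non-homologs unless `--min-identity` is set.
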