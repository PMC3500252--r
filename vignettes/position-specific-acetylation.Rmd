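---
title: "Position-specific prediction of lysine acetylation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific prediction of lysine acetylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysace)
```

## The problem

Lysine acetylation is a reversible post-translational modification written by
lysine acetyltransferases (KATs) and erased by deacetylases (KDACs/HDACs).
Which lysines get acetylated is partly encoded in the residues flanking the
site: KAT complexes recognize short linear contexts, and those contexts are
not symmetric around the site — structural work on KAT–substrate complexes
shows the enzyme does not dock on a contiguously balanced window. `lysace`
implements a sequence-only predictor built around that observation: instead
of encoding a fixed contiguous window, it ranks every window offset by how
much it tells us about the acetylation status and encodes only the
informative ones.

The unit of analysis is a *fragment*: a window of `m` residues upstream and
`n` downstream of a candidate lysine (defaults `m = n = 10`, a 21-mer),
indexed by signed offsets `-m..+n` with the lysine at offset 0. Offsets past
a protein terminus carry the pad symbol `X`, which is information-free in
every encoder (all-zero one-hot block, property value 0, similarity 0).

## Corpus construction

`read_fasta()` and `read_site_annotations()` load sequences and validated
1-based site positions (the annotated residue must be lysine).
`extract_fragments()` cuts the windows; `enumerate_negative_sites()` takes
every unannotated lysine in the same proteins as a candidate negative, the
usual closed-world assumption for PTM predictors.

Two sampling conventions matter:

* **Fragment redundancy.** Two aligned 21-mers that agree at more than 30%
  of their offsets are considered redundant and only the first (in
  deterministic `(protein_id, position)` scan order) is kept
  (`reduce_redundancy()`). Identity is exact positional match over the
  fixed-length alignment — fragments are already aligned by construction, so
  no gapped alignment is involved. The threshold is strict (`> 0.30`
  discards). Redundancy is reduced within each class independently; whether
  negatives should additionally be de-redundified against positives is not
  settled, and we chose the within-class convention because it never
  silently deletes signal from one class based on the other.
* **Balanced negative sets.** Negative lysines vastly outnumber positives.
  Rather than training one unbalanced model, `sample_balanced_negative_sets()`
  draws (by default) five independent negative subsamples of exactly the
  positive-set size; every evaluation is repeated per set and reported as
  mean ± standard deviation over the sets, so the quoted spread tracks
  negative-resampling variability. Sets may overlap each other; within a
  set, sampling is without replacement.

Whole-protein homology reduction (e.g. 30% identity clustering with CD-HIT)
is out of scope: supply already-clustered FASTA if you need it.
`hold_out_proteins()` provides the protein-level train/holdout split (default
10%) so no protein contributes fragments to both sides.

## Feature encoders

Three blocks, concatenated by `assemble_features()` as `[BE | KNN | AASA]`
with a recorded layout; any subset can be selected for ablations.

**Binary encoding (BE).** Each encoded position is a 20-slot one-hot
indicator in the fixed alphabet order `ACDEFGHIKLMNPQRSTVWY`; a mask of `L`
positions yields `20 L` columns. Pads encode as all zeros.

**KNN scores.** For a query fragment, the distance to every labeled
reference fragment is

$$D(S_1, S_2) = 1 - \frac{1}{L}\sum_{i=1}^{L} \mathrm{Sim}(S_1[i], S_2[i]),$$

where `Sim` is BLOSUM62 min–max normalized globally to `[0, 1]`
(`Sim = (M - \min M)/(\max M - \min M)`; for BLOSUM62 the range is −4..11).
The KNN score is the fraction of positive-labeled fragments among the `k`
nearest neighbors; five scores are taken with `k` equal to 0.025%, 0.05%,
0.1%, 0.2% and 0.4% of the reference size (`k = max(1,
\mathrm{round}_{half\text{-}up}(f N))`). Scores above 0.5 mean the local
sequence neighborhood looks like known acetylation sites. Numerical
conventions that make the scores bit-reproducible: reference fragments are
ranked with ties broken by `(protein_id, position)` order; distances are
quantized at 1e-9 before ranking (true distances live on a lattice no finer
than `1/(15L)`, so this only removes floating-point summation noise); and a
reference fragment is excluded as a self-match when it shares the query's
`(protein_id, position)` identity — not when its distance is zero, so a
duplicated sequence from a different protein still counts as a neighbor.
The choice of global (rather than per-row) normalization of the
substitution matrix is a convention; only the induced neighbor ranking
matters, and `normalize_substitution_matrix()` accepts any symmetric
substitution matrix if you want to experiment.

**AASA.** Each encoded position contributes the average accessible surface
area of its residue, from the bundled AAindex entry JANJ780101 (Janin et
al.; PTM sites prefer solvent-exposed side chains, and lysine itself tops
this index at 103 Å²). Values are min–max scaled to `[0, 1]` by default so
the block is commensurate with the 0/1 one-hot block; `scaling = "none"`
keeps raw units. Any AAindex1 flat file can be substituted via
`read_aaindex()`, and `screen_property_indices()` reproduces the screening
harness that ranks candidate indices by single-property cross-validated SVM
accuracy — on a balanced corpus an uninformative (constant) index sits at
chance, ~50%.

Because all three blocks are constructed in `[0, 1]`, the SVM is run on the
raw features by default (`scale = FALSE`); standardization fit on the
training fold is available with `scale = TRUE`.

## Information-gain position selection

For window offset `c` with observed residue `Y_c` (20 amino acids plus the
pad, which is kept as an observable 21st symbol — terminal windows carry
real information about site position), the information gain on the class
variable `X` is

$$IG(c) = H(X) - H(X \mid Y_c), \qquad
H(X \mid Y_c) = \sum_j P(y_j)\, H(X \mid Y_c = y_j),$$

in bits (the log base only rescales the ranking, so it is inert
downstream). Probabilities are unsmoothed maximum-likelihood counts with the
`0 log 0 = 0` convention; a Laplace pseudocount is available for tiny
corpora. The center offset is constant lysine and scores exactly 0.
`select_positions()` keeps the `size` highest-IG offsets (ties: smaller
absolute offset, then upstream first), and `preset_mask()` provides the
published position-specific masks (`IG9` … `IG17`) alongside contiguous
`general9` … `general21` windows for comparison. Masks never include the
center; a size-13 position-specific mask therefore encodes 13 positions
while a length-13 contiguous window encodes 12.

`composition_frequencies()` and `positionwise_enrichment()` implement the
accompanying composition analysis. The per-(offset, residue) enrichment test
is a two-proportion z-test without continuity correction — the construction
two-sample-logo tools use — flagged at a fixed `p ≤ 1e-4` with no
multiple-testing correction; the number of tests performed is recorded on
the result so readers can calibrate that threshold themselves.

## Model and evaluation protocol

The classifier is an RBF-kernel SVM (libsvm via `e1071`).
`grid_search_train()` tunes `(C, γ)` by stratified inner cross-validation
over coarse powers-of-two grids (defaults `2^-5..2^15` and `2^-15..2^3`, ×4
steps), breaking ties toward the smaller `C` then smaller `γ`; a
single-point grid skips the search. `cross_validate()` runs the full
protocol: for each balanced negative set, a stratified 10-fold split
(stratification by label is our choice; it keeps every fold balanced); per
fold, the KNN reference is the *training fold only*, and tuning runs inside
the training fold (`tuning = "per-fold"`, the leakage-safe default; a
`"global"` per-set mode is provided for speed). Metrics are accuracy,
sensitivity, specificity and the Matthews correlation coefficient, in
percent, with MCC defined 0 when a denominator factor vanishes. Fold
metrics are averaged within a set first; the headline numbers are mean ± sd
over the sets.

`compare_mcc()` compares two configurations on their per-set MCC values
with Welch's unequal-variance t-test. (A "paired Welch" test is a
contradiction in terms — Welch's correction exists for the unpaired case —
so the default is Welch's unpaired test, with `paired = TRUE` available.)
`evaluate_holdout()` scores a trained model on an independent corpus, using
the full training corpus as the KNN reference, and refuses protein overlap
with the training reference unless explicitly overridden.

## The synthetic generator and what passing tests mean

`generate_fragments()` plants a positional motif: at each informative
offset, positives carry the enriched residue with probability exactly
`p_enrich` (misses redraw from the background excluding that residue, so
`p_enrich` is the exact occurrence probability), negatives are pure
background, and offset 0 is always lysine. Defaults mirror the qualitative
signal around real acetylation sites — lysine enriched across offsets
−8..−1 and arginine at +1, `p_enrich = 0.35` against a uniform background
(0.05) — so the planted truth structurally matches the size-9
position-specific mask. Setting `p_enrich` to the background frequency
gives an exact null; a background excluding the enriched residue with
`p_enrich = 1` makes an offset perfectly class-determining, driving its IG
to the full class entropy. `generate_annotated_proteins()` packs fragments
into synthetic proteins and emits FASTA + annotation TSV that round-trip
exactly through the corpus readers.

These corpora deliberately do *not* imitate real proteome composition,
homology structure, KAT-family substructure, or correlated positions:
passing tests demonstrate that the machinery recovers planted signal under
its stated conditions, not that real acetylomes reach any particular
accuracy. Against real data the expected behaviour is qualitative —
position-specific masks should beat contiguous windows when the true signal
is non-contiguous.

## Problem sizes and numerical choices

The calibration experiments use 2,000 positive fragments with a 10,000
negative pool (each balanced set 2,000 + 2,000), 10-fold cross-validation,
and a fixed `(C = 1, γ = 1/278)` RBF point for the headline runs — with the
strongly planted default motif, accuracy sits near 89% and the grid search
adds little beyond runtime, so the wide grid is reserved for real-data use.
The mask-versus-window comparison runs five generator seeds and compares
mean MCC of the IG-selected 13-offset mask against the contiguous length-13
window under identical folds and hyperparameters. Degenerate inputs are
handled explicitly: empty corpora pass through the redundancy filter,
single-class corpora are rejected by the IG profile, all-constant feature
matrices are rejected before SVM training, and `k` larger than the
post-self-exclusion reference is an error rather than a silent clamp.

## Known limitations

* The negative class is the closed-world complement of the annotations;
  some "negatives" are undiscovered positives, which depresses measured
  specificity on real data.
* Fragment-level redundancy reduction does not substitute for
  protein-level homology clustering.
* No PSSM/profile or secondary-structure features; reports in the
  acetylation-prediction literature suggest predicted secondary structure
  adds little here.
* No probability calibration: predictions are decision values thresholded
  at 0.
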