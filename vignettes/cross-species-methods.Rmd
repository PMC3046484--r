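---
title: "Methods: cross-species comparison of global expression patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species comparison of global expression patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossortho)
```

`crossortho` compares global gene-expression structure between two species
measured on different microarray platforms, using one-to-one orthologous
gene pairs as the bridge. This vignette is the package's account of the
models and procedures it implements, the parameters that matter, and what
its synthetic-data tests do and do not establish.

## The analysis chain

The pipeline takes two probeset-by-sample matrices of RMA-style log2
intensities (one per species), per-sample annotations (species, tissue
category, experiment accession), a one-to-one ortholog gene table, and
probe sequences per probeset. It proceeds: array QC → ortholog probeset
pairing → robust normalization → merging → global-pattern analysis
(PCA, tissue correlation, clustering) → corCor → variance-window sharing →
list-overlap testing. Each stage is an exported function; `run_pipeline()`
chains them from a configuration and records a manifest with file
checksums so reruns are verifiable.

## Array quality control

`filter_arrays()` applies per-metric acceptance ranges to a precomputed QC
table: average background 20–150, percent present 25–65%, RNA degradation
slope < 1.7, scale factor 0.1–2.5, NUSE 0.97–1.05, RLE −0.15–0.15. An
array passes only if every metric is in range, and the report lists every
violated criterion. All bounds are inclusive except the RNA-degradation
bound, which is strict; the sources that recommend these ranges do not say
whether their bounds are inclusive, so the inclusive reading was chosen
and the thresholds are fully configurable through `qc_thresholds()`.
Computing the metrics themselves from raw CEL files is out of scope: it
requires platform libraries and raw data, while the filtering rule is
platform-free.

## Ortholog probeset pairing by probe alignment

Because probe effects dominate microarray intensities, orthologous genes
are matched at the probeset level by probe-sequence similarity rather than
by annotation alone. For each orthologous gene pair, every probe of every
candidate probeset on side A is aligned against every probe on side B
(`align_probes()`): Smith–Waterman local alignment with match +1,
mismatch −3, affine gap open 5 / extend 2 (a gap of length L costs
5 + 2L), and a seed requirement — a shared exact 7-mer — without which the
score is 0. These are legacy nucleotide-BLAST conventions; the substitution
scores are configurable since pairing only needs a consistent ranking.
E-values and bit scores are deliberately omitted for the same reason.

`best_one_to_one_matches()` retains matches greedily by descending score,
each probe used at most once, ties broken lexicographically by probe ids
so results are reproducible. Greedy matching (rather than an optimal
assignment) mirrors how "best reciprocal hit" style procedures are run in
practice; the greedy order is also the natural reading of retaining "the
best match" repeatedly. `pair_probesets()` then picks the probeset
combination with the most retained matches, breaking ties by total
alignment score and then by probeset id. Gene pairs with no
positive-scoring probe match at all are flagged unpairable and excluded
downstream rather than silently dropped.

Probes are aligned as given (same strand, no reverse complement): probes
for one platform family are strandwise consistent. The ortholog table must
be one-to-one; reducing many-to-many ortholog families to pairs is an
upstream curation step this package does not attempt.

## Median/MAD normalization and merging

`normalize_by_probeset()` centers each row on median zero and divides by
the row's median absolute deviation; `normalize_by_sample()` does the same
by columns. Two numerical choices matter:

* **The MAD is unscaled** — `median(|x − median(x)|)` without the 1.4826
  normal-consistency factor. Nothing downstream depends on the scale being
  comparable to a standard deviation, and the plain MAD is the more
  literal reading of "divided by median absolute deviation". A constant
  factor would cancel out of every correlation-based stage anyway.
* **MAD-zero vectors** (constant, or majority-constant, rows/columns)
  cannot be scaled. They are set to all zeros and flagged
  (`mad_zero_ids()`) instead of dropped, preserving row alignment between
  the two species' matrices.

Medians of even-length vectors are the mean of the two central order
statistics (R's default). The `scale_tag` attribute tracks the applied
mode; normalizing twice, or merging two matrices normalized in different
modes, is an error rather than a silent renormalization. `merge_matrices()`
concatenates sample columns over the pairing without touching the values.

Tissue categories heavily dominated by one species distort global
structure; `filter_unbalanced_tissues()` removes them from both species,
either by an explicit drop-list (the default, since the right list is a
curation judgment) or by a maximum between-species share ratio.

## PCA, silhouettes, and the tissue-correlation matrix

`pca()` treats samples as observations (the matrix is transposed before
decomposition), mean-centers variables and does not rescale them — the
`prcomp` defaults. PCA signs are arbitrary, so each loading vector is
flipped to make its largest-magnitude entry positive; scores follow. The
package's tests verify the decomposition against a direct
eigendecomposition of the sample covariance.

The original argument that samples "cluster by tissue" is visual; a
quantitative surrogate is needed for testing, and the silhouette width
(Euclidean distance on the first k = 3 score dimensions,
`cluster_separation()`) is the standard choice. The headline phenomenon is
a contrast: after by-probeset normalization the per-probeset
species/platform offset is removed exactly (it is constant within a row
and each species is centered separately), so tissue dominates the top
components; after by-sample normalization the offset survives and species
separates first. Both directions are asserted in the tests.

`tissue_correlation_matrix()` crosses species with tissue category
(2T groups), computes Pearson correlations between all sample pairs
across probeset rows, and averages them per group pair. Within-group
entries exclude each sample's correlation with itself, which would
otherwise inflate the diagonal toward 1. `hierarchical_cluster()` applies
complete-linkage clustering on Euclidean distances between the matrix
rows — the defaults of the usual heatmap tooling, which the original
workflow relied on. `sibling_tissue_fraction()` scores how often the two
species' groups for the same tissue merge with each other first.

## corCor

For ortholog pair (A, A′) on platforms with n paired genes,
v(A) is the length n − 1 vector of Spearman correlations of A with every
other gene of its own platform, entries ordered by the pairing; corCor is
the correlation between v(A) and v(A′). The inner correlation is Spearman
(rank-based, robust to monotone distortions across platforms — corCor is
invariant to any strictly monotone per-row transform, and the tests check
this); the outer correlation is Pearson by default with Spearman available
via `outer_method`, since the procedure's description does not fix it and
Pearson matches the integrative-correlation tradition this statistic comes
from.

Implementation: each matrix is rank-transformed once per row, the n × n
correlation matrix computed by matrix products, and profiles read off by
dropping the self-entry — O(n²·s) overall, keeping compendium scale
(~6,000 pairs) tractable. Constant rows have no defined rank correlation;
their profile entries are set to 0 and flagged. A profile vector with zero
variance makes corCor undefined; it is recorded as missing, never as 0,
and `count_exceeding()` (strict inequality, as in "corCor > 0.1") reports
defined and undefined counts separately.

`corcor_null()` randomizes the matrices and recomputes everything. The
default mode shuffles each row independently across samples, destroying
gene–gene correlation while preserving per-gene marginals; a global
shuffle is available because the phrase "the expression values were
randomized" admits both readings. Under the null the corCor of a pair is
approximately N(0, 1/(n−1)), so with n ≥ 1,000 pairs essentially no null
pair exceeds 0.1 — the package's analogue of the original negative
control.

## Variance-window sharing

`gene_variance_ranking()` computes per-gene sample variance (denominator
n − 1) within one tissue and one species and sorts descending, ties broken
by gene id. `window_shared_fraction()` cuts both species' rankings into
consecutive non-overlapping windows (600 genes at compendium scale;
remainder genes are dropped from windowed summaries but kept for
top-fraction lists) and reports, per window, the fraction of genes whose
ortholog falls in the same-index window of the other species — in both
directions, which coincide for a one-to-one pairing over a common
universe (asserted at run time). `randomized_baseline()` replaces both
rankings with uniform permutations; its expectation is exactly
window/n (600/6180 ≈ 9.7%, the "about 10%" negative control).
`top_conserved_list()` takes the orthologs in both species' top
⌈f·n⌉ (f = 10% by default; "600 genes" and "top 10%" are both exposed
because 600 of 6,180 is 9.7%).

`hypergeom_overlap_test()` computes the exact upper tail P(X ≥ k) for an
overlap of k between lists of K and n genes from a universe of N, via the
log-space stable tail of `phyper`. The "at least k" tail is the right
formalization of the chance of seeing k or more shared genes; the tests pin the
implementation against exhaustive enumeration of all draws for small
universes and against a reference three-tissue comparison
(N = 1,344: nervous system P = 2.9×10⁻⁶, heart/muscle 1.8×10⁻⁸,
liver 2.3×10⁻⁷).

## The synthetic-data generator

The generator emulates the structure of a two-species compendium so every
downstream stage can be tested against known ground truth:

* **Baseline** intensities 8 + N(0, σ) on the log2 scale, with a
  conserved per-gene residual sd σ_g = `noise_sd` × exp(N(0, 0.25)) —
  orthologs inherit the same σ_g, because per-gene expression variability
  is itself conserved, and without that conservation cross-species
  variance rankings would share nothing by construction.
* **Tissue-specific genes** (`n_specific_per_tissue` per tissue, disjoint
  across tissues) are up-shifted by `effect_size` (default 2 log2 units)
  in their tissue in both species, and modulated per sample with a
  conserved per-gene amplitude `effect_size` × U(0.75, 1.75). The
  modulation reflects that a tissue category in a compendium pools labs,
  conditions and sample states that strongly modulate signature genes; it
  is what makes these genes the most variable genes within their own
  tissue, in both species.
* **Housekeeping genes** have residual sd `noise_sd`/2 everywhere
  (variance at most a quarter of background) and no tissue term.
* **Batch effects**: samples of each tissue/species split into
  experiments; each (experiment, 50-gene block) receives an additive
  N(0, `batch_sd`) offset — a coarse model of lab effects.
* **Species/platform offset**: each species-B probeset gets a constant
  additive N(0, `species_shift_sd`) shift. The default of 2 log2 units
  makes the platform effect dominate raw data, as probe-affinity
  differences do on real arrays; row-wise normalization removes it
  exactly, which is the point of the by-probeset mode.
* **Probes**: 11 probes of 25 nt per probeset; species-B probes are
  species-A probes with i.i.d. substitutions at rate `probe_divergence`
  (default 15%, roughly the exonic divergence of the two genomes). A
  configurable fraction of genes carries a second, more strongly diverged
  decoy probeset pair, so pairing has real choices to make; the intended
  pair is defined as the minimum-divergence combination *recomputed from
  the emitted sequences*, not assumed from the construction. Indels are
  excluded by default to keep the pairing oracle exact.

All generator randomness flows from a single recorded seed per call, and
identical (design, seed) inputs reproduce byte-identical artifacts.

What the generator does **not** emulate: probe-level (CEL) intensities and
RMA itself (the generator produces RMA-like output directly), correlated
gene networks beyond tissue signatures, non-Gaussian heavy tails, platform
differences beyond an additive probeset offset, and annotation errors.
Passing tests therefore establish that the implementation recovers planted
structure under a faithful but idealized noise model — not that the
biological conclusions transfer to any particular real dataset.

## Problem sizes and numerical tolerances

The test suite runs the full chain on miniatures: typically 100 ortholog
pairs, 3 tissues, 15 samples per tissue per species. Fifteen samples per
tissue is deliberate — the real compendia have on the order of a hundred
samples per tissue category, and within-tissue variance rankings need a
two-digit sample count before they stabilize; miniatures with 5–6 samples
per tissue are qualitatively outside the regime the method operates in.
Pairing recovery is tested at 5% probe divergence over five seeds
(≥ 95% recovery required), alignment scores against an exhaustive
dynamic-programming oracle on 1,000 random probe pairs, normalization
medians to 1e−12, PCA against an eigensolve to 1e−8, corCor against a
nested-loop oracle to 1e−10, and the hypergeometric tail against
exhaustive enumeration to 1e−12. The randomized window baseline uses the
full 6,180/600 geometry (100 replicates, < 1 s) since it needs no
expression data.

## Known limitations

* The aligner scores nucleotide probes only ({A, C, G, T, N}); `N`
  mismatches everything, and there is no reverse-complement search.
* Greedy one-to-one matching can differ from the optimal assignment on
  adversarial score matrices; for real probe sets the two rarely disagree,
  and the greedy order is the documented, deterministic behaviour.
* The tissue-balance filter defaults to an explicit drop-list; the
  ratio-based rule is a convenience, not a reconstruction of any
  particular study's curation.
* corCor at single-tissue scale is weak by construction (platform and lab
  effects dominate homogeneous samples); the variance-window analysis is
  the tool intended for tissue-level questions.
* The hypergeometric test assumes exchangeable draws from a fixed
  universe; dependence between gene lists (e.g. shared ascertainment)
  makes its P-values optimistic.
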