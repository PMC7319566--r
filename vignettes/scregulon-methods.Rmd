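---
title: "Inferring cell-type-specific regulons: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-type-specific regulons: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scregulon)
```

`scregulon` infers cell-type-specific regulons (CTSRs) from a gene-by-cell
expression matrix, a genome with gene annotation, and a library of known
transcription-factor (TF) motifs. This vignette explains the statistical
model behind each stage, the parameters that matter, the design choices
that were genuinely open, and what the synthetic tests do and do not
establish about real data.

## The model, stage by stage

### Pre-processing

Genes with zero values in more than 99.9% of cells carry no usable signal
and are removed (`gene_min_cell_fraction = 0.001`; the boundary case — a
gene non-zero in exactly 0.1% of cells — is kept). Cells expressing fewer
than 200 genes (`cell_min_genes = 200`) are treated as empty droplets or
debris and removed. The gene filter runs first and is not recomputed after
cell removal: a second pass would change results only marginally while
making the filter's output harder to reason about.

Raw counts are recognized by their values: if every non-zero entry is an
integer (tolerance 1e-9 on the fractional part, so counts stored as
floating point still count as integers), the matrix is treated as
unnormalized. Unnormalized cells are scaled by median-library size factors
`s_c = lib_c / median(lib)`. Size-factor estimation by pooled
deconvolution is a well-established alternative; we use the simpler
median-library factors deliberately, because every downstream score in
this package is computed from *within-cell expression ranks*, which are
invariant to any per-cell scale factor — the choice of size-factor method
cannot change a RAS, an RSS, or a CTSR call. Finally `log(x + 1)` (natural
log) is applied. An imputation hook exists (`preprocess(impute_fn = )`)
but defaults to the identity; imputation is out of scope.

### Qualitative biclustering

Co-expressed gene modules are found by QUBIC-style qualitative
biclustering. Each gene's values are reduced to \{−1, 0, +1\}: the top
`⌈q·n⌉` cells (default `q = 0.06`) become +1, the bottom `⌈q·n⌉` −1,
everything else 0. Three guard rules keep the discretization meaningful on
sparse single-cell data: a raw zero never becomes +1, a constant gene
stays all-zero, and ties are broken by ascending cell index so the result
is deterministic.

Seeding and expansion follow the classic two-step recipe. For each level,
every gene pair is weighted by the number of cells in which both genes
carry that level; pairs with weight < 2 are dropped and the rest processed
in decreasing weight order (ties lexicographic by gene id). A seed's
initial cell set is the pair's agreement set; genes are then added
greedily — a candidate gene trims the cell set to the cells where it also
carries the level, and the addition is accepted only while at least
`max(2, c · |initial cells|)` cells survive (`consistency c = 0.95`).
Every retained (gene, cell) entry therefore carries the block's level,
which is re-checked as an invariant in the tests. A new block is kept only
if its gene-set Jaccard overlap with every kept block is below
`f = 0.75`, up to `max_biclusters = 500` blocks (100 in fast mode).

Two design points deserve emphasis:

* **Per-level seeding, up-regulated by default.** Pair weights are
  computed per level rather than pooled across +1 and −1. With the
  deterministic tie rule, the −1 side of a sparse matrix is dominated by
  shared zero-valued cells: nearly all genes receive their −1 marks on the
  same low-index zero cells, which would flood a pooled seed ranking with
  biologically empty "co-silence" blocks. Regulons are sought among
  actively expressed genes, so `run_biclustering()` seeds on +1 only by
  default; −1 blocks are available through the `levels` field of
  `bicluster_params()`.
* **Count-consistency expansion.** The expansion rule is fully specified
  and deterministic, and on noise-free planted blocks at `c = 1` it
  provably returns the maximal all-level block containing the seed (the
  test suite verifies this against exhaustive enumeration on matrices up
  to 12 × 12). A mixture-model discretizer and divergence-based expansion
  are known alternatives; they introduce estimation steps whose behavior
  on small planted fixtures cannot be verified exactly, which is why the
  quantile/count variant was chosen.

### Active-module assignment

A bicluster is "active" in a cell type when its cell set is improbably
concentrated there: with `k` of the bicluster's `n` cells inside a type of
size `K` among `N` cells, the raw p-value is the hypergeometric upper tail
`P(X ≥ k)`. P-values are Bonferroni-adjusted by the *global* multiplier
`N_celltype × N_bicluster`, with `N_bicluster` the total number of
biclusters tested (before any filtering); significant pairs
(`adjusted p < 0.05`) become gene modules. A bicluster significant in
several types yields one module per type — collapsing to a single type
would discard exactly the cross-type structure the test detected; the most
significant type is flagged (`is_best`). The global multiplier makes the
test deliberately conservative: only blocks whose cell sets are both
sizable and nearly pure reach significance, which is what makes the
negative control (no planted signal) come out empty.

### Promoters and motif scanning

Promoters are the `L = 1000` bp immediately upstream of the TSS, strand
oriented: `[tss − L, tss − 1]` on the plus strand, the reverse complement
of `[tss + 1, tss + L]` on the minus strand (1-based closed internally;
BED export converts to 0-based half-open). Promoters are clipped at
chromosome ends; genes whose chromosome is absent or whose upstream region
is empty are skipped with a warning; `N` bases are kept and any scan
window containing one is skipped.

Scanning uses additive log-odds scores
`score(i, b) = log2((p_ib + 1e-4 · bg_b) / ((1 + 1e-4) · bg_b))` in bits,
integer-scaled at 1/1000 bit. The integer scaling allows the *exact* null
score distribution to be computed by convolving the per-position score
distributions under the background (uniform by default) — the same device
used by exact PWM-scanning tools — so the per-window threshold at
`scan_alpha = 1e-4` is an exact tail quantile, not an approximation. Both
strands are scanned; minus-strand hits are reported at forward
coordinates. Per cell type and TF, module genes with at least one hit form
the candidate regulon; motifs sharing a TF name are merged by gene union,
and regulons below `min_genes = 5` are dropped to avoid degenerate
near-singleton regulons.

This stage replaces de novo motif discovery plus motif-database matching
with direct scanning of a user-supplied known-PWM library: the contract —
module genes sharing a TF's motif form a regulon — is preserved, while the
two external discovery/matching steps and their databases are not needed.
The discovery route's significance filter maps onto the scan p-value
threshold.

### Regulon scoring

Within each cell, genes are ranked by expression descending (rank 1 =
highest; ties by gene index). The regulon activity score of gene set `S`
in a cell is the normalized recovery-curve AUC over the top
`K = ⌈0.05 · n_genes⌉` ranks:

$$\mathrm{RAS} = \frac{\sum_{k=1}^{K} |\{g \in S : r_g \le k\}|}{\sum_{k=1}^{K} \min(k, |S|)} \in [0, 1].$$

Being rank-based, RAS is invariant to any per-cell monotone transform of
expression. The `top_fraction = 0.05` window is exposed as a parameter;
5% of the ranking is the conventional recovery window for activity
scoring of gene sets in single cells.

Specificity compares the activity distribution with the cell-type
indicator: with `p` the RAS vector normalized to sum 1 over cells and `q`
the normalized indicator of the type,

$$\mathrm{RSS} = 1 - \sqrt{\mathrm{JSD}(p, q)}, \qquad
\mathrm{JSD}(p,q) = H\!\left(\tfrac{p+q}{2}\right) - \tfrac{H(p)+H(q)}{2}$$

with entropies in base-2 logs so JSD ∈ [0, 1] and RSS ∈ [0, 1] exactly;
RSS = 1 iff the normalized activity equals the indicator, RSS = 0 iff the
supports are disjoint. An all-zero RAS is defined as RSS 0 with a warning.

Significance comes from a gene-set null: `n_boot = 10000` random gene
sets of the regulon's size are drawn uniformly *without replacement* from
all matrix genes (a gene set with repeated members is not meaningful, so
"bootstrap" here means resampled null sets, not resampling with
replacement), each scored against the same cell type, and

$$p = \frac{1 + \#\{\mathrm{RSS}_{null} \ge \mathrm{RSS}_{obs}\}}{1 + n_{boot}}.$$

The `+1/(n+1)` estimator never returns 0 and is the standard choice for
empirical p-values. P-values are Bonferroni-adjusted by the number of
regulons in the same cell type; regulons with adjusted p below `alpha`
(0.001, 0.01 or 0.05) are CTSRs. Names are `CTn-Rm`: `n` numbers cell
types in label order, `m` ranks regulons within a type by ascending
empirical p (ties: descending RSS, then TF name).

The null draws are vectorized (a sparse indicator matrix times the
precomputed recovery-weight matrix); the tests verify the vectorized path
is numerically identical to scoring each draw individually.

### Evaluation utilities

One-vs-rest Wilcoxon rank-sum marker detection reports, per cell type and
gene, the two-sided p (exact distribution for tie-free groups under 50,
otherwise the normal approximation with tie and continuity correction —
matching the behavior of `stats::wilcox.test`), the log2 fold change of
`expm1` means with a +1 pseudocount, and BH-adjusted p within each cell
type (the per-cluster convention for marker genes). `deg_coverage()`
reports the fraction of a regulon's genes that are markers of its cell
type. Clustering agreement offers the Rand, adjusted Rand, Jaccard and
Fowlkes–Mallows indexes from pair counts; user labels always take
precedence over the PCA + k-means fallback clusterer.

## The synthetic study configuration

`generate_dataset()` defines the study conditions under which the package
is validated: 2000 genes × 600 cells in 3 equal cell types; baseline
counts negative binomial with mean 2 and dispersion 0.5 (variance
`μ + 0.5 μ²`, a typical droplet-data regime); 3 planted regulons of 30
disjoint target genes, assigned round-robin to cell types, with target
means multiplied by fold change 4 in their type before sampling; dropout
as independent zeroing with probability 0.3; 1000 bp uniform-ACGT
promoters with each TF's 12-bp consensus planted at a uniform random
offset in every target promoter; PWMs with probability 0.85 on the
consensus base. Every gene sits on its own chromosome so annotation
parsing, promoter extraction and strand logic are exercised end to end.
All draws flow from a single integer seed; two calls with the same seed
are byte-identical.

Under these conditions the full pipeline recovers all three planted
regulons as CTSRs of their planted types with gene Jaccard above 0.8, and
the fold-change-1 negative control yields zero CTSRs at the 0.001
threshold. The generator emulates overdispersed counts, dropout, and
motif-bearing promoters; it does **not** emulate batch effects, doublets,
UMI saturation, correlated background gene programs, non-uniform promoter
composition, or shared targets between TFs. Passing these tests therefore
demonstrates the correctness and calibration of the machinery, not
performance on any particular real tissue.

Test and acceptance problem sizes (600 cells; 500–1000 bootstrap draws in
calibration checks; 10 negative-control seeds) were chosen so the whole
suite runs on a laptop-class single core in minutes while keeping every
statistical check at a scale where its nominal level is meaningful.

## Numerical and degenerate-input choices

* Hypergeometric tails come from the stable distribution function, checked
  to 1e-12 against direct pmf summation.
* PWM rows within 1e-3 of summing to 1 are renormalized (motif databases
  round their matrices); larger deviations are errors.
* The integer score scaling (1/1000 bit) bounds the scan-score error at
  half a unit per position; the exact-distribution threshold uses the same
  integer grid, so threshold comparisons are exact.
* JSD is clamped to [0, 1] before the square root to absorb floating-point
  drift at the boundaries.
* Duplicate gene ids keep the row with the largest total (deterministic
  and close to common practice); duplicate cell labels with conflicting
  types are an error, exact duplicates are collapsed.
* A label file's first row is treated as a header iff its second field is
  not reused as a label by more than one other row.
* Empty filter results, zero-library cells, empty regulons and inconsistent
  hypergeometric arguments raise typed errors (`scregulon_*_error`).
* Every stochastic step (k-means, bootstrap draws, the generator) takes an
  explicit seed and restores the caller's RNG state.

## Known limitations

* The biclustering variant is a deterministic stand-in for
  mixture-model-based qualitative biclustering; on data where
  down-regulation is the discriminating signal, the default up-only
  seeding must be widened via `bicluster_params(levels = c(1L, -1L))`.
* The conservative global Bonferroni multiplier means small datasets (a
  few hundred cells) rarely yield significant modules; the scale of the
  study configuration is roughly the practical minimum.
* Known-PWM scanning cannot discover novel motifs; regulons are limited to
  TFs present in the supplied library.
* User-supplied gene-module lists bypass biclustering and are considered
  candidates for *every* cell type (their cell support is unknown), so
  their specificity is established only at the scoring stage.
* RAS/RSS formulas satisfy the standard constraints (rank-based activity;
  entropy-based specificity in [0, 1]) but other normalizations exist;
  `top_fraction` is the knob that matters and is exposed.
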