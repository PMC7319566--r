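# scregulon

Cell-type-specific regulon inference from single-cell RNA-seq in R.

A **regulon** is a maximal group of genes co-regulated by the same
transcription factor (TF), sharing that TF's cis-regulatory motif in their
promoters. A **cell-type-specific regulon (CTSR)** is a regulon whose
activity is significantly concentrated in one cell type, so it can be used
to characterize the regulatory program that distinguishes that type from
the rest of a heterogeneous tissue. `scregulon` infers CTSRs from a
gene-by-cell expression matrix together with a genome, a gene annotation
and a library of known TF motifs.

## Method

The pipeline runs seven stages:

1. **Pre-processing** — genes with zero values in more than 99.9% of cells
   and cells expressing fewer than 200 genes are removed; raw counts are
   detected by their integer values and scaled by median-library size
   factors `s_c = lib_c / median(lib)`; all values get `log(x + 1)`.
2. **Cell labels** — user-supplied labels are used when available; a
   PCA + k-means fallback clusterer (top 10 components over the top 2000
   variable genes) is provided as plumbing.
3. **Gene-module detection** — qualitative (QUBIC-style) biclustering:
   per gene, the top/bottom `⌈q·n⌉` cells (q = 0.06) are discretized to
   ±1; gene pairs are ranked by the number of cells sharing the same
   non-zero level and greedily expanded into blocks under a consistency
   constraint c = 0.95, with a Jaccard overlap filter f = 0.75 and a cap
   of 500 blocks (100 in `--fast` mode).
4. **Active-module assignment** — each bicluster's cell set is tested for
   enrichment in each cell type with the hypergeometric upper tail
   `P(X ≥ k)`, Bonferroni-adjusted by `N_celltype × N_bicluster`; pairs
   with adjusted p < 0.05 become active gene modules.
5. **Promoter extraction** — the 1000 bp strand-oriented region upstream
   of each module gene's TSS.
6. **Regulon assembly** — promoters are scanned on both strands with
   log-odds PWMs; per-window significance uses the *exact* null score
   distribution (dynamic program over all 4^w words); per cell type, the
   nonredundant union of module genes carrying a TF's motif forms that
   TF's candidate regulon (minimum 5 genes).
7. **CTSR inference** — the regulon activity score (RAS) of a regulon in
   a cell is the normalized recovery-curve AUC of its genes over the top
   5% of the cell's expression ranking (rank 1 = highest). The regulon
   specificity score is

   `RSS = 1 − sqrt(JSD(p, q))`

   where `p` is the RAS vector normalized over cells, `q` the normalized
   cell-type indicator, and JSD the Jensen–Shannon divergence in base-2
   logs, so RSS ∈ [0, 1] with 1 meaning activity exactly matching the
   cell type. Each RSS gets an empirical p-value against 10 000 random
   gene sets of the same size, `p = (1 + #{RSS_null ≥ RSS_obs}) / (1 + n)`,
   Bonferroni-adjusted by the number of regulons in that cell type.
   Regulons with adjusted p below the chosen threshold (0.001 / 0.01 /
   0.05) are CTSRs, named `CTn-Rm` with `m` ranked by ascending empirical
   p-value.

A synthetic-data generator with planted cell types, modules, regulons and
promoter motifs (negative binomial counts with dropout) makes every stage
testable end to end; `evaluate_recovery()` scores predictions against the
planted truth. Wilcoxon one-vs-rest marker detection and four
clustering-agreement indexes (Rand, adjusted Rand, Jaccard,
Fowlkes–Mallows) are included for evaluation.

## Worked example

Generate a synthetic dataset (2000 genes × 600 cells, three equal cell
types, three planted 30-gene regulons at fold change 4 with 30% dropout)
and run the full pipeline:

```r
library(scregulon)

ds <- generate_dataset(seed = 1)   # defaults = the configuration above
write_synthetic_dataset(ds, "demo")

cfg <- pipeline_config(
  expression = "demo/matrix.csv", genome = "demo/genome.fa",
  annotation = "demo/genes.gtf",  motifs = "demo/motifs.meme",
  labels = "demo/labels.tsv",     out_dir = "demo/out", seed = 1)
res <- run_pipeline(cfg)
```

The run logs per-stage counts and writes `regulons.tsv`,
`regulon_genes.tsv`, `results.json` and `manifest.json`:

```
input: 2000 genes x 600 cells
preprocess: retained 2000 genes x 600 cells
labels (user): 3 cell types over 600 cells
biclustering: 500 bicluster(s)
modules (biclustering): 70 active module(s)
regulons: 3 candidate regulon(s)
scoring: 3 regulon(s), 3 CTSR(s)
```

```
name    cell_type  tf   n_genes  rss    p_empirical  p_adjusted  is_ctsr
CT3-R1  CT3        TF3  24       0.740  9.999e-05    9.999e-05   true
CT2-R1  CT2        TF2  27       0.740  9.999e-05    9.999e-05   true
CT1-R1  CT1        TF1  25       0.742  9.999e-05    9.999e-05   true
```

All three planted regulons are recovered as CTSRs of their planted cell
types: each keeps 24–27 of its 30 planted targets (gene Jaccard ≥ 0.8),
the RSS around 0.74 reflects the concentration of their activity in one of
the three types, and the empirical p-value sits at its floor `1/10001`
(nothing among 10 000 random gene sets matched the observed specificity).

A thin command-line wrapper with `run`, `synth` and `score` subcommands is
installed at `inst/cli/scregulon`.

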