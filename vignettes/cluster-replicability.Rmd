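---
title: "Assessing cell-cluster replicability across paired brain atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cell-cluster replicability across paired brain atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasrep)
```

## The problem

Whole-brain transcriptomic atlases built from single-cell and single-nucleus
RNA sequencing each partition millions of cells into thousands of clusters.
Before a cluster is treated as a biological cell type, it should replicate:
an independent atlas, built with a different protocol, should contain a
cluster that is recognizably the same population. Two protocols differ in
systematic ways — nuclei lose cytoplasmic transcripts, so a subset of genes
is depleted in single-nucleus data, and sequencing depth per cell differs —
so replicability assessment must be robust to global, protocol-driven shifts
while staying sensitive to genuine between-cluster differences.

`atlasrep` implements a complete cross-atlas replicability analysis:

1. **Marker evaluation** — how well author-provided marker genes identify
   their cluster, globally and against the most confusable cluster.
2. **Neighbor voting** — transcriptome-wide cluster matching on a
   Spearman-correlation cell network, with reciprocal best-hit detection,
   best-vs-next discrimination, and portable pretrained models.
3. **Spatial validation** — centroid-correlation cell calling on a
   reduced-gene-panel spatial dataset, concordance of calls from the two
   references, and spatial proximity of matched cluster centroids.
4. **Coordinated expression** — per-gene agreement of expression profiles
   across the matched cluster centroids, with a specificity percentile.
5. **Synthetic atlases** — a seeded generator that plants ground-truth
   correspondences so every stage can be validated end-to-end.

## Neighbor voting on a Spearman network

Each cell is represented by the mid-ranks of its expression over a set of
highly variable genes (HVGs), computed *within* the cell, then mean-centered
and scaled to unit norm (`rank_normalize()`). With this representation the
inner product of two cells equals the Spearman correlation of their HVG
expression exactly, so cluster-level voting reduces to matrix products:

* The **vote** of reference cluster $c$ for target cell $j$ is the mean
  Spearman correlation between $j$ and the cells of $c$ — computed as the
  inner product of $j$'s vector with the cluster's mean vector. This is the
  fast formulation; it is a mathematical identity, not an approximation, and
  the test suite verifies it against the explicit cell-by-cell correlation
  matrix to $10^{-8}$.
* The **one-vs-all AUROC** for reference cluster $c$ and target cluster $d$
  asks how well the votes of $c$ rank the cells of $d$ above all other cells
  of the target dataset. Because ranks are computed within cells, the score
  is invariant to any monotone per-cell transform of expression, which is
  what buys robustness to protocol shifts.
* The **symmetric AUROC** averages the two directions,
  $(AB_{cd} + BA_{dc})/2$, and **reciprocal top hits** are pairs that are
  mutually each other's best symmetric score. Argmax ties are broken by the
  smallest cluster label and logged.
* The **best-vs-next AUROC** restricts the votes of a reference cluster to
  the two most similar target clusters. Values near 1 mean the local
  distinction is real; values near 0.5 mean the two clusters cannot be told
  apart from this reference's viewpoint. A Wilcoxon rank-sum test on the two
  vote samples gives significance, Bonferroni-corrected across the reference
  clusters of an atlas.

**Pretrained models** (`build_pretrained()`) store only the per-cluster mean
rank vectors over a named gene list. Applying one to a new dataset restricts
both sides to the shared genes, re-centers and re-normalizes, and scores
target clusters by one-vs-all AUROC. At full gene overlap this reproduces
the training AUROC table exactly (re-normalization rescales each model
cluster's votes positively, leaving within-row rankings unchanged).

## Marker evaluation

Marker sets are scored by the mean z-scored log-CPM expression of their
genes (`marker_score_cells()`), giving one score per cell; the one-vs-all
AUROC of those scores for every cluster yields a marker-set by cluster
matrix whose diagonal holds on-target scores. The **local** (best-vs-next)
marker AUROC recomputes the score restricted to the target cluster and its
best off-target cluster. Sibling clusters that share markers land at 0.5:
globally excellent markers can be locally uninformative, which is the
central cautionary observation this analysis quantifies.

Cross-atlas marker overlap uses an upper-tail hypergeometric test over the
shared gene universe (configurable; defaults to the shared gene count), with
either an all-pairs Bonferroni correction or the relaxed per-atlas
correction. Marker-based cluster pairing assigns each marker set to its
best-scoring cluster in the other atlas, keeping only the strongest set per
target cluster. Unlike reciprocal voting, marker pairing has no mutuality
filter — every set is paired with something — which is one reason its
pairings agree less well with planted truth and with dissection regions.

## Spatial validation

`call_cells()` implements centroid-correlation calling: for each spatial
cell and each of 100 rounds, a random 80% of the genes shared with the
reference centroids is drawn, and the cell is assigned to the most
Pearson-correlated log-CPM centroid. The final call is the modal winner
(ties: higher mean winning correlation, then smaller label); cells whose
mean winning correlation falls below 0.5 are flagged as not confidently
called. The 0.5 pass threshold follows the convention that cells *below*
0.5 cannot be confidently assigned.

Downstream statistics: per-cell concordance (both references' calls land on
one reciprocal pair), per-slice concordance proportions and detected-cluster
counts, a subsampling-based diversity mismatch between references, log2
regional enrichment of concordant cells, Euclidean distances between matched
cluster centroids (slices contribute a third coordinate via a configurable
0.2 mm spacing), and modal dissection-region agreement of matched clusters.

## Coordinated expression

For the matched pairs, each gene has two profiles: its centroid expression
across the pair columns in atlas A and in atlas B. The per-gene Spearman
correlation of these profiles measures coordinated expression. Genes used to
find the pairs (the HVGs) are excluded so the signal is not circular. The
**specificity percentile** compares the same-gene correlation against all
cross-gene correlations involving that gene in either direction, with ties
counted half; `is_top` flags genes that beat every competitor strictly. The
full cross-gene matrix is computed with one rank-standardized matrix
product, verified against looped Spearman calls to $10^{-10}$. Pair-column
subsampling curves and gene-set (GMT) summaries with rank-sum tests and BH
correction complete the module.

## The synthetic-atlas generator

The generator plants a known truth so that the pipeline's operating
characteristics can be measured. Its defaults are the package's study
conditions and are deliberately fixed:

| parameter | default | rationale |
|---|---|---|
| shared types / cells per type / genes | 40 / 60 / 1500 | large enough for stable AUROCs, small enough for fast tests |
| mean depth A / B | 8000 / 4000 | single-nucleus libraries are roughly half as deep |
| NB dispersion | 0.3 | typical droplet-data overdispersion |
| between-type log-effect SD | 1.0 | brain cell types are globally well separated |
| retention | 30% of genes, U(0.1, 0.7) | cytoplasmic transcript loss hits a subset of genes, up to ~10x |
| markers per cluster | 4 | the atlases' median marker-list length |
| regions / slices / spatial SD | 5 / 8 / 0.3 mm | coarse dissection scheme; compact spatial types |

Counts are negative binomial: gene-and-type log-normal program means times a
log-normal library size, with per-gene retention factors multiplying atlas
B's means (so a retention factor of 0.5 halves a gene's expected count at
equal library size — an invariant the tests verify by Monte Carlo). Split
types appear as one cluster in A and two perturbed subclusters in B
(log-normal perturbation, SD 0.3). Planted-unique types are drawn with twice
the between-type spread: a type labelled unique must be unambiguously
distinct, otherwise the truth table itself would be wrong. Marker catalogs
are planted per atlas as the top fold-change genes against all non-sibling
clusters; the children of a split type inherit the parent's (type-level)
markers, so siblings share markers — recreating the regime in which markers
identify a cluster globally but cannot separate close neighbors. Types are
assigned to slices so that later slices accumulate more, and less
replicable, types, planting the anticorrelation between slice-level cluster
diversity and call concordance. A single master seed fans out to named
substreams (`substream_seed()`), so every stage is independently
reproducible.

**What the generator does not emulate:** real atlases' scale (millions of
cells), hierarchical taxonomy depth, heavy-tailed cluster sizes, doublets,
ambient RNA, batch structure within an atlas, or correlated gene programs
within cell families. Passing tests therefore demonstrate the pipeline's
correctness and calibration under a faithful but idealized noise model, not
performance claims about any real atlas pair.

## Numerical choices and edge cases

* Log base for log-CPM is natural log and configurable; every downstream
  statistic (ranks, Spearman, Pearson) is invariant to it (asserted on a
  fixture).
* Z-scores use sample SD (ddof 1); zero-variance genes map to zero rows so
  marker averages stay finite.
* Zeros within a cell tie at the shared minimum mid-rank; cells constant
  across the HVGs get zero vectors, are flagged, and are excluded from
  AUROC computation.
* Clusters need at least 2 cells to participate in an AUROC (one positive
  and one negative must exist); no larger floor is imposed since real
  atlases align clusters with as few as 9 cells.
* All argmax ties (best hit, best off-target, modal call winner) break by
  smallest label, deterministically.
* Exact rank-sum enumeration below 20 combined observations; tie-corrected
  normal approximation with continuity correction above. Two-sided Fisher
  sums tables with point probability at most the observed (the dominant
  convention); the odds ratio reported is the sample `ad/bc`.
* Empirical permutation p-values use the +1 correction, so p = 0 is
  impossible.
* The HVG procedure (mean-binned variance quantile, 10 bins, 0.75 quantile,
  intersected across datasets) is a parameterized choice recorded in the
  output provenance; other reasonable selectors would serve, and the rest of
  the pipeline only assumes a shared, duplicate-free gene list.

## Design choices where the design was open

* **Reciprocity** is defined on the symmetric AUROC matrix, with an optional
  stricter mode requiring directional agreement (`top_hits(directional=)`).
* **Enrichment of reciprocal clusters** in an independent dataset's best
  matches is tested against availability: the 2x2 table crosses best-match
  counts (on reciprocal vs other model clusters) with the model's own
  composition, via Fisher's exact test.
* **Best-vs-next significance** is Bonferroni-corrected across the reference
  clusters of one atlas.
* **Pair markers** (`select_pair_markers()`) contrast each side of a pair
  against that atlas's next-nearest cluster from the symmetric AUROC
  profile, scoring genes by the weaker of the two per-atlas AUROCs.
* **Configuration** is YAML; the pipeline writes TSV tables with provenance
  headers plus a JSON manifest with per-stage content hashes, enabling
  `resume` runs that recompute only stages downstream of a change.
* High-confidence pair selection uses symmetric AUROC >= 0.95 where a
  quality cut is needed (e.g. comparing region agreement of voting-derived
  and marker-derived pairings); accidental reciprocal pairs among leftover
  clusters sit well below this.

## Problem sizes used in validation

The test suite and the acceptance script run the full analysis on the
default 40-type pair (2400 cells per atlas), a 20-type split fixture, a
250-gene spatial panel (20 cells per cluster) with 100 calling rounds, and a
109-gene panel for pretrained-model transfer. These sizes give stable
statistics (binomial/rank SEs well inside the asserted margins) while
keeping a complete run in tens of seconds.

## Worked example

```{r example, eval = FALSE}
library(atlasrep)

sim <- simulate_pair(generator_config())
nv_a <- normalize_log_cpm(sim$a)
nv_b <- normalize_log_cpm(sim$b)
hvg <- select_hvgs(list(nv_a, nv_b))

ab  <- one_vs_all_auroc(nv_a, nv_b, hvg)
ba  <- one_vs_all_auroc(nv_b, nv_a, hvg)
sym <- symmetric_auroc(ab, ba)
pairs <- top_hits(sym)
head(pairs)
autoplot(sym)
```

Or run every stage with one call and inspect the TSV/JSON artifacts:

```{r pipeline, eval = FALSE}
cfg <- pipeline_config("my_run", seed = 1)
run_pipeline(cfg)
```

## Known limitations

* Marker catalogs must name clusters with the dataset's labels; no fuzzy
  matching is attempted.
* The pipeline's `enrich` stage uses region labels as the class annotation
  for the synthetic study; real analyses should supply a taxonomy-derived
  cluster-to-class table to `class_enrichment()` directly.
* `apply_pretrained()` assumes the target dataset already uses the model's
  gene namespace (orthologs must be mapped beforehand).
* Spatial calling assumes the panel shares at least 10 informative genes
  with the reference centroids; very small panels degrade gracefully but
  are not specially handled.
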