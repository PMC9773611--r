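---
title: "gastroTME: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gastroTME: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind each stage:
what is modelled, which parameters matter, which choices were genuinely open
and how they were resolved, and what the validation on synthetic cohorts does
and does not establish about real data.

## The analysis problem

Multi-patient tumor/normal single-cell RNA-seq cohorts of the gastric tumor
microenvironment (TME) pose a chain of inference problems: removing
low-quality cells and dissociation-induced expression artifacts, resolving
cell populations at two levels of granularity across library chemistries,
inferring which populations communicate through ligand–receptor signalling
and which act as network hubs, attributing bulk-RNA-seq differential genes to
the cell populations that express them, and quantifying how population
abundances and marker signatures relate to malignancy and therapy response.
`gastroTME` implements this chain as composable functions over
`SingleCellExperiment` objects, with a ground-truthed synthetic cohort
generator so every stage can be validated end to end.

## Quality control and normalization

Cells are filtered on detected genes, total UMI and mitochondrial fraction.
The defaults — 200–7500 genes, 500–75,000 UMI, mitochondrial fraction
strictly below 10% — are the standard droplet QC window for this tissue
type; gene and UMI bounds are inclusive, the mitochondrial bound is strict,
and `filterCells` is idempotent.

Normalization is `log1p` of depth-scaled counts with target sum equal to the
median cell depth. This is deliberately minimal: every downstream consumer
(variance ranking, rank-based tests, affinity products) requires only a
depth-invariant monotone transform, so a regularized variance-stabilizing
model would add machinery without changing any decision the pipeline makes.
The method name and target sum are recorded in the object's provenance, as is
the id of any subtracted artifact component, so an affinity matrix can always
state which expression values it consumed (post-artifact-removal values by
default).

## Dissociation-artifact removal by ICA

Enzymatic dissociation induces a stress (heat-shock-like) transcriptional
program in a sample-dependent way. The package models such artifacts as
statistically independent gene programs: fixed-point fast ICA (logcosh
contrast, PCA whitening, symmetric decorrelation, via `ica::icafast`)
decomposes the gene-centered normalized matrix into components with
unit-variance cell scores; each component is re-signed so its
largest-magnitude gene loading is positive, making the decomposition
deterministic.

Sample specificity of a component is scored as the variance across samples of
the per-sample mean cell score divided by the pooled within-sample variance —
an F-like ratio that is near zero for biological programs spread over all
samples and large for programs confined to a few samples. Components are
ordered by this score, and the artifact is selected automatically as the top
component exceeding `median + 5 × MAD` of all scores, replacing visual
inspection with an explicit rule (the score and rule are a stand-in: no
quantitative definition of "highly sample-specific" exists upstream, and the
provenance records the automated selection). Removal subtracts the rank-1
term `loadings ⊗ scores`; all other components' projections are untouched,
and removal commutes with cell subsetting.

The component count is configurable with a paper-scale default of 128. For
the 600-gene desk-scale synthetic cohort the analyses here use 20 components,
roughly 2–3× the generative rank (8 cell types + 1 artifact program): on
matrices this small a much larger component count leaves symmetric fast ICA
optimizing in noise-dominated directions, where it can fragment the artifact
program across components.

## Stepwise two-round clustering

Round one: the top 1000 variance-ranked genes (ties broken by gene
identifier), PCA on the gene-centered matrix (deterministic sign convention),
a batch-balanced kNN graph, and Leiden community detection
(modularity objective). The balanced graph connects every cell to its
`k_within` nearest neighbors *within each* library-chemistry batch
(default `k_within = 3`, Euclidean distance in PC space), so neither
chemistry dominates the neighborhood structure. Graph clustering at
modularity resolution 1.0 deliberately over-partitions; the over-split
clusters are then merged by a user-supplied canonical-marker mapping
(`mergeClustersByMarkers`): each cluster takes the label whose marker set has
the highest mean z-scored expression, and clusters sharing a label merge.
This encodes the curation step — merging transcriptional clusters into named
populations — as configuration rather than code. Round two repeats the
pipeline inside each major population (600 variable genes, 25 PCs by
default), with minor labels namespaced by the major label.

Per-cluster markers come from one-vs-rest Wilcoxon rank-sum tests
(tie-corrected normal approximation on shared midranks), BH- and
Holm-adjusted within each cluster. A gene is a DEG of a cluster iff its BH
p-value is below 0.05, its in-cluster expressed fraction exceeds 30% **and**
its fold change is positive. The positivity condition follows the field's
marker convention: without it, a two-sided test would label genes *depleted*
in a cluster (for example another population's markers) as its "DEGs". Fold
changes are computed on `expm1` of mean normalized values with a `1e-9`
pseudocount. Low-quality clusters are flagged when the median
detected-gene count is at most 250 (a deliberately generous bound around the
~200 seen in degraded droplets) **and** the cluster has no unique DEG, or
when the cluster-median mitochondrial fraction exceeds 7.5%. Top markers per
cluster are ranked by descending fold change, ties by ascending Holm p, then
by gene id.

One caveat found during validation: depth normalization couples cluster
compositions, so in cohorts of a few thousand cells the one-vs-rest test can
flag weak (log2FC < 0.5) but statistically real enrichments of another
population's baseline-level genes. Marker-grade effects (log2FC ≥ 2 in the
synthetic cohort) are unaffected.

## Cell–cell communication

For a ligand–receptor pair *i* and cells C1, C2, the directed affinity is
`E(C1, L_i) × E(C2, R_i)`; the total affinity sums both directions over the
pair database and is computed as two low-rank matrix products, identical to
the naive quadruple loop to 1e-8. The dense cell × cell matrix is only
materialized below a configurable cell count (default 5000); above that,
neighbor search runs block-wise over the low-rank factors. A modified kNN
graph links every cell to its `k = 15` *highest-affinity* partners (ties by
cell order, union-symmetrized, self excluded) — note this is an
affinity-maximizing construction, not a distance-minimizing one; the choice
of k follows common neighbor-graph practice since nothing upstream pins it.

Cluster-pair communication strength is the graph-abstraction connectivity:
observed inter-cluster edge count divided by its expectation under random
edge placement given cluster sizes and total edge count
(`expected = E · n_M · n_N / C(n, 2)`). Connections with connectivity above
0.05 are significant. Hubs are ranked by closeness centrality on the
significant subgraph with edge length `1/connectivity`; closeness is
(reachable nodes)/(sum of shortest-path lengths), computed per connected
component, isolated clusters scoring 0. Per-pair contributions to a
cluster-pair interaction use the factorized mean
`mean(ligand in M) × mean(receptor in N)`, normalized to sum to 1; pairs
above 0.01 are flagged for display. A compact curated human ligand–receptor
CSV (~150 pairs across the major signalling families) ships in
`inst/extdata/` and is user-replaceable; per-cell-pair terms are recomputed
on demand rather than stored.

## Bulk ↔ single-cell integration by gene bi-clustering

Bulk DEG lists (TSV: gene, log2fc, padj; upstream contract filters such as
adjusted p < 1e-5 / log2FC > 2 for tumor–normal lists or adjusted p < 0.1 /
log2FC > 0.25 for responder lists are applied and recorded by
`readDEGTable`) are mapped onto the single-cell landscape by averaging
normalized expression per cluster, z-scoring per gene across clusters, and
hierarchically clustering gene rows with correlation distance (1 − Pearson)
and average linkage — the standard pairing for z-scored profiles, chosen
here because the upstream heatmap-based procedure does not state its
distance or linkage. The tree is cut at a user-chosen number of gene
clusters (no automatic cut is applied; the cluster counts reported for
responder/non-responder runs upstream follow no stated rule), labels are
ordered by each cluster's first gene in the linkage leaf order, and up- and
downregulated genes are clustered in separate runs. Robustness is assessed
by repeatedly removing a fraction (default 90%) of a target cell type,
re-deriving the assignment, matching new to original gene clusters by
maximal-overlap Hungarian assignment, and reporting the per-cluster fraction
of genes that keep their assignment.

## Cohort-level statistics

Abundance analysis computes the percentage of each cluster per sample after
excluding samples with fewer than 200 cells (and, in lineage-restricted
runs, samples with fewer than 50 cells of that lineage); percentages re-sum
to 100 after exclusions. Tumor-vs-normal comparisons use the Wilcoxon
rank-sum test on per-sample percentages (a per-patient paired signed-rank
variant is selectable), Holm correction across clusters, and a log2 ratio of
mean percentages with a 0.1-percentage-point pseudocount so tumor-exclusive
populations stay finite. `rankSumTest` enumerates the exact permutation
distribution (midranks, doubling convention) whenever the assignment count
is small enough, which keeps small-cohort p-values exact even with ties, and
falls back to the tie-corrected normal approximation otherwise.

Gene-signature scores are rank-based: genes are ranked by decreasing
expression within each unit (cell or bulk sample), ranks are clipped at
`maxRank + 1` (absent genes take the clipped worst rank), and the signature's
Mann–Whitney U statistic is mapped to `1 − U/(n · maxRank)`, clamped to
[0, 1]. The `maxRank = 1500` default is inherited from the customary
rank-based scoring convention rather than derived here. Scores are invariant
to any monotone transform of the unit's expression vector. AUROC for
response classification is the tie-corrected `U/(n1·n0)` with a full
threshold sweep.

## The synthetic cohort generator

The generator is the package's test bed: a negative-binomial (Gamma–Poisson)
count model — the standard desk-scale surrogate for droplet UMI data — with
per-gene lognormal baseline means, shared dispersion, and multiplicative
log2 mean shifts planting every structure the pipeline must recover:

* **Cell types.** `nMajorTypes × nMinorPerMajor` minor clusters
  (`M<i>.<j>`); each minor carries its major's marker block plus its own
  (disjoint blocks, default 10 genes at log2 effect 2). Marker and
  ligand/receptor baseline means are floored at the cohort mean scale:
  canonical markers are by construction well-detected genes, and an
  undetectable "marker" could never satisfy the 30% expressed-fraction rule.
* **Programs.** Each minor cluster additionally owns `degsPerModule`
  (default 20) program genes at the marker effect; synthetic bulk DEG lists
  draw from these, plus an optional decoy fraction of background genes.
* **Artifact.** 50 genes shifted by log2 effect 2 in two designated samples
  (both samples of patient 1), additive on the log-mean scale — a
  sample-restricted stress program.
* **Communication.** Five ligand–receptor axes from one hub cluster to five
  receivers at log2 effect 3, embedded in a pair database with 20 decoy
  pairs over background genes.
* **Composition.** Per-sample cluster proportions are Dirichlet-multinomial
  (concentration 60) around tissue-specific expectations. Planted tumor fold
  changes (default: one cluster 5×, one 0.2×) are exact on the expected
  percentage scale, with unmapped clusters absorbing the renormalization —
  renormalizing all clusters would silently distort the planted effects.
* **Low-quality cells.** Optionally, marker-free cells restricted to the
  background-gene support with doubled mitochondrial means (cluster-median
  mito ≈ 9%, median detected genes ≈ 230), emulating a degraded population
  that passes per-cell QC but fails cluster-level quality rules. Off by
  default.

Defaults — 6 patients × (tumor + normal) × 120 cells, 600 genes, 4 majors ×
2 minors — are chosen so the default cohort falls entirely inside the QC
window, every cluster draws cells from at least 5 patients, and the full
validation suite (including 100-seed recovery runs) completes on a single
CPU in minutes. Abundance analyses use a dedicated 10-patient × 250-cell
configuration so the 200-cell sample-exclusion rule is exercised
meaningfully. One master seed drives everything; child seeds for the gene
universe, composition and count draws are derived by fixed offsets
(Mersenne-Twister), making cohorts bit-reproducible.

What the generator does **not** emulate: doublets, ambient RNA,
gene–gene correlation beyond the planted modules, batch effects on the mean
structure beyond the artifact program, or T-cell receptor data. Passing the
synthetic suite therefore demonstrates that each algorithm recovers the
structure it targets under NB noise at realistic effect sizes — not that
real tissue meets these assumptions.

## Numerical and degenerate-case conventions

* Variance ties in gene selection and affinity ties in the kNN break by
  identifier/cell order; PCA and ICA components are re-signed so the
  largest-magnitude loading is positive.
* A gene constant across clusters z-scores to an all-zero profile row and is
  assigned correlation distance 1 to every other gene.
* Wilcoxon with zero rank variance (all ties) returns p = 1; empty
  contribution totals return an empty table with a warning; isolated
  clusters get closeness 0; all-zero cells get mitochondrial fraction 0.
* Cluster matching across downsampling repetitions uses Hungarian
  maximal-overlap assignment, so preservation stays well-defined when
  cluster counts drift.

## Known limitations

* The normalization is depth-only; strong mean–variance trends in real data
  would reach the variance-ranked gene selection unshrunk.
* The sample-specificity score is a surrogate for an unquantified upstream
  criterion; artifact selection on data with genuinely sample-restricted
  biology (e.g. patient-private tumor programs) needs manual review of the
  flagged component's loadings.
* Closeness ranking depends on the significance cutoff (0.05) inherited from
  the connectivity statistic; near-threshold edges can reorder mid-table
  ranks, though hub identification was stable across 100 seeds.
* The exact rank-test path enumerates up to `choose(n, n1) ≤ 2e5`
  assignments; beyond that, small-p accuracy rests on the tie-corrected
  normal approximation.
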