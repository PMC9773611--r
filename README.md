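# gastroTME

Analysis toolkit for dissecting the tumor microenvironment (TME) from
multi-patient tumor/normal single-cell RNA-seq cohorts, written for
computational biologists who need each stage of such an analysis as a tested,
composable function rather than a monolithic pipeline. It covers:

* per-cell quality control (detected genes, UMI, mitochondrial fraction) and
  depth normalization;
* identification and subtraction of sample-specific dissociation-artifact
  gene programs by independent component analysis;
* stepwise two-round clustering: variance-ranked genes → PCA →
  batch-balanced kNN graph → Leiden, with canonical-marker-driven merging,
  one-vs-rest Wilcoxon marker detection, low-quality-cluster flagging and
  patient-contribution checks;
* ligand–receptor cell–cell communication: affinity scoring, an
  affinity-based neighbor graph, graph-abstraction cluster connectivity,
  closeness-centrality hub ranking and per-pair contribution tables;
* bulk ↔ single-cell integration: bi-clustering bulk differential genes over
  cluster-averaged profiles, with downsampling robustness;
* cohort statistics: tumor-vs-normal abundance testing with exclusion rules,
  rank-based gene-signature scoring, AUROC response classification.

A negative-binomial synthetic cohort generator with fully known ground truth
(planted markers, artifact program, communication axes with a designated hub,
abundance fold changes and bulk-DEG programs) makes every stage verifiable.

## The models in brief

**Communication.** For ligand–receptor pair *i* and cells C1, C2 the
affinity is `A(C1,C2,i) = E(C1,Li) · E(C2,Ri)`; total affinity sums both
directions over the pair database,

```
A(C1,C2) = Σ_i E(C1,Li)·E(C2,Ri) + Σ_i E(C1,Ri)·E(C2,Li),
```

computed as two low-rank products. Cells link to their k strongest affinity
partners; cluster-pair communication strength is the graph-abstraction
connectivity (observed / expected inter-cluster edges, significant above
0.05); hubs are ranked by closeness centrality with edge length
1/connectivity; the contribution of pair *i* to a cluster pair (M, N) is its
mean affinity `mean(E(Li) in M) · mean(E(Ri) in N)` normalized across pairs.

**Statistics.** Wilcoxon rank-sum / signed-rank tests with an exact
enumeration path for small groups (valid under ties) and tie-corrected
normal approximation otherwise; BH and Holm adjustment; rank-based signature
scores `1 − U/(n·maxRank)` with rank clipping; AUROC as tie-corrected
`U/(n1·n0)`.

See `vignettes/gastroTME-methods.Rmd` for assumptions, parameter defaults
and design rationale.

## Worked example

```r
library(gastroTME)
library(SingleCellExperiment)

cfg <- syntheticConfig(seed = 42)        # 6 patients x T/N x 120 cells
sce <- generateCohort(cfg)

keep <- filterCells(computeQCMetrics(sce), qcThresholds())
sum(keep)                                 # 1440 — default cohort passes QC
sce <- normalizeCounts(sce[, keep])

dec <- decomposeICA(sce, nComponents = 20, samples = colData(sce)$sample)
id <- selectArtifactComponent(dec)        # -> component 1, specificity 10.1
sce <- removeArtifactProgram(sce, dec, id)

tr <- groundTruth(sce)
cl <- clusterTwoRound(sce, tr$markerSets[paste0("M", 1:4)],
                      tr$markerSets[-(1:4)], seed = 42)
table(cl$minor, tr$cellClusters[cl$cell])[1:4, 1:4]
#>        M1.1 M1.2 M2.1 M2.2
#>   M1.1  126    0    0    0
#>   M1.2    0  119    0    0
#>   M2.1    0    0  149    0
#>   M2.2    0    0    0  494

g <- affinityKNN(totalAffinity(sce, tr$lrDatabase), k = 15)
comm <- clusterConnectivity(g, setNames(cl$minor, cl$cell))
head(closenessCentrality(comm), 3)
#>   cluster closeness rank
#> 1    M1.1  5.195572    1      <- the planted sender hub
#> 2    M3.2  2.953851    2
#> 3    M2.2  2.938488    3
```

The recovered clustering matches the planted cell types (the 494-cell M2.2
column is the planted 5× tumor-enriched population), the artifact selector
picks the single dominant sample-specific component, and the planted hub
cluster tops the closeness ranking. `lrContribution(sce, ..., "M1.1",
"M2.1")` then attributes that interaction to individual ligand–receptor
pairs (the planted axis carries the largest contribution, 0.30 in this run).

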