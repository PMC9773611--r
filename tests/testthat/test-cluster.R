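test_that("variable-gene selection ranks by variance with identifier tie-break", {
  x <- matrix(1, 4, 6, dimnames = list(c("gB", "gA", "gD", "gC"), NULL))
  expect_identical(selectVariableGenes(x, 3), c("gA", "gB", "gC"))
  set.seed(1)
  y <- matrix(rnorm(40), 4, 10, dimnames = list(rownames(x), NULL))
  full <- selectVariableGenes(y, 4)
  expect_setequal(full, rownames(y))
  expect_error(selectVariableGenes(y, 9), "exceeds")
  # planted markers have the highest variance when they are the only
  # planted variable structure
  sce <- normalizeCounts(generateCohort(plainMarkerConfig()))
  tr <- groundTruth(sce)
  mk <- unlist(tr$markerSets)
  top <- selectVariableGenes(sce, 2 * length(mk))
  expect_true(all(mk %in% top))
})

test_that("PCA embedding matches a dense eigendecomposition oracle", {
  set.seed(5)
  e <- matrix(rnorm(100 * 40), 100, 40,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:40)))
  emb <- embedPCA(e, nComponents = 10)
  ev <- attr(emb, "explained_variance")
  cov <- stats::cov(scale(t(e), center = TRUE, scale = FALSE))
  eig <- sort(eigen(cov, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(unname(ev), eig[1:10], tolerance = 1e-8)
  # rank-2 data reconstructs from 2 components
  r2 <- matrix(rnorm(20), 10, 2) %*% matrix(rnorm(16), 2, 8)
  dimnames(r2) <- list(paste0("g", 1:10), paste0("c", 1:8))
  emb2 <- embedPCA(r2, nComponents = 2)
  expect_lt(sum(attr(emb2, "explained_variance")) -
              sum(diag(stats::cov(scale(t(r2), scale = FALSE)))), 1e-8)
  # duplicated cell gives duplicated embedding rows
  e2 <- cbind(e, dup = e[, 7])
  emb3 <- embedPCA(e2, nComponents = 5)
  expect_equal(unname(emb3["dup", ]), unname(emb3["c7", ]))
  expect_error(embedPCA(e, nComponents = 1000), "exceeds")
})

test_that("balanced kNN equals brute-force per-batch neighbor search", {
  set.seed(8)
  emb <- matrix(rnorm(30 * 4), 30, 4,
                dimnames = list(sprintf("c%02d", 1:30), NULL))
  batch <- rep(c("b1", "b2"), 15)
  g <- buildBalancedKNN(emb, batch, kWithin = 3)
  expect_identical(graphEdgeSet(g), oracleBalancedKNNEdges(emb, batch, 3))
  # single batch reduces to ordinary symmetrized kNN
  g1 <- buildBalancedKNN(emb, NULL, kWithin = 4)
  expect_identical(graphEdgeSet(g1),
                   oracleBalancedKNNEdges(emb, rep("all", 30), 4))
  # duplicated batches: every cell links to its duplicate
  embDup <- rbind(emb, emb)
  rownames(embDup) <- sprintf("d%02d", 1:60)
  gd <- buildBalancedKNN(embDup, rep(c("x", "y"), each = 30), kWithin = 1)
  for (i in 1:30)
    expect_true(igraph::are_adjacent(gd, i, i + 30))
  expect_warning(buildBalancedKNN(emb[1:4, ], c("a", "a", "b", "b"), 3),
                 "fewer than")
})

test_that("Leiden finds planted partitions deterministically", {
  skip_if_not_installed("mclust")
  g <- igraph::add_edges(
    igraph::disjoint_union(igraph::make_full_graph(8),
                           igraph::make_full_graph(8)), c(1, 9))
  igraph::V(g)$name <- paste0("v", 1:16)
  cl <- leidenCluster(g, 1.0, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:8])), 1)
  # 5 planted blobs in an embedding
  set.seed(9)
  n <- 60
  emb <- do.call(rbind, lapply(1:5, function(i)
    sweep(matrix(rnorm(n * 10), n, 10), 2, diag(10)[i, ] * 8, "+")))
  rownames(emb) <- sprintf("c%03d", seq_len(5 * n))
  gk <- buildBalancedKNN(emb, NULL, kWithin = 10)
  mem <- leidenCluster(gk, 1.0, seed = 2)
  expect_gte(mclust::adjustedRandIndex(mem, rep(1:5, each = n)), 0.9)
  expect_identical(leidenCluster(gk, 1.0, seed = 2), mem)
  expect_error(leidenCluster(igraph::make_empty_graph(0), 1, 1), "empty")
})

test_that("cluster DEG detection agrees with the rank-sum test and planted truth", {
  # flat gene is never a DEG
  set.seed(11)
  e <- rbind(flat = rep(2, 40),
             up = c(rnorm(20, 6), rnorm(20, 1)),
             dn = c(rnorm(20, 1), rnorm(20, 6)))
  colnames(e) <- paste0("c", 1:40)
  cl <- rep(c("A", "B"), each = 20)
  degs <- findClusterDEGs(e, cl, minClusterSize = 2)
  dA <- degs[degs$cluster == "A", ]
  expect_equal(dA$p[dA$gene == "flat"], 1)
  expect_false(dA$is_deg[dA$gene == "flat"])
  expect_true(dA$is_deg[dA$gene == "up"])
  expect_false(dA$is_deg[dA$gene == "dn"])    # downregulated, not a marker
  # statistic and approximate p agree with rankSumTest's normal path
  rs <- rankSumTest(e["up", 1:20], e["up", 21:40], exactLimit = 0)
  expect_equal(dA$p[dA$gene == "up"], rs$p.value, tolerance = 1e-12)
  # planted markers are DEGs of their own cluster only
  sce <- defaultCohort(); tr <- cohortTruth(sce)
  degsC <- findClusterDEGs(sce, tr$cellClusters)
  hits <- degsC[degsC$is_deg, ]
  for (mn in unique(tr$cellClusters)) {
    mk <- tr$markerSets[[mn]]
    mine <- hits$gene[hits$cluster == mn]
    expect_true(all(mk %in% mine))
    # no marker shows marker-grade enrichment in an unrelated cluster
    # (depth normalization couples compositions, so weak sub-0.5 log2FC
    # significance can arise in large one-vs-rest comparisons)
    others <- hits$gene[hits$cluster != mn & hits$log2fc >= 0.5 &
                          !startsWith(hits$cluster, sub("\\..*", "", mn))]
    expect_length(intersect(mk, others), 0)
  }
  expect_warning(findClusterDEGs(e, c(rep("A", 38), "B", "B"),
                                 minClusterSize = 3), "fewer than")
})

test_that("low-quality flagging combines complexity, unique DEGs and mito", {
  metrics <- data.frame(
    genes_detected = c(rep(180, 10), rep(2000, 10), rep(150, 10)),
    total_umi = 1000, mito_frac = 0.01,
    row.names = paste0("c", 1:30))
  cl <- rep(c("low", "rich", "lowWithDegs"), each = 10)
  names(cl) <- rownames(metrics)
  degs <- data.frame(
    cluster = c(rep("rich", 50), rep("lowWithDegs", 3)),
    gene = c(paste0("g", 1:50), paste0("u", 1:3)),
    is_deg = TRUE)
  expect_identical(flagLowQualityClusters(cl, metrics, degs), "low")
  # a cluster with unique DEGs is never flagged on complexity alone
  degs2 <- rbind(degs, data.frame(cluster = "low", gene = paste0("x", 1:50),
                                  is_deg = TRUE))
  expect_length(flagLowQualityClusters(cl, metrics, degs2), 0)
  # shared DEGs do not count as unique
  degs3 <- rbind(degs,
                 data.frame(cluster = "low", gene = paste0("g", 1:5),
                            is_deg = TRUE))
  expect_identical(flagLowQualityClusters(cl, metrics, degs3), "low")
  # high-mito clusters are flagged regardless
  metrics$mito_frac[11:20] <- 0.09
  expect_setequal(flagLowQualityClusters(cl, metrics, degs2),
                  c("rich"))
})

test_that("a planted junk cluster is the only one flagged", {
  cfg <- syntheticConfig(junkCellsPerSample = 15, seed = 21)
  sce <- generateCohort(cfg)
  tr <- groundTruth(sce)
  m <- computeQCMetrics(sce)
  keep <- filterCells(m)
  sceF <- sce[, keep]
  sceF <- normalizeCounts(sceF)
  cl <- tr$cellClusters[colnames(sceF)]
  degs <- findClusterDEGs(sceF, cl)
  flagged <- flagLowQualityClusters(cl, m[colnames(sceF), ], degs)
  expect_identical(flagged, "junk")
})

test_that("subclustering recovers planted minors and namespaces labels", {
  skip_if_not_installed("mclust")
  sce <- defaultCohort(); tr <- cohortTruth(sce)
  major <- tr$cellMajor
  sub <- subclusterMajor(sce, major, "M1", batch = colData(sce)$batch,
                         nComponents = 20, seed = 7)
  expect_true(all(startsWith(levels(sub), "M1.")))
  merged <- mergeClustersByMarkers(
    assay(sce, "normalized")[, names(sub)], sub,
    tr$markerSets[c("M1.1", "M1.2")])
  expect_gte(mclust::adjustedRandIndex(merged, tr$cellClusters[names(sub)]),
             0.9)
  # homogeneous population at low resolution stays one cluster
  # (cohort without artifact substructure, so the cluster is truly uniform)
  sceP <- normalizeCounts(generateCohort(plainMarkerConfig()))
  trP <- groundTruth(sceP)
  one <- subclusterMajor(sceP, trP$cellClusters, "M2.1",
                         batch = NULL, nComponents = 10, kWithin = 10,
                         resolution = 0.1, seed = 1, minCells = 30)
  expect_equal(length(unique(one)), 1)
  expect_true(all(startsWith(as.character(one), "M2.1.")))
  expect_warning(
    subclusterMajor(sce, major, "M1", minCells = 10 * ncol(sce)), "skipped")
})

test_that("two-round clustering recovers major and minor structure", {
  skip_if_not_installed("mclust")
  sce <- defaultCohort(); tr <- cohortTruth(sce)
  cl <- clusterTwoRound(sce, majorMarkerSets(tr), minorMarkerSets(tr),
                        seed = 33)
  expect_gte(mclust::adjustedRandIndex(cl$major, tr$cellMajor[cl$cell]), 0.9)
  expect_gte(mclust::adjustedRandIndex(cl$minor, tr$cellClusters[cl$cell]),
             0.9)
})

test_that("patient contribution counts distinct patients and flags floors", {
  cl <- c(a = "C1", b = "C1", c = "C2")
  pats <- c("P1", "P1", "P2")
  out <- patientContribution(cl, pats, floor = 2)
  expect_equal(out$n_patients, c(1L, 1L))
  expect_true(all(out$flagged))
  expect_error(patientContribution(c("C1", NA), c("P1", "P2")), "empty")
  # default cohort: uniform mixing puts >= 5 patients in every cluster
  sce <- defaultCohort(); tr <- cohortTruth(sce)
  pc <- patientContribution(tr$cellClusters, colData(sce)$patient)
  expect_true(all(pc$n_patients >= 5))
  expect_false(any(pc$flagged))
})

test_that("top-marker selection ranks by fold change then Holm p then gene", {
  degs <- data.frame(
    cluster = "A",
    gene = c("g1", "g2", "g3", "g4"),
    log2fc = c(3, 2, 2, 1.5),
    padj_holm = c(0.5, 0.01, 0.001, 0.2),
    is_deg = TRUE)
  top <- selectTopMarkers(degs, k = 3)
  expect_identical(top[["A"]], c("g1", "g3", "g2"))
  expect_identical(selectTopMarkers(degs, k = 0)[["A"]], character(0))
  expect_warning(selectTopMarkers(degs, k = 10), "fewer than")
  # planted markers dominate when they carry the largest effects
  cfg <- syntheticConfig(nPatients = 3, cellsPerSample = 80,
                         degsPerModule = 0, markerLog2Effect = 2.5,
                         lrPairs = data.frame(ligand = NA_character_,
                                              receptor = NA_character_,
                                              sender = "M1.1",
                                              receiver = "M2.1", effect = 1),
                         seed = 12)
  sce <- normalizeCounts(generateCohort(cfg))
  tr <- groundTruth(sce)
  degsC <- findClusterDEGs(sce, tr$cellClusters)
  top3 <- selectTopMarkers(degsC, k = 3)
  for (mn in names(top3)) {
    mj <- sub("\\..*", "", mn)
    planted <- c(tr$markerSets[[mn]], tr$markerSets[[mj]])
    expect_true(all(top3[[mn]] %in% planted))
  }
})
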