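#' Top variable genes of a normalized matrix
#'
#' Genes ranked by variance across cells; ties broken by gene identifier
#' order.
#'
#' @param x normalized matrix (genes x cells) or SCE with assay
#'   \code{normalized}.
#' @param n number of genes to return.
#' @return character vector of \code{n} gene ids.
#' @export
selectVariableGenes <- function(x, n = 1000) {
  e <- .normMatrix(x)
  if (n > nrow(e)) stop("n exceeds the number of genes")
  v <- apply(e, 1, stats::var)
  ids <- rownames(e)
  if (is.null(ids)) ids <- sprintf("g%06d", seq_len(nrow(e)))
  ids[order(-v, ids)][seq_len(n)]
}

#' PCA embedding of cells over a gene subset
#'
#' Principal components of the gene-centered matrix, ordered by decreasing
#' explained variance, with a deterministic sign convention (the
#' largest-magnitude gene loading of each component is positive).
#'
#' @param x normalized matrix or SCE.
#' @param genes gene subset to embed on (must exist in the matrix).
#' @param nComponents number of principal components.
#' @return cell x component embedding with the per-component explained
#'   variance as attribute \code{"explained_variance"}.
#' @export
embedPCA <- function(x, genes = NULL, nComponents = 50) {
  e <- .normMatrix(x)
  if (!is.null(genes)) {
    if (!all(genes %in% rownames(e))) stop("unknown genes requested")
    e <- e[genes, , drop = FALSE]
  }
  if (nComponents > min(dim(e))) stop("nComponents exceeds matrix rank bound")
  xt <- scale(t(e), center = TRUE, scale = FALSE)  # cells x genes
  pc <- stats::prcomp(xt, center = FALSE, scale. = FALSE, rank. = nComponents)
  rot <- pc$rotation
  emb <- pc$x
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) { rot[, k] <- -rot[, k]; emb[, k] <- -emb[, k] }
  }
  rownames(emb) <- colnames(e)
  attr(emb, "explained_variance") <- pc$sdev[seq_len(ncol(emb))]^2
  emb
}

#' Batch-balanced k-nearest-neighbor cell graph
#'
#' Each cell is connected to its \code{kWithin} nearest neighbors (Euclidean
#' distance in the embedding) within every batch, so a cell gains up to
#' \code{kWithin * n_batches} neighbors; the union of directed neighbor sets
#' is symmetrized into an undirected simple graph. This balances the graph
#' across library chemistries the way batch-balanced kNN integration does.
#'
#' @param embedding cell x component matrix (rownames = cell ids).
#' @param batch per-cell batch labels (single batch gives ordinary kNN).
#' @param kWithin neighbors per batch.
#' @return an undirected \code{igraph} with vertex names = cell ids.
#' @export
buildBalancedKNN <- function(embedding, batch = NULL, kWithin = 3) {
  n <- nrow(embedding)
  if (is.null(batch)) batch <- rep("all", n)
  if (kWithin < 1) stop("kWithin must be >= 1")
  batch <- as.character(batch)
  cells <- rownames(embedding)
  if (is.null(cells)) cells <- sprintf("c%06d", seq_len(n))
  edges <- vector("list", length(unique(batch)))
  bi <- 0
  for (b in unique(batch)) {
    bi <- bi + 1
    idx <- which(batch == b)
    k <- kWithin
    if (length(idx) < kWithin + 1) {
      warning("batch '", b, "' has fewer than kWithin+1 cells; using all")
      k <- max(length(idx) - 1L, 0L)
    }
    if (k == 0) next
    d2 <- .crossDist2(embedding, embedding[idx, , drop = FALSE])
    nb <- matrix(0L, n, k)
    for (i in seq_len(n)) {
      di <- d2[i, ]
      di[idx == i] <- Inf                      # exclude self
      nb[i, ] <- idx[order(di)[seq_len(k)]]
    }
    edges[[bi]] <- cbind(rep(seq_len(n), k), as.vector(nb))
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- cells[seq_len(igraph::vcount(g))]
  g
}

#' Leiden community detection on a cell graph
#'
#' Modularity-objective Leiden clustering; deterministic under a fixed seed.
#'
#' @param graph an \code{igraph} cell graph.
#' @param resolution modularity resolution.
#' @param seed RNG seed.
#' @param nIterations Leiden refinement iterations.
#' @return factor of cluster labels ("1", "2", ...) named by cell.
#' @export
leidenCluster <- function(graph, resolution = 1.0, seed = 1L,
                          nIterations = 5L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = nIterations)
  stats::setNames(factor(igraph::membership(cl)), igraph::V(graph)$name)
}

#' One-vs-rest Wilcoxon differential expression per cluster
#'
#' For every cluster, genes are tested cluster-vs-rest with a Wilcoxon
#' rank-sum test (tie-corrected normal approximation on midranks, shared
#' ranks across clusters), BH- and Holm-adjusted within each cluster's gene
#' family. A gene is a DEG of a cluster iff its BH-adjusted p-value is below
#' \code{alpha}, the in-cluster expressed fraction exceeds \code{minFrac} and
#' the fold change is positive (upregulation, the marker convention). Fold
#' changes are computed on \code{expm1} of the normalized means with a small
#' pseudocount.
#'
#' @param x normalized matrix or SCE (assay \code{normalized}); when an SCE is
#'   given, expressed fractions use the raw \code{counts} assay.
#' @param clusters per-cell cluster labels.
#' @param counts optional raw count matrix for the expressed-fraction rule
#'   (defaults to \code{x > 0} on the normalized values).
#' @param alpha BH significance cutoff (default 0.05).
#' @param minFrac in-cluster expressed-fraction cutoff (default 0.30).
#' @param minClusterSize clusters smaller than this are skipped with a
#'   warning (default 3).
#' @return data.frame(cluster, gene, log2fc, p, padj, padj_holm, frac_in,
#'   frac_out, is_deg).
#' @export
findClusterDEGs <- function(x, clusters, counts = NULL, alpha = 0.05,
                            minFrac = 0.30, minClusterSize = 3) {
  if (methods::is(x, "SummarizedExperiment") && is.null(counts))
    counts <- SummarizedExperiment::assay(x, "counts")
  e <- .normMatrix(x)
  clusters <- stats::setNames(as.character(clusters),
                              names(clusters) %||% colnames(e))
  clusters <- clusters[colnames(e)]
  if (length(unique(clusters)) < 2) stop("need at least two clusters")
  expressed <- if (is.null(counts)) e > 0 else as.matrix(counts > 0)
  rk <- .rowRanksTies(e)
  n <- ncol(e)
  out <- list()
  for (cl in sort(unique(clusters))) {
    inIdx <- which(clusters == cl)
    n1 <- length(inIdx); n2 <- n - n1
    if (n1 < minClusterSize) {
      warning("cluster '", cl, "' has fewer than ", minClusterSize,
              " cells; skipped")
      next
    }
    u <- rowSums(rk$ranks[, inIdx, drop = FALSE]) - n1 * (n1 + 1) / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - rk$tiesum / (n * (n - 1)))
    z <- ifelse(sig2 > 0, (u - n1 * n2 / 2) / sqrt(pmax(sig2, 0)), 0)
    p <- ifelse(sig2 > 0, 2 * stats::pnorm(-abs(z)), 1)
    mIn <- rowMeans(e[, inIdx, drop = FALSE])
    mOut <- rowMeans(e[, -inIdx, drop = FALSE])
    l2fc <- log2((expm1(mIn) + 1e-9) / (expm1(mOut) + 1e-9))
    fracIn <- rowMeans(expressed[, inIdx, drop = FALSE])
    fracOut <- rowMeans(expressed[, -inIdx, drop = FALSE])
    padj <- stats::p.adjust(p, "BH")
    holm <- stats::p.adjust(p, "holm")
    out[[cl]] <- data.frame(cluster = cl, gene = rownames(e), log2fc = l2fc,
                            p = p, padj = padj, padj_holm = holm,
                            frac_in = fracIn, frac_out = fracOut,
                            is_deg = padj < alpha & fracIn > minFrac &
                              l2fc > 0,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag low-quality clusters
#'
#' A cluster is flagged iff (its median detected-gene count is at or below
#' \code{medianGenesMax} AND it has no unique DEG — a DEG of this cluster and
#' of no other), or its median mitochondrial fraction exceeds
#' \code{medianMitoMax} (high-mitochondrial clusters).
#'
#' @param clusters per-cell cluster labels.
#' @param metrics per-cell QC metrics (\code{\link{computeQCMetrics}}),
#'   aligned with \code{clusters} by cell name.
#' @param degs DEG table from \code{\link{findClusterDEGs}}.
#' @param medianGenesMax detected-genes threshold (default 250).
#' @param medianMitoMax cluster-median mitochondrial-fraction threshold
#'   (default 0.075).
#' @return character vector of flagged cluster ids.
#' @export
flagLowQualityClusters <- function(clusters, metrics, degs,
                                   medianGenesMax = 250,
                                   medianMitoMax = 0.075) {
  clusters <- stats::setNames(as.character(clusters), names(clusters))
  cells <- names(clusters) %||% rownames(metrics)
  metrics <- metrics[cells, , drop = FALSE]
  degGenes <- degs[degs$is_deg, c("cluster", "gene")]
  nClustersPerGene <- table(degGenes$gene)
  uniqueCount <- vapply(sort(unique(clusters)), function(cl) {
    gs <- degGenes$gene[degGenes$cluster == cl]
    sum(nClustersPerGene[gs] == 1)
  }, numeric(1))
  flagged <- character(0)
  for (cl in sort(unique(clusters))) {
    idx <- clusters == cl
    medGenes <- stats::median(metrics$genes_detected[idx])
    medMito <- stats::median(metrics$mito_frac[idx])
    if ((medGenes <= medianGenesMax && uniqueCount[[cl]] == 0) ||
        medMito > medianMitoMax)
      flagged <- c(flagged, cl)
  }
  flagged
}

#' Label clusters by canonical marker sets and merge shared labels
#'
#' Encodes the manual curation step of merging over-split graph clusters into
#' annotated populations: each cluster is assigned the marker-set label whose
#' genes have the highest mean z-scored expression in the cluster, and
#' clusters sharing a label are merged.
#'
#' @param x normalized matrix or SCE.
#' @param clusters per-cell cluster labels.
#' @param markerSets named list: label -> character vector of marker genes.
#' @return factor of merged labels named by cell.
#' @export
mergeClustersByMarkers <- function(x, clusters, markerSets) {
  e <- .normMatrix(x)
  clusters <- stats::setNames(as.character(clusters),
                              names(clusters) %||% colnames(e))
  z <- t(scale(t(e)))
  z[is.na(z)] <- 0
  labs <- names(markerSets)
  out <- clusters
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    sc <- vapply(labs, function(l) {
      gs <- intersect(markerSets[[l]], rownames(e))
      if (!length(gs)) return(-Inf)
      mean(z[gs, idx, drop = FALSE])
    }, numeric(1))
    out[idx] <- labs[which.max(sc)]
  }
  stats::setNames(factor(out), names(clusters))
}

#' Subcluster one major population
#'
#' Re-runs variable-gene selection, PCA, batch-balanced kNN and Leiden on the
#' cells of a single major cluster; minor ids are namespaced by the major id
#' (\code{"<major>.<k>"}).
#'
#' @param x normalized matrix or SCE.
#' @param clusters per-cell major labels.
#' @param major major cluster id to subcluster.
#' @param batch per-cell batch labels (aligned with columns of \code{x}).
#' @param nGenes variable genes (default 600).
#' @param nComponents principal components (default 25).
#' @param kWithin per-batch neighbors.
#' @param resolution,seed Leiden parameters.
#' @param minCells skip (with a warning) majors smaller than this.
#' @return factor of minor labels named by the major's cells, or \code{NULL}
#'   when skipped.
#' @export
subclusterMajor <- function(x, clusters, major, batch = NULL, nGenes = 600,
                            nComponents = 25, kWithin = 3, resolution = 1.0,
                            seed = 1L, minCells = 100) {
  e <- .normMatrix(x)
  clusters <- stats::setNames(as.character(clusters),
                              names(clusters) %||% colnames(e))
  idx <- which(clusters[colnames(e)] == major)
  if (length(idx) < minCells) {
    warning("major cluster '", major, "' too small to subcluster; skipped")
    return(NULL)
  }
  sub <- e[, idx, drop = FALSE]
  vg <- selectVariableGenes(sub, min(nGenes, nrow(sub)))
  emb <- embedPCA(sub, vg, min(nComponents, length(vg) - 1L,
                               ncol(sub) - 1L))
  g <- buildBalancedKNN(emb, if (is.null(batch)) NULL else batch[idx], kWithin)
  mem <- leidenCluster(g, resolution, seed)
  stats::setNames(factor(paste0(major, ".", as.character(mem))), names(mem))
}

#' Stepwise two-round clustering with marker-driven merging
#'
#' Round 1: variable genes, PCA, batch-balanced kNN, Leiden on all cells,
#' merged into major populations via \code{\link{mergeClustersByMarkers}} with
#' the major canonical-marker sets. Round 2: each major is subclustered and
#' its Leiden subclusters merged with the minor canonical-marker sets.
#'
#' @param x SCE with assay \code{normalized} (or normalized matrix).
#' @param majorMarkers,minorMarkers named lists of canonical marker sets;
#'   minor labels must be namespaced by the major label
#'   (\code{"<major>.<k>"}).
#' @param batch per-cell batch labels (defaults to \code{colData(x)$batch}).
#' @param nGenesMajor,nPCsMajor,nGenesMinor,nPCsMinor round-specific gene and
#'   PC counts.
#' @param kWithin per-batch neighbors.
#' @param resolutionMajor,resolutionMinor Leiden resolutions.
#' @param seed RNG seed.
#' @return data.frame(cell, major, minor).
#' @export
clusterTwoRound <- function(x, majorMarkers, minorMarkers, batch = NULL,
                            nGenesMajor = 1000, nPCsMajor = 50,
                            nGenesMinor = 600, nPCsMinor = 25, kWithin = 3,
                            resolutionMajor = 1.0, resolutionMinor = 1.0,
                            seed = 1L) {
  if (methods::is(x, "SummarizedExperiment") && is.null(batch))
    batch <- SummarizedExperiment::colData(x)$batch
  e <- .normMatrix(x)
  vg <- selectVariableGenes(e, min(nGenesMajor, nrow(e)))
  emb <- embedPCA(e, vg, min(nPCsMajor, length(vg) - 1L, ncol(e) - 1L))
  g <- buildBalancedKNN(emb, batch, kWithin)
  lv1 <- leidenCluster(g, resolutionMajor, seed)
  major <- mergeClustersByMarkers(e, lv1, majorMarkers)
  minor <- stats::setNames(rep(NA_character_, ncol(e)), colnames(e))
  for (mj in levels(droplevels(major))) {
    sub <- subclusterMajor(e, major, mj, batch, nGenesMinor, nPCsMinor,
                           kWithin, resolutionMinor, seed,
                           minCells = min(100, sum(major == mj)))
    if (is.null(sub)) { minor[major == mj] <- mj; next }
    sets <- minorMarkers[startsWith(names(minorMarkers), paste0(mj, "."))]
    if (!length(sets)) { minor[names(sub)] <- mj; next }
    merged <- mergeClustersByMarkers(e[, names(sub), drop = FALSE], sub, sets)
    minor[names(merged)] <- as.character(merged)
  }
  data.frame(cell = colnames(e), major = as.character(major),
             minor = minor, stringsAsFactors = FALSE, row.names = NULL)
}

#' Patients contributing to each cluster
#'
#' @param clusters per-cell cluster labels.
#' @param patients per-cell patient ids (aligned with \code{clusters}).
#' @param floor clusters with fewer contributing patients are flagged
#'   (default 5).
#' @return data.frame(cluster, n_patients, flagged).
#' @export
patientContribution <- function(clusters, patients, floor = 5) {
  clusters <- as.character(clusters)
  if (any(is.na(clusters) | clusters == ""))
    stop("empty cluster id encountered")
  if (length(clusters) != length(patients))
    stop("clusters and patients must be aligned")
  cl <- sort(unique(clusters))
  np <- vapply(cl, function(x) length(unique(patients[clusters == x])),
               numeric(1))
  data.frame(cluster = cl, n_patients = as.integer(np),
             flagged = np < floor, stringsAsFactors = FALSE, row.names = NULL)
}

#' Top marker genes per cluster
#'
#' Ranks each cluster's DEGs by descending fold change, ties by ascending
#' Holm-adjusted p-value, then by gene id, and returns the first \code{k}.
#'
#' @param degs DEG table from \code{\link{findClusterDEGs}}.
#' @param k markers per cluster (default 3).
#' @return named list: cluster -> character vector of up to \code{k} genes.
#' @export
selectTopMarkers <- function(degs, k = 3) {
  out <- list()
  for (cl in sort(unique(degs$cluster))) {
    d <- degs[degs$cluster == cl & degs$is_deg, , drop = FALSE]
    d <- d[order(-d$log2fc, d$padj_holm, d$gene), , drop = FALSE]
    if (nrow(d) < k)
      warning("cluster '", cl, "' has fewer than ", k, " DEGs")
    out[[cl]] <- utils::head(d$gene, k)
  }
  out
}
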