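#' Cluster-averaged, per-gene z-scored expression profiles
#'
#' Arithmetic mean of normalized expression per cluster for the requested
#' genes, then z-scored per gene across clusters ("scaled average
#' expression"); genes constant across clusters become all-zero rows. Genes
#' absent from the matrix are dropped with a warning.
#'
#' @param x normalized matrix or SCE (assay \code{normalized}).
#' @param clusters per-cell cluster labels.
#' @param genes genes to profile (default: all).
#' @return gene x cluster matrix.
#' @export
clusterProfile <- function(x, clusters, genes = NULL) {
  e <- .normMatrix(x)
  clusters <- stats::setNames(as.character(clusters),
                              names(clusters) %||% colnames(e))
  clusters <- clusters[colnames(e)]
  if (is.null(genes)) genes <- rownames(e)
  missing <- setdiff(genes, rownames(e))
  if (length(missing)) {
    warning(length(missing), " gene(s) absent from the matrix; dropped")
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) stop("no requested gene present in the matrix")
  lev <- sort(unique(clusters))
  prof <- vapply(lev, function(cl)
    rowMeans(e[genes, clusters == cl, drop = FALSE]), numeric(length(genes)))
  prof <- matrix(prof, nrow = length(genes), dimnames = list(genes, lev))
  ctr <- prof - rowMeans(prof)
  sdv <- sqrt(rowSums(ctr^2) / (ncol(prof) - 1))
  z <- ctr / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z
}

#' Hierarchical bi-clustering of genes over cluster profiles
#'
#' Agglomerative clustering of gene rows with correlation distance
#' (1 - Pearson) and average linkage, cut at \code{nGeneClusters}. Labels are
#' ordered by the position of each cluster's first gene in the linkage leaf
#' order and prefixed with \code{prefix} (e.g. U1, U2, ... for upregulated
#' runs). Genes with an undefined profile correlation (constant rows) get
#' distance 1 to every other gene.
#'
#' @param profile gene x cluster matrix from \code{\link{clusterProfile}}.
#' @param nGeneClusters clusters to cut.
#' @param prefix label prefix (default "C").
#' @return factor of gene-cluster labels named by gene, with the linkage leaf
#'   order as attribute \code{"leaf_order"}.
#' @export
biclusterGenes <- function(profile, nGeneClusters, prefix = "C") {
  if (nrow(profile) < 2) stop("need at least two genes")
  if (nGeneClusters > nrow(profile))
    stop("nGeneClusters exceeds the gene count")
  cr <- suppressWarnings(stats::cor(t(profile)))
  cr[is.na(cr)] <- 0
  d <- stats::as.dist(1 - cr)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = nGeneClusters)
  leaf <- hc$order
  firstPos <- vapply(seq_len(nGeneClusters), function(k)
    min(match(which(raw == k), leaf)), numeric(1))
  newId <- rank(firstPos, ties.method = "first")
  lab <- paste0(prefix, newId[raw])
  out <- factor(lab, levels = paste0(prefix, seq_len(nGeneClusters)))
  names(out) <- rownames(profile)
  attr(out, "leaf_order") <- rownames(profile)[leaf]
  out
}

#' Robustness of gene bi-clusters to downsampling of a target cell type
#'
#' Repeatedly removes a fraction of the target cells at random, recomputes the
#' cluster-averaged profile and the bi-clustering at the same cut, matches the
#' new gene clusters to the original ones by maximal overlap (Hungarian
#' assignment) and records, per original gene cluster, the fraction of its
#' genes that stay with their matched cluster.
#'
#' @param x normalized matrix or SCE.
#' @param clusters per-cell cluster labels.
#' @param genes genes to bi-cluster.
#' @param target cluster id(s) whose cells are downsampled.
#' @param nGeneClusters bi-cluster cut.
#' @param frac fraction of target cells removed each repetition
#'   (default 0.9).
#' @param reps repetitions (default 100).
#' @param seed RNG seed; repetition r uses child seed \code{seed + r}.
#' @return list with \code{original} (the full-data assignment),
#'   \code{preservation} (named numeric: mean preserved fraction per original
#'   gene cluster) and \code{perRep} (reps x clusters matrix).
#' @export
downsampleRobustness <- function(x, clusters, genes, target, nGeneClusters,
                                 frac = 0.9, reps = 100, seed = 1L) {
  if (frac < 0 || frac >= 1) stop("frac must lie in [0, 1)")
  e <- .normMatrix(x)
  clusters <- stats::setNames(as.character(clusters),
                              names(clusters) %||% colnames(e))
  clusters <- clusters[colnames(e)]
  tIdx <- which(clusters %in% target)
  if (length(tIdx) < 2) stop("target cell type too small to downsample")
  orig <- biclusterGenes(clusterProfile(e, clusters, genes), nGeneClusters)
  lev <- levels(orig)
  per <- matrix(NA_real_, reps, length(lev), dimnames = list(NULL, lev))
  for (r in seq_len(reps)) {
    set.seed(.childSeed(seed, 100 + r))
    drop <- sample(tIdx, floor(frac * length(tIdx)))
    keep <- setdiff(seq_len(ncol(e)), drop)
    sub <- e[, keep, drop = FALSE]
    subCl <- clusters[keep]
    prof <- clusterProfile(sub, subCl, genes)
    newAs <- biclusterGenes(prof, min(nGeneClusters, nrow(prof)))
    map <- matchClusterLabels(orig[names(newAs)], newAs)
    matched <- stats::setNames(map[as.character(newAs)], names(newAs))
    for (cl in lev) {
      gs <- names(orig)[orig == cl]
      gs <- intersect(gs, names(matched))
      per[r, cl] <- if (length(gs))
        mean(!is.na(matched[gs]) & matched[gs] == cl) else NA_real_
    }
  }
  list(original = orig,
       preservation = colMeans(per, na.rm = TRUE),
       perRep = per)
}
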