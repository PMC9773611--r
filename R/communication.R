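#' Read a ligand-receptor pair table
#'
#' CSV with columns \code{ligand,receptor[,annotation]}. Duplicate pairs are
#' removed. A compact curated human pair set ships with the package at
#' \code{system.file("extdata", "lr_pairs_human.csv", package = "gastroTME")}
#' and can be replaced by any user table.
#'
#' @param path CSV path.
#' @return data.frame(ligand, receptor, ...).
#' @export
readLRPairs <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(db)))
    stop("LR table must have columns ligand, receptor")
  db[!duplicated(db[, c("ligand", "receptor")]), , drop = FALSE]
}

#' Affinity of one ligand-receptor pair between two cells
#'
#' The directed single-pair affinity: ligand expression in the sender cell
#' times receptor expression in the receiver cell.
#'
#' @param e1,e2 named expression vectors of the sender and receiver cell.
#' @param pair list/row with \code{ligand} and \code{receptor} gene ids.
#' @return numeric scalar \code{e1[ligand] * e2[receptor]}.
#' @export
pairAffinity <- function(e1, e2, pair) {
  unname(e1[[pair$ligand]] * e2[[pair$receptor]])
}

#' Total ligand-receptor affinity between all cell pairs
#'
#' For cells C1, C2 and pair database i = 1..P:
#' \deqn{A_{C1,C2} = \sum_i E_{C1,L_i} E_{C2,R_i} + \sum_i E_{C1,R_i} E_{C2,L_i}}
#' computed as two low-rank products over the ligand- and receptor-expression
#' blocks. Pairs whose ligand or receptor is absent from the matrix are
#' dropped (with a message); duplicated pairs are removed by default. The
#' dense cell x cell matrix (diagonal zeroed) is materialized only up to
#' \code{maxCells} cells; above that, only the low-rank factors are kept and
#' neighbor search runs block-wise.
#'
#' @param x normalized matrix (genes x cells) or SCE with assay
#'   \code{normalized}.
#' @param db data.frame(ligand, receptor).
#' @param dedupe drop duplicated pairs (default TRUE).
#' @param maxCells materialization limit (default 5000).
#' @return an \code{\link{AffinityMatrix}}.
#' @export
totalAffinity <- function(x, db, dedupe = TRUE, maxCells = 5000) {
  e <- .normMatrix(x)
  if (dedupe) db <- db[!duplicated(db[, c("ligand", "receptor")]), ,
                       drop = FALSE]
  keep <- db$ligand %in% rownames(e) & db$receptor %in% rownames(e)
  if (!all(keep))
    message(sum(!keep), " pair(s) dropped (genes absent from matrix)")
  db <- db[keep, , drop = FALSE]
  if (nrow(db) == 0) stop("no ligand-receptor pair left after intersection")
  lig <- t(e[db$ligand, , drop = FALSE])       # cells x pairs
  rec <- t(e[db$receptor, , drop = FALSE])
  mat <- matrix(numeric(0), 0, 0)
  if (ncol(e) <= maxCells) {
    mat <- tcrossprod(lig, rec)
    mat <- mat + t(mat)
    diag(mat) <- 0
    dimnames(mat) <- list(colnames(e), colnames(e))
  }
  methods::new("AffinityMatrix", ligandExpr = lig, receptorExpr = rec,
               matrix = mat,
               pairs = data.frame(ligand = db$ligand, receptor = db$receptor,
                                  stringsAsFactors = FALSE))
}

#' Affinity-based k-nearest-neighbor cell graph
#'
#' Links every cell to the \code{k} cells of highest total affinity (self
#' excluded), ties broken by cell order; the union of directed neighbor sets
#' is symmetrized.
#'
#' @param aff an \code{\link{AffinityMatrix}}.
#' @param k neighbors per cell; \code{k >= n - 1} yields the complete graph
#'   with a warning.
#' @param blockSize rows per block when the dense matrix is not materialized.
#' @return undirected \code{igraph} with vertex names = cell ids.
#' @export
affinityKNN <- function(aff, k = 15, blockSize = 512) {
  n <- dim(aff)[1]
  cells <- rownames(aff@ligandExpr) %||% sprintf("c%06d", seq_len(n))
  if (k >= n - 1) {
    warning("k >= n - 1; returning the complete graph")
    k <- n - 1L
  }
  if (k < 1) stop("k must be >= 1")
  nb <- matrix(0L, n, k)
  dense <- length(aff@matrix) > 0
  starts <- seq(1, n, by = blockSize)
  for (s in starts) {
    rows <- s:min(s + blockSize - 1, n)
    a <- if (dense) aff@matrix[rows, , drop = FALSE] else {
      blk <- tcrossprod(aff@ligandExpr[rows, , drop = FALSE],
                        aff@receptorExpr) +
        tcrossprod(aff@receptorExpr[rows, , drop = FALSE], aff@ligandExpr)
      blk
    }
    for (ri in seq_along(rows)) {
      i <- rows[ri]
      ai <- a[ri, ]
      ai[i] <- -Inf
      nb[i, ] <- order(-ai, seq_len(n))[seq_len(k)]
    }
  }
  em <- cbind(rep(seq_len(n), k), as.vector(nb))
  g <- igraph::simplify(igraph::graph_from_edgelist(em, directed = FALSE))
  igraph::V(g)$name <- cells
  g
}

#' Cluster-pair connectivity by graph abstraction
#'
#' For clusters M, N the connectivity is the observed inter-cluster edge count
#' divided by its expectation under random placement of the graph's edges
#' given cluster sizes: \code{expected = E * n_M * n_N / choose(n, 2)} for
#' M != N (and \code{E * choose(n_M, 2) / choose(n, 2)} on the diagonal).
#' Off-diagonal connectivities above \code{cutoff} are flagged significant.
#'
#' @param graph undirected cell \code{igraph} (vertex names = cell ids).
#' @param clusters per-cell cluster labels (named by cell id, or aligned with
#'   vertex order).
#' @param cutoff significance cutoff (default 0.05).
#' @return a \code{\link{CommunicationGraph}}.
#' @export
clusterConnectivity <- function(graph, clusters, cutoff = 0.05) {
  cells <- igraph::V(graph)$name
  clusters <- stats::setNames(as.character(clusters),
                              names(clusters) %||% cells)
  clusters <- clusters[cells]
  if (anyNA(clusters)) stop("every cell in the graph must be clustered")
  sizes <- table(clusters)
  if (any(sizes == 0)) stop("cluster with zero cells")
  lev <- sort(names(sizes))
  em <- igraph::as_edgelist(graph, names = FALSE)
  ci <- match(clusters[em[, 1]], lev); cj <- match(clusters[em[, 2]], lev)
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  tab <- table(factor(lo, levels = seq_along(lev)),
               factor(hi, levels = seq_along(lev)))
  obs <- unclass(tab) + t(unclass(tab))
  diag(obs) <- diag(unclass(tab))
  dimnames(obs) <- list(lev, lev)
  n <- length(cells)
  m <- nrow(em)
  ns <- as.numeric(sizes[lev])
  expect <- outer(ns, ns) * m / choose(n, 2)
  diag(expect) <- m * choose(ns, 2) / choose(n, 2)
  conn <- ifelse(expect > 0, obs / expect, 0)
  dimnames(conn) <- list(lev, lev)
  methods::new("CommunicationGraph", connectivity = conn, cutoff = cutoff,
               clusterSizes = stats::setNames(as.integer(sizes[lev]), lev),
               nEdges = as.integer(m))
}

#' Closeness-centrality hub ranking of the communication graph
#'
#' On the subgraph of significant connections (edge length = 1/connectivity),
#' closeness of a cluster is (reachable clusters)/(sum of shortest-path
#' lengths to them), computed per connected component; isolated clusters get
#' 0. Returned in descending closeness order, ties broken by cluster id.
#'
#' @param comm a \code{\link{CommunicationGraph}}.
#' @return data.frame(cluster, closeness, rank).
#' @export
closenessCentrality <- function(comm) {
  mask <- significanceMask(comm)
  lev <- rownames(connectivity(comm))
  if (length(lev) < 2) stop("need at least two clusters")
  w <- 1 / connectivity(comm)
  g <- igraph::graph_from_adjacency_matrix(
    ifelse(mask, w, 0), mode = "undirected", weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  clo <- vapply(seq_along(lev), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) return(0)
    sum(reach) / sum(di[reach])
  }, numeric(1))
  out <- data.frame(cluster = lev, closeness = clo, stringsAsFactors = FALSE)
  out <- out[order(-out$closeness, out$cluster), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Ligand-receptor contributions to one cluster-pair interaction
#'
#' Direction-specific (ligand on the M side): the mean per-pair affinity over
#' all cell pairs (Cm in M, Cn in N) is
#' \deqn{Affinity_{L,R,M,N} = \sum_{m,n} E_{Cm,L} E_{Cn,R} / m / n}
#' which factorizes into (mean ligand expression in M) x (mean receptor
#' expression in N). Contributions normalize the per-pair affinities to sum
#' to 1 for the cluster pair; rows above \code{threshold} are flagged.
#'
#' @param x normalized matrix or SCE.
#' @param clusters per-cell cluster labels.
#' @param db data.frame(ligand, receptor) (deduplicated, intersected).
#' @param M,N sender and receiver cluster ids.
#' @param threshold contribution display cutoff (default 0.01).
#' @return data.frame(cluster_m, cluster_n, ligand, receptor, affinity,
#'   contribution, above_threshold); empty (with a warning) when the total
#'   affinity is zero.
#' @export
lrContribution <- function(x, clusters, db, M, N, threshold = 0.01) {
  e <- .normMatrix(x)
  clusters <- stats::setNames(as.character(clusters),
                              names(clusters) %||% colnames(e))
  clusters <- clusters[colnames(e)]
  db <- db[!duplicated(db[, c("ligand", "receptor")]), , drop = FALSE]
  db <- db[db$ligand %in% rownames(e) & db$receptor %in% rownames(e), ,
           drop = FALSE]
  if (nrow(db) == 0) stop("no ligand-receptor pair left after intersection")
  mIdx <- which(clusters == M); nIdx <- which(clusters == N)
  if (!length(mIdx) || !length(nIdx)) stop("empty cluster requested")
  ligM <- rowMeans(e[db$ligand, mIdx, drop = FALSE])
  recN <- rowMeans(e[db$receptor, nIdx, drop = FALSE])
  affin <- ligM * recN
  tot <- sum(affin)
  if (tot == 0) {
    warning("total affinity between '", M, "' and '", N, "' is zero")
    return(data.frame(cluster_m = character(), cluster_n = character(),
                      ligand = character(), receptor = character(),
                      affinity = numeric(), contribution = numeric(),
                      above_threshold = logical()))
  }
  data.frame(cluster_m = M, cluster_n = N, ligand = db$ligand,
             receptor = db$receptor, affinity = unname(affin),
             contribution = unname(affin / tot),
             above_threshold = unname(affin / tot > threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}
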