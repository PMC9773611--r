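# Independent oracles used across the suite. Each is a deliberately naive,
# separately written implementation (enumeration, brute force, closed form)
# of the quantity the package computes by its production path.

# Exact two-sample rank-sum p-value by enumerating every assignment of the
# pooled values to group 1 (valid with ties via midranks). Doubling
# convention for the two-sided p.
oracleRankSumExact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# Exact signed-rank p-value by enumerating all 2^m sign assignments.
oracleSignedRankExact <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), m))
  vs <- as.matrix(signs) %*% r
  min(1, 2 * min(mean(vs <= vObs), mean(vs >= vObs)))
}

# Direct formula implementations of the step-down Holm and step-up BH
# adjustments.
oracleHolm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, (n - seq_len(n) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(n); out[o] <- adj
  out
}

oracleBH <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, n / (n - seq_len(n) + 1) * p[o])
  adj <- cummin(adj)
  out <- numeric(n); out[o] <- adj
  out
}

# AUROC as the fraction of concordant positive/negative pairs (ties count
# one half).
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Naive quadruple-loop total affinity over cells and pairs.
oracleTotalAffinity <- function(e, db) {
  n <- ncol(e)
  a <- matrix(0, n, n, dimnames = list(colnames(e), colnames(e)))
  for (c1 in seq_len(n)) for (c2 in seq_len(n)) {
    if (c1 == c2) next
    s <- 0
    for (i in seq_len(nrow(db)))
      s <- s + e[db$ligand[i], c1] * e[db$receptor[i], c2] +
        e[db$receptor[i], c1] * e[db$ligand[i], c2]
    a[c1, c2] <- s
  }
  a
}

# Direction-specific mean per-pair affinity by the double loop over cell
# pairs.
oracleLRMeans <- function(e, clusters, db, M, N) {
  mIdx <- which(clusters == M); nIdx <- which(clusters == N)
  vapply(seq_len(nrow(db)), function(i) {
    s <- 0
    for (cm in mIdx) for (cn in nIdx)
      s <- s + e[db$ligand[i], cm] * e[db$receptor[i], cn]
    s / length(mIdx) / length(nIdx)
  }, numeric(1))
}

# All-pairs shortest paths by Floyd-Warshall on a weight matrix with Inf for
# missing edges.
oracleFloydWarshall <- function(w) {
  n <- nrow(w)
  d <- w; diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Brute-force per-batch k-nearest-neighbor edge set (sorted unique pairs).
oracleBalancedKNNEdges <- function(emb, batch, k) {
  n <- nrow(emb)
  edges <- NULL
  for (b in unique(batch)) {
    idx <- which(batch == b)
    for (i in seq_len(n)) {
      cand <- setdiff(idx, i)
      d <- sqrt(colSums((t(emb[cand, , drop = FALSE]) - emb[i, ])^2))
      nb <- cand[order(d)][seq_len(min(k, length(cand)))]
      edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# Edge set of an igraph as a sorted two-column matrix of vertex indices.
graphEdgeSet <- function(g) {
  em <- igraph::as_edgelist(g, names = FALSE)
  em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  mode(em) <- "integer"
  unique(em[order(em[, 1], em[, 2]), , drop = FALSE])
}
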