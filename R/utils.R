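#' Wilcoxon rank-sum / signed-rank test with an exact small-sample path
#'
#' Two-sample rank test used throughout the package (cluster marker detection,
#' tumor-vs-normal abundance comparison). For small problems the permutation
#' distribution is enumerated exactly, which remains valid in the presence of
#' ties (midranks); otherwise a tie-corrected normal approximation is used.
#' Two-sided p-values follow the doubling convention
#' \code{min(1, 2 * min(P(U <= u), P(U >= u)))}.
#'
#' @param x,y numeric vectors; for \code{paired = TRUE} both must have the
#'   same length and the signed-rank test is applied to \code{x - y}.
#' @param paired logical; signed-rank test on paired differences.
#' @param exactLimit maximum number of enumerated assignments (unpaired:
#'   \code{choose(n, n1)}; paired: \code{2^m}) before falling back to the
#'   normal approximation.
#' @return list with \code{statistic} (Mann-Whitney U, or V for the paired
#'   test), \code{p.value} and \code{method}.
#' @export
rankSumTest <- function(x, y, paired = FALSE, exactLimit = 2e5) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired) {
    if (length(x) != length(y)) stop("paired test needs equal lengths")
    return(.signedRankTest(x - y, exactLimit))
  }
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= exactLimit) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    return(list(statistic = u, p.value = p, method = "exact enumeration"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tiecor)
  if (sig2 <= 0) return(list(statistic = u, p.value = 1,
                             method = "normal approximation"))
  z <- (u - mu) / sqrt(sig2)
  list(statistic = u, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

.signedRankTest <- function(d, exactLimit = 2e5) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(list(statistic = 0, p.value = 1,
                           method = "degenerate (all zero differences)"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (2^m <= exactLimit) {
    # enumerate all sign assignments over the observed |d| ranks
    vs <- 0
    for (i in seq_len(m)) vs <- c(vs, vs + r[i])
    p <- min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
    return(list(statistic = v, p.value = p, method = "exact enumeration"))
  }
  mu <- m * (m + 1) / 4
  ties <- table(r)
  sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(statistic = v, p.value = 1,
                             method = "normal approximation"))
  z <- (v - mu) / sqrt(sig2)
  list(statistic = v, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

# Row-wise midranks of a dense matrix (genes x cells), plus the per-row tie
# correction term sum(t^3 - t) needed by the vectorized Wilcoxon.
.rowRanksTies <- function(m) {
  rk <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  tiesum <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    rk[i, ] <- rank(m[i, ])
    tt <- table(m[i, ])
    tiesum[i] <- sum(tt^3 - tt)
  }
  list(ranks = rk, tiesum = tiesum)
}

# Squared Euclidean cross-distances between rows of a and rows of b.
.crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Maximal-overlap matching of two label vectors over the same items.
# Returns a named character vector mapping levels of `new` to levels of `ref`
# (unmatched new levels map to NA). Hungarian assignment on the contingency
# table via clue::solve_LSAP.
matchClusterLabels <- function(ref, new) {
  ref <- as.character(ref); new <- as.character(new)
  tab <- table(new, ref)
  nr <- nrow(tab); nc <- ncol(tab)
  k <- max(nr, nc)
  m <- matrix(0, k, k)
  m[seq_len(nr), seq_len(nc)] <- tab
  sol <- clue::solve_LSAP(m, maximum = TRUE)
  map <- rep(NA_character_, nr)
  for (i in seq_len(nr)) if (sol[i] <= nc) map[i] <- colnames(tab)[sol[i]]
  names(map) <- rownames(tab)
  map
}

# Derive a child RNG seed from a master seed by fixed offset, keeping the
# result inside the 32-bit integer range.
.childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483587)
}
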