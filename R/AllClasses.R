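#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Independent-component decomposition of a normalized expression matrix
#'
#' Holds the gene loadings, cell scores and per-component sample-specificity
#' scores of an ICA decomposition, with the per-gene centering vector needed to
#' reconstruct the input as \code{loadings \%*\% scores + center}.
#'
#' @slot loadings gene x component matrix of gene weights.
#' @slot scores component x cell matrix of unit-variance cell scores.
#' @slot center per-gene mean subtracted before decomposition.
#' @slot specificity per-component sample-specificity score (between-sample
#'   variance of the sample-mean score over pooled within-sample variance);
#'   \code{NA} until \code{\link{scoreSampleSpecificity}} has been applied.
#' @slot method character, decomposition algorithm.
#' @slot iterations iterations used by the fixed-point algorithm.
#' @slot converged logical convergence flag.
#' @export
setClass("ComponentDecomposition",
  representation(loadings = "matrix", scores = "matrix", center = "numeric",
                 specificity = "numeric", method = "character",
                 iterations = "integer", converged = "logical"))

setValidity("ComponentDecomposition", function(object) {
  k <- ncol(object@loadings)
  msg <- character()
  if (nrow(object@scores) != k)
    msg <- c(msg, "loadings and scores disagree on component count")
  if (length(object@center) != nrow(object@loadings))
    msg <- c(msg, "center length must equal gene count")
  if (length(object@specificity) != k)
    msg <- c(msg, "specificity length must equal component count")
  if (length(msg)) msg else TRUE
})

#' @describeIn ComponentDecomposition number of components
#' @param x,object a \code{ComponentDecomposition}
#' @export
nComponents <- function(x) ncol(x@loadings)

#' @describeIn ComponentDecomposition gene x component loading matrix
#' @export
componentLoadings <- function(x) x@loadings

#' @describeIn ComponentDecomposition component x cell score matrix
#' @export
componentScores <- function(x) x@scores

#' @describeIn ComponentDecomposition per-component sample-specificity scores
#' @export
sampleSpecificity <- function(x) x@specificity

setMethod("show", "ComponentDecomposition", function(object) {
  cat("ComponentDecomposition:", nrow(object@loadings), "genes x",
      ncol(object@loadings), "components x", ncol(object@scores), "cells\n")
  cat("  method:", object@method,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  if (!all(is.na(object@specificity)))
    cat("  top sample-specificity:",
        format(max(object@specificity), digits = 4), "\n")
})

#' Low-rank ligand-receptor affinity between all cell pairs
#'
#' The total affinity between cells C1 and C2 is
#' \deqn{A_{C1,C2} = \sum_i E_{C1,L_i} E_{C2,R_i} + \sum_i E_{C1,R_i} E_{C2,L_i}}
#' summed over a ligand-receptor pair table. The object stores the two
#' cell x pair expression factors; the dense cell x cell matrix is only
#' materialized below a configurable cell count (see
#' \code{\link{totalAffinity}}).
#'
#' @slot ligandExpr cell x pair matrix of ligand expression.
#' @slot receptorExpr cell x pair matrix of receptor expression.
#' @slot matrix dense cell x cell affinity matrix, or a 0x0 matrix when not
#'   materialized.
#' @slot pairs the ligand-receptor table used (columns ligand, receptor).
#' @export
setClass("AffinityMatrix",
  representation(ligandExpr = "matrix", receptorExpr = "matrix",
                 matrix = "matrix", pairs = "data.frame"))

setValidity("AffinityMatrix", function(object) {
  if (!identical(dim(object@ligandExpr), dim(object@receptorExpr)))
    return("ligand and receptor factors must have identical dimensions")
  n <- nrow(object@ligandExpr)
  if (length(object@matrix) && !identical(dim(object@matrix), c(n, n)))
    return("materialized matrix must be cells x cells")
  TRUE
})

#' @describeIn AffinityMatrix number of cells
#' @param x,object an \code{AffinityMatrix}
#' @export
setMethod("dim", "AffinityMatrix", function(x)
  c(nrow(x@ligandExpr), nrow(x@ligandExpr)))

#' @describeIn AffinityMatrix materialize the dense cell x cell matrix
#' @export
affinityMatrix <- function(x) {
  if (length(x@matrix)) return(x@matrix)
  a <- tcrossprod(x@ligandExpr, x@receptorExpr)
  a <- a + t(a)
  diag(a) <- 0
  a
}

setMethod("show", "AffinityMatrix", function(object) {
  cat("AffinityMatrix:", nrow(object@ligandExpr), "cells,",
      ncol(object@ligandExpr), "ligand-receptor pairs",
      if (length(object@matrix)) "(materialized)\n" else "(low-rank only)\n")
})

#' Cluster-level communication graph
#'
#' Cluster x cluster connectivity from graph abstraction over a cell-level
#' affinity neighbor graph: observed inter-cluster edge counts divided by
#' their expectation under random edge placement given cluster sizes and the
#' total edge count. Connections with connectivity above \code{cutoff}
#' (default 0.05) are flagged significant.
#'
#' @slot connectivity symmetric cluster x cluster matrix of observed/expected
#'   edge-count ratios.
#' @slot cutoff significance cutoff on connectivity.
#' @slot clusterSizes named integer vector of cluster sizes.
#' @slot nEdges total edge count of the underlying cell graph.
#' @export
setClass("CommunicationGraph",
  representation(connectivity = "matrix", cutoff = "numeric",
                 clusterSizes = "integer", nEdges = "integer"))

setValidity("CommunicationGraph", function(object) {
  msg <- character()
  cm <- object@connectivity
  if (nrow(cm) != ncol(cm)) msg <- c(msg, "connectivity must be square")
  if (max(abs(cm - t(cm))) > 1e-8) msg <- c(msg, "connectivity must be symmetric")
  if (nrow(cm) != length(object@clusterSizes))
    msg <- c(msg, "clusterSizes must match connectivity dimension")
  if (length(msg)) msg else TRUE
})

#' @describeIn CommunicationGraph connectivity matrix
#' @param x,object a \code{CommunicationGraph}
#' @export
connectivity <- function(x) x@connectivity

#' @describeIn CommunicationGraph logical matrix of significant inter-cluster
#'   connections (off-diagonal connectivity strictly above the cutoff)
#' @export
significanceMask <- function(x) {
  m <- x@connectivity > x@cutoff
  diag(m) <- FALSE
  m
}

setMethod("show", "CommunicationGraph", function(object) {
  k <- nrow(object@connectivity)
  ns <- sum(significanceMask(object)) / 2
  cat("CommunicationGraph:", k, "clusters,", ns,
      "significant connections (connectivity >", object@cutoff, ")\n")
})
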