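#' Quality-control thresholds for cell filtering
#'
#' Defaults follow the standard droplet QC window for gastric-cohort data:
#' 200-7500 detected genes, 500-75,000 UMI counts (both ranges inclusive) and
#' strictly less than 10% mitochondrial reads.
#'
#' @param minGenes,maxGenes inclusive bounds on detected genes per cell.
#' @param minUMI,maxUMI inclusive bounds on total UMI per cell.
#' @param maxMitoFrac strict upper bound on the mitochondrial read fraction.
#' @return a validated \code{QCThresholds} list.
#' @export
qcThresholds <- function(minGenes = 200, maxGenes = 7500, minUMI = 500,
                         maxUMI = 75000, maxMitoFrac = 0.10) {
  if (minGenes >= maxGenes || minUMI >= maxUMI)
    stop("QC ranges must satisfy min < max")
  if (maxMitoFrac < 0 || maxMitoFrac > 1)
    stop("maxMitoFrac must lie in [0, 1]")
  structure(list(minGenes = minGenes, maxGenes = maxGenes, minUMI = minUMI,
                 maxUMI = maxUMI, maxMitoFrac = maxMitoFrac),
            class = "QCThresholds")
}

#' Per-cell QC metrics
#'
#' @param x a \code{SingleCellExperiment} with a \code{counts} assay and a
#'   logical \code{mito} column in \code{rowData}, or a count matrix with
#'   \code{mito} supplied.
#' @param mito logical per-gene mitochondrial flag (taken from
#'   \code{rowData(x)$mito} when \code{x} is an SCE).
#' @return data.frame with \code{genes_detected}, \code{total_umi},
#'   \code{mito_frac} per cell (\code{mito_frac = 0} for all-zero cells).
#' @export
computeQCMetrics <- function(x, mito = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    mito <- SummarizedExperiment::rowData(x)$mito
    x <- SummarizedExperiment::assay(x, "counts")
  }
  if (is.null(mito)) stop("mitochondrial gene flags are required")
  if (length(mito) != nrow(x)) stop("mito flag length must match gene count")
  umi <- Matrix::colSums(x)
  mitoUmi <- Matrix::colSums(x[mito, , drop = FALSE])
  data.frame(genes_detected = Matrix::colSums(x > 0),
             total_umi = umi,
             mito_frac = ifelse(umi == 0, 0, mitoUmi / umi),
             row.names = colnames(x))
}

#' Cell keep-mask from QC metrics
#'
#' A cell is kept iff its detected genes and UMI count fall inside the
#' inclusive QC ranges and its mitochondrial fraction is strictly below the
#' cutoff.
#'
#' @param metrics output of \code{\link{computeQCMetrics}}.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return logical keep-mask named by cell.
#' @export
filterCells <- function(metrics, thresholds = qcThresholds()) {
  keep <- metrics$genes_detected >= thresholds$minGenes &
    metrics$genes_detected <= thresholds$maxGenes &
    metrics$total_umi >= thresholds$minUMI &
    metrics$total_umi <= thresholds$maxUMI &
    metrics$mito_frac < thresholds$maxMitoFrac
  stats::setNames(keep, rownames(metrics))
}

#' Depth normalization of QC-filtered counts
#'
#' \code{log1p} of per-cell depth-scaled counts with target sum equal to the
#' median cell depth. This is a depth-invariant monotone transform; the method
#' name and target sum are recorded in the provenance so downstream affinity
#' computations can state which matrix they consumed.
#'
#' @param x \code{SingleCellExperiment} (assay \code{counts}) or count matrix.
#' @return for an SCE input, the SCE with a dense \code{normalized} assay and
#'   provenance in \code{metadata(x)$normalization}; for a matrix input, the
#'   normalized dense matrix with the provenance as attribute.
#' @export
normalizeCounts <- function(x) {
  sce <- NULL
  if (methods::is(x, "SummarizedExperiment")) {
    sce <- x
    x <- SummarizedExperiment::assay(x, "counts")
  }
  depth <- Matrix::colSums(x)
  if (any(depth == 0)) stop("zero-depth cell encountered; run QC first")
  target <- stats::median(depth)
  e <- log1p(sweep(as.matrix(x), 2, target / depth, "*"))
  dimnames(e) <- dimnames(x)
  prov <- list(method = "lognorm-median-depth", target_sum = target,
               removed_components = integer(0))
  if (!is.null(sce)) {
    SummarizedExperiment::assay(sce, "normalized") <- e
    S4Vectors::metadata(sce)$normalization <- prov
    return(sce)
  }
  attr(e, "normalization") <- prov
  e
}

# Pull the normalized gene x cell matrix out of an SCE or pass a matrix through.
.normMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(as.matrix(SummarizedExperiment::assay(x, "normalized")))
  as.matrix(x)
}

#' Independent component analysis of a normalized matrix
#'
#' Decomposes the gene-centered normalized matrix into statistically
#' independent gene programs using fixed-point fast ICA (logcosh contrast,
#' symmetric decorrelation, PCA whitening). Cell scores are scaled to unit
#' variance; each component is re-signed so its largest-magnitude gene loading
#' is positive. When sample labels are supplied, per-component
#' sample-specificity scores are computed and components are ordered by them
#' (descending); otherwise components keep their variance order.
#'
#' @param x normalized matrix (genes x cells) or SCE with assay
#'   \code{normalized}.
#' @param nComponents number of components (capped at \code{min(dim) - 1}).
#' @param samples optional per-cell sample labels for specificity scoring.
#' @param seed seed for the (optional) random rotation start; the default
#'   identity start makes the decomposition seed-independent.
#' @param maxit,tol fixed-point iteration controls.
#' @param randomStart use a random initial rotation instead of the identity.
#' @return a \code{\link{ComponentDecomposition}}.
#' @export
decomposeICA <- function(x, nComponents = 128, samples = NULL, seed = 1L,
                         maxit = 200, tol = 1e-6, randomStart = FALSE) {
  e <- .normMatrix(x)
  nc <- min(nComponents, nrow(e) - 1L, ncol(e) - 1L)
  xt <- t(e)                                   # cells x genes
  ctr <- colMeans(xt)
  set.seed(seed)
  rmat <- if (randomStart) {
    q <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))
    q
  } else diag(nc)
  fit <- ica::icafast(xt, nc = nc, center = TRUE, maxit = maxit, tol = tol,
                      Rmat = rmat, alg = "par", fun = "logcosh")
  iters <- if (!is.null(fit$iter)) as.integer(fit$iter) else NA_integer_
  converged <- is.null(fit$converged) || isTRUE(fit$converged) ||
    (is.numeric(fit$iter) && fit$iter < maxit)
  if (!converged)
    warning("ICA did not converge within ", maxit, " iterations")
  s <- fit$S                                   # cells x nc sources
  m <- fit$M                                   # genes x nc mixing
  if (nc == 1L) {                              # icafast drops to 1 x genes
    s <- matrix(as.numeric(s), ncol = 1)
    m <- matrix(as.numeric(m), ncol = 1)
  }
  sd_s <- apply(s, 2, stats::sd)
  sd_s[sd_s == 0] <- 1
  s <- sweep(s, 2, sd_s, "/")
  m <- sweep(m, 2, sd_s, "*")
  # deterministic sign: largest-|loading| gene positive
  for (k in seq_len(ncol(m))) {
    j <- which.max(abs(m[, k]))
    if (m[j, k] < 0) { m[, k] <- -m[, k]; s[, k] <- -s[, k] }
  }
  rownames(m) <- rownames(e)
  scores <- t(s)
  colnames(scores) <- colnames(e)
  spec <- rep(NA_real_, ncol(m))
  dec <- methods::new("ComponentDecomposition", loadings = m, scores = scores,
                      center = ctr, specificity = spec, method = "fastICA",
                      iterations = iters, converged = converged)
  if (!is.null(samples)) {
    spec <- scoreSampleSpecificity(dec, samples)
    ord <- order(-spec)
    dec@loadings <- dec@loadings[, ord, drop = FALSE]
    dec@scores <- dec@scores[ord, , drop = FALSE]
    dec@specificity <- spec[ord]
  }
  dec
}

#' Sample-specificity score of each component
#'
#' Score = variance across samples of the per-sample mean cell score, divided
#' by the pooled within-sample variance. Components tracking a
#' sample-restricted artifact program score high; biological programs spread
#' across samples score low. Invariant to cell order.
#'
#' @param decomp a \code{\link{ComponentDecomposition}} (or score matrix
#'   components x cells).
#' @param samples per-cell sample labels (>= 2 distinct samples required).
#' @return numeric score per component.
#' @export
scoreSampleSpecificity <- function(decomp, samples) {
  s <- if (methods::is(decomp, "ComponentDecomposition"))
    componentScores(decomp) else as.matrix(decomp)
  samples <- as.character(samples)
  if (length(samples) != ncol(s))
    stop("sample labels must match cell count")
  if (length(unique(samples)) < 2)
    stop("sample specificity is undefined for a single sample")
  us <- unique(samples)
  apply(s, 1, function(v) {
    mns <- vapply(us, function(g) mean(v[samples == g]), numeric(1))
    wss <- 0; dof <- 0
    for (g in us) {
      vg <- v[samples == g]
      if (length(vg) > 1) {
        wss <- wss + sum((vg - mean(vg))^2); dof <- dof + length(vg) - 1
      }
    }
    between <- stats::var(mns)
    if (between == 0) return(0)
    within <- if (dof > 0) wss / dof else 0
    if (within == 0) return(Inf)
    between / within
  })
}

#' Select the artifact component by sample specificity
#'
#' Flags components whose specificity exceeds
#' \code{median + zCutoff * MAD} of all component scores and returns the top
#' one. The paper-scale analogue selects the dissociation/heat-shock program
#' among ~128 components; selection here is automated rather than by
#' inspection.
#'
#' @param decomp decomposition with specificity scores filled in.
#' @param zCutoff MAD multiplier (default 5).
#' @return integer component index, or \code{integer(0)} when no component
#'   stands out.
#' @export
selectArtifactComponent <- function(decomp, zCutoff = 5) {
  spec <- sampleSpecificity(decomp)
  if (all(is.na(spec))) stop("specificity scores missing; pass sample labels")
  fin <- spec[is.finite(spec)]
  cut <- stats::median(fin) + zCutoff * stats::mad(fin)
  hits <- which(spec > cut | is.infinite(spec))
  if (!length(hits)) return(integer(0))
  hits[which.max(spec[hits])]
}

#' Subtract a component's gene program from the normalized matrix
#'
#' Removes the rank-1 term \code{loadings[, id] \%o\% scores[id, ]} from the
#' normalized matrix; projections of all other components are unchanged.
#'
#' @param x normalized matrix (genes x cells) or SCE with assay
#'   \code{normalized}.
#' @param decomp a \code{\link{ComponentDecomposition}} of that matrix.
#' @param component component index to remove.
#' @return same shape as the input; for an SCE the \code{normalized} assay is
#'   replaced and the removed component id appended to the provenance.
#' @export
removeArtifactProgram <- function(x, decomp, component) {
  if (length(component) != 1 || component < 1 ||
      component > nComponents(decomp)) stop("invalid component id")
  e <- .normMatrix(x)
  prog <- componentLoadings(decomp)[, component] %o%
    componentScores(decomp)[component, ]
  out <- e - prog
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "normalized") <- out
    prov <- S4Vectors::metadata(x)$normalization
    prov$removed_components <- c(prov$removed_components, component)
    S4Vectors::metadata(x)$normalization <- prov
    return(x)
  }
  out
}
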