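#' Per-sample cell-type abundance table with exclusion rules
#'
#' Computes the percentage of every cluster per sample. Samples with fewer
#' than \code{minCellsSample} cells in total are excluded; in a
#' lineage-restricted run (\code{lineageClusters} given), samples with fewer
#' than \code{minCellsLineage} cells of that lineage are additionally
#' excluded and percentages are taken within the lineage.
#'
#' @param clusters per-cell cluster labels.
#' @param meta per-cell data.frame with columns \code{sample}, \code{tissue}
#'   (\code{"tumor"}/\code{"normal"}) and \code{patient}, aligned with
#'   \code{clusters}.
#' @param minCellsSample whole-sample exclusion threshold (default 200).
#' @param minCellsLineage lineage-run exclusion threshold (default 50).
#' @param lineageClusters optional cluster ids defining the lineage.
#' @return data.frame(sample, patient, tissue, cluster, n_cells, percent);
#'   percentages per sample sum to 100 over included clusters.
#' @export
abundanceTable <- function(clusters, meta, minCellsSample = 200,
                           minCellsLineage = 50, lineageClusters = NULL) {
  clusters <- as.character(clusters)
  if (length(clusters) != nrow(meta))
    stop("clusters and meta must be aligned")
  if (!all(c("sample", "tissue", "patient") %in% names(meta)))
    stop("meta needs columns sample, tissue, patient")
  totals <- table(meta$sample)
  keepSamples <- names(totals)[totals >= minCellsSample]
  sel <- meta$sample %in% keepSamples
  if (!is.null(lineageClusters)) {
    inLin <- clusters %in% lineageClusters
    linCount <- table(factor(meta$sample[inLin], levels = keepSamples))
    keepSamples <- names(linCount)[linCount >= minCellsLineage]
    sel <- sel & inLin & meta$sample %in% keepSamples
  }
  if (!any(sel)) stop("all samples excluded by the cell-count rules")
  cl <- sort(unique(clusters[sel]))
  rows <- list()
  for (s in sort(unique(meta$sample[sel]))) {
    idx <- sel & meta$sample == s
    tab <- table(factor(clusters[idx], levels = cl))
    rows[[s]] <- data.frame(
      sample = s,
      patient = meta$patient[idx][1],
      tissue = meta$tissue[idx][1],
      cluster = cl,
      n_cells = as.integer(tab),
      percent = 100 * as.numeric(tab) / sum(tab),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Tumor-vs-normal abundance comparison per cluster
#'
#' Wilcoxon rank-sum test on per-sample percentages between tumor and normal
#' samples (unpaired by default; the paired signed-rank variant matches
#' samples per patient), Holm correction across clusters, and the log2 ratio
#' of mean percentages with a pseudocount to guard tumor- or normal-exclusive
#' clusters.
#'
#' @param table output of \code{\link{abundanceTable}}.
#' @param paired use the per-patient paired variant (patients lacking either
#'   tissue are dropped).
#' @param pseudocount percentage-point pseudocount in the log ratio
#'   (default 0.1).
#' @return data.frame(cluster, mean_tumor, mean_normal, log2_ratio, p,
#'   p_holm); \code{p = NA} when a group is empty.
#' @export
compareAbundance <- function(table, paired = FALSE, pseudocount = 0.1) {
  cl <- sort(unique(table$cluster))
  res <- lapply(cl, function(cc) {
    d <- table[table$cluster == cc, , drop = FALSE]
    tu <- d[d$tissue == "tumor", , drop = FALSE]
    no <- d[d$tissue == "normal", , drop = FALSE]
    mt <- mean(tu$percent); mn <- mean(no$percent)
    if (nrow(tu) == 0 || nrow(no) == 0)
      return(data.frame(cluster = cc, mean_tumor = mt, mean_normal = mn,
                        log2_ratio = NA_real_, p = NA_real_))
    if (paired) {
      pts <- intersect(tu$patient, no$patient)
      if (length(pts) < 1)
        return(data.frame(cluster = cc, mean_tumor = mt, mean_normal = mn,
                          log2_ratio = NA_real_, p = NA_real_))
      xt <- tu$percent[match(pts, tu$patient)]
      xn <- no$percent[match(pts, no$patient)]
      p <- rankSumTest(xt, xn, paired = TRUE)$p.value
    } else {
      p <- rankSumTest(tu$percent, no$percent)$p.value
    }
    data.frame(cluster = cc, mean_tumor = mt, mean_normal = mn,
               log2_ratio = log2((mt + pseudocount) / (mn + pseudocount)),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, "holm")
  rownames(out) <- NULL
  out
}

#' Rank-based gene-signature scores
#'
#' For each unit (cell or bulk sample), genes are ranked by decreasing
#' expression (midranks for ties, ranks clipped at \code{maxRank + 1}; genes
#' absent from the matrix receive the clipped worst rank) and the signature's
#' Mann-Whitney U statistic is converted to a score in [0, 1]:
#' \code{1 - (sum(r') - n(n+1)/2) / (n * maxRank)}, clamped to [0, 1]. A
#' signature occupying the top n ranks scores exactly 1; scores are invariant
#' to any monotone transform of the unit's expression vector.
#'
#' @param x expression matrix (genes x units; cells or bulk samples) or SCE
#'   (assay \code{normalized}).
#' @param signatures named list of gene sets.
#' @param maxRank rank clip (default 1500, the customary default of rank-based
#'   signature scoring).
#' @return unit x signature matrix of scores.
#' @export
signatureScore <- function(x, signatures, maxRank = 1500) {
  e <- .normMatrix(x)
  if (!length(signatures)) stop("no signature supplied")
  if (is.null(names(signatures)))
    names(signatures) <- paste0("S", seq_along(signatures))
  for (nm in names(signatures))
    if (!any(signatures[[nm]] %in% rownames(e)))
      stop("signature '", nm, "' shares no gene with the expression space")
  nUnit <- ncol(e)
  out <- matrix(NA_real_, nUnit, length(signatures),
                dimnames = list(colnames(e), names(signatures)))
  worst <- maxRank + 1
  for (j in seq_len(nUnit)) {
    r <- rank(-e[, j])                         # decreasing expression
    r <- pmin(r, worst)
    for (nm in names(signatures)) {
      gs <- signatures[[nm]]
      ri <- ifelse(gs %in% rownames(e), r[gs], worst)
      nS <- length(ri)
      u <- sum(ri) - nS * (nS + 1) / 2
      out[j, nm] <- min(1, max(0, 1 - u / (nS * maxRank)))
    }
  }
  out
}

#' AUROC of a score against binary response labels
#'
#' AUROC computed as the tie-corrected Mann-Whitney statistic
#' \code{U / (n1 * n0)}, with a full threshold sweep of sensitivity and
#' specificity (predict positive when score >= threshold).
#'
#' @param scores numeric score per sample.
#' @param labels binary response labels (logical, 0/1 or two-level factor;
#'   the second/TRUE level is "positive").
#' @return list with \code{auroc} and \code{sweep}
#'   (data.frame(threshold, sensitivity, specificity)).
#' @export
aurocScore <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  sweep <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t)
      mean(scores[labels == 1] >= t), numeric(1)),
    specificity = vapply(thr, function(t)
      mean(scores[labels == 0] < t), numeric(1)))
  list(auroc = auc, sweep = sweep)
}
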