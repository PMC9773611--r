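#' Write a cohort to Matrix Market format with TSV sidecars
#'
#' Writes \code{matrix.mtx} (gene x cell raw counts), \code{genes.tsv}
#' (id, mito flag, module), \code{barcodes.tsv}, \code{cells.tsv} (per-cell
#' metadata) and, for generated cohorts, \code{truth.json}.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  rd <- as.data.frame(SummarizedExperiment::rowData(sce))
  utils::write.table(cbind(gene = rownames(sce), rd),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  utils::write.table(cbind(cell = colnames(sce), cd),
                     file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- S4Vectors::metadata(sce)$truth
  if (!is.null(truth) && requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- truth
    tr$generativeMeans <- NULL                 # bulky; regenerate instead
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory with \code{matrix.mtx}, \code{genes.tsv},
#'   \code{barcodes.tsv}, \code{cells.tsv}.
#' @return a \code{SingleCellExperiment} with assay \code{counts} and the
#'   per-cell metadata in \code{colData}.
#' @export
readCohort <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes$gene, barcodes)
  rd <- S4Vectors::DataFrame(genes[, setdiff(names(genes), "gene"),
                                   drop = FALSE], row.names = genes$gene)
  cd <- S4Vectors::DataFrame(cells[, setdiff(names(cells), "cell"),
                                   drop = FALSE], row.names = cells$cell)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
}

#' Read a bulk DEG list with its input-contract filters
#'
#' TSV with header \code{gene}, \code{log2fc}, \code{padj} as produced by an
#' upstream bulk differential-expression run. Optional thresholds apply the
#' upstream contract (e.g. adjusted p < 1e-5 and log2FC > 2 for tumor/normal
#' lists; adjusted p < 0.1 and log2FC > 0.25 for response lists) and are
#' recorded as attributes.
#'
#' @param path TSV path.
#' @param maxPadj,minLog2FC optional contract filters.
#' @return data.frame(gene, log2fc, padj) with attributes \code{max_padj},
#'   \code{min_log2fc} when filters were applied.
#' @export
readDEGTable <- function(path, maxPadj = NULL, minLog2FC = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc", "padj") %in% names(d)))
    stop("DEG table must have columns gene, log2fc, padj")
  if (!is.null(maxPadj)) {
    d <- d[d$padj < maxPadj, , drop = FALSE]
    attr(d, "max_padj") <- maxPadj
  }
  if (!is.null(minLog2FC)) {
    d <- d[d$log2fc > minLog2FC, , drop = FALSE]
    attr(d, "min_log2fc") <- minLog2FC
  }
  d
}

#' Write a bulk DEG list
#' @param degs data.frame(gene, log2fc, padj, ...).
#' @param path output TSV path.
#' @export
writeDEGTable <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
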