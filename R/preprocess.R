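#' Cell quality-control thresholds
#'
#' Cells are removed when they have fewer than `min_umi` UMIs, fewer than
#' `min_genes` detected genes, or more than `max_mito` mitochondrial UMI
#' fraction.  The boundary semantics are strict: a cell sitting exactly at
#' 1000 UMIs, 400 genes and 25% mitochondrial reads is retained.
#'
#' @param min_umi minimum total UMI count (default 1000).
#' @param min_genes minimum number of detected genes (default 400).
#' @param max_mito maximum mitochondrial UMI fraction (default 0.25).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umi = 1000, min_genes = 400, max_mito = 0.25) {
  stopifnot(min_umi >= 0, min_genes >= 0, max_mito >= 0, max_mito <= 1)
  structure(list(min_umi = min_umi, min_genes = min_genes, max_mito = max_mito),
            class = "qc_thresholds")
}

#' Remove low-quality cells
#'
#' Retains exactly the cells with `total_umi >= min_umi`,
#' `n_genes_detected >= min_genes` and `mito_fraction <= max_mito`,
#' preserving cell order.  Removal counts per criterion are reported via
#' `message()` and attached as attribute `"qc_report"`.
#'
#' @param cells a [cell_matrix()].
#' @param thr a [qc_thresholds()].
#' @return the filtered `cell_matrix` (with a `qc_report` attribute:
#'   data.frame of cells failing each criterion and totals).  If every cell
#'   is removed, an empty `cell_matrix` is returned with a warning.
#' @export
filter_cells <- function(cells, thr = qc_thresholds()) {
  stopifnot(inherits(cells, "cell_matrix"), inherits(thr, "qc_thresholds"))
  m <- cells$cell_meta
  fail_umi <- m$total_umi < thr$min_umi
  fail_genes <- m$n_genes_detected < thr$min_genes
  fail_mito <- m$mito_fraction > thr$max_mito
  keep <- !(fail_umi | fail_genes | fail_mito)
  report <- data.frame(
    criterion = c("low_umi", "low_genes", "high_mito", "removed_total", "retained"),
    n_cells = c(sum(fail_umi), sum(fail_genes), sum(fail_mito), sum(!keep), sum(keep))
  )
  message(sprintf(
    "filter_cells: removed %d / %d cells (%d low UMI, %d low gene count, %d high mito)",
    sum(!keep), length(keep), sum(fail_umi), sum(fail_genes), sum(fail_mito)))
  if (!any(keep)) warning("filter_cells: all cells removed by QC")
  out <- subset_cells(cells, keep)
  attr(out, "qc_report") <- report
  out
}

#' Log-normalize UMI counts
#'
#' Computes `lognorm[g, c] = ln(1 + scale * counts[g, c] / total_umi[c])`,
#' the standard library-size log-normalization of droplet scRNA-seq data
#' (natural log, scale factor 1e4 by default).  Cells with zero total UMIs
#' get an all-zero column with a warning.
#'
#' @param cells a [cell_matrix()].
#' @param scale scale factor (default 10000).
#' @return the `cell_matrix` with the `lognorm` layer populated.
#' @export
log_normalize <- function(cells, scale = 1e4) {
  stopifnot(inherits(cells, "cell_matrix"), scale > 0)
  total <- cells$cell_meta$total_umi
  zero <- total == 0
  if (any(zero))
    warning(sprintf("log_normalize: %d cell(s) with zero total UMIs left all-zero", sum(zero)))
  inv <- ifelse(zero, 0, scale / total)
  ln <- cells$counts %*% Matrix::Diagonal(x = inv)
  ln@x <- log1p(ln@x)          # log1p(0) = 0, so sparsity is preserved
  ln <- methods::as(ln, "CsparseMatrix")
  dimnames(ln) <- dimnames(cells$counts)
  cells$lognorm <- ln
  cells
}
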