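#' Container for a genes x cells UMI count matrix with per-cell metadata
#'
#' A `cell_matrix` bundles a sparse non-negative integer UMI count matrix
#' (genes in rows, cells in columns), per-cell metadata, and an optional
#' log-normalized expression layer of the same shape.  Per-cell QC totals
#' (`total_umi`, `n_genes_detected`, `mito_fraction`) are computed on
#' construction; mitochondrial genes are identified by a symbol prefix
#' (default `"MT-"`).
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or any \pkg{Matrix} sparse class; stored as `dgCMatrix`).  Must
#'   carry row names (gene symbols) and column names (cell ids).
#' @param patient optional per-cell patient identifier (recycled if length 1).
#' @param idh_status optional per-cell IDH mutation label, `"WT"` or `"MUT"`.
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @param lognorm optional log-normalized layer, same dimensions as `counts`.
#'
#' @return An object of class `cell_matrix`: a list with elements `counts`
#'   (`dgCMatrix`), `cell_meta` (data.frame with one row per cell) and
#'   `lognorm` (`dgCMatrix` or `NULL`).
#' @export
cell_matrix <- function(counts, patient = NA_character_, idh_status = NA_character_,
                        mito_prefix = "MT-", lognorm = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene symbols as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene symbols in counts matrix")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  n <- ncol(counts)
  total_umi <- Matrix::colSums(counts)
  n_genes_detected <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else numeric(n)
  # cells with zero total get mito_fraction 0 (they fail UMI-based QC anyway)
  mito_fraction <- ifelse(total_umi > 0, mito_umi / total_umi, 0)
  meta <- data.frame(
    cell_id = colnames(counts),
    patient = rep_len(as.character(patient), n),
    idh_status = rep_len(as.character(idh_status), n),
    total_umi = as.numeric(total_umi),
    n_genes_detected = as.integer(n_genes_detected),
    mito_fraction = as.numeric(mito_fraction),
    stringsAsFactors = FALSE
  )
  bad_idh <- !is.na(meta$idh_status) & !meta$idh_status %in% c("WT", "MUT")
  if (any(bad_idh)) stop("idh_status must be 'WT' or 'MUT' (or NA)")
  if (!is.null(lognorm)) {
    lognorm <- methods::as(methods::as(methods::as(lognorm, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (!identical(dim(lognorm), dim(counts)))
      stop("lognorm layer dimensions do not match counts")
    dimnames(lognorm) <- dimnames(counts)
  }
  structure(list(counts = counts, cell_meta = meta, lognorm = lognorm,
                 mito_prefix = mito_prefix),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  median UMI/cell: %s; lognorm layer: %s\n",
              format(stats::median(x$cell_meta$total_umi)),
              if (is.null(x$lognorm)) "absent" else "present"))
  pts <- unique(x$cell_meta$patient)
  if (!all(is.na(pts))) cat(sprintf("  patients: %d\n", length(pts)))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Number of genes / cells in a cell_matrix
#' @param x a `cell_matrix`
#' @return integer count
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) nrow(x$counts)

#' Subset a cell_matrix by cell index
#'
#' Keeps the given cells (logical or integer index over columns), preserving
#' order and all layers.
#'
#' @param x a `cell_matrix`
#' @param cells logical or integer index over cells
#' @return a `cell_matrix`
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "cell_matrix"))
  out <- x
  out$counts <- x$counts[, cells, drop = FALSE]
  out$cell_meta <- x$cell_meta[cells, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  if (!is.null(x$lognorm)) out$lognorm <- x$lognorm[, cells, drop = FALSE]
  out
}
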