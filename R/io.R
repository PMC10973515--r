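#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects a directory holding a MatrixMarket file (`matrix.mtx`), a gene
#' file (`genes.tsv` or `features.tsv`; first column used as symbol) and a
#' barcode file (`barcodes.tsv`), the usual 10x triplet layout.  Indices are
#' 1-based on disk per the MatrixMarket standard.  An optional cell metadata
#' CSV (`cell_meta.csv`, columns `cell_id`, `patient`, `idh_status`) is
#' joined by barcode when present.
#'
#' @param dir_path directory containing the triplet files.
#' @param mito_prefix mitochondrial gene-symbol prefix, passed to
#'   [cell_matrix()].
#' @return a [cell_matrix()] with QC totals computed.
#' @export
read_mtx_triplet <- function(dir_path, mito_prefix = "MT-") {
  pick <- function(cands) {
    for (f in cands) {
      p <- file.path(dir_path, f)
      if (file.exists(p)) return(p)
    }
    stop(sprintf("missing file in '%s': expected one of %s", dir_path,
                 paste(cands, collapse = ", ")))
  }
  mtx_path <- pick(c("matrix.mtx"))
  gene_path <- pick(c("genes.tsv", "features.tsv"))
  bc_path <- pick(c("barcodes.tsv"))
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.table(gene_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
  barcodes <- utils::read.table(bc_path, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
  if (nrow(genes) != nrow(m))
    stop(sprintf("gene file lists %d genes but matrix has %d rows", nrow(genes), nrow(m)))
  if (nrow(barcodes) != ncol(m))
    stop(sprintf("barcode file lists %d cells but matrix has %d columns", nrow(barcodes), ncol(m)))
  dimnames(m) <- list(genes[[1]], barcodes[[1]])
  patient <- NA_character_; idh <- NA_character_
  meta_path <- file.path(dir_path, "cell_meta.csv")
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, colClasses = "character")
    i <- match(colnames(m), meta$cell_id)
    if (anyNA(i)) stop("cell_meta.csv does not cover all barcodes")
    if ("patient" %in% names(meta)) patient <- meta$patient[i]
    if ("idh_status" %in% names(meta)) idh <- meta$idh_status[i]
  }
  cell_matrix(m, patient = patient, idh_status = idh, mito_prefix = mito_prefix)
}

#' Write a cell_matrix as a 10x-style MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `cell_meta.csv`
#' under `dir_path`.  Round-trips bit-exactly through [read_mtx_triplet()].
#'
#' @param cells a [cell_matrix()]
#' @param dir_path output directory (created if absent)
#' @return `dir_path`, invisibly.
#' @export
write_mtx_triplet <- function(cells, dir_path) {
  stopifnot(inherits(cells, "cell_matrix"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cells$counts, file.path(dir_path, "matrix.mtx"))
  utils::write.table(data.frame(rownames(cells$counts), rownames(cells$counts)),
                     file.path(dir_path, "genes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(colnames(cells$counts), file.path(dir_path, "barcodes.tsv"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(cells$cell_meta[, c("cell_id", "patient", "idh_status")],
                   file.path(dir_path, "cell_meta.csv"), row.names = FALSE)
  invisible(dir_path)
}

#' Read gene signatures from a GMT file
#'
#' GMT dialect: one set per line, tab-delimited `name`, `description`,
#' then member gene symbols.  Gene order is preserved; duplicates within a
#' line are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @return a named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT format error at line %d: fewer than 3 tab-separated fields", i))
    sigs[[i]] <- gene_signature(fields[[1]], fields[-(1:2)])
  }
  names(sigs) <- vapply(sigs, function(s) s$name, character(1))
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param sigs a [gene_signature()] or list of them.
#' @param path output path.
#' @param description description field written for every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path, description = "na") {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table from delimited text
#'
#' Reads a per-gene DEG table (one contrast) with columns for gene symbol,
#' log2 fold-change, raw p and (optionally) adjusted p.  The field
#' separator is comma by default; tab is accepted.  Rows whose numeric
#' fields fail to parse are dropped with a message; `"NA"` in the adjusted-p
#' column yields a missing value.  Duplicate gene symbols are an error
#' (per-contrast tables are per-gene unique).
#'
#' @param path delimited text file with a header row.
#' @param colmap named character vector mapping the roles `gene`, `log2fc`,
#'   `pval` and optionally `padj` to column names in the file.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return a `deg_table`: data.frame with columns `gene`, `log2fc`, `pval`,
#'   `padj` (NA when absent).
#' @export
read_deg_table <- function(path,
                           colmap = c(gene = "gene", log2fc = "log2fc",
                                      pval = "pval", padj = "padj"),
                           sep = ",") {
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("gene", "log2fc", "pval")
  if (!all(need %in% names(colmap)))
    stop("colmap must name at least the gene, log2fc and pval columns")
  missing_cols <- setdiff(colmap[intersect(names(colmap), c(need, "padj"))], names(raw))
  if (length(missing_cols))
    stop("columns not found in file: ", paste(missing_cols, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  tab <- data.frame(
    gene = raw[[colmap[["gene"]]]],
    log2fc = num(raw[[colmap[["log2fc"]]]]),
    pval = num(raw[[colmap[["pval"]]]]),
    padj = if ("padj" %in% names(colmap)) num(raw[[colmap[["padj"]]]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  # padj may legitimately be NA (absent / filtered); the other fields may not
  bad <- !is.finite(tab$log2fc) | is.na(tab$pval)
  if (any(bad)) {
    message(sprintf("read_deg_table: dropped %d row(s) with unparseable numeric fields", sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (any(tab$pval < 0 | tab$pval > 1, na.rm = TRUE) ||
      any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  dup <- unique(tab$gene[duplicated(tab$gene)])
  if (length(dup))
    stop("duplicate gene symbols in DEG table: ",
         paste(utils::head(dup, 10), collapse = ", "),
         if (length(dup) > 10) ", ..." else "")
  rownames(tab) <- NULL
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Upper-case gene symbols in a signature or character vector
#'
#' Symbol matching throughout the package is case-sensitive; this explicit
#' normalization pass upper-cases symbols for data sources that use mixed
#' case (human symbols are conventionally upper-case).
#'
#' @param x a `signature` or character vector.
#' @return same type as `x` with upper-cased symbols.
#' @export
normalize_symbols <- function(x) {
  if (inherits(x, "gene_signature"))
    return(gene_signature(x$name, toupper(x$genes), direction = unname(x$direction)))
  toupper(x)
}
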