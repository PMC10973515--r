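#' Gene signature: a named, ordered set of gene symbols
#'
#' @param name signature name.
#' @param genes character vector of gene symbols; duplicates are dropped
#'   (first occurrence kept) with a warning.
#' @param direction optional per-gene direction labels, `"up"` or `"down"`,
#'   same length as `genes` (after deduplication the label of the first
#'   occurrence is kept).
#'
#' @return An object of class `signature`: list with `name`, `genes` and
#'   optionally `direction` (named by gene).
#' @export
gene_signature <- function(name, genes, direction = NULL) {
  genes <- as.character(genes)
  if (!is.null(direction)) {
    if (length(direction) != length(genes))
      stop("direction must have one label per gene")
    if (!all(direction %in% c("up", "down")))
      stop("direction labels must be 'up' or 'down'")
  }
  dup <- duplicated(genes)
  if (any(dup)) {
    warning(sprintf("signature '%s': %d duplicate gene symbol(s) dropped", name, sum(dup)))
    if (!is.null(direction)) direction <- direction[!dup]
    genes <- genes[!dup]
  }
  if (!is.null(direction)) names(direction) <- genes
  structure(list(name = as.character(name), genes = genes, direction = direction),
            class = "gene_signature")
}

as_signature <- function(x, name = "signature") {
  if (inherits(x, "gene_signature")) return(x)
  if (is.character(x)) return(gene_signature(name, x))
  stop("cannot interpret object as a gene signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("signature '%s': %d genes%s\n", x$name, length(x$genes),
              if (is.null(x$direction)) "" else
                sprintf(" (%d up / %d down)", sum(x$direction == "up"),
                        sum(x$direction == "down"))))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)
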