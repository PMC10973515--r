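#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps `stats::p.adjust(method = "BH")` with input validation: sort the
#' p-values, multiply `p[(i)]` by `m/i`, enforce monotonicity from the
#' largest rank down, cap at 1, and return in input order.  `NA` entries are
#' propagated.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Differential-expression cutoffs
#'
#' Defaults follow the usual stringent convention for hypoxia contrasts:
#' absolute log2 fold-change above 1 (strict) and adjusted p below 0.01
#' (strict).
#'
#' @param min_abs_log2fc log2 fold-change magnitude threshold (strict `>`).
#' @param max_padj adjusted-p threshold (strict `<`).
#' @return a `deg_cutoffs` list.
#' @export
deg_cutoffs <- function(min_abs_log2fc = 1, max_padj = 0.01) {
  stopifnot(min_abs_log2fc > 0, max_padj > 0)
  structure(list(min_abs_log2fc = min_abs_log2fc, max_padj = max_padj),
            class = "deg_cutoffs")
}

#' Filter a DEG table into a directed signature
#'
#' Selects genes with `|log2fc| > min_abs_log2fc` and `padj < max_padj`
#' (both strict; a gene at exactly log2FC = 1 is excluded).  When the table
#' carries no adjusted p-values at all they are computed from the raw
#' p-values with [bh_adjust()]; genes whose `padj` is `NA` (e.g. filtered
#' upstream) never pass.
#'
#' @param tab a `deg_table` (see [read_deg_table()]) or data.frame with
#'   columns `gene`, `log2fc`, `pval`, optionally `padj`.
#' @param cut a [deg_cutoffs()].
#' @param name name for the resulting signature.
#' @return a [gene_signature()] with per-gene `direction` (`"up"` if
#'   `log2fc > 0`, else `"down"`), in the table's gene order.
#' @export
filter_degs <- function(tab, cut = deg_cutoffs(), name = "DEGs") {
  stopifnot(all(c("gene", "log2fc", "pval") %in% names(tab)))
  padj <- if ("padj" %in% names(tab)) tab$padj else rep(NA_real_, nrow(tab))
  if (all(is.na(padj))) padj <- bh_adjust(tab$pval)
  hit <- !is.na(padj) & abs(tab$log2fc) > cut$min_abs_log2fc & padj < cut$max_padj
  gene_signature(name, tab$gene[hit],
                 direction = ifelse(tab$log2fc[hit] > 0, "up", "down"))
}

#' Derive the shared directed signature of two DEG contrasts
#'
#' Intersects two direction-labelled signatures by gene symbol, excludes
#' genes whose direction disagrees between the contrasts ("opposing
#' directionality"), and extracts the up-regulated subset, which is the
#' shared hypoxia signature used for per-cell scoring.
#'
#' @param a,b [gene_signature()] objects carrying direction labels.
#' @param name name for the shared signature (`"_up"` appended for the
#'   up-regulated subset).
#' @return list with elements `shared` (concordant intersection, directed),
#'   `up_only` (its up-regulated subset), and `n_overlap` (size of the raw
#'   symbol intersection before the directionality exclusion).
#' @export
derive_shared_signature <- function(a, b, name = "shared") {
  if (is.null(a$direction) || is.null(b$direction))
    stop("both signatures must carry direction labels")
  common <- intersect(a$genes, b$genes)
  concordant <- common[a$direction[common] == b$direction[common]]
  shared <- gene_signature(name, concordant, direction = unname(a$direction[concordant]))
  up <- shared$genes[shared$direction == "up"]
  list(shared = shared,
       up_only = gene_signature(paste0(name, "_up"), up),
       n_overlap = length(common))
}

#' Overlap between two gene signatures
#'
#' @param a,b [gene_signature()] objects or character vectors.
#' @return list with `k` (intersection size) and `jaccard`
#'   (`k / |union|`; 0 when both sets are empty).
#' @export
signature_overlap <- function(a, b) {
  ga <- unique(as_signature(a)$genes); gb <- unique(as_signature(b)$genes)
  k <- length(intersect(ga, gb))
  u <- length(union(ga, gb))
  list(k = k, jaccard = if (u == 0) 0 else k / u)
}

#' Over-representation analysis with the odds-ratio x (-ln p) combined score
#'
#' For each library set, computes the hypergeometric upper-tail p-value of
#' observing at least the seen overlap between the query and the set within
#' the gene universe, the odds ratio of the 2x2 membership table (Haldane
#' 0.5 correction applied when any cell is zero), and the combined score
#' `odds_ratio * (-ln p)` used for ranking.  P-values are BH-adjusted
#' across the library.
#'
#' @param query a [gene_signature()] or character vector of query genes.
#'   Genes outside the universe are dropped with a warning.
#' @param library a list of [gene_signature()] objects (the gene-set
#'   library); set members outside the universe are ignored.
#' @param universe character vector of background gene symbols (typically
#'   the genes detected in the expression matrix).
#' @return data.frame with one row per library set: `set_name`,
#'   `overlap_k`, `set_size`, `query_size`, `universe_size`, `pval`,
#'   `padj`, `odds_ratio`, `combined_score`, sorted by combined score
#'   descending.
#' @export
ora_enrich <- function(query, library, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  q <- unique(as_signature(query, "query")$genes)
  outside <- setdiff(q, universe)
  if (length(outside)) {
    warning(sprintf("ora_enrich: %d query gene(s) outside the universe dropped", length(outside)))
    q <- intersect(q, universe)
  }
  if (!length(q)) stop("empty query after restricting to the universe")
  if (inherits(library, "gene_signature")) library <- list(library)
  N <- length(universe); n <- length(q)
  res <- lapply(library, function(s) {
    set <- intersect(unique(s$genes), universe)
    K <- length(set)
    k <- length(intersect(set, q))
    # P(X >= k), X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * cc)
    data.frame(set_name = s$name, overlap_k = k, set_size = K, query_size = n,
               universe_size = N, pval = p, odds_ratio = or,
               combined_score = or * (-log(p)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$pval)
  out <- out[order(-out$combined_score), c("set_name", "overlap_k", "set_size",
                                           "query_size", "universe_size", "pval",
                                           "padj", "odds_ratio", "combined_score")]
  rownames(out) <- NULL
  out
}
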