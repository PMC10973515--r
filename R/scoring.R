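#' Module-score parameters
#'
#' `n_bins` expression bins and `n_ctrl` control genes per signature gene,
#' the conventional defaults for binned-control module scoring (24 bins,
#' 100 controls).  `seed` keys the deterministic control sampling (see
#' [module_score()]).
#'
#' @param n_bins number of equal-frequency average-expression bins.
#' @param n_ctrl control genes sampled (with replacement) per signature gene.
#' @param seed integer seed for control sampling.
#' @return a `score_params` list.
#' @export
score_params <- function(n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(n_bins >= 1, n_ctrl >= 1)
  structure(list(n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed)), class = "score_params")
}

# Deterministic 31-adic string hash modulo 2^31 - 1.  Exact in double
# arithmetic (intermediate values stay below 2^53).
str_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

# Control-draw seed for one (seed, signature, gene) triple.  Keying the
# stream by gene identity (not gene index) makes scores invariant to gene
# and cell permutations of the input matrix.
ctrl_seed <- function(seed, sig_name, gene) {
  ((seed %% 2147483647) * 7919 + str_hash(sig_name) * 31 + str_hash(gene)) %% 2147483647
}

# Sample `n` values from `pool` with replacement under a local seed,
# leaving the caller's RNG state untouched.
seeded_sample <- function(pool, n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  pool[sample.int(length(pool), n, replace = TRUE)]
}

# Candidate control genes for signature gene `g`: members of its
# average-expression bin, excluding all signature genes.  If a bin holds
# only signature genes, widen to the nearest bin (lower bin preferred on
# ties) that has non-signature members.
control_pool <- function(bin, g, sig_idx) {
  n_b <- max(bin)
  b <- bin[g]
  for (d in 0:n_b) {
    for (bb in unique(c(b - d, b + d))) {
      if (bb < 1 || bb > n_b) next
      pool <- setdiff(which(bin == bb), sig_idx)
      if (length(pool)) return(pool)
    }
  }
  stop("no control genes available outside the signature")
}

# Equal-frequency bin assignment on average expression; ties broken by
# gene-name order for determinism.
expression_bins <- function(avg, gene_names, n_bins) {
  n <- length(avg)
  ord <- order(avg, gene_names)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  bin
}

#' Per-cell module score for a gene signature with binned control genes
#'
#' Scores each cell for a gene set on the log-normalized layer:
#' \enumerate{
#'   \item average each gene's log-normalized expression across all cells;
#'   \item rank genes by this average and cut into `n_bins`
#'     equal-frequency bins (ties broken by gene name);
#'   \item for each signature gene, draw `n_ctrl` control genes uniformly
#'     with replacement from its bin, excluding signature genes;
#'   \item score(cell) = mean log-normalized expression over the signature
#'     genes minus the mean over the pooled control draws.
#' }
#' Control draws are seeded per `(seed, signature name, gene symbol)`, so
#' scores are reproducible and invariant to gene and cell order; the exact
#' random stream of other implementations of this scheme is deliberately
#' not reproduced.  Signature genes absent from the matrix are dropped with
#' a warning; if none are present this is an error.
#'
#' @param cells a [cell_matrix()] with the `lognorm` layer present
#'   (see [log_normalize()]).
#' @param sig a [gene_signature()] or character vector of gene symbols.
#' @param params a [score_params()].
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(cells, sig, params = score_params()) {
  stopifnot(inherits(cells, "cell_matrix"))
  ln <- cells$lognorm
  if (is.null(ln)) stop("lognorm layer missing; run log_normalize() first")
  sig <- as_signature(sig)
  idx <- match(unique(sig$genes), rownames(ln))
  if (anyNA(idx)) {
    miss <- sum(is.na(idx))
    if (miss == length(idx))
      stop(sprintf("no gene of signature '%s' present in the matrix", sig$name))
    warning(sprintf("module_score: %d gene(s) of signature '%s' absent from matrix, dropped",
                    miss, sig$name))
    idx <- idx[!is.na(idx)]
  }
  avg <- Matrix::rowMeans(ln)
  bin <- expression_bins(avg, rownames(ln), params$n_bins)
  w <- numeric(nrow(ln))
  for (g in idx) {
    pool <- control_pool(bin, g, idx)
    # canonical name order so draws do not depend on matrix row order
    pool <- pool[order(rownames(ln)[pool])]
    draws <- seeded_sample(pool, params$n_ctrl,
                           ctrl_seed(params$seed, sig$name, rownames(ln)[g]))
    w <- w + tabulate(draws, nbins = nrow(ln))
  }
  sig_mean <- Matrix::colMeans(ln[idx, , drop = FALSE])
  ctrl_mean <- as.numeric(w %*% ln) / sum(w)
  score <- as.numeric(sig_mean) - ctrl_mean
  names(score) <- colnames(ln)
  score
}

.state_set_names <- c("MES1", "MES2", "AC", "OPC", "NPC1", "NPC2")
.state_collapse <- c(MES1 = "MES", MES2 = "MES", AC = "AC", OPC = "OPC",
                     NPC1 = "NPC", NPC2 = "NPC")

#' Score and assign Neftel cellular states
#'
#' Computes six module scores (MES1, MES2, AC, OPC, NPC1, NPC2) per cell,
#' assigns `state_raw` as the argmax (ties broken by the fixed order
#' MES1 < MES2 < AC < OPC < NPC1 < NPC2 and reported via `message()`), and
#' collapses MES1/MES2 to MES and NPC1/NPC2 to NPC.
#'
#' @param cells a [cell_matrix()] with `lognorm` present.
#' @param neftel_sets list of six [gene_signature()]s named `MES1`, `MES2`,
#'   `AC`, `OPC`, `NPC1`, `NPC2`.
#' @param params a [score_params()].
#' @return list with `scores` (cells x 6 matrix), `state_raw` and `state`
#'   (character vectors per cell).
#' @export
score_states <- function(cells, neftel_sets, params = score_params()) {
  if (!all(.state_set_names %in% names(neftel_sets)))
    stop("neftel_sets must contain the six sets ",
         paste(.state_set_names, collapse = ", "))
  scores <- sapply(.state_set_names, function(nm) {
    s <- neftel_sets[[nm]]
    s$name <- nm
    module_score(cells, s, params)
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(colnames(cells$counts),
                                                             .state_set_names))
  top <- max.col(scores, ties.method = "first")
  n_tie <- sum(rowSums(scores == scores[cbind(seq_len(nrow(scores)), top)]) > 1)
  if (n_tie > 0)
    message(sprintf("score_states: %d cell(s) with tied top scores, first label in fixed order used", n_tie))
  state_raw <- .state_set_names[top]
  list(scores = scores, state_raw = state_raw,
       state = unname(.state_collapse[state_raw]))
}

#' Two-dimensional Neftel state-plot coordinates
#'
#' Computes the quadrant-plot coordinates from the six state scores:
#' `y = max(OPC, NPCmax) - max(AC, MESmax)` with `NPCmax = max(NPC1, NPC2)`
#' and `MESmax = max(MES1, MES2)`.  The x coordinate is the sign-encoded
#' log of the within-hemisphere score difference: for `y > 0`,
#' `d = NPCmax - OPC` (NPC plotted to the right, OPC to the left); for
#' `y <= 0`, `d = MESmax - AC` (MES right, AC left);
#' `x = sign(d) * log2(|d| + 1)`.
#'
#' @param scores cells x 6 score matrix with columns `MES1`, `MES2`, `AC`,
#'   `OPC`, `NPC1`, `NPC2` (as returned by [score_states()]).
#' @return data.frame with `coord_x`, `coord_y` per cell.
#' @export
state_coordinates <- function(scores) {
  if (!all(.state_set_names %in% colnames(scores)))
    stop("scores must have columns ", paste(.state_set_names, collapse = ", "))
  npc <- pmax(scores[, "NPC1"], scores[, "NPC2"])
  mes <- pmax(scores[, "MES1"], scores[, "MES2"])
  y <- pmax(scores[, "OPC"], npc) - pmax(scores[, "AC"], mes)
  d <- ifelse(y > 0, npc - scores[, "OPC"], mes - scores[, "AC"])
  data.frame(coord_x = sign(d) * log2(abs(d) + 1), coord_y = as.numeric(y))
}
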