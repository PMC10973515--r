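# Independent, loop-based oracle implementations used to verify the
# package's vectorized code paths.  These are deliberately written
# step-by-step from the procedure definitions, not by calling the package.

# --- binned-control module score, brute force over dense matrices --------
oracle_str_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

oracle_module_score <- function(lognorm, sig_genes, sig_name, n_bins, n_ctrl, seed) {
  lognorm <- as.matrix(lognorm)
  gn <- rownames(lognorm)
  n <- nrow(lognorm)
  avg <- numeric(n)
  for (g in seq_len(n)) avg[g] <- mean(lognorm[g, ])
  ord <- order(avg, gn)
  bin <- integer(n)
  for (pos in seq_len(n)) bin[ord[pos]] <- ceiling(pos * n_bins / n)
  sig_idx <- match(sig_genes, gn)
  sig_idx <- sig_idx[!is.na(sig_idx)]
  draws <- integer(0)
  for (g in sig_idx) {
    pool <- integer(0)
    for (d in 0:max(bin)) {
      for (bb in unique(c(bin[g] - d, bin[g] + d))) {
        if (bb < 1 || bb > max(bin)) next
        cand <- setdiff(which(bin == bb), sig_idx)
        if (length(cand)) { pool <- cand; break }
      }
      if (length(pool)) break
    }
    pool <- pool[order(gn[pool])]       # canonical name order
    h <- ((seed %% 2147483647) * 7919 + oracle_str_hash(sig_name) * 31 +
            oracle_str_hash(gn[g])) %% 2147483647
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(h)
    draws <- c(draws, pool[sample.int(length(pool), n_ctrl, replace = TRUE)])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  score <- numeric(ncol(lognorm))
  for (cell in seq_len(ncol(lognorm)))
    score[cell] <- mean(lognorm[sig_idx, cell]) - mean(lognorm[draws, cell])
  score
}

# --- Benjamini-Hochberg step-up, by the textbook recipe ------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, (m / i) * p[o[i]])
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# --- hypergeometric upper tail by exhaustive enumeration -----------------
# P(|Q ∩ S| >= k) over all query draws of size n from a universe of size N
# containing a set S of size K.
oracle_hyper_enum <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  hits <- 0
  for (j in seq_len(ncol(sets)))
    if (sum(sets[, j] <= K) >= k) hits <- hits + 1
  hits / ncol(sets)
}

# --- exact two-sided rank-sum p by enumeration of allocations ------------
# Mann-Whitney U for sample `a` against `b`, doubling rule with cap at 1,
# lower tail used at the exact centre (mirrors the convention of the
# implementation under test).
oracle_ranksum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  alloc <- utils::combn(na + nb, na)
  u_all <- apply(alloc, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- if (u_obs > na * nb / 2) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# --- small random fixtures ----------------------------------------------
random_cells <- function(n_genes, n_cells, seed, lambda = 5) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells,
                   dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                   sprintf("C%03d", seq_len(n_cells))))
  log_normalize(cell_matrix(counts))
}

# lognorm layer set directly (counts are placeholders)
cells_with_lognorm <- function(lognorm) {
  counts <- matrix(1, nrow(lognorm), ncol(lognorm), dimnames = dimnames(lognorm))
  cell_matrix(counts, lognorm = lognorm)
}
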