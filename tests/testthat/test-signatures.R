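test_that("BH adjustment matches the hand-computed step-up on the worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the step-up oracle and dominates the input", {
  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_identical(adj, oracle_bh(p))
    expect_true(all(adj >= p))
  }
})

test_that("DEG filtering applies strict cutoffs and direction labels", {
  tab <- data.frame(gene = c("A", "B", "C", "D"),
                    log2fc = c(1.0, -1.5, 2.0, 3.0),
                    pval = c(1e-5, 1e-5, 1e-5, 0.5),
                    padj = c(1e-4, 1e-3, 0.01, 0.9))
  sig <- filter_degs(tab)
  expect_identical(sig$genes, "B")          # A: fc == 1 excluded; C: padj == 0.01 excluded
  expect_identical(unname(sig$direction), "down")
})

test_that("DEG filtering shrinks as either cutoff tightens", {
  bulk <- simulate_bulk_contrast(n_universe = 800, n_shared_up = 60, n_shared_down = 20,
                                 n_opposing = 2, n_unique_a_up = 30, n_unique_a_down = 10,
                                 n_unique_b_up = 30, n_unique_b_down = 10, seed = 33)
  tab <- bulk$a
  base <- filter_degs(tab, deg_cutoffs(1, 0.01))
  for (cut in list(deg_cutoffs(1.5, 0.01), deg_cutoffs(1, 0.001), deg_cutoffs(2, 1e-4))) {
    tighter <- filter_degs(tab, cut)
    expect_true(all(tighter$genes %in% base$genes))
  }
  # padj computed from pval when the column is absent
  no_padj <- filter_degs(tab[, c("gene", "log2fc", "pval")])
  with_padj <- filter_degs(data.frame(tab[, c("gene", "log2fc", "pval")],
                                      padj = bh_adjust(tab$pval)))
  expect_identical(no_padj$genes, with_padj$genes)
})

test_that("shared-signature derivation is symmetric and its up set is nested", {
  a <- gene_signature("a", c("G1", "G2", "G3", "G4"),
                      direction = c("up", "up", "down", "up"))
  b <- gene_signature("b", c("G2", "G3", "G4", "G5"),
                      direction = c("up", "down", "down", "up"))
  sh <- derive_shared_signature(a, b)
  expect_equal(sh$n_overlap, 3)                       # G2 G3 G4
  expect_identical(sh$shared$genes, c("G2", "G3"))    # G4 opposes
  expect_identical(sh$up_only$genes, "G2")
  # symmetry as sets
  sh2 <- derive_shared_signature(b, a)
  expect_setequal(sh2$shared$genes, sh$shared$genes)
  expect_setequal(sh2$up_only$genes, sh$up_only$genes)
  expect_true(all(sh$up_only$genes %in% sh$shared$genes))
  # identity and disjoint edge cases
  self <- derive_shared_signature(a, a)
  expect_identical(self$shared$genes, a$genes)
  expect_identical(self$up_only$genes, c("G1", "G2", "G4"))
  dis <- derive_shared_signature(a, gene_signature("z", "ZZ", direction = "up"))
  expect_length(dis$shared, 0)
  expect_error(derive_shared_signature(a, gene_signature("n", "G1")), "direction")
})

test_that("signature overlap counts and Jaccard behave on edge cases", {
  a <- gene_signature("a", sprintf("G%d", 1:10))
  expect_equal(signature_overlap(a, a), list(k = 10, jaccard = 1))
  b <- gene_signature("b", sprintf("H%d", 1:5))
  expect_equal(signature_overlap(a, b), list(k = 0, jaccard = 0))
  c <- gene_signature("c", sprintf("G%d", 6:15))
  expect_equal(signature_overlap(a, c)$k, 5)
  expect_equal(signature_overlap(a, c)$jaccard, 5 / 15)
})

test_that("hypergeometric enrichment matches closed form and exhaustive enumeration", {
  # full-overlap closed form: universe 20, set 5, query 5, overlap 5
  universe <- sprintf("U%02d", 1:20)
  res <- ora_enrich(gene_signature("q", universe[1:5]),
                    list(gene_signature("S", universe[1:5])), universe)
  expect_equal(res$pval, 1 / choose(20, 5), tolerance = 1e-12)

  # enumeration oracle over small universes, including zero overlap
  cases <- list(c(N = 12, K = 4, n = 5, k = 2), c(N = 10, K = 3, n = 4, k = 0),
                c(N = 15, K = 6, n = 4, k = 3), c(N = 20, K = 5, n = 5, k = 1))
  for (cs in cases) {
    universe <- sprintf("U%02d", seq_len(cs[["N"]]))
    set <- universe[seq_len(cs[["K"]])]
    query <- c(universe[seq_len(cs[["k"]])],
               rev(setdiff(universe, set))[seq_len(cs[["n"]] - cs[["k"]])])
    res <- ora_enrich(gene_signature("q", query), list(gene_signature("S", set)), universe)
    expect_equal(res$overlap_k, unname(cs[["k"]]))
    expect_equal(res$pval,
                 oracle_hyper_enum(cs[["N"]], cs[["K"]], cs[["n"]], cs[["k"]]),
                 tolerance = 1e-12)
  }
})

test_that("the combined score is the odds ratio times -ln p", {
  universe <- sprintf("U%02d", 1:40)
  lib <- list(gene_signature("S1", universe[1:10]),
              gene_signature("S2", universe[11:14]),
              gene_signature("S3", universe[c(1:3, 20:25)]))
  res <- ora_enrich(gene_signature("q", universe[c(1:6, 30:33)]), lib, universe)
  expect_equal(res$combined_score, res$odds_ratio * (-log(res$pval)), tolerance = 1e-12)
  expect_true(all(diff(res$combined_score) <= 0))   # sorted descending
  expect_true(all(res$combined_score >= 0))
  expect_equal(res$padj[order(res$set_name)],
               bh_adjust(res$pval[order(res$set_name)]))
  # Haldane correction keeps zero-cell tables finite
  z <- ora_enrich(gene_signature("q", universe[1:4]),
                  list(gene_signature("S", universe[30:35])), universe)
  expect_true(is.finite(z$odds_ratio) && z$odds_ratio > 0)
  expect_error(ora_enrich(gene_signature("q", character(0)), lib, universe))
  expect_warning(ora_enrich(gene_signature("q", c(universe[1:3], "ELSEWHERE")), lib, universe),
                 "outside the universe")
})
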