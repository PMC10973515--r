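small_cfg <- function(seed = 11, ...) {
  sim_config(n_patients = 2, idh_status = c("WT", "MUT"),
             n_cells_per_patient = 400, seed = seed, ...)
}

test_that("simulation is bit-identical for the same seed and differs across seeds", {
  a <- simulate_cells(small_cfg())
  b <- simulate_cells(small_cfg())
  expect_identical(as.matrix(a$cells$counts), as.matrix(b$cells$counts))
  expect_identical(a$truth, b$truth)
  c <- simulate_cells(small_cfg(seed = 12))
  expect_false(identical(as.matrix(a$cells$counts), as.matrix(c$cells$counts)))
})

test_that("with zero effects and no hypoxia, no gene separates the state groups", {
  cfg <- small_cfg(program_effect = 0, hypoxia_effect = 0, hypoxia_fraction = 0,
                   marker_hypoxic_mean = 0.05)
  sim <- simulate_cells(cfg)
  expect_false(any(sim$truth$cell$true_hypoxic))
  x <- as.matrix(sim$cells$counts)
  g1 <- sim$truth$cell$true_state == "MES"
  g2 <- sim$truth$cell$true_state == "NPC"
  # vectorized pooled-variance t per gene; p-values should be uniform
  m1 <- rowMeans(x[, g1]); m2 <- rowMeans(x[, g2])
  v1 <- apply(x[, g1], 1, var); v2 <- apply(x[, g2], 1, var)
  tt <- (m1 - m2) / sqrt(v1 / sum(g1) + v2 / sum(g2))
  p <- 2 * pnorm(-abs(tt))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted hypoxia fraction and state shift match their binomial targets", {
  cohort <- main_sim()
  tr <- cohort$truth$cell
  n <- nrow(tr)
  # 99% binomial CI around f = 0.04
  expect_lt(abs(mean(tr$true_hypoxic) - 0.04),
            2.576 * sqrt(0.04 * 0.96 / n))
  # WT hypoxic cells redrawn with P(MES) = 0.75
  wt_h <- tr$true_hypoxic & tr$idh_status == "WT"
  expect_lt(abs(mean(tr$true_state[wt_h] == "MES") - 0.75),
            2.576 * sqrt(0.75 * 0.25 / sum(wt_h)))
})

test_that("marginal count moments match the configured negative binomial", {
  # mitochondrial genes have a fixed mean, giving a known NB target
  cfg <- sim_config(n_patients = 1, idh_status = "WT", n_cells_per_patient = 5000,
                    n_mito_genes = 20, mito_mean = 20, nb_dispersion = 2,
                    hypoxia_fraction = 0, seed = 3)
  sim <- simulate_cells(cfg)
  mt <- as.matrix(sim$cells$counts[startsWith(rownames(sim$cells$counts), "MT-"), ])
  draws <- as.numeric(mt)  # 1e5 draws
  mu <- 20; size <- 2
  v <- mu + mu^2 / size
  expect_lt(abs(mean(draws) - mu), 4 * sqrt(v / length(draws)))
  expect_lt(abs(var(draws) / v - 1), 0.1)
})

test_that("program genes outside the gene universe are impossible by construction", {
  cfg <- small_cfg()
  gt <- simulate_cells(cfg)$truth$gene
  expect_equal(sum(gt$program %in% c("MES", "AC", "OPC", "NPC")), 4 * cfg$n_program_genes)
  expect_setequal(unique(gt$program),
                  c("MES", "AC", "OPC", "NPC", "hypoxia", "marker", "mito", "background"))
  expect_error(sim_config(n_genes = 100), "n_genes")
})

test_that("invalid probability vectors are rejected", {
  expect_error(sim_config(state_priors = c(MES = 0.5, AC = 0.5, OPC = 0.1, NPC = 0)),
               "summing to 1")
  expect_error(sim_config(hypoxia_fraction = 1.5))
})

test_that("bulk contrasts plant the requested structure and pass table invariants", {
  bulk <- simulate_bulk_contrast(seed = 5)
  for (tab in list(bulk$a, bulk$b)) {
    expect_false(anyDuplicated(tab$gene) > 0)
    expect_true(all(tab$pval >= 0 & tab$pval <= 1))
    expect_true(all(tab$padj >= 0 & tab$padj <= 1))
    expect_true(all(is.finite(tab$log2fc)))
  }
  # planted genes with log2FC magnitude 4 and tiny replicate noise all pass |fc| > 1
  planted_a <- with(bulk$truth, c(shared_up, shared_down, opposing, unique_a_up, unique_a_down))
  expect_true(all(abs(bulk$a$log2fc[bulk$a$gene %in% planted_a]) > 1))
  # determinism
  again <- simulate_bulk_contrast(seed = 5)
  expect_identical(bulk$a, again$a)
})

test_that("a null bulk contrast yields no DEGs at the stated cutoffs", {
  bulk <- simulate_bulk_contrast(n_shared_up = 0, n_shared_down = 0, n_opposing = 0,
                                 n_unique_a_up = 0, n_unique_a_down = 0,
                                 n_unique_b_up = 0, n_unique_b_down = 0,
                                 n_universe = 1000, seed = 8)
  expect_length(filter_degs(bulk$a), 0)
  expect_length(filter_degs(bulk$b), 0)
})
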