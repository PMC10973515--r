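#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds (a) the single-cell glioma cohort — 11 patients (5 IDH-WT, 6
# IDH-MUT), ~30,000 cells, a 4% planted hypoxia program, a VEGFA-like
# hypoxia marker and four planted state programs — and (b) writes it out
# as a 10x-style MTX triplet with cell metadata, the planted truth table,
# and a GMT of the planted gene programs, so the later stages can run from
# files exactly as they would on a public dataset.

suppressMessages(library(hypoxiaShift))

seed <- 20240915
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_cells(cfg)
print(sim$cells)

write_mtx_triplet(sim$cells, out)
write.csv(sim$truth$cell, file.path(out, "truth_cells.csv"), row.names = FALSE)
write.csv(sim$truth$gene, file.path(out, "truth_genes.csv"), row.names = FALSE)

sets <- state_signatures(sim$truth$gene)
hyp <- gene_signature("hypoxia",
                      sim$truth$gene$gene[sim$truth$gene$program == "hypoxia"])
write_gmt(c(list(hypoxia = hyp), sets), file.path(out, "programs.gmt"))

cat(sprintf("cohort: %d cells, %d genes, %.1f%% planted hypoxic\n",
            n_cells(sim$cells), n_genes(sim$cells),
            100 * mean(sim$truth$cell$true_hypoxic)))
cat("wrote MTX triplet, truth tables and programs.gmt under", out, "\n")
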