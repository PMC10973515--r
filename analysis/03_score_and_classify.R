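#!/usr/bin/env Rscript
# Stage 3: score single cells and classify hypoxia.
#
# Reads the cohort written by 01_simulate_cohort.R from its MTX triplet
# (exercising the same file path a public dataset would take), applies the
# QC gates (>= 1000 UMIs, >= 400 genes, <= 25% mitochondrial), log
# normalizes, scores the hypoxia program with binned-control module
# scores, sweeps the threshold grid against the VEGFA-positive fraction
# (>= 2 UMIs), classifies cells, and assigns Neftel states.

suppressMessages(library(hypoxiaShift))

sim_dir <- "results/sim"
out <- "results/scores"
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate_cohort.R first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cells <- read_mtx_triplet(sim_dir)
sigs <- read_gmt(file.path(sim_dir, "programs.gmt"))

cells <- filter_cells(cells)
write.csv(attr(cells, "qc_report"), file.path(out, "qc_report.csv"), row.names = FALSE)
cells <- log_normalize(cells)

res <- annotate_cells(cells, sigs$hypoxia,
                      sigs[c("MES1", "MES2", "AC", "OPC", "NPC1", "NPC2")],
                      params = score_params(seed = 20240915))
print(res$calibration)
write.csv(res$calibration$table, file.path(out, "calibration.csv"), row.names = FALSE)
write.csv(res$annotation, file.path(out, "cell_annotations.csv"), row.names = FALSE)

cat(sprintf("classified %.2f%% of %d cells as hypoxic (threshold %.2f, VEGFA+ %.2f%%)\n",
            100 * mean(res$annotation$hypoxic), nrow(res$annotation),
            res$calibration$chosen, 100 * res$calibration$marker_fraction))
print(table(res$annotation$state))
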