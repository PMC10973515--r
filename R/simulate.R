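# Run an expression with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of the synthetic glioma single-cell cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: per-patient negative-binomial UMI counts (variance
#' `mu + mu^2 / size`), four planted cell-state expression programs
#' (MES/AC/OPC/NPC), a planted hypoxia program active in a small fraction
#' of cells, a hypoxia-coupled VEGFA-like marker gene, mitochondrial genes
#' for QC, and IDH-status-dependent coupling between hypoxia and state
#' membership (hypoxic cells in wildtype patients shift mainly to MES, in
#' mutant patients to AC).
#'
#' Defaults describe an 11-patient high-grade glioma cohort (5 IDH-WT,
#' 6 IDH-MUT, about 30,000 cells), a hypoxic fraction of 4% per patient,
#' baseline state frequencies of roughly 25/21/17/38% (MES/AC/OPC/NPC),
#' and hypoxia-conditional state distributions whose patient-weighted
#' pooled composition approximates 48/26/7/19%.
#'
#' @param n_patients number of patients.
#' @param idh_status per-patient IDH label, `"WT"` or `"MUT"`.
#' @param n_cells_per_patient cells per patient (scalar or per-patient
#'   vector).
#' @param n_genes total genes, including program, marker and mitochondrial
#'   genes.
#' @param baseline_log_mean `c(meanlog=, sdlog=)` of the log-normal from
#'   which per-gene baseline NB means are drawn.
#' @param nb_dispersion NB size parameter (variance `mu + mu^2/size`).
#' @param n_program_genes genes per state program and per hypoxia program.
#' @param program_effect natural-log fold boost of state-program genes in
#'   cells of that state.
#' @param hypoxia_effect natural-log fold boost of hypoxia-program genes in
#'   hypoxic cells.
#' @param hypoxia_fraction probability a cell is hypoxic (scalar or
#'   per-patient).
#' @param state_priors baseline state probabilities (named, sum to 1).
#' @param hypoxia_state_shift list with elements `WT` and `MUT`: state
#'   probabilities for hypoxic cells in each IDH group (each sums to 1).
#' @param marker_gene symbol of the hypoxia-coupled marker gene.
#' @param marker_base_mean,marker_hypoxic_mean marker NB mean in
#'   non-hypoxic / hypoxic cells.
#' @param n_mito_genes,mito_mean mitochondrial gene count and per-gene NB
#'   mean (symbols prefixed `MT-`).
#' @param seed integer seed; all draws derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 11,
                       idh_status = rep(c("WT", "MUT"), c(5, 6)),
                       n_cells_per_patient = 2727,
                       n_genes = 600,
                       baseline_log_mean = c(meanlog = log(2), sdlog = 1),
                       nb_dispersion = 2,
                       n_program_genes = 40,
                       program_effect = 1.2,
                       hypoxia_effect = 1.5,
                       hypoxia_fraction = 0.04,
                       state_priors = c(MES = 0.249, AC = 0.209,
                                        OPC = 0.165, NPC = 0.376) / 0.999,
                       hypoxia_state_shift = list(
                         WT = c(MES = 0.75, AC = 0.05, OPC = 0.03, NPC = 0.17),
                         MUT = c(MES = 0.2513, AC = 0.4313,
                                 OPC = 0.1070, NPC = 0.2067) / 0.9963),
                       marker_gene = "VEGFA",
                       marker_base_mean = 0.05,
                       marker_hypoxic_mean = 10,
                       n_mito_genes = 10,
                       mito_mean = 20,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1,
            length(cfg$idh_status) == cfg$n_patients,
            all(cfg$idh_status %in% c("WT", "MUT")),
            cfg$n_genes >= 4 * cfg$n_program_genes + cfg$n_program_genes +
              cfg$n_mito_genes + 1,
            cfg$nb_dispersion > 0,
            is.finite(cfg$program_effect), is.finite(cfg$hypoxia_effect))
  f <- rep_len(cfg$hypoxia_fraction, cfg$n_patients)
  stopifnot(all(f >= 0 & f <= 1))
  check_prob <- function(p, what) {
    if (!setequal(names(p), .states)) stop(what, " must be named over ", paste(.states, collapse = ", "))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop(what, " must be a probability vector summing to 1 (within 1e-12)")
  }
  check_prob(cfg$state_priors, "state_priors")
  check_prob(cfg$hypoxia_state_shift$WT, "hypoxia_state_shift$WT")
  check_prob(cfg$hypoxia_state_shift$MUT, "hypoxia_state_shift$MUT")
  invisible(cfg)
}

# Gene universe layout: program blocks first, then the marker gene,
# mitochondrial genes, and background genes.
sim_gene_table <- function(cfg) {
  k <- cfg$n_program_genes
  prog <- c(rep(.states, each = k), rep("hypoxia", k))
  gene <- c(sprintf("%s_%02d", rep(.states, each = k), rep(seq_len(k), 4)),
            sprintf("HYP_%02d", seq_len(k)),
            cfg$marker_gene,
            sprintf("MT-%d", seq_len(cfg$n_mito_genes)))
  prog <- c(prog, "marker", rep("mito", cfg$n_mito_genes))
  n_bg <- cfg$n_genes - length(gene)
  gene <- c(gene, sprintf("BG_%04d", seq_len(n_bg)))
  prog <- c(prog, rep("background", n_bg))
  data.frame(gene = gene, program = prog, stringsAsFactors = FALSE)
}

#' Simulate a single-cell glioma cohort with planted programs
#'
#' Draws, for each cell: its patient, a state from the baseline priors,
#' and a hypoxic flag with the per-patient hypoxia probability; hypoxic
#' cells have their state redrawn from the IDH-appropriate
#' hypoxia-conditional distribution.  UMI counts are negative binomial
#' with per-gene baseline means (log-normal across genes) multiplied by
#' `exp(effect)` for the programs active in the cell; the marker gene's
#' mean switches between its non-hypoxic and hypoxic values.  Fully
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `cells` (a [cell_matrix()]) and `truth` (list with
#'   per-cell data.frame `cell`: `cell_id`, `patient`, `idh_status`,
#'   `true_state`, `true_hypoxic`; and per-gene data.frame `gene`:
#'   `gene`, `program`).
#' @export
simulate_cells <- function(config = sim_config()) {
  validate_sim_config(config)
  gt <- sim_gene_table(config)
  with_seed(config$seed, {
    n_per <- rep_len(config$n_cells_per_patient, config$n_patients)
    f <- rep_len(config$hypoxia_fraction, config$n_patients)
    patient_id <- sprintf("P%02d", seq_len(config$n_patients))
    patient <- rep(patient_id, n_per)
    idh <- rep(config$idh_status, n_per)
    n <- length(patient)
    state <- sample(.states, n, replace = TRUE, prob = config$state_priors[.states])
    hyp <- stats::runif(n) < rep(f, n_per)
    for (grp in c("WT", "MUT")) {
      i <- which(hyp & idh == grp)
      if (length(i))
        state[i] <- sample(.states, length(i), replace = TRUE,
                           prob = config$hypoxia_state_shift[[grp]][.states])
    }
    base <- stats::rlnorm(config$n_genes,
                          meanlog = config$baseline_log_mean[["meanlog"]],
                          sdlog = config$baseline_log_mean[["sdlog"]])
    base[gt$program == "marker"] <- config$marker_base_mean
    base[gt$program == "mito"] <- config$mito_mean
    counts <- matrix(0, nrow = config$n_genes, ncol = n)
    for (st in .states) for (h in c(FALSE, TRUE)) {
      cols <- which(state == st & hyp == h)
      if (!length(cols)) next
      mu <- base
      mu[gt$program == st] <- mu[gt$program == st] * exp(config$program_effect)
      if (h) {
        mu[gt$program == "hypoxia"] <- mu[gt$program == "hypoxia"] * exp(config$hypoxia_effect)
        mu[gt$program == "marker"] <- config$marker_hypoxic_mean
      }
      counts[, cols] <- stats::rnbinom(config$n_genes * length(cols),
                                       mu = mu, size = config$nb_dispersion)
    }
    cell_id <- sprintf("%s_C%05d", patient, unlist(lapply(n_per, seq_len)))
    dimnames(counts) <- list(gt$gene, cell_id)
    cells <- cell_matrix(counts, patient = patient, idh_status = idh)
    truth <- list(
      cell = data.frame(cell_id = cell_id, patient = patient, idh_status = idh,
                        true_state = state, true_hypoxic = hyp,
                        stringsAsFactors = FALSE),
      gene = gt)
    list(cells = cells, truth = truth)
  })
}

#' Build the six Neftel-style state signatures from planted programs
#'
#' Splits the planted MES and NPC programs into halves (MES1/MES2,
#' NPC1/NPC2) and uses the full AC and OPC programs, yielding the six sets
#' required by [score_states()].
#'
#' @param truth_gene the per-gene truth table from [simulate_cells()]
#'   (columns `gene`, `program`).
#' @return named list of six [gene_signature()]s.
#' @export
state_signatures <- function(truth_gene) {
  half <- function(g, first) {
    k <- length(g)
    if (first) g[seq_len(ceiling(k / 2))] else g[(ceiling(k / 2) + 1):k]
  }
  mes <- truth_gene$gene[truth_gene$program == "MES"]
  npc <- truth_gene$gene[truth_gene$program == "NPC"]
  list(
    MES1 = gene_signature("MES1", half(mes, TRUE)),
    MES2 = gene_signature("MES2", half(mes, FALSE)),
    AC = gene_signature("AC", truth_gene$gene[truth_gene$program == "AC"]),
    OPC = gene_signature("OPC", truth_gene$gene[truth_gene$program == "OPC"]),
    NPC1 = gene_signature("NPC1", half(npc, TRUE)),
    NPC2 = gene_signature("NPC2", half(npc, FALSE)))
}

#' Simulate two bulk differential-expression contrasts with planted DEGs
#'
#' Generates two hypoxia-vs-normoxia contrasts over a common gene universe
#' with planted structure: a shared set of DEGs regulated in both contrasts
#' (some up, some down, and a configurable handful with opposing signs
#' between the contrasts), plus contrast-specific unique DEG sets.  Counts
#' are negative binomial over `n_reps` replicates per condition; per-gene
#' log2 fold-changes are the difference of mean `log2(count + 1)` and
#' p-values come from a per-gene Welch t-test on the same values (a simple
#' stand-in two-sample test for synthetic end-to-end runs), BH-adjusted
#' per contrast.  Deterministic given `seed`.
#'
#' Defaults plant the composition of the glioma stem-cell study this
#' package models: 248 shared DEGs (193 up in both, 50 down in both, 5
#' opposing), 386 DEGs unique to contrast A (249 up / 137 down) and 738
#' unique to contrast B (438 up / 300 down), so contrast A carries 634 and
#' contrast B 986 planted DEGs in total.
#'
#' @param n_shared_up,n_shared_down shared genes up-/down-regulated in both
#'   contrasts.
#' @param n_opposing shared genes up in contrast A but down in contrast B.
#' @param n_unique_a_up,n_unique_a_down DEGs unique to contrast A.
#' @param n_unique_b_up,n_unique_b_down DEGs unique to contrast B.
#' @param n_universe total genes per contrast table.
#' @param n_reps replicates per condition.
#' @param effect_log2fc planted absolute log2 fold-change.
#' @param dispersion bulk NB dispersion (variance `mu + dispersion*mu^2`).
#' @param planted_meanlog,planted_sdlog log-normal parameters of baseline
#'   means for planted genes.
#' @param null_meanlog,null_sdlog log-normal parameters for null genes.
#' @param seed integer seed.
#' @return list with `a` and `b` (`deg_table` data.frames: `gene`,
#'   `log2fc`, `pval`, `padj`) and `truth` (named list of planted gene-name
#'   vectors: `shared_up`, `shared_down`, `opposing`, `unique_a_up`,
#'   `unique_a_down`, `unique_b_up`, `unique_b_down`).
#' @export
simulate_bulk_contrast <- function(n_shared_up = 193, n_shared_down = 50,
                                   n_opposing = 5,
                                   n_unique_a_up = 249, n_unique_a_down = 137,
                                   n_unique_b_up = 438, n_unique_b_down = 300,
                                   n_universe = 2000, n_reps = 3,
                                   effect_log2fc = 4, dispersion = 0.01,
                                   planted_meanlog = log(1000), planted_sdlog = 0.5,
                                   null_meanlog = log(200), null_sdlog = 0.8,
                                   seed = 1L) {
  lab <- function(pre, n) if (n > 0) sprintf("%s_%03d", pre, seq_len(n)) else character(0)
  truth <- list(shared_up = lab("SHUP", n_shared_up),
                shared_down = lab("SHDN", n_shared_down),
                opposing = lab("SHOPP", n_opposing),
                unique_a_up = lab("UAUP", n_unique_a_up),
                unique_a_down = lab("UADN", n_unique_a_down),
                unique_b_up = lab("UBUP", n_unique_b_up),
                unique_b_down = lab("UBDN", n_unique_b_down))
  planted <- unlist(truth, use.names = FALSE)
  if (anyDuplicated(planted)) stop("planted gene sets must be disjoint")
  if (length(planted) > n_universe)
    stop("planted gene sets exceed the gene universe")
  genes <- c(planted, lab("NULL", n_universe - length(planted)))
  # signed planted log2 effects per contrast
  eff <- function(up, down) {
    e <- numeric(n_universe); names(e) <- genes
    e[up] <- effect_log2fc; e[down] <- -effect_log2fc
    e
  }
  eff_a <- eff(c(truth$shared_up, truth$opposing, truth$unique_a_up),
               c(truth$shared_down, truth$unique_a_down))
  eff_b <- eff(c(truth$shared_up, truth$unique_b_up),
               c(truth$shared_down, truth$opposing, truth$unique_b_down))
  with_seed(seed, {
    base <- stats::rlnorm(n_universe, null_meanlog, null_sdlog)
    is_planted <- genes %in% planted
    base[is_planted] <- stats::rlnorm(sum(is_planted), planted_meanlog, planted_sdlog)
    one_contrast <- function(effect) {
      mu <- cbind(matrix(base, n_universe, n_reps),
                  matrix(base * 2^effect, n_universe, n_reps))
      counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                       n_universe, 2 * n_reps)
      lx <- log2(counts + 1)
      i_n <- seq_len(n_reps); i_h <- n_reps + i_n
      m1 <- rowMeans(lx[, i_n, drop = FALSE]); m2 <- rowMeans(lx[, i_h, drop = FALSE])
      v1 <- rowSums((lx[, i_n, drop = FALSE] - m1)^2) / (n_reps - 1)
      v2 <- rowSums((lx[, i_h, drop = FALSE] - m2)^2) / (n_reps - 1)
      # pooled-variance two-sample t (equal replicate numbers per condition)
      se2 <- (v1 + v2) / n_reps
      se <- sqrt(pmax(se2, 1e-16))
      tstat <- (m2 - m1) / se
      p <- 2 * stats::pt(-abs(tstat), df = 2 * (n_reps - 1))
      p[se2 <= 1e-16 & m1 == m2] <- 1
      tab <- data.frame(gene = genes, log2fc = m2 - m1, pval = p,
                        padj = bh_adjust(p), stringsAsFactors = FALSE)
      class(tab) <- c("deg_table", "data.frame")
      tab
    }
    list(a = one_contrast(eff_a), b = one_contrast(eff_b), truth = truth)
  })
}
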