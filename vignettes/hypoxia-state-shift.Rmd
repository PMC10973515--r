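---
title: "Scoring hypoxia and quantifying cell-state shifts in glioma single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring hypoxia and quantifying cell-state shifts in glioma single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxiaShift)
```

## The analysis in one paragraph

Hypoxia is a defining micro-environmental stress of high-grade glioma.
This package operationalizes a question about its cellular consequences:
when a glioma cell mounts a hypoxia transcriptional response, which of the
four Neftel differentiation states (mesenchymal-like MES, astrocyte-like
AC, oligodendrocyte-precursor-like OPC, neural-progenitor-like NPC) does it
occupy, and does the answer depend on the tumor's IDH mutation status?
The pipeline derives a hypoxia gene signature from two bulk
differential-expression contrasts, scores every cell of a droplet scRNA-seq
cohort for that signature, classifies cells as hypoxic with a
marker-calibrated threshold, assigns each cell a state by module-score
argmax, and compares per-patient state shifts between IDH-wildtype and
IDH-mutant patients.

## Signature derivation

A gene is a DEG when its |log2 fold-change| exceeds 1 **strictly** and its
BH-adjusted p-value is below 0.01 **strictly** (`filter_degs()`); a gene at
exactly log2FC = 1 is excluded. The multiple-testing procedure is
Benjamini–Hochberg step-up (`bh_adjust()`, delegating to
`stats::p.adjust`); the procedure is the de-facto default of bulk DE
pipelines and we state it explicitly since "adjusted p" alone does not pin
it down. Two directed DEG sets are then intersected by symbol
(`derive_shared_signature()`); genes whose fold-change sign disagrees
between the contrasts ("opposing directionality") are excluded — a sign of
exactly zero cannot occur after the |log2FC| > 1 filter, so no sign-of-zero
rule is needed — and the up-regulated concordant subset is the scored
signature. Over-representation of a query set against a library
(`ora_enrich()`) uses the hypergeometric upper tail, an odds ratio with
Haldane 0.5 correction for zero cells (the table orientation of public
enrichment servers is not documented, so we fix and document our own), and
the ranking statistic `odds_ratio × (−ln p)`.

## Per-cell module scoring

`module_score()` implements binned-control scoring: genes are ranked by
average log-normalized expression over all cells and cut into `n_bins = 24`
equal-frequency bins (ties broken by gene name); each signature gene
contributes `n_ctrl = 100` control draws, sampled uniformly with
replacement from its bin; the score is the mean signature expression minus
the mean over the pooled control draws. The defaults follow the
widely used convention for this scheme. Two deliberate design choices
differ from the common Seurat implementation and are unit-tested:

* **Deterministic, identity-keyed control sampling.** Each gene's control
  draws are seeded by a hash of (seed, signature name, gene symbol), so a
  score never depends on the order of rows or columns in the matrix, and
  re-running the same data gives bit-identical output. Bit-level parity
  with Seurat's RNG stream is a non-goal; a correlation cross-check against
  `Seurat::AddModuleScore` on planted data is part of the test suite.
* **Signature genes are excluded from control pools** (with a fallback to
  the nearest bin if a bin holds only signature genes). This removes
  self-contamination of the background and gives the scheme clean analytic
  identities that the tests exploit: a constant matrix scores exactly 0,
  and adding +c to the signature genes of a constant matrix scores exactly
  c.

Both properties — gene/cell permutation invariance and invariance to adding
a constant to the whole matrix — are verified against a brute-force oracle
implementation to 1e-12.

## Hypoxia classification

The threshold on the hypoxia score is not free: it is calibrated against an
independent marker of hypoxia induction, the fraction of VEGFA⁺ cells
(≥ 2 raw UMIs; raw counts, not normalized values). `calibrate_threshold()`
sweeps a grid (default 0.05–0.95 in steps of 0.05) and chooses the
candidate whose above-threshold fraction is closest to the overall
VEGFA⁺ fraction, ties toward the lower threshold. The original analyses
this models selected their cutoffs (0.25 for the shared signature, 0.55
for a pan-cancer HIF metagene) by visual inspection of the same guide; the
package makes the rule explicit and always allows a manual `override` to
reproduce a fixed published value. Classification is strict:
hypoxic ⇔ score > threshold, so a cell at exactly the threshold is
non-hypoxic.

## State assignment and coordinates

Six sets (MES1, MES2, AC, OPC, NPC1, NPC2) are module-scored; the raw
state is the argmax, with exact ties broken by the fixed order
MES1 < MES2 < AC < OPC < NPC1 < NPC2 (ties are counted and reported);
MES1/2 collapse to MES and NPC1/2 to NPC *after* the argmax — the
collapse-then-argmax alternative is not what the stated procedure
describes. Quadrant-plot coordinates use
`y = max(OPC, NPCmax) − max(AC, MESmax)` and a sign-encoded
`log2(|Δ| + 1)` of the within-hemisphere difference for x. The x-axis
orientation (NPC right / OPC left above the axis; MES right / AC left
below) is a convention we fix and document, since quadrant plots appear
with both orientations in the literature.

## QC and normalization

Cells with fewer than 1000 UMIs, fewer than 400 detected genes, or more
than 25% mitochondrial UMIs (symbol prefix `MT-`, configurable) are
removed; all three boundaries are strict for removal, so a cell at exactly
(1000, 400, 0.25) is retained. Log-normalization is
`ln(1 + 10^4 · count/total)`; base and scale follow the convention of the
standard droplet workflow and are configurable. Scores are computed on
pooled log-normalized data without batch integration: in the workflow this
models, integration feeds only the UMAP embedding, which is visualization
and out of scope here.

## The synthetic cohort: what it emulates and what it does not

`sim_config()` defaults define the study conditions used throughout the
tests and the acceptance script:

* 11 patients (5 IDH-WT, 6 IDH-MUT), 2727 cells each (~30,000 total);
* 600 genes: four 40-gene state programs, a 40-gene hypoxia program, a
  VEGFA-like marker, 10 mitochondrial genes, and background;
* negative-binomial counts, variance `μ + μ²/size` with size 2, per-gene
  baseline means log-normal (meanlog = ln 2, sdlog = 1) — cells land near
  2,500 total UMIs, a realistic droplet depth;
* baseline state priors 24.9/20.9/16.5/37.6% (MES/AC/OPC/NPC), the
  non-hypoxic composition reported for the cohort this emulates;
* hypoxia in 4% of cells per patient; hypoxic cells redraw their state
  from an IDH-conditional distribution — WT (75% MES), MUT (~25/43/11/21
  MES/AC/OPC/NPC) — chosen so the patient-weighted pooled hypoxic
  composition approximates the reported 48/26/7/19%;
* marker mean 0.05 (non-hypoxic) vs 10 (hypoxic), making the VEGFA⁺
  fraction track the planted hypoxic fraction the way the real guide
  tracks hypoxia induction;
* program effects of 1.2 (state) and 1.5 (hypoxia) natural-log units —
  strong, well-separated programs.

The bulk generator (`simulate_bulk_contrast()`) plants the composition of
the modelled contrasts — 248 shared DEGs (193 up-both, 50 down-both, 5
opposing), 386 and 738 contrast-specific DEGs — over a 2000-gene universe
with triplicate negative-binomial counts (dispersion 0.01, typical of
cell-line technical triplicates) and per-gene pooled-variance t-tests on
log2(count+1) as a simple stand-in two-sample test (the full DE model is
out of scope). With these settings the planted structure is recovered
exactly at the stated cutoffs, which is what makes the set-algebra counts
meaningful integration checks rather than coin flips.

What the simulation does **not** emulate: library-size confounding,
doublets, ambient RNA, batch effects beyond the patient index, correlated
program membership (state programs and the hypoxia program are disjoint by
default, although overlap is biologically real for MES), or realistic
transcriptome size. Passing the recovery tests therefore demonstrates that
the pipeline's machinery is correct and well-calibrated under its own
assumptions — not that a 4%-hypoxic fraction or a MES shift would be
recovered from any particular real dataset, where signature quality and
confounding dominate.

## Statistical choices

Rank-sum comparisons (`rank_sum_test()`) are two-sided throughout; the
exact null distribution is used when `n_a + n_b ≤ 12` and the data are
tie-free, otherwise the normal approximation with tie and continuity
correction (delegating to `stats::wilcox.test`; an enumeration oracle
verifies the exact path in the tests). The IDH contrast compares the
per-patient, per-state shift `delta = prop_hypoxic − prop_nonhypoxic`
between groups — the statistic that directly operationalizes per-patient
shift plots; the hypoxic-class proportion alone is available via
`value = "prop_hypoxic"`. No multiplicity correction is applied across the
four states, mirroring the modelled analysis; significance stars use
0.05/0.01/0.001.

With 5 vs 6 patients the smallest achievable exact two-sided p is
2/C(11,5) ≈ 0.0043, so a "significant in ≥ 90% of replicates" power
criterion is demanding but attainable only because the planted group
separation is large relative to per-patient sampling noise
(~110 hypoxic cells per patient at 4% of 2727).

## Numerical and degenerate-input policy

Probability vectors in `sim_config()` must sum to 1 within 1e-12 (the
shipped defaults are normalized exactly). Cells with zero total UMIs
log-normalize to all-zero columns with a warning; strata with an empty
hypoxic class report NA proportions (never silent zeros); an empty QC
result is a warning, not an error; readers reject dimension mismatches
rather than truncating. All seeds flow from a single configuration value;
no function leaves the global RNG state altered.

## Problem sizes

The test suite runs the full 30,000-cell cohort once (shared across test
files), a 25-replicate cohort sweep for the power check, 1000-vector BH
oracle comparisons, and exhaustive enumerations for universes ≤ 20 and
rank-sum sizes ≤ 10 — sizes chosen so the whole suite completes in a few
minutes while still exercising the pipeline at the cohort scale the
defaults describe.

## Known limitations

* The signature is a plain gene list; no weighting by effect size.
* Threshold calibration assumes the marker guide is itself trustworthy;
  when marker expression is decoupled from the scored program the chosen
  threshold is arbitrary (the calibration table is always written so this
  can be inspected).
* The hybrid-state refinements of the Neftel scheme and cell-cycle
  scoring are not implemented; argmax assignment forces a single state.
* Enrichment reproduces the documented combined-score formula, not any
  server's rank-based z-score variant.
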