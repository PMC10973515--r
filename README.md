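# hypoxiaShift

Hypoxia signature scoring and cell-state shift analysis for glioma
single-cell transcriptomics.

Glioblastoma tumors contain hypoxic niches, and tumor cells respond to low
oxygen by switching transcriptional programs. This package implements, as a
tested pipeline, a complete analysis chain for asking how hypoxia reshapes
the distribution of Neftel cellular states (MES, AC, OPC, NPC) in glioma,
and whether that response differs between IDH-wildtype and IDH-mutant
tumors:

1. **Shared signature derivation** — two bulk hypoxia-vs-normoxia
   differential-expression contrasts are filtered at |log2FC| > 1 and
   BH-adjusted p < 0.01, intersected by symbol, genes with opposing
   directionality are excluded, and the up-regulated concordant genes form
   the shared hypoxia signature used for scoring.
2. **Per-cell module scoring** — for a gene set *S*, each cell's score is

   `score(c) = mean_{g in S} x_gc − mean_{g' in ctrl(S)} x_g'c`

   where `x` is log-normalized expression (`ln(1 + 1e4 · count/total)`),
   and `ctrl(S)` draws, for every signature gene, 100 control genes (with
   replacement) from its average-expression bin among 24 equal-frequency
   bins. Control draws are seeded per (seed, signature, gene symbol), so
   scores are reproducible and invariant to gene/cell order; signature
   genes are excluded from control pools.
3. **Threshold calibration** — a candidate-threshold grid is swept and the
   fraction of cells scoring above each candidate is compared against the
   fraction of VEGFA⁺ cells (≥ 2 raw UMIs), the marker guide for hypoxia
   induction; the closest match is chosen (a fixed published cutoff can be
   imposed instead). Cells with score strictly above the threshold are
   hypoxic.
4. **State assignment** — six Neftel state sets (MES1/2, AC, OPC, NPC1/2)
   are module-scored; the argmax assigns the state, MES1/2 and NPC1/2
   collapse to MES and NPC, and 2D quadrant-plot coordinates are computed.
5. **Shift analysis** — per patient, the state composition of hypoxic vs
   non-hypoxic cells; per state, the per-patient shift
   `delta = prop_hypoxic − prop_nonhypoxic` is compared between IDH-WT and
   IDH-MUT patients with two-sided Wilcoxon rank-sum tests.

A first-class synthetic-data module (`sim_config()`, `simulate_cells()`,
`simulate_bulk_contrast()`) generates negative-binomial UMI cohorts with
planted state programs, a planted hypoxia program, a hypoxia-coupled
VEGFA-like marker, mitochondrial genes for QC, and IDH-dependent coupling
between hypoxia and state, so the whole chain is testable end to end with
known ground truth. Readers/writers are included for 10x-style MatrixMarket
triplets, GMT gene sets and delimited DEG tables.

## Worked example

The numbered drivers under `analysis/` run the full chain on the synthetic
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort -> MTX triplet + truth + GMT
Rscript analysis/02_derive_signature.R    # bulk contrasts -> shared signature
Rscript analysis/03_score_and_classify.R  # QC, scoring, threshold, states
Rscript analysis/04_state_shift.R         # composition + IDH rank-sum tests
```

Stage 2 prints the signature set algebra on the planted composition:

```
contrast A: 634 DEGs; contrast B: 986 DEGs
symbol overlap 248; concordant 243; up-regulated 193
```

i.e. of 248 DEGs shared by symbol, 5 oppose in direction and 193 of the
remaining 243 are up-regulated in both contrasts — those 193 genes are the
scored hypoxia signature. Stage 3 calibrates the threshold against the
VEGFA guide and classifies:

```
classified 3.95% of 29921 cells as hypoxic (threshold 0.95, VEGFA+ 3.86%)
```

and stage 4 reports the hypoxia-driven state shifts and their IDH contrast:

```
pooled composition (percent, non-hypoxic -> hypoxic):
  MES  24.8 ->  47.7
  AC   21.0 ->  25.1
  OPC  16.6 ->   6.8
  NPC  37.5 ->  20.5

IDH-WT vs IDH-MUT per-state shift (rank-sum, two-sided):
  state statistic        pval stars n_wt n_mut    mean_wt     mean_mut
1   MES        30 0.004329004    **    5     6  0.5230107 -0.008611406
2    AC         0 0.004329004    **    5     6 -0.1566501  0.200678837
...
against planted truth: sensitivity 0.987, specificity 1.000, state accuracy 1.000
```

Hypoxic cells are strongly enriched for the MES state in every IDH-WT
patient, while IDH-MUT patients shift toward AC instead — the planted
divergence, recovered by the pipeline from raw counts.

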