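# transeff

Estimation of per-gene **translation efficiency (TE)** from paired mRNA and
protein abundance across cell lines.

mRNA levels typically explain well under half of the variation in protein
levels, and one missing ingredient is how efficiently each transcript is
translated. `transeff` is for researchers who have genome-wide transcript
abundances (FPKM), protein abundances (mass-spectrometry iBAQ) and protein
turnover measurements (pulsed-SILAC half-lives) for the same cells, and who
want a per-gene, per-cell-line estimate of translation efficiency together
with an assessment of how consistent that efficiency is between cell lines.

## The model

At steady state the protein synthesised per unit time equals the protein
degraded, so with first-order protein decay,

```
TE = iBAQ × PSAT / FPKM,        PSAT = 1 − exp(−k_deg · Δt),
k_deg = ln 2 / t½  (per hour, Δt = 1 h)
```

where PSAT — the *protein stability accounting term* — is the fraction of
the protein pool turned over per hour. A stable protein (t½ = 72 h, PSAT ≈
0.0096) needs far less synthesis to maintain its level than an unstable one
(t½ = 18 h, PSAT ≈ 0.038), which is what distinguishes TE from a naive
protein/mRNA ratio. TE is in relative units (proportional to proteins per
mRNA per hour).

Around this core the package provides:

* **iBAQ conversion** — in-silico tryptic digestion (`digestProtein`,
  rules `trypsin-simple` and `trypsin-keil`), counting peptides of 6–30
  residues, and `intensityToIbaq` with explicit exclusion reporting for
  proteins whose isoforms disagree on the peptide count;
* **between-sample quantile normalization** of protein quantifications
  (`normalizeBetweenSamples`);
* **pairing and filtering** (`pairExpression`; FPKM < 0.1 excluded) and TE
  estimation (`translationEfficiency`), with per-gene summaries, Spearman
  mRNA–protein correlations and per-gene log-linear fits;
* **consistency analysis** — coefficient of variation of log10 TE across
  cell lines (`teCv`), a within-column permutation null with a Welch t-test
  (`permutationNull`), quintile assignment and TE × stability quintile
  intersections;
* **enrichment** — a local EASE-score (jackknifed one-sided Fisher) engine
  with Benjamini–Hochberg correction (`easeScore`, `enrichGroups`);
* **synthetic data with planted ground truth** (`simulateTeDataset`,
  `simulateProteinSequences`, `simulateAnnotation`) so the whole pipeline is
  testable end to end;
* a `TEExperiment` container (extends `SummarizedExperiment`) holding the
  `fpkm`, `ibaq`, `psat`, `te` and `log10te` assays with per-gene summaries
  in `rowData`.

## Worked example

```r
library(transeff)

cfg <- simulationConfig(n_genes = 1000, n_cell_lines = 5, seed = 42)
ds  <- simulateTeDataset(cfg)
run <- runPipeline(pipelineConfig(mrna = ds$mrna, protein = ds$protein,
                                  stability = ds$stability, seed = 42))
run$te_experiment
#> TEExperiment: 993 genes x 5 cell lines (3190 TE estimates)
#> cell lines: CL1, CL2, CL3, CL4, CL5
#> median log10 TE (all estimates): 3.12
#> genes with cross-line CV: 107 (median CV 0.070)

p <- run$permutation
sprintf("observed mean CV %.3f vs permuted %.3f (Welch p = %.3g)",
        mean(p$observed_cvs), mean(p$permuted_cvs), p$p_value)
#> "observed mean CV 0.122 vs permuted 0.216 (Welch p = 2.92e-14)"

signif(psat(kdegFromHalfLife(c(18, 72))), 2)
#> [1] 0.0380 0.0096
```

The simulated dataset plants half of its genes with a cell-line-constant
TE. After estimation, the median log10 TE recovers the configured 3.12; the
107 genes observed in all five lines have a lower mean CV than their
permutation null (p ≈ 3e-14), i.e. the planted consistency is detected; and
the two PSAT values show the ~4-fold synthesis-demand difference between an
18-hour and a 72-hour half-life protein. With real data, replace the three
simulated tables with TSVs of columns `gene_id, cell_line, fpkm`,
`gene_id, cell_line, ibaq` (or raw `intensity` plus a FASTA, to let the
package compute iBAQ) and `gene_id, half_life_h`.

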