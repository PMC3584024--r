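---
title: "Estimating translation efficiency from paired mRNA and protein abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating translation efficiency from paired mRNA and protein abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transeff)
```

## The model and its assumptions

`transeff` estimates, for each gene in each cell line, how efficiently its
mRNA is translated into protein. Protein level alone cannot tell translation
apart from stability: an abundant protein may be abundant because it is made
quickly or because it is degraded slowly. The package therefore combines
three measurements — transcript abundance (FPKM), protein abundance (iBAQ)
and protein turnover (half-life from pulsed-SILAC experiments) — under two
assumptions:

1. **Steady state.** Both mRNA and protein pools are constant over the
   measurement window, so synthesis balances degradation.
2. **First-order protein decay** with rate constant
   $k_{deg} = \ln 2 / t_{1/2}$ (h$^{-1}$).

The fraction of the protein pool degraded — and hence resynthesised — in a
window $\Delta t$ is the *protein stability accounting term*,
$PSAT = 1 - e^{-k_{deg}\Delta t}$, and the translation efficiency estimate is

$$TE = \frac{iBAQ \times PSAT}{FPKM},$$

in relative units proportional to proteins per mRNA per hour. The default
window is $\Delta t = 1$ h; it is an explicit argument of `psat()` rather
than a constant baked into the formula. No calibration to absolute
proteins/mRNA/h is applied; `adjustTeForSequestration()` provides the
related correction for transcripts of which a fraction $f$ is
translationally inactive ($\log_{10} TE - \log_{10}(1-f)$), relevant for
TOP-element mRNAs such as those of ribosomal proteins.

mRNA stability is deliberately *not* modelled: FPKM is an absolute
abundance, so transcript turnover is already folded into it. A single,
cell-line-independent stability table is used for every line (matching the
practice of applying one cell line's turnover data across related lines);
`translationEfficiency()` accepts any stability table, so per-line tables
can be substituted when available.

## From raw intensities to iBAQ

When protein data arrive as raw MS intensities, `digestProtein()` performs
complete in-silico trypsin digestion and counts peptides of 6–30 residues
(inclusive on both ends — the bound is declared rather than guessed
silently), and `intensityToIbaq()` divides intensity by that count. Two
cleavage rules are available: `trypsin-simple` (cleave after K/R, not before
P) — the default, because it is unambiguous and reproducible — and
`trypsin-keil`, a Keil-style exception table (cleavage despite proline after
`WK`/`MR`; suppression in the contexts CKD, DKD, CKH, CKY, KKR, RRH, RRR,
CRK, DRD). The active rule is recorded in the digest output. Nonstandard
residues (X, B, Z, U) never cleave and count toward peptide length, so real
FASTA files digest deterministically. Proteins whose sequence isoforms
disagree on the quantifiable-peptide count have an ambiguous denominator and
are excluded with reason `ambiguous_peptide_count`; zero-count proteins are
excluded as `zero_quantifiable_count`. Exclusions are reported, never
silent.

`normalizeBetweenSamples()` then forces each cell line's detected
quantifications onto a common empirical distribution (rank-preserving
quantile normalization; missing values stay missing, and columns of unequal
depth are mapped through interpolated quantile positions). The reference
distribution is the mean of the columns' quantile functions on the *linear*
scale, so two equal-depth columns are replaced by the element-wise mean of
their sorted vectors; a `scale = "log"` option averages geometrically
instead. The linear default was chosen because it reproduces the standard
limma-style quantile normalization exactly on complete matrices, which also
serves as an independent cross-check in the test suite.

## Pairing, filtering and summaries

`pairExpression()` inner-joins mRNA and protein on (gene, cell line) and
drops pairs with FPKM < 0.1 (strict: a value of exactly 0.1 is kept), the
conventional floor below which FPKM estimates are unreliable. Duplicate keys
are a data-integrity error, not a silent aggregation. Genes with several
stability records are collapsed to the geometric mean $k_{deg}$ (the natural
average for a rate constant) and reported. Per-gene summaries use the median
of log10 TE across cell lines; correlations report tie-corrected Spearman
$r$ and the squared Pearson correlation of the log10 values; per-gene
log-linear fits (`perGeneLogLinearFit`) are ordinary least squares of
log10(iBAQ) on log10(FPKM), refused below 3 points.

## Consistency across cell lines

The cross-line consistency statistic is the coefficient of variation
(sample SD over mean, $n-1$ denominator) of **log10** TE. The log10 scale
was chosen because the consistency thresholds that make the analysis
interpretable (CVs of order 0.05–0.2 for log10 values near 3) are only
meaningful on that scale; the same function applies unchanged to linear TE
if a user prefers it. CV and quintile analyses default to complete-case
genes (data in *all* cell lines), relaxable via `min_lines_cv`.

`permutationNull()` builds the chance expectation by independently
shuffling values within each cell-line column — the minimal scheme that
preserves every line's TE distribution exactly while breaking the per-gene
linkage — and recomputes per-gene CVs; each replicate asserts that the
column multisets are preserved. Observed and pooled permuted CVs are
compared by a two-sided Welch t-test (no variance-equality assumption, since
the permuted pool is much larger and differently shaped). The reported
"consistent fraction" threshold defaults to the 20th percentile of the
observed CVs — the lower-quintile boundary — because that boundary is a
property of the data, not a universal constant. A `scheme = "global"` flag
swaps in a single whole-matrix shuffle. The default of 20 replicates matches
the package's reference analysis; the t-test pools all replicates.

`assignQuintiles()` splits genes into five rank groups whose sizes differ by
at most one, any remainder going to the *lower* quintiles, with ties broken
by lexicographic gene id — both conventions exist purely to make the
partition deterministic and are documented rather than implicit.
`intersectQuintiles()` forms the four corner groups between two rankings
(typically TE and protein half-life).

## Enrichment

`easeScore()` implements the jackknifed one-sided Fisher test: the overlap
count $a$ is decremented by one (floored at 0, other cells unchanged) before
taking the upper hypergeometric tail, so a single-gene overlap carries no
evidence ($a \le 1 \Rightarrow p = 1$) and the score is always $\ge$ the
plain Fisher p-value. This particular convention — decrement $a$, leave $b$,
$c$, $d$ alone — is stated explicitly because jackknifed tests are sensitive
to how the margins are treated; it is verified in the tests against full
enumeration of the hypergeometric support. Benjamini–Hochberg correction is
applied within each group × annotation-category family by default (matching
how chart-style enrichment tools correct per run), with a
`global_correction` flag; terms need at least 2 group genes
(`min_genes = 2`) and pass at BH < 0.05. The annotation source is a plain
gene–term table supplied by the user (or simulated), never a live database:
term databases are versioned, so live lookups are inherently
non-reproducible.

## The synthetic-data generator

`simulateTeDataset()` generates the inputs with the statistical structure
the analysis assumes, plus the planted truth needed for parameter-recovery
tests:

* planted log10 TE $\sim N(3.12, 0.72^2)$ — the location and spread of the
  log10 TE distribution in the reference analysis;
* half-lives log-normal with median 36 h and log-SD 0.44, chosen so the
  implied PSAT interquartile range is roughly 0.015–0.027 (about 1.85-fold);
* FPKM log-normal with log-SD 1.8, giving an interdecile range of about two
  orders of magnitude;
* a fraction `frac_consistent` (default 0.5) of genes keeps one planted TE
  across every cell line; the rest redraw it independently per line;
* protein abundance is the *inversion* of the TE formula,
  $iBAQ = TE \times FPKM / PSAT$, times log-normal noise of log10-SD
  `te_noise_sd` (default 0.1; mRNA is treated as exact by default so that
  noise-free TE recovery is an algebraic identity);
* dropout removes each mRNA and protein observation independently with
  probability 0.2, mirroring the partial overlap of genes across real cell
  lines.

The default noise SD of 0.1 log10 units is a free parameter of the
generator, not a measured quantity; it was fixed once at a level that makes
consistent and inconsistent genes clearly distinct while keeping observed
CVs in a realistic range. One global seed is expanded into independent
per-table substreams (via a seeded draw of sub-seeds), so adding a table to
the generator never changes the draws of existing tables; all randomness
uses R's default Mersenne–Twister generator, making outputs bit-identical
across runs and platforms for a fixed seed.

What the generator does **not** emulate: correlation between TE and
stability or abundance; saturation of high-abundance protein measurements;
isoform mixtures; batch structure between laboratories; and the true
(unknown) error distribution of iBAQ. Passing tests therefore demonstrate
that the estimation machinery is correct and that the statistical analyses
behave as designed under the assumed data model — not that the model
captures every property of real proteome data.

`simulateProteinSequences()` draws residues uniformly over the 20 standard
amino acids (overridable frequencies): digestion tests need K/R placement,
not biological realism. `simulateAnnotation()` plants term enrichment in a
chosen quintile with a configurable odds ratio against a uniform background.

## Numerical choices and degenerate inputs

* PSAT saturates at 1 in double precision for $k_{deg} \gtrsim 37$ h$^{-1}$
  (half-lives below ~70 ms); the monotonicity tests stay below that range.
* TE of 0 (zero iBAQ) is retained with `log10_te = NA` rather than
  $-\infty$.
* `teCv()` returns `NA` for fewer than two values or a zero mean; such genes
  are excluded from CV analyses and counted.
* A constant TE matrix makes the permutation test degenerate; the result is
  flagged instead of reporting a meaningless p-value.
* Stability tables supplying both half-life and $k_{deg}$ must agree to
  1e-9 relative; disagreement is an error, not a silent preference.
* Quantile normalization with a single detected value in a column places it
  at the distribution median.

## Problem sizes

The test suite and reference analyses run at deliberately modest sizes —
hundreds to a few thousand simulated genes, five cell lines, 20 permutation
replicates, 100-seed Monte-Carlo batches for power/recovery properties —
which are sufficient for the Monte-Carlo margins asserted and keep the full
suite fast on a single CPU. All sizes are arguments, so users can scale any
analysis up.

## Known limitations

* TE units are relative; comparisons are valid within an analysis, not
  across studies, unless an external calibration is applied.
* Using one cell line's stability data for all lines biases TE for lines
  whose turnover differs systematically; `compareStabilityTables()` exists
  to quantify such differences when a second table is available.
* Gene-level aggregation cannot separate alternatively spliced isoforms
  with different translation efficiencies.
* The digestion model has no missed cleavages and no peptide-detectability
  model; it predicts the iBAQ denominator, not observable spectra.
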