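## Core translation-efficiency estimation: pairing, filtering, TE = iBAQ*PSAT/FPKM,
## per-gene summaries and correlation statistics.

#' Pair mRNA and protein quantifications by gene and cell line
#'
#' Inner-joins a transcript table and a protein table on
#' (`gene_id`, `cell_line`) and applies the low-expression filter: pairs with
#' FPKM strictly below `fpkm_min` are excluded (a value exactly at the
#' threshold is retained).  The numbers of unmatched and filtered records are
#' reported so that no record is dropped silently.
#'
#' @param mrna A `data.frame` with columns `gene_id`, `cell_line`, `fpkm`.
#' @param protein A `data.frame` with columns `gene_id`, `cell_line`, `ibaq`.
#' @param fpkm_min FPKM exclusion threshold (default 0.1; strict less-than).
#' @return A list with `pairs` (`data.frame`: `gene_id`, `cell_line`, `fpkm`,
#'   `ibaq`) and `counts` (named integer vector: `mrna_in`, `protein_in`,
#'   `matched`, `below_fpkm_min`, `kept`, `mrna_unmatched`,
#'   `protein_unmatched`).
#' @export
pairExpression <- function(mrna, protein, fpkm_min = 0.1) {
  stopIfNot(all(c("gene_id", "cell_line", "fpkm") %in% names(mrna)),
            "'mrna' needs gene_id, cell_line, fpkm")
  stopIfNot(all(c("gene_id", "cell_line", "ibaq") %in% names(protein)),
            "'protein' needs gene_id, cell_line, ibaq")
  checkScalarNumeric(fpkm_min, "fpkm_min", lower = 0)
  key_m <- paste(mrna$gene_id, mrna$cell_line, sep = "\r")
  key_p <- paste(protein$gene_id, protein$cell_line, sep = "\r")
  for (nm in list(c("mrna", "m"), c("protein", "p"))) {
    k <- if (nm[2] == "m") key_m else key_p
    if (anyDuplicated(k)) {
      d <- sub("\r", " / ", k[duplicated(k)][1])
      stop(sprintf("duplicate (gene_id, cell_line) key in %s table: %s",
                   nm[1], d), call. = FALSE)
    }
  }
  idx <- match(key_m, key_p)
  matched <- !is.na(idx)
  pairs <- data.frame(
    gene_id = mrna$gene_id[matched],
    cell_line = mrna$cell_line[matched],
    fpkm = mrna$fpkm[matched],
    ibaq = protein$ibaq[idx[matched]],
    stringsAsFactors = FALSE
  )
  low <- pairs$fpkm < fpkm_min
  kept <- pairs[!low, , drop = FALSE]
  rownames(kept) <- NULL
  list(
    pairs = kept,
    counts = c(
      mrna_in = nrow(mrna),
      protein_in = nrow(protein),
      matched = sum(matched),
      below_fpkm_min = sum(low),
      kept = nrow(kept),
      mrna_unmatched = sum(!matched),
      protein_unmatched = nrow(protein) - sum(matched)
    )
  )
}

#' Estimate translation efficiency for paired expression data
#'
#' Under the steady-state assumption the amount of protein synthesised per
#' unit time equals the amount degraded, so the translation efficiency of a
#' gene is estimated as
#' \deqn{TE = \frac{iBAQ \times PSAT}{FPKM}, \qquad PSAT = 1 - e^{-k_{deg}},}
#' in relative units (protein per mRNA per hour up to a global calibration
#' constant).  The stability table is cell-line independent: the same
#' \eqn{k_{deg}} is applied to every cell line, mirroring the use of a single
#' turnover dataset for all lines.  Genes without a stability record are
#' excluded and reported; genes with several stability records are collapsed
#' to the geometric mean \eqn{k_{deg}} and the collision reported.
#'
#' @param pairs A `data.frame` of paired expression as produced by
#'   [pairExpression()] (`gene_id`, `cell_line`, `fpkm`, `ibaq`).
#' @param stability A stability table accepted by [readStabilityTable()].
#' @param delta_t_h PSAT time window in hours (default 1).
#' @return A list with `te` (`data.frame`: `gene_id`, `cell_line`, `fpkm`,
#'   `ibaq`, `psat`, `te`, `log10_te`; `log10_te` is `NA` where `te` is 0),
#'   `no_stability` (gene ids excluded) and `stability_collisions` (gene ids
#'   with multiple stability records).
#' @examples
#' p <- data.frame(gene_id = "STAT6", cell_line = "HeLa",
#'                 fpkm = 56, ibaq = 555142)
#' s <- data.frame(gene_id = "STAT6", half_life_h = 18)
#' translationEfficiency(p, s)$te$log10_te  # ~2.57
#' @export
translationEfficiency <- function(pairs, stability, delta_t_h = 1) {
  stopIfNot(all(c("gene_id", "cell_line", "fpkm", "ibaq") %in% names(pairs)),
            "'pairs' needs gene_id, cell_line, fpkm, ibaq")
  stopIfNot(all(pairs$fpkm > 0), "'pairs' must be FPKM-filtered (fpkm > 0)")
  stopIfNot(all(pairs$ibaq >= 0), "ibaq must be >= 0")
  cs <- collapseStability(stability)
  stab <- cs$stability
  kd <- stab$kdeg_per_h[match(pairs$gene_id, stab$gene_id)]
  has <- !is.na(kd)
  te_tab <- pairs[has, , drop = FALSE]
  te_tab$psat <- if (any(has)) psat(kd[has], delta_t_h) else numeric(0)
  te_tab$te <- te_tab$ibaq * te_tab$psat / te_tab$fpkm
  te_tab$log10_te <- ifelse(te_tab$te > 0, log10(te_tab$te), NA_real_)
  rownames(te_tab) <- NULL
  list(
    te = te_tab,
    no_stability = sort(unique(pairs$gene_id[!has])),
    stability_collisions = cs$collisions
  )
}

#' Adjust a log10 TE estimate for translationally sequestered mRNA
#'
#' TE is computed over *all* mRNA of a gene; if a fraction `f` of the
#' transcripts is sequestered and translationally inactive (as for
#' TOP-element mRNAs of ribosomal proteins), the efficiency per
#' translationally active mRNA is higher by a factor \eqn{1/(1-f)}:
#' \deqn{\log_{10} TE_{adj} = \log_{10} TE - \log_{10}(1 - f).}
#'
#' @param log10_te Observed log10 TE (vectorised).
#' @param sequestered_fraction Fraction `f` in \[0, 1).
#' @return Adjusted log10 TE.
#' @examples
#' adjustTeForSequestration(2.93, 0.30)  # ~3.08
#' @export
adjustTeForSequestration <- function(log10_te, sequestered_fraction) {
  stopIfNot(is.numeric(log10_te) && all(is.finite(log10_te)),
            "'log10_te' must be finite numeric")
  checkScalarNumeric(sequestered_fraction, "sequestered_fraction", lower = 0)
  stopIfNot(sequestered_fraction < 1, "'sequestered_fraction' must be < 1")
  log10_te - log10(1 - sequestered_fraction)
}

#' Summarize per-gene TE across cell lines
#'
#' For each gene, the median of the per-cell-line log10 TE values (even-count
#' median is the midpoint of the two central values, the usual convention)
#' and the number of cell lines with an estimate.
#'
#' @param te A TE table as produced by [translationEfficiency()] (columns
#'   `gene_id`, `cell_line`, `log10_te`); rows with `NA` log10 TE are ignored.
#' @return A `data.frame` with `gene_id`, `median_log10_te`, `n_cell_lines`.
#' @export
summarizeGeneTe <- function(te) {
  stopIfNot(all(c("gene_id", "log10_te") %in% names(te)),
            "'te' needs gene_id and log10_te")
  te <- te[!is.na(te$log10_te), , drop = FALSE]
  stopIfNot(nrow(te) >= 1L, "no usable log10 TE values")
  med <- tapply(te$log10_te, te$gene_id, median)
  n <- tapply(te$log10_te, te$gene_id, length)
  data.frame(gene_id = names(med),
             median_log10_te = as.numeric(med),
             n_cell_lines = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between mRNA and protein levels
#'
#' Spearman rank correlation (tie-corrected, via midranks) of FPKM and iBAQ,
#' and the coefficient of determination \eqn{R^2} as the squared Pearson
#' correlation of the log10-transformed values, per cell line and for all
#' pairs combined.  Pairs with non-positive iBAQ are dropped from the log
#' statistics and counted.
#'
#' @param pairs A paired expression table (`gene_id`, `cell_line`, `fpkm`,
#'   `ibaq`).
#' @param grouping `"per_cell_line"`, `"combined"`, or `"both"` (default).
#' @return A `data.frame` with `cell_line` (`"combined"` for the pooled row),
#'   `n_pairs`, `spearman_r`, `r_squared`, `degenerate` (TRUE when a column
#'   is constant and the correlation undefined).
#' @export
correlationSummary <- function(pairs,
                               grouping = c("both", "per_cell_line", "combined")) {
  grouping <- match.arg(grouping)
  stopIfNot(all(c("cell_line", "fpkm", "ibaq") %in% names(pairs)),
            "'pairs' needs cell_line, fpkm, ibaq")
  one <- function(df, label) {
    ok <- df$fpkm > 0 & df$ibaq > 0
    df <- df[ok, , drop = FALSE]
    stopIfNot(nrow(df) >= 3L,
              sprintf("need >= 3 positive pairs in group '%s'", label))
    degen <- (sd(df$fpkm) == 0 || sd(df$ibaq) == 0)
    data.frame(
      cell_line = label,
      n_pairs = nrow(df),
      spearman_r = if (degen) NA_real_ else
        cor(df$fpkm, df$ibaq, method = "spearman"),
      r_squared = if (degen) NA_real_ else
        cor(log10(df$fpkm), log10(df$ibaq))^2,
      degenerate = degen,
      stringsAsFactors = FALSE
    )
  }
  out <- list()
  if (grouping %in% c("both", "per_cell_line")) {
    out <- lapply(split(pairs, pairs$cell_line), function(d)
      one(d, d$cell_line[1]))
  }
  if (grouping %in% c("both", "combined")) {
    out <- c(out, list(one(pairs, "combined")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene log-linear fit of protein on mRNA across cell lines
#'
#' Ordinary least squares of log10(iBAQ) on log10(FPKM) across the cell lines
#' of one gene; genes whose mRNA and protein levels move proportionally have
#' slope near 1 and high \eqn{R^2}.  Genes with fewer than `min_points` cell
#' lines (or with constant FPKM) are flagged rather than fitted.
#'
#' @param pairs A paired expression table for one or more genes (`gene_id`,
#'   `cell_line`, `fpkm`, `ibaq`); non-positive values are dropped per gene.
#' @param min_points Minimum cell lines required for a fit (default 3).
#' @return A `data.frame` with `gene_id`, `n_points`, `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided test of nonzero slope), `fitted`
#'   (FALSE when the fit was refused).
#' @export
perGeneLogLinearFit <- function(pairs, min_points = 3L) {
  stopIfNot(all(c("gene_id", "fpkm", "ibaq") %in% names(pairs)),
            "'pairs' needs gene_id, fpkm, ibaq")
  min_points <- checkCount(min_points, "min_points", min = 3L)
  fits <- lapply(split(pairs, pairs$gene_id), function(df) {
    g <- df$gene_id[1]
    df <- df[df$fpkm > 0 & df$ibaq > 0, , drop = FALSE]
    refuse <- data.frame(gene_id = g, n_points = nrow(df), slope = NA_real_,
                         intercept = NA_real_, r_squared = NA_real_,
                         p_value = NA_real_, fitted = FALSE,
                         stringsAsFactors = FALSE)
    if (nrow(df) < min_points || sd(log10(df$fpkm)) == 0) return(refuse)
    fit <- lm(log10(ibaq) ~ log10(fpkm), data = df)
    sm <- summary(fit)
    data.frame(
      gene_id = g,
      n_points = nrow(df),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = sm$coefficients[2, 4],
      fitted = TRUE,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, fits)
  rownames(res) <- NULL
  res
}
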