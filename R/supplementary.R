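## Ingestion of a processed per-gene data table of the form distributed as a
## study supplement (FPKM, iBAQ and kdeg columns per gene and cell line),
## and the summary statistics recomputable from it.

#' Read a processed FPKM/iBAQ/kdeg supplementary table
#'
#' Accepts a TSV (or `data.frame`) with columns `gene_id`, `cell_line`,
#' `fpkm`, `ibaq` and `kdeg_per_h`, the processed per-gene values that a
#' published TE study distributes as a supplementary spreadsheet (exported to
#' TSV).  No such table ships with this package; the function exists so that
#' a user who has obtained one can recompute its summary statistics locally.
#'
#' @param x Path to a TSV file or a `data.frame`.
#' @return A `data.frame` with the five columns above.
#' @export
readSupplementaryTable <- function(x) {
  df <- if (is.character(x)) readTsv(x) else as.data.frame(x)
  need <- c("gene_id", "cell_line", "fpkm", "ibaq", "kdeg_per_h")
  stopIfNot(all(need %in% names(df)),
            sprintf("supplementary table needs columns: %s",
                    paste(need, collapse = ", ")))
  df[, need]
}

#' Summary statistics of a supplementary table
#'
#' Recomputes, from the per-gene values alone: the interquartile ratio of
#' the PSAT factor (75th percentile / 25th percentile over the unique genes'
#' degradation constants) and the overall median log10 TE across all
#' gene-by-cell-line estimates, with TE = iBAQ x PSAT / FPKM.
#'
#' @param df A table from [readSupplementaryTable()].
#' @param fpkm_min FPKM exclusion threshold applied before TE (default 0.1).
#' @return A list with `psat_iqr_ratio`, `median_log10_te`, `n_genes`,
#'   `n_estimates`.
#' @export
supplementarySummary <- function(df, fpkm_min = 0.1) {
  df <- readSupplementaryTable(df)
  df <- df[df$fpkm >= fpkm_min & df$ibaq > 0 & df$kdeg_per_h > 0, ,
           drop = FALSE]
  stopIfNot(nrow(df) >= 1L, "no usable records after filtering")
  per_gene_kdeg <- tapply(df$kdeg_per_h, df$gene_id, function(v) v[1])
  ps <- psat(as.numeric(per_gene_kdeg))
  q <- quantile(ps, c(0.25, 0.75))
  log10_te <- log10(df$ibaq * psat(df$kdeg_per_h) / df$fpkm)
  list(
    psat_iqr_ratio = unname(q[2] / q[1]),
    median_log10_te = median(log10_te),
    n_genes = length(per_gene_kdeg),
    n_estimates = nrow(df)
  )
}

#' Write a simulated dataset to disk
#'
#' Writes the tables of [simulateTeDataset()] in the package's external
#' formats: TSVs for the mRNA, protein and stability tables, optionally a
#' FASTA of accompanying sequences, and a JSON file with the planted truth.
#'
#' @param dataset A list from [simulateTeDataset()].
#' @param out_dir Output directory (created if needed).
#' @param sequences Optional `AAStringSet` written as `sequences.fasta`.
#' @return `out_dir`, invisibly.
#' @export
writeSimulatedDataset <- function(dataset, out_dir, sequences = NULL) {
  stopIfNot(all(c("mrna", "protein", "stability", "truth") %in%
                  names(dataset)),
            "'dataset' must come from simulateTeDataset()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(dataset$mrna, file.path(out_dir, "mrna.tsv"))
  writeTsv(dataset$protein, file.path(out_dir, "protein.tsv"))
  writeTsv(dataset$stability, file.path(out_dir, "stability.tsv"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(log10_te = truth$log10_te,
         genes = rownames(truth$log10_te),
         cell_lines = colnames(truth$log10_te),
         consistent = as.list(truth$consistent),
         half_life_h = as.list(truth$half_life_h)),
    file.path(out_dir, "truth.json"), digits = NA)
  if (!is.null(sequences)) {
    Biostrings::writeXStringSet(sequences,
                                file.path(out_dir, "sequences.fasta"))
  }
  invisible(out_dir)
}
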