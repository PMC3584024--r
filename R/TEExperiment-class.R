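## Central container: a SummarizedExperiment of gene x cell-line assays for
## the TE pipeline, with per-gene stability and summary statistics in rowData.

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

.TE_ASSAYS <- c("fpkm", "ibaq", "psat", "te", "log10te")

#' TEExperiment: gene-by-cell-line translation efficiency container
#'
#' An S4 class extending
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the five assays of the TE pipeline (`fpkm`, `ibaq`, `psat`, `te`,
#' `log10te`; `NA` marks a missing observation) with per-gene stability and
#' summary statistics (`half_life_h`, `kdeg_per_h`, `median_log10_te`,
#' `te_cv`, quintiles where assigned) in `rowData`.
#'
#' @slot .. see SummarizedExperiment; no additional slots are added.
#' @aliases TEExperiment-class
#' @exportClass TEExperiment
setClass("TEExperiment", contains = "SummarizedExperiment")

setValidity("TEExperiment", function(object) {
  miss <- setdiff(.TE_ASSAYS, assayNames(object))
  if (length(miss)) {
    return(sprintf("missing assay(s): %s", paste(miss, collapse = ", ")))
  }
  te <- assay(object, "te")
  if (any(te < 0, na.rm = TRUE)) return("'te' assay has negative values")
  ps <- assay(object, "psat")
  if (any(ps <= 0 | ps >= 1, na.rm = TRUE)) {
    return("'psat' assay must lie in (0, 1)")
  }
  TRUE
})

#' Construct a TEExperiment from a long TE table
#'
#' @param te A TE table as produced by [translationEfficiency()] (columns
#'   `gene_id`, `cell_line`, `fpkm`, `ibaq`, `psat`, `te`, `log10_te`).
#' @param stability Optional stability table ([readStabilityTable()]) used to
#'   fill `half_life_h` / `kdeg_per_h` in `rowData`.
#' @param gene_summaries Optional per-gene `data.frame` keyed by `gene_id`
#'   (e.g. median log10 TE, CV, quintiles) merged into `rowData`.
#' @return A `TEExperiment`.
#' @export
TEExperiment <- function(te, stability = NULL, gene_summaries = NULL) {
  stopIfNot(all(c("gene_id", "cell_line", "fpkm", "ibaq", "psat", "te",
                  "log10_te") %in% names(te)),
            "'te' must be a translationEfficiency() table")
  assays <- list(
    fpkm = longToMatrix(te, "fpkm"),
    ibaq = longToMatrix(te, "ibaq"),
    psat = longToMatrix(te, "psat"),
    te = longToMatrix(te, "te"),
    log10te = longToMatrix(te, "log10_te")
  )
  genes <- rownames(assays$fpkm)
  rd <- DataFrame(row.names = genes)
  if (!is.null(stability)) {
    stab <- collapseStability(stability)$stability
    idx <- match(genes, stab$gene_id)
    rd$half_life_h <- stab$half_life_h[idx]
    rd$kdeg_per_h <- stab$kdeg_per_h[idx]
  }
  if (!is.null(gene_summaries)) {
    stopIfNot("gene_id" %in% names(gene_summaries),
              "'gene_summaries' needs a gene_id column")
    idx <- match(genes, gene_summaries$gene_id)
    for (col in setdiff(names(gene_summaries), "gene_id")) {
      rd[[col]] <- gene_summaries[[col]][idx]
    }
  }
  se <- SummarizedExperiment(assays = assays, rowData = rd)
  new("TEExperiment", se)
}

#' @describeIn TEExperiment Long-format table of per-gene, per-cell-line TE
#'   estimates (rows where TE is observed).
#' @param x A `TEExperiment`.
#' @export
setGeneric("teEstimates", function(x) standardGeneric("teEstimates"))

#' @rdname TEExperiment
#' @export
setMethod("teEstimates", "TEExperiment", function(x) {
  out <- matrixToLong(assay(x, "te"), "te")
  for (nm in c("fpkm", "ibaq", "psat")) {
    m <- assay(x, nm)
    out[[nm]] <- m[cbind(match(out$gene_id, rownames(m)),
                         match(out$cell_line, colnames(m)))]
  }
  l10 <- assay(x, "log10te")
  out$log10_te <- l10[cbind(match(out$gene_id, rownames(l10)),
                            match(out$cell_line, colnames(l10)))]
  out[, c("gene_id", "cell_line", "fpkm", "ibaq", "psat", "te", "log10_te")]
})

#' @describeIn TEExperiment Per-gene summary statistics (the `rowData`) as a
#'   plain `data.frame` with a `gene_id` column.
#' @export
setGeneric("geneSummaries", function(x) standardGeneric("geneSummaries"))

#' @rdname TEExperiment
#' @export
setMethod("geneSummaries", "TEExperiment", function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(data.frame(gene_id = rownames(rd), stringsAsFactors = FALSE),
        rd, row.names = NULL)
})

#' @describeIn TEExperiment Compact display.
#' @param object A `TEExperiment`.
#' @export
setMethod("show", "TEExperiment", function(object) {
  te <- assay(object, "te")
  cat(sprintf("TEExperiment: %d genes x %d cell lines (%d TE estimates)\n",
              nrow(te), ncol(te), sum(!is.na(te))))
  cat("cell lines:", paste(colnames(te), collapse = ", "), "\n")
  obs <- assay(object, "log10te")
  if (any(!is.na(obs))) {
    cat(sprintf("median log10 TE (all estimates): %.2f\n",
                median(obs, na.rm = TRUE)))
  }
  if ("te_cv" %in% names(rowData(object))) {
    cv <- rowData(object)$te_cv
    cat(sprintf("genes with cross-line CV: %d (median CV %.3f)\n",
                sum(!is.na(cv)), median(cv, na.rm = TRUE)))
  }
  invisible(NULL)
})
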