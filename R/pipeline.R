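## End-to-end orchestration: ibaq -> normalize -> pair/filter -> TE ->
## variation -> enrichment -> per-gene report, with a run manifest.

#' Configuration for a full pipeline run
#'
#' Inputs may be file paths (TSV/FASTA) or in-memory objects of the same
#' shape.  Either precomputed iBAQ values (`protein`) or raw intensities plus
#' sequences (`intensities` + `sequences`) must be supplied.
#'
#' @param mrna Transcript table (`gene_id`, `cell_line`, `fpkm`) or TSV path.
#' @param protein Optional protein table (`gene_id`, `cell_line`, `ibaq`) or
#'   TSV path, when iBAQ is precomputed.
#' @param intensities Optional raw intensity table (`protein_id`, `gene_id`,
#'   `cell_line`, `intensity`) or TSV path.
#' @param sequences Optional protein sequences (FASTA path, named character
#'   vector or `AAStringSet`); required with `intensities`.
#' @param stability Stability table ([readStabilityTable()]) or TSV path.
#' @param annotation Optional annotation table (`gene_id`, `term_id`,
#'   `category`) or TSV path; enrichment is skipped when absent.
#' @param fpkm_min FPKM exclusion threshold (default 0.1).
#' @param digestion_rule Cleavage rule for iBAQ conversion (default
#'   `"trypsin-simple"`).
#' @param normalize Quantile-normalize iBAQ between cell lines (default TRUE).
#' @param n_perm Permutation replicates for the CV null (default 20).
#' @param seed Integer seed for the permutation null.
#' @param min_genes,bh_max Enrichment thresholds (defaults 2 and 0.05).
#' @param min_lines_cv Minimum cell lines per gene for the CV/quintile
#'   analysis; `NULL` (default) requires data in *all* cell lines
#'   (complete-case).
#' @param out_dir Optional directory; when set, [runPipeline()] writes all
#'   tables and the manifest there.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(mrna, protein = NULL, intensities = NULL,
                           sequences = NULL, stability, annotation = NULL,
                           fpkm_min = 0.1,
                           digestion_rule = c("trypsin-simple", "trypsin-keil"),
                           normalize = TRUE, n_perm = 20L, seed = 1L,
                           min_genes = 2L, bh_max = 0.05,
                           min_lines_cv = NULL, out_dir = NULL) {
  digestion_rule <- match.arg(digestion_rule)
  stopIfNot(!is.null(protein) || (!is.null(intensities) && !is.null(sequences)),
            "supply 'protein' (iBAQ) or 'intensities' + 'sequences'")
  cfg <- list(
    mrna = mrna, protein = protein, intensities = intensities,
    sequences = sequences, stability = stability, annotation = annotation,
    fpkm_min = checkScalarNumeric(fpkm_min, "fpkm_min", lower = 0),
    digestion_rule = digestion_rule,
    normalize = isTRUE(normalize),
    n_perm = checkCount(n_perm, "n_perm"),
    seed = checkCount(seed, "seed", min = 0L),
    min_genes = checkCount(min_genes, "min_genes", min = 0L),
    bh_max = checkScalarNumeric(bh_max, "bh_max", 0, 1),
    min_lines_cv = if (is.null(min_lines_cv)) NULL else
      checkCount(min_lines_cv, "min_lines_cv", min = 2L),
    out_dir = out_dir
  )
  class(cfg) <- "PipelineConfig"
  cfg
}

.loadTable <- function(x, cols, what) {
  df <- if (is.character(x) && length(x) == 1L) readTsv(x) else
    as.data.frame(x)
  stopIfNot(all(cols %in% names(df)),
            sprintf("%s table needs columns: %s", what,
                    paste(cols, collapse = ", ")))
  df
}

.loadSequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readAAStringSet(x)
    names(x) <- sub("\\s.*$", "", names(x))
  }
  x
}

#' Run the full translation-efficiency pipeline
#'
#' Stages, in order: iBAQ conversion (when raw intensities are supplied),
#' between-sample normalization, mRNA/protein pairing with the FPKM filter,
#' TE estimation, per-gene summaries (median log10 TE, cross-line CV,
#' quintiles by median TE and by CV, per-gene log-linear fits), the
#' permutation null for TE consistency, TE x stability quintile
#' intersections, and annotation enrichment for the quintile and intersection
#' groups.  A manifest records the seed, thresholds and per-stage record
#' counts so that every excluded record is accounted for.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @return A list bundle: `ibaq_exclusions`, `pairs`, `te`, `no_stability`,
#'   `gene_summaries`, `fits`, `correlations`, `permutation`,
#'   `intersections`, `enrichment` (NULL without annotation),
#'   `te_experiment` (a [TEExperiment]) and `manifest`.  When
#'   `config$out_dir` is set the tables and manifest are also written there.
#' @export
runPipeline <- function(config) {
  stopIfNot(inherits(config, "PipelineConfig"),
            "'config' must come from pipelineConfig()")
  manifest <- list(seed = config$seed, fpkm_min = config$fpkm_min,
                   digestion_rule = config$digestion_rule,
                   n_perm = config$n_perm, min_genes = config$min_genes,
                   bh_max = config$bh_max,
                   package_version = as.character(utils::packageVersion("transeff")))

  mrna <- .loadTable(config$mrna, c("gene_id", "cell_line", "fpkm"), "mrna")
  stability <- readStabilityTable(config$stability)

  ## stage: ibaq conversion -------------------------------------------------
  ibaq_exclusions <- NULL
  if (!is.null(config$intensities)) {
    intens <- .loadTable(config$intensities,
                         c("protein_id", "gene_id", "cell_line", "intensity"),
                         "intensities")
    seqs <- .loadSequences(config$sequences)
    digests <- digestProteins(seqs, config$digestion_rule)
    conv <- intensityToIbaq(intens, digests)
    protein <- conv$ibaq
    ibaq_exclusions <- conv$exclusions
    manifest$ibaq <- list(records_in = nrow(intens),
                          records_out = nrow(protein),
                          proteins_excluded = nrow(ibaq_exclusions))
  } else {
    protein <- .loadTable(config$protein, c("gene_id", "cell_line", "ibaq"),
                          "protein")
  }

  ## stage: between-sample normalization -------------------------------------
  if (config$normalize && length(unique(protein$cell_line)) >= 2L) {
    m <- longToMatrix(protein, "ibaq")
    protein <- matrixToLong(normalizeBetweenSamples(m), "ibaq")
  }

  ## stage: pair + filter -----------------------------------------------------
  paired <- pairExpression(mrna, protein, config$fpkm_min)
  manifest$pairing <- as.list(paired$counts)

  ## stage: TE ----------------------------------------------------------------
  te_res <- translationEfficiency(paired$pairs, stability)
  manifest$te <- list(pairs_in = nrow(paired$pairs),
                      estimates = nrow(te_res$te),
                      genes_no_stability = length(te_res$no_stability),
                      stability_collisions = length(te_res$stability_collisions))

  ## stage: summaries + variation --------------------------------------------
  te_tab <- te_res$te[!is.na(te_res$te$log10_te), , drop = FALSE]
  summaries <- if (nrow(te_tab)) summarizeGeneTe(te_tab) else
    data.frame(gene_id = character(), median_log10_te = numeric(),
               n_cell_lines = integer(), stringsAsFactors = FALSE)
  n_lines <- length(unique(te_tab$cell_line))
  need <- if (is.null(config$min_lines_cv)) n_lines else config$min_lines_cv
  cv_by_gene <- tapply(te_tab$log10_te, te_tab$gene_id, teCv)
  summaries$te_cv <- ifelse(summaries$n_cell_lines >= need,
                            as.numeric(cv_by_gene[summaries$gene_id]),
                            NA_real_)

  complete <- summaries$gene_id[summaries$n_cell_lines >= need &
                                  !is.na(summaries$te_cv)]
  summaries$te_quintile <- rep(NA_integer_, nrow(summaries))
  summaries$cv_quintile <- rep(NA_integer_, nrow(summaries))
  permutation <- NULL
  intersections <- NULL
  if (length(complete) >= 5L) {
    med <- setNames(summaries$median_log10_te, summaries$gene_id)[complete]
    cvv <- setNames(summaries$te_cv, summaries$gene_id)[complete]
    tq <- assignQuintiles(med)
    cq <- assignQuintiles(cvv)
    summaries$te_quintile[match(complete, summaries$gene_id)] <-
      tq[complete]
    summaries$cv_quintile[match(complete, summaries$gene_id)] <-
      cq[complete]

    full <- te_tab[te_tab$gene_id %in% complete, , drop = FALSE]
    te_mat <- longToMatrix(full, "log10_te")
    if (is.null(config$min_lines_cv) && !anyNA(te_mat) && nrow(te_mat) >= 2L) {
      permutation <- permutationNull(te_mat, config$n_perm, config$seed)
    }

    stab_genes <- intersect(complete, stability$gene_id)
    if (length(stab_genes) >= 5L) {
      kd <- collapseStability(stability)$stability
      sq <- assignQuintiles(setNames(
        kd$half_life_h[match(stab_genes, kd$gene_id)], stab_genes))
      intersections <- intersectQuintiles(tq[stab_genes], sq)
    }
  }
  manifest$variation <- list(genes_summarized = nrow(summaries),
                             genes_complete_case = length(complete),
                             required_lines = need)

  ## stage: per-gene fits ------------------------------------------------------
  fits <- if (nrow(te_tab)) perGeneLogLinearFit(te_tab) else NULL
  correlations <- if (nrow(te_tab) >= 3L) correlationSummary(te_tab) else NULL

  ## stage: enrichment ---------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$annotation) && length(complete) >= 5L) {
    ann <- .loadTable(config$annotation, c("gene_id", "term_id"), "annotation")
    groups <- split(complete,
                    paste0("te_q", summaries$te_quintile[
                      match(complete, summaries$gene_id)]))
    if (!is.null(intersections)) {
      groups <- c(groups, Filter(length, intersections))
    }
    enrichment <- enrichGroups(groups, ann, background = complete,
                               min_genes = config$min_genes,
                               bh_max = config$bh_max)
    manifest$enrichment <- list(groups = length(groups),
                                terms_tested = nrow(enrichment),
                                terms_passing = sum(enrichment$passes))
  }

  tex <- if (nrow(te_res$te)) {
    TEExperiment(te_res$te, stability, summaries)
  } else NULL

  bundle <- list(
    ibaq_exclusions = ibaq_exclusions,
    pairs = paired$pairs,
    te = te_res$te,
    no_stability = te_res$no_stability,
    gene_summaries = summaries,
    fits = fits,
    correlations = correlations,
    permutation = permutation,
    intersections = intersections,
    enrichment = enrichment,
    te_experiment = tex,
    manifest = manifest
  )
  if (!is.null(config$out_dir)) .writeBundle(bundle, config$out_dir)
  bundle
}

.writeBundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(bundle$te, file.path(out_dir, "te_estimates.tsv"))
  writeTsv(bundle$gene_summaries, file.path(out_dir, "gene_summaries.tsv"))
  if (!is.null(bundle$fits)) {
    writeTsv(bundle$fits, file.path(out_dir, "gene_fits.tsv"))
  }
  if (!is.null(bundle$enrichment)) {
    writeTsv(bundle$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(bundle$ibaq_exclusions)) {
    writeTsv(bundle$ibaq_exclusions, file.path(out_dir, "ibaq_exclusions.tsv"))
  }
  if (!is.null(bundle$permutation)) {
    p <- bundle$permutation
    jsonlite::write_json(
      list(n_perm = p$n_perm, t_statistic = p$t_statistic,
           p_value = p$p_value, cv_threshold = p$cv_threshold,
           frac_observed_below_threshold = p$frac_observed_below_threshold,
           frac_permuted_below_threshold = p$frac_permuted_below_threshold),
      file.path(out_dir, "permutation.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Export a per-gene report
#'
#' One record per requested gene with its per-cell-line estimates and
#' summary statistics; genes without a TE estimate are flagged rather than
#' omitted, and unknown gene ids are listed in a `not_found` block.
#'
#' @param bundle A result bundle from [runPipeline()].
#' @param gene_ids Character vector of genes to report; `NULL` (default)
#'   reports every gene in the TE table.
#' @return A list with `report` (`data.frame`, one row per gene and cell
#'   line plus summary columns) and `not_found` (character).
#' @export
exportGeneReport <- function(bundle, gene_ids = NULL) {
  stopIfNot(is.list(bundle) && !is.null(bundle$te) &&
              !is.null(bundle$gene_summaries),
            "'bundle' must come from runPipeline()")
  known <- unique(bundle$te$gene_id)
  if (is.null(gene_ids)) gene_ids <- known
  not_found <- setdiff(gene_ids, known)
  found <- intersect(gene_ids, known)
  rep_tab <- bundle$te[bundle$te$gene_id %in% found, , drop = FALSE]
  sm <- bundle$gene_summaries
  idx <- match(rep_tab$gene_id, sm$gene_id)
  for (col in setdiff(names(sm), "gene_id")) {
    rep_tab[[col]] <- sm[[col]][idx]
  }
  if (!is.null(bundle$fits)) {
    fidx <- match(rep_tab$gene_id, bundle$fits$gene_id)
    rep_tab$fit_r_squared <- bundle$fits$r_squared[fidx]
    rep_tab$fit_p_value <- bundle$fits$p_value[fidx]
  }
  rownames(rep_tab) <- NULL
  list(report = rep_tab, not_found = not_found)
}
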