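## Synthetic data with planted ground truth.  The generator emulates the
## statistical structure the analysis assumes -- approximately log-normal
## FPKM, iBAQ and TE, log-normal protein half-lives, a subpopulation of genes
## with a constant planted TE across cell lines -- so every downstream stage
## is testable without external data.

#' Configuration for the synthetic TE dataset generator
#'
#' Defaults encode the study conditions the generator emulates: five cell
#' lines; planted log10 TE drawn from N(3.12, 0.72^2) (the observed location
#' and spread of the log10 TE distribution); half-lives log-normal with
#' median 36 h and a log-sd of 0.44, which reproduces an interquartile PSAT
#' range of roughly 0.015--0.027; FPKM log-normal with a log10 interdecile
#' range of about two orders of magnitude; 20% dropout per observation
#' (mirroring the partial overlap of genes across lines); and half the genes
#' planted with a cell-line-constant TE.
#'
#' @param n_genes Number of genes.
#' @param n_cell_lines Number of cell lines (default 5).
#' @param seed Integer seed; expanded internally into independent per-table
#'   substreams so adding a table never shifts existing draws.
#' @param frac_consistent Fraction of genes whose planted log10 TE is
#'   identical in every cell line (default 0.5); the rest redraw it
#'   independently per line.
#' @param log10_te_median,log10_te_sd Location and SD of planted log10 TE
#'   (defaults 3.12 and 0.72).
#' @param te_noise_sd Log10-scale SD of multiplicative measurement noise
#'   applied to protein abundance (default 0.1; 0 = noise-free).
#' @param half_life_log_mean,half_life_log_sd Natural-log parameters of the
#'   lognormal half-life distribution in hours (defaults log(36) and 0.44).
#' @param fpkm_log_mean,fpkm_log_sd Natural-log parameters of the lognormal
#'   FPKM distribution (defaults log(10) and 1.8).
#' @param dropout_rate Probability that any single mRNA or protein
#'   observation is missing, applied independently to each (default 0.2).
#' @param mrna_noise_sd Optional log10-scale noise on FPKM (default 0: mRNA
#'   treated as exact so TE recovery is analytically checkable).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_genes = 2000L, n_cell_lines = 5L, seed = 1L,
                             frac_consistent = 0.5,
                             log10_te_median = 3.12, log10_te_sd = 0.72,
                             te_noise_sd = 0.1,
                             half_life_log_mean = log(36),
                             half_life_log_sd = 0.44,
                             fpkm_log_mean = log(10), fpkm_log_sd = 1.8,
                             dropout_rate = 0.2, mrna_noise_sd = 0) {
  cfg <- list(
    n_genes = checkCount(n_genes, "n_genes"),
    n_cell_lines = checkCount(n_cell_lines, "n_cell_lines"),
    seed = checkCount(seed, "seed", min = 0L),
    frac_consistent = checkScalarNumeric(frac_consistent, "frac_consistent",
                                         0, 1),
    log10_te_median = checkScalarNumeric(log10_te_median, "log10_te_median"),
    log10_te_sd = checkScalarNumeric(log10_te_sd, "log10_te_sd", lower = 0),
    te_noise_sd = checkScalarNumeric(te_noise_sd, "te_noise_sd", lower = 0),
    half_life_log_mean = checkScalarNumeric(half_life_log_mean,
                                            "half_life_log_mean"),
    half_life_log_sd = checkScalarNumeric(half_life_log_sd,
                                          "half_life_log_sd", lower = 0),
    fpkm_log_mean = checkScalarNumeric(fpkm_log_mean, "fpkm_log_mean"),
    fpkm_log_sd = checkScalarNumeric(fpkm_log_sd, "fpkm_log_sd", lower = 0),
    dropout_rate = checkScalarNumeric(dropout_rate, "dropout_rate", 0, 1),
    mrna_noise_sd = checkScalarNumeric(mrna_noise_sd, "mrna_noise_sd",
                                       lower = 0)
  )
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Generate random protein sequences
#'
#' Sequences over the 20 standard amino acids with uniform residue
#' frequencies by default (overridable); digestion and iBAQ tests only need
#' K/R placement, not biological realism.
#'
#' @param n Number of sequences.
#' @param length_range Integer interval `c(min, max)` of sequence lengths.
#' @param seed Integer seed.
#' @param residue_freqs Optional named numeric vector of residue frequencies
#'   over the 20-letter alphabet (normalised internally).
#' @return A `Biostrings::AAStringSet` named `P0001`, `P0002`, ...
#' @export
simulateProteinSequences <- function(n, length_range = c(50L, 400L), seed = 1L,
                                     residue_freqs = NULL) {
  n <- checkCount(n, "n")
  seed <- checkCount(seed, "seed", min = 0L)
  stopIfNot(is.numeric(length_range) && length(length_range) == 2L &&
              all(length_range >= 1) && length_range[1] <= length_range[2],
            "'length_range' must be an interval of lengths >= 1")
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(residue_freqs)) {
    probs <- rep(1 / 20, 20)
  } else {
    stopIfNot(all(names(residue_freqs) %in% alphabet) &&
                all(residue_freqs >= 0) && sum(residue_freqs) > 0,
              "'residue_freqs' must be named by standard residues, >= 0")
    probs <- setNames(rep(0, 20), alphabet)
    probs[names(residue_freqs)] <- residue_freqs
    probs <- probs / sum(probs)
  }
  set.seed(seed)
  lens <- sample(seq.int(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(alphabet, L, replace = TRUE, prob = probs), collapse = ""),
    character(1))
  names(seqs) <- sprintf("P%04d", seq_len(n))
  Biostrings::AAStringSet(seqs)
}

#' Generate a synthetic paired expression dataset with planted truth
#'
#' For each gene a half-life is drawn log-normally and converted to a PSAT;
#' FPKM is drawn log-normally per gene and cell line; a planted log10 TE is
#' drawn from N(`log10_te_median`, `log10_te_sd`^2) once per gene (consistent
#' genes) or once per gene and line (the rest); protein abundance is then the
#' inversion of the TE formula, iBAQ = TE x FPKM / PSAT, multiplied by
#' lognormal measurement noise of log10-sd `te_noise_sd`.  Dropout removes
#' each mRNA and each protein observation independently.  Before dropout the
#' gene sets of all tables are identical.
#'
#' @param config A `SimulationConfig` from [simulationConfig()].
#' @return A list with `mrna` (`gene_id`, `cell_line`, `fpkm`), `protein`
#'   (`gene_id`, `cell_line`, `ibaq`), `stability` (`gene_id`, `half_life_h`,
#'   `kdeg_per_h`) and `truth` (list: `log10_te` gene x line matrix of
#'   planted values, `consistent` named logical, `half_life_h` named
#'   numeric).
#' @export
simulateTeDataset <- function(config = simulationConfig()) {
  stopIfNot(inherits(config, "SimulationConfig"),
            "'config' must come from simulationConfig()")
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  lines <- sprintf("CL%d", seq_len(cfg$n_cell_lines))
  ## independent substreams per table: stability, fpkm, planted TE,
  ## consistency flags, protein noise, dropout (reserved order)
  ss <- substreamSeeds(cfg$seed, 6L)

  set.seed(ss[1])
  half_life <- rlnorm(cfg$n_genes, cfg$half_life_log_mean,
                      cfg$half_life_log_sd)
  names(half_life) <- genes
  psat_g <- psat(kdegFromHalfLife(half_life))

  set.seed(ss[2])
  fpkm <- matrix(rlnorm(cfg$n_genes * cfg$n_cell_lines,
                        cfg$fpkm_log_mean, cfg$fpkm_log_sd),
                 nrow = cfg$n_genes, dimnames = list(genes, lines))
  if (cfg$mrna_noise_sd > 0) {
    fpkm <- fpkm * 10^matrix(rnorm(length(fpkm), 0, cfg$mrna_noise_sd),
                             nrow = cfg$n_genes)
  }

  set.seed(ss[4])
  consistent <- setNames(seq_len(cfg$n_genes) <=
                           round(cfg$frac_consistent * cfg$n_genes), genes)

  set.seed(ss[3])
  per_gene <- rnorm(cfg$n_genes, cfg$log10_te_median, cfg$log10_te_sd)
  per_cell <- matrix(rnorm(cfg$n_genes * cfg$n_cell_lines,
                           cfg$log10_te_median, cfg$log10_te_sd),
                     nrow = cfg$n_genes)
  log10_te <- ifelse(matrix(consistent, nrow = cfg$n_genes,
                            ncol = cfg$n_cell_lines),
                     matrix(per_gene, nrow = cfg$n_genes,
                            ncol = cfg$n_cell_lines),
                     per_cell)
  dimnames(log10_te) <- list(genes, lines)

  ibaq <- 10^log10_te * fpkm / psat_g
  set.seed(ss[5])
  if (cfg$te_noise_sd > 0) {
    ibaq <- ibaq * 10^matrix(rnorm(length(ibaq), 0, cfg$te_noise_sd),
                             nrow = cfg$n_genes)
  }

  set.seed(ss[6])
  drop_m <- matrix(runif(length(fpkm)) < cfg$dropout_rate,
                   nrow = cfg$n_genes)
  drop_p <- matrix(runif(length(ibaq)) < cfg$dropout_rate,
                   nrow = cfg$n_genes)
  fpkm_obs <- fpkm; fpkm_obs[drop_m] <- NA_real_
  ibaq_obs <- ibaq; ibaq_obs[drop_p] <- NA_real_

  list(
    mrna = matrixToLong(fpkm_obs, "fpkm"),
    protein = matrixToLong(ibaq_obs, "ibaq"),
    stability = data.frame(gene_id = genes,
                           half_life_h = unname(half_life),
                           kdeg_per_h = unname(kdegFromHalfLife(half_life)),
                           stringsAsFactors = FALSE),
    truth = list(log10_te = log10_te, consistent = consistent,
                 half_life_h = half_life)
  )
}

#' Generate a synthetic gene-to-term annotation with planted enrichment
#'
#' Background terms sample their genes uniformly from the universe; planted
#' terms sample preferentially from a target quintile with the stated odds
#' ratio (a gene in the target quintile is `odds_ratio` times as likely to
#' be picked as any other gene).  An odds ratio of 1 makes planted terms
#' indistinguishable from background.
#'
#' @param genes Character vector of gene ids (the universe).
#' @param quintiles Named integer vector (1..5) over `genes`, e.g. from
#'   [assignQuintiles()].
#' @param n_terms Number of background terms (may be 0).
#' @param planted Named integer vector: term id -> target quintile in 1..5
#'   (may be empty).
#' @param odds_ratio Sampling odds ratio for planted terms (default 20).
#' @param term_size Genes per term (default 50).
#' @param seed Integer seed.
#' @param category Category label for all terms (default "SIM").
#' @return A `data.frame` with `gene_id`, `term_id`, `category`.
#' @export
simulateAnnotation <- function(genes, quintiles, n_terms, planted = integer(),
                               odds_ratio = 20, term_size = 50L, seed = 1L,
                               category = "SIM") {
  stopIfNot(length(genes) >= 1L, "'genes' must be non-empty")
  n_terms <- checkCount(n_terms, "n_terms", min = 0L)
  term_size <- checkCount(term_size, "term_size")
  checkScalarNumeric(odds_ratio, "odds_ratio", lower = 0,
                     strict_lower = TRUE)
  seed <- checkCount(seed, "seed", min = 0L)
  stopIfNot(term_size <= length(genes), "'term_size' exceeds the universe")
  if (length(planted)) {
    stopIfNot(!is.null(names(planted)) && all(planted %in% 1:5),
              "'planted' must map term ids to quintiles in 1..5")
    stopIfNot(all(genes %in% names(quintiles)),
              "'quintiles' must cover all genes when terms are planted")
  }
  set.seed(seed)
  rows <- list()
  for (t in seq_len(n_terms)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sample(genes, term_size),
      term_id = sprintf("BG%04d", t), category = category,
      stringsAsFactors = FALSE)
  }
  for (term in names(planted)) {
    w <- ifelse(quintiles[genes] == planted[[term]], odds_ratio, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sample(genes, term_size, prob = w),
      term_id = term, category = category, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), term_id = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
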