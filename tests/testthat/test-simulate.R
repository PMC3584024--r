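test_that("sequence generation is deterministic and respects the length interval", {
  s1 <- simulateProteinSequences(3, c(50, 60), seed = 1)
  s2 <- simulateProteinSequences(3, c(50, 60), seed = 1)
  expect_identical(as.character(s1), as.character(s2))
  expect_true(all(Biostrings::width(s1) >= 50 & Biostrings::width(s1) <= 60))

  one <- simulateProteinSequences(1, c(10, 10), seed = 7)
  expect_equal(Biostrings::width(one), 10)

  expect_error(simulateProteinSequences(0, c(5, 10)), "n")
  expect_error(simulateProteinSequences(2, c(10, 5)), "length_range")
})

test_that("K/R frequency sits inside exact binomial 99% bounds", {
  seqs <- simulateProteinSequences(100, c(20, 400), seed = 2)
  residues <- unlist(strsplit(as.character(seqs), ""))
  n <- length(residues)
  k <- sum(residues %in% c("K", "R"))
  # uniform alphabet: P(K or R) = 2/20; exact central 99% binomial bounds
  bounds <- qbinom(c(0.005, 0.995), n, 2 / 20)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  # frequency override shifts composition as requested
  krOnly <- simulateProteinSequences(5, c(30, 30), seed = 3,
                                     residue_freqs = c(K = 1, R = 1))
  expect_true(all(strsplit(paste(as.character(krOnly), collapse = ""),
                           "")[[1]] %in% c("K", "R")))
})

test_that("dataset generation is deterministic and keeps gene sets aligned", {
  cfg <- simulationConfig(n_genes = 200, seed = 5, dropout_rate = 0)
  d1 <- simulateTeDataset(cfg)
  d2 <- simulateTeDataset(cfg)
  expect_identical(d1, d2)
  # before dropout every table covers the same gene multiset
  expect_setequal(unique(d1$mrna$gene_id), d1$stability$gene_id)
  expect_setequal(unique(d1$protein$gene_id), d1$stability$gene_id)
  expect_equal(nrow(d1$mrna), 200 * 5)
})

test_that("planted log10 TE distribution matches the configured median", {
  cfg <- simulationConfig(n_genes = 2000, seed = 6)
  ds <- simulateTeDataset(cfg)
  expect_lt(abs(median(ds$truth$log10_te) - 3.12), 0.05)
  # consistent genes carry identical planted TE in every cell line
  cons <- names(ds$truth$consistent)[ds$truth$consistent]
  expect_true(all(apply(ds$truth$log10_te[cons, ], 1,
                        function(r) length(unique(r)) == 1)))
  incons <- names(ds$truth$consistent)[!ds$truth$consistent]
  expect_true(all(apply(ds$truth$log10_te[incons, ], 1,
                        function(r) length(unique(r)) > 1)))
})

test_that("noise-free recovery: TE CV is zero and ranks are preserved", {
  cfg <- simulationConfig(n_genes = 300, seed = 7, frac_consistent = 1,
                          te_noise_sd = 0, dropout_rate = 0)
  ds <- simulateTeDataset(cfg)
  pr <- pairExpression(ds$mrna, ds$protein)
  te <- translationEfficiency(pr$pairs, ds$stability)$te
  cvs <- tapply(te$log10_te, te$gene_id, teCv)
  expect_lt(max(abs(cvs)), 1e-12)
  planted <- ds$truth$log10_te[cbind(te$gene_id, te$cell_line)]
  expect_gt(cor(te$log10_te, planted, method = "spearman"), 0.99)
})

test_that("dropout thins tables at about the configured rate", {
  cfg <- simulationConfig(n_genes = 1000, seed = 8, dropout_rate = 0.3)
  ds <- simulateTeDataset(cfg)
  frac_m <- nrow(ds$mrna) / (1000 * 5)
  frac_p <- nrow(ds$protein) / (1000 * 5)
  expect_lt(abs(frac_m - 0.7), 0.02)
  expect_lt(abs(frac_p - 0.7), 0.02)
})

test_that("annotation generator: empty, invalid quintile, and null odds ratio", {
  genes <- sprintf("g%03d", 1:500)
  quint <- assignQuintiles(setNames(seq_along(genes), genes))
  expect_equal(nrow(simulateAnnotation(genes, quint, n_terms = 0)), 0)
  expect_error(simulateAnnotation(genes, quint, 1,
                                  planted = c(t1 = 9L)), "1..5")

  # odds ratio 1: planted-term gene counts per quintile look uniform
  # (chi-square p-values over replicate seeds are not skewed small; a large
  # universe keeps the without-replacement correction negligible)
  big <- sprintf("G%04d", 1:5000)
  bigq <- assignQuintiles(setNames(seq_along(big), big))
  ps <- sapply(1:40, function(s) {
    ann <- simulateAnnotation(big, bigq, n_terms = 0,
                              planted = c(t1 = 3L), odds_ratio = 1,
                              term_size = 100, seed = s)
    counts <- table(factor(bigq[ann$gene_id], levels = 1:5))
    suppressWarnings(chisq.test(counts)$p.value)
  })
  expect_lt(mean(ps < 0.05), 0.25)
  # chi-square p-values are mildly discrete; suppress the KS ties note
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
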