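toy_mrna <- data.frame(
  gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
  cell_line = "A",
  fpkm = c(5, 0.05, 0.1, 12, 0.09, 3)
)
toy_protein <- data.frame(
  gene_id = c("g1", "g2", "g3", "g4", "g5"),
  cell_line = "A",
  ibaq = c(100, 200, 300, 400, 500)
)

test_that("pairing joins, filters below-threshold FPKM, and reports counts", {
  out <- pairExpression(toy_mrna, toy_protein)
  # g6 unmatched; g2 and g5 below 0.1; g3 at exactly 0.1 is retained
  expect_setequal(out$pairs$gene_id, c("g1", "g3", "g4"))
  expect_equal(unname(out$counts["kept"]), 3L)
  expect_equal(unname(out$counts["below_fpkm_min"]), 2L)
  expect_equal(unname(out$counts["mrna_unmatched"]), 1L)
  expect_equal(unname(out$counts["matched"]),
               unname(out$counts["kept"] + out$counts["below_fpkm_min"]))
})

test_that("duplicate (gene, cell line) keys are a data-integrity error", {
  dup <- rbind(toy_mrna, toy_mrna[1, ])
  expect_error(pairExpression(dup, toy_protein), "duplicate.*g1")
})

test_that("TE equals the direct formula and scales linearly", {
  set.seed(5)
  n <- 50
  pairs <- data.frame(gene_id = sprintf("g%02d", 1:n), cell_line = "A",
                      fpkm = rlnorm(n, 2, 1), ibaq = rlnorm(n, 10, 2))
  stab <- data.frame(gene_id = pairs$gene_id,
                     half_life_h = rlnorm(n, log(36), 0.4))
  te <- translationEfficiency(pairs, stab)$te
  direct <- pairs$ibaq * (1 - exp(-log(2) / stab$half_life_h)) / pairs$fpkm
  expect_equal(te$te, direct, tolerance = 1e-12)
  expect_equal(te$log10_te, log10(direct), tolerance = 1e-12)

  up <- pairs; up$ibaq <- up$ibaq * 3
  expect_equal(translationEfficiency(up, stab)$te$te, te$te * 3)
  wide <- pairs; wide$fpkm <- wide$fpkm * 4
  expect_equal(translationEfficiency(wide, stab)$te$te, te$te / 4)
})

test_that("genes without stability are excluded and reported, not dropped silently", {
  pairs <- data.frame(gene_id = c("g1", "g2"), cell_line = "A",
                      fpkm = c(1, 2), ibaq = c(10, 20))
  stab <- data.frame(gene_id = "g1", half_life_h = 36)
  out <- translationEfficiency(pairs, stab)
  expect_equal(out$te$gene_id, "g1")
  expect_equal(out$no_stability, "g2")
})

test_that("duplicated stability entries collapse to the geometric mean kdeg", {
  pairs <- data.frame(gene_id = "g1", cell_line = "A", fpkm = 1, ibaq = 1)
  stab <- data.frame(gene_id = c("g1", "g1"), half_life_h = c(18, 72))
  out <- translationEfficiency(pairs, stab)
  expect_equal(out$stability_collisions, "g1")
  gm_kdeg <- exp(mean(log(log(2) / c(18, 72))))
  expect_equal(out$te$psat, 1 - exp(-gm_kdeg))
})

test_that("zero iBAQ yields TE 0 with undefined log10 TE", {
  pairs <- data.frame(gene_id = "g1", cell_line = "A", fpkm = 1, ibaq = 0)
  stab <- data.frame(gene_id = "g1", half_life_h = 36)
  te <- translationEfficiency(pairs, stab)$te
  expect_equal(te$te, 0)
  expect_true(is.na(te$log10_te))
})

test_that("sequestration adjustment has the right identities", {
  expect_equal(adjustTeForSequestration(2.5, 0), 2.5)
  expect_equal(adjustTeForSequestration(1.2, 0.9), 2.2)  # log10(10) = 1
  expect_error(adjustTeForSequestration(2.5, 1), "< 1")
})

test_that("per-gene median follows the order-statistic conventions", {
  expect_equal(summarizeGeneTe(data.frame(
    gene_id = "g", log10_te = rep(3.3, 5)))$median_log10_te, 3.3)
  expect_equal(summarizeGeneTe(data.frame(
    gene_id = "g", log10_te = c(1, 2, 10)))$median_log10_te, 2)
  # even count: midpoint of the two central order statistics, against a
  # sorting oracle over random draws
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(4)
    s <- sort(v)
    expect_equal(summarizeGeneTe(data.frame(
      gene_id = "g", log10_te = v))$median_log10_te, (s[2] + s[3]) / 2)
  }
  expect_error(summarizeGeneTe(data.frame(gene_id = character(),
                                          log10_te = numeric())), "usable")
})

test_that("correlation summary: monotone extremes and the rank-formula oracle", {
  inc <- data.frame(gene_id = sprintf("g%d", 1:10), cell_line = "A",
                    fpkm = 1:10, ibaq = (1:10)^2)
  expect_equal(correlationSummary(inc, "combined")$spearman_r, 1)
  dec <- inc; dec$ibaq <- rev(dec$ibaq)
  expect_equal(correlationSummary(dec, "combined")$spearman_r, -1)

  set.seed(9)
  rnd <- data.frame(gene_id = sprintf("g%d", 1:10), cell_line = "A",
                    fpkm = rlnorm(10), ibaq = rlnorm(10))
  expect_equal(correlationSummary(rnd, "combined")$spearman_r,
               oracleSpearmanTieFree(rnd$fpkm, rnd$ibaq), tolerance = 1e-12)

  const <- inc; const$ibaq <- 5
  expect_true(correlationSummary(const, "combined")$degenerate)
})

test_that("correlation summary groups per cell line and combined", {
  set.seed(10)
  df <- data.frame(gene_id = rep(sprintf("g%d", 1:8), 2),
                   cell_line = rep(c("A", "B"), each = 8),
                   fpkm = rlnorm(16), ibaq = rlnorm(16))
  out <- correlationSummary(df)
  expect_setequal(out$cell_line, c("A", "B", "combined"))
  expect_equal(out$n_pairs[out$cell_line == "combined"], 16L)
})

test_that("per-gene log-linear fit: collinear, closed form, and refusal", {
  col <- data.frame(gene_id = "g", cell_line = c("A", "B", "C", "D"),
                    fpkm = c(1, 10, 100, 1000), ibaq = c(2, 20, 200, 2000))
  f <- suppressWarnings(perGeneLogLinearFit(col))  # exact fit warns in summary.lm
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$slope, 1, tolerance = 1e-12)

  # 3-point closed-form least squares in the log10 coordinates
  x <- log10(c(1, 4, 9)); y <- log10(c(3, 7, 50))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  icpt <- mean(y) - slope * mean(x)
  df3 <- data.frame(gene_id = "g", cell_line = c("A", "B", "C"),
                    fpkm = c(1, 4, 9), ibaq = c(3, 7, 50))
  f3 <- perGeneLogLinearFit(df3)
  expect_equal(f3$slope, slope, tolerance = 1e-12)
  expect_equal(f3$intercept, icpt, tolerance = 1e-12)

  two <- df3[1:2, ]
  expect_false(perGeneLogLinearFit(two)$fitted)

  # slope-0 data with noise: p-values behave like a null test (roughly
  # uniform rejection rate at alpha = 0.2 over replicate fits)
  set.seed(12)
  ps <- replicate(200, {
    d <- data.frame(gene_id = "g", cell_line = paste0("L", 1:5),
                    fpkm = rlnorm(5, 1, 1), ibaq = rlnorm(5, 5, 0.5))
    perGeneLogLinearFit(d)$p_value
  })
  expect_gt(mean(ps < 0.2), 0.10)
  expect_lt(mean(ps < 0.2), 0.32)
})
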