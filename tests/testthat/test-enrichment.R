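test_that("EASE score: jackknife degenerate cases give p = 1", {
  expect_equal(easeScore(0, 10, 5, 100), 1)
  expect_equal(easeScore(1, 10, 5, 100), 1)
  expect_error(easeScore(-1, 2, 3, 4), "non-negative")
})

test_that("EASE equals the exhaustive hypergeometric enumeration", {
  expect_equal(easeScore(5, 5, 5, 5), oracleUpperTail(4, 5, 5, 5),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:200) {
    a <- sample(0:12, 1); b <- sample(0:30, 1)
    c_ <- sample(0:40, 1); d <- sample(0:200, 1)
    expect_equal(easeScore(a, b, c_, d),
                 oracleUpperTail(max(a - 1, 0), b, c_, d),
                 tolerance = 1e-10)
    # cross-check the plain upper tail against fisher.test
    if (a + b > 0 && c_ + d > 0 && a + c_ > 0 && b + d > 0) {
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                        alternative = "greater")$p.value
      expect_equal(fisherUpperTail(a, b, c_, d), ft, tolerance = 1e-9)
    }
  }
})

test_that("EASE is never smaller than the plain Fisher upper tail", {
  set.seed(42)
  for (i in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:30, 1)
    c_ <- sample(0:30, 1); d <- sample(0:100, 1)
    expect_gte(easeScore(a, b, c_, d), fisherUpperTail(a, b, c_, d))
  }
})

test_that("Benjamini-Hochberg step-up behaves as specified", {
  expect_equal(benjaminiHochberg(0.03), 0.03)
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  # order preserved; monotone non-decreasing on sorted input
  p <- c(0.04, 0.001, 0.5, 0.2)
  adj <- benjaminiHochberg(p)
  expect_equal(adj, benjaminiHochberg(sort(p))[rank(p)])
  expect_true(all(diff(benjaminiHochberg(sort(p))) >= 0))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichGroups builds correct tables, skips a < min_genes, flags at BH", {
  bg <- sprintf("g%02d", 1:40)
  groups <- list(grp = bg[1:10])
  ann <- rbind(
    data.frame(gene_id = bg[1:8], term_id = "hit", category = "GO"),
    data.frame(gene_id = bg, term_id = "everything", category = "GO"),
    data.frame(gene_id = bg[c(1, 25)], term_id = "singleton", category = "GO")
  )
  res <- enrichGroups(groups, ann, bg)
  # term annotating every background gene discriminates nothing
  expect_equal(res$ease_p[res$term_id == "everything"], 1)
  # a = 1 in the group is below the min_genes = 2 threshold
  expect_false("singleton" %in% res$term_id)
  hit <- res[res$term_id == "hit", ]
  expect_equal(c(hit$a, hit$b, hit$c, hit$d), c(8, 2, 0, 30))
  expect_equal(hit$ease_p, oracleUpperTail(7, 2, 0, 30), tolerance = 1e-12)
  expect_true(hit$passes)
  # group gene outside the background is a data-integrity error
  expect_error(enrichGroups(list(g = "absent"), ann, bg), "absent")
})

test_that("planted enrichment is recovered and the null is controlled", {
  genes <- sprintf("g%04d", 1:2000)
  set.seed(43)
  quint <- assignQuintiles(setNames(rnorm(2000), genes))
  ann <- simulateAnnotation(genes, quint, n_terms = 10,
                            planted = c(planted_term = 5L),
                            odds_ratio = 20, term_size = 50, seed = 7)
  groups <- split(names(quint), quint)
  names(groups) <- paste0("q", names(groups))
  res <- enrichGroups(groups, ann, genes)
  top5 <- res[res$group == "q5" & res$term_id == "planted_term", ]
  expect_true(top5$passes)
  # background terms do not pass in the target quintile
  expect_false(any(res$passes[res$group == "q5" &
                                res$term_id != "planted_term"]))
})
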