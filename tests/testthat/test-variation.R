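test_that("TE CV follows the sample-SD-over-mean definition", {
  expect_equal(teCv(c(2, 2, 2, 2)), 0)
  expect_equal(teCv(c(1, 2, 3)), 0.5)          # sample SD 1, mean 2
  expect_equal(teCv(7 * c(1, 2, 3)), 0.5)      # scale invariance
  expect_true(is.na(teCv(3)))                  # < 2 values
  expect_true(is.na(teCv(c(-1, 1))))           # zero mean
})

test_that("permutation null separates planted-consistent data from its null", {
  m <- observedTeMatrix(120, seed = 31, frac_consistent = 1, te_noise_sd = 0)
  res <- permutationNull(m, n_perm = 20, seed = 1)
  expect_true(all(abs(res$observed_cvs) < 1e-12))
  expect_gt(mean(res$permuted_cvs), 0.01)
  expect_lt(res$p_value, 1e-10)
  expect_equal(length(res$permuted_cvs), 20 * nrow(m))
})

test_that("permutation null is calm under exchangeability and deterministic", {
  # i.i.d. values across genes and lines: observed and permuted CV means
  # agree within Monte-Carlo error
  set.seed(32)
  diffs <- sapply(1:5, function(s) {
    m <- matrix(rnorm(150 * 5, 3, 0.7), 150, 5)
    r <- permutationNull(m, n_perm = 20, seed = s)
    mean(r$observed_cvs, na.rm = TRUE) - mean(r$permuted_cvs, na.rm = TRUE)
  })
  expect_lt(max(abs(diffs)), 0.05)

  m <- matrix(rnorm(60 * 5, 3, 0.7), 60, 5)
  r1 <- permutationNull(m, n_perm = 10, seed = 99)
  r2 <- permutationNull(m, n_perm = 10, seed = 99)
  expect_identical(r1, r2)

  expect_error(permutationNull(m, n_perm = 0), "n_perm")
  const <- matrix(1, 10, 3)
  expect_true(permutationNull(const, n_perm = 2, seed = 1)$degenerate)
})

test_that("quintile assignment partitions with near-equal sizes", {
  set.seed(33)
  v <- setNames(rnorm(1810), sprintf("g%04d", 1:1810))
  q <- assignQuintiles(v)
  expect_equal(as.integer(table(q)), rep(362L, 5))
  # remainder goes to the lower quintiles
  v2 <- setNames(rnorm(1807), sprintf("g%04d", 1:1807))
  expect_equal(as.integer(table(assignQuintiles(v2))),
               c(362L, 362L, 361L, 361L, 361L))
  # quintile 1 holds the lowest values
  expect_true(max(v[q == 1]) <= min(v[q == 5]))
})

test_that("quintiles: five distinct values, ties, and the brute-force oracle", {
  v <- setNames(c(10, 2, 7, 1, 5), letters[1:5])
  q <- assignQuintiles(v)
  expect_equal(unname(q[order(v)]), 1:5)

  # tie spanning a boundary resolves by lexicographic gene id
  vt <- setNames(c(1, 2, 2, 2, 3, 4, 5, 6, 7, 8),
                 c("j", "b", "a", "c", "e", "f", "g", "h", "i", "d"))
  qt <- assignQuintiles(vt)
  expect_equal(qt, oracleQuintiles(vt))
  expect_equal(unname(qt[c("a", "b", "c")]), c(1L, 2L, 2L))

  set.seed(34)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    vv <- setNames(sample(1:8, n, replace = TRUE),
                   sample(sprintf("g%02d", 1:n)))
    expect_equal(assignQuintiles(vv), oracleQuintiles(vv))
  }
  expect_error(assignQuintiles(setNames(1:4, letters[1:4])), "at least 5")
})

test_that("quintile intersections form the four corners correctly", {
  # identical rankings: opposing corners are empty
  v <- setNames(1:100, sprintf("g%03d", 1:100))
  q <- assignQuintiles(v)
  ix <- intersectQuintiles(q, q)
  expect_length(ix$highTE_lowstability, 0)
  expect_length(ix$lowTE_highstability, 0)
  expect_length(ix$highTE_highstability, 20)

  # 25-gene worked grid against exhaustive enumeration
  g <- sprintf("g%02d", 1:25)
  qa <- assignQuintiles(setNames(1:25, g))
  qb <- assignQuintiles(setNames(c(13:25, 1:12), g))
  ix2 <- intersectQuintiles(qa, qb)
  brute <- list(
    hh = g[qa == 5 & qb == 5], hl = g[qa == 5 & qb == 1],
    lh = g[qa == 1 & qb == 5], ll = g[qa == 1 & qb == 1]
  )
  expect_setequal(ix2$highTE_highstability, brute$hh)
  expect_setequal(ix2$highTE_lowstability, brute$hl)
  expect_setequal(ix2$lowTE_highstability, brute$lh)
  expect_setequal(ix2$lowTE_lowstability, brute$ll)

  expect_warning(intersectQuintiles(qa, setNames(qb, paste0("x", g))),
                 "disjoint")
})

test_that("independent rankings put about 4% of genes in each corner", {
  set.seed(35)
  fracs <- replicate(20, {
    g <- sprintf("g%04d", 1:1000)
    qa <- assignQuintiles(setNames(rnorm(1000), g))
    qb <- assignQuintiles(setNames(rnorm(1000), g))
    length(intersectQuintiles(qa, qb)$highTE_highstability) / 1000
  })
  # binomial(1000, 0.04): mean of 20 replicates within generous bounds
  expect_gt(mean(fracs), 0.03)
  expect_lt(mean(fracs), 0.05)
})
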