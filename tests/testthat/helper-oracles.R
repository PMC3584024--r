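# Independent oracles used across the suite.  Each is written as a direct,
# definitional computation sharing no code path with the implementation.

# Positional brute-force trypsin digestion: test every bond independently.
oracleDigest <- function(sequence, rule = "trypsin-simple") {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cuts <- integer(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    site <- res[i] %in% c("K", "R")
    if (!site) next
    nxt <- res[i + 1L]
    prev <- if (i >= 2L) res[i - 1L] else ""
    ok <- if (rule == "trypsin-simple") {
      nxt != "P"
    } else {
      trip <- paste0(prev, res[i], nxt)
      if (nxt == "P") trip %in% c("WKP", "MRP")
      else !(trip %in% c("CKD", "DKD", "CKH", "CKY", "KKR",
                         "RRH", "RRR", "CRK", "DRD"))
    }
    if (ok) cuts <- c(cuts, i)
  }
  bounds <- c(0L, cuts, n)
  vapply(seq_len(length(bounds) - 1L), function(k)
    paste(res[(bounds[k] + 1L):bounds[k + 1L]], collapse = ""), character(1))
}

# Definitional Spearman for tie-free data: 1 - 6*sum(d^2)/(n(n^2-1)).
oracleSpearmanTieFree <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Upper-tail hypergeometric probability by full enumeration over the support.
oracleUpperTail <- function(a, b, c, d) {
  m <- a + c; k <- a + b; N <- a + b + c + d
  support <- max(0, k - (N - m)):min(k, m)
  sum(vapply(support[support >= a], function(x)
    choose(m, x) * choose(N - m, k - x), numeric(1))) / choose(N, k)
}

# Quintile assignment by explicit enumeration: sort (value, id) pairs and
# hand out group sizes low-to-high, remainder to the lower groups.
oracleQuintiles <- function(values) {
  n <- length(values)
  sizes <- rep(n %/% 5, 5)
  if (n %% 5 > 0) sizes[1:(n %% 5)] <- sizes[1:(n %% 5)] + 1
  ord <- names(values)[order(values, names(values))]
  q <- rep(1:5, times = sizes)
  setNames(q[match(names(values), ord)], names(values))
}

# Random protein-like sequence for property tests.
randomSequence <- function(len, p_kr = 0.2) {
  other <- setdiff(strsplit("ACDEFGHILMNPQSTVWY", "")[[1]], c("K", "R"))
  paste(sample(c("K", "R", other), len, replace = TRUE,
               prob = c(p_kr / 2, p_kr / 2,
                        rep((1 - p_kr) / length(other), length(other)))),
        collapse = "")
}

# Build an observed log10 TE matrix (genes x cell lines) by running the
# simulator through the estimation path.
observedTeMatrix <- function(n_genes, seed, frac_consistent = 0.5,
                             te_noise_sd = 0.1) {
  cfg <- simulationConfig(n_genes = n_genes, seed = seed,
                          frac_consistent = frac_consistent,
                          te_noise_sd = te_noise_sd, dropout_rate = 0)
  ds <- simulateTeDataset(cfg)
  pr <- pairExpression(ds$mrna, ds$protein)
  te <- translationEfficiency(pr$pairs, ds$stability)$te
  m <- matrix(NA_real_, n_genes, cfg$n_cell_lines,
              dimnames = list(sort(unique(te$gene_id)),
                              sort(unique(te$cell_line))))
  m[cbind(te$gene_id, te$cell_line)] <- te$log10_te
  m[rowSums(is.na(m)) == 0, , drop = FALSE]
}
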