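## Cross-cell-line consistency of TE: CV, permutation null, quintiles and
## quintile intersections.

#' Coefficient of variation of per-cell-line TE values
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.  By
#' convention the CV is computed on the log10 TE scale, which is the scale on
#' which the consistency thresholds in this pipeline are defined; the same
#' function applies unchanged to linear TE values if passed them.
#'
#' @param values Numeric vector of per-cell-line (log10) TE values for one
#'   gene; at least 2 values with nonzero mean, otherwise `NA` is returned.
#' @return Non-negative CV, or `NA_real_` when undefined.
#' @examples
#' teCv(c(1, 2, 3))  # sample SD 1 / mean 2 = 0.5
#' @export
teCv <- function(values) {
  stopIfNot(is.numeric(values), "'values' must be numeric")
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  sd(values) / m
}

#' Permutation null for cross-cell-line TE consistency
#'
#' Tests whether per-gene TE is more consistent across cell lines than
#' expected by chance.  The observed statistic is the per-gene CV of log10 TE
#' over a complete gene-by-cell-line matrix.  Each permutation replicate
#' independently shuffles the values *within every cell-line column* (so each
#' column's value multiset is exactly preserved but the per-gene linkage
#' across lines is broken), and per-gene CVs are recomputed.  The observed
#' CVs are compared with the pooled permuted CVs by a two-sided Welch t-test,
#' and the fraction of genes below a consistency threshold is reported for
#' both distributions.
#'
#' @param te_matrix Complete numeric matrix, genes in rows, cell lines in
#'   columns (no `NA`).
#' @param n_perm Number of permutation replicates (default 20).
#' @param seed Integer seed; fixes the replicate shuffles.
#' @param cv_threshold Consistency threshold for the reported fractions;
#'   `NULL` (default) uses the 20th percentile of the observed CVs (the lower
#'   quintile boundary, which is data-derived rather than a constant).
#' @param scheme `"within_column"` (default, described above) or `"global"`
#'   (a single shuffle of the whole matrix per replicate).
#' @return A list of class `PermutationResult`: `observed_cvs`,
#'   `permuted_cvs` (pooled over replicates), `n_perm`, `t_statistic`,
#'   `p_value`, `cv_threshold`, `frac_observed_below_threshold`,
#'   `frac_permuted_below_threshold`, `degenerate`.
#' @export
permutationNull <- function(te_matrix, n_perm = 20L, seed = 1L,
                            cv_threshold = NULL,
                            scheme = c("within_column", "global")) {
  scheme <- match.arg(scheme)
  stopIfNot(is.matrix(te_matrix) && is.numeric(te_matrix) &&
              !anyNA(te_matrix) && ncol(te_matrix) >= 2L && nrow(te_matrix) >= 2L,
            "'te_matrix' must be a complete numeric matrix (genes x cell lines)")
  n_perm <- checkCount(n_perm, "n_perm")
  seed <- checkCount(seed, "seed", min = 0L)

  rowCv <- function(m) apply(m, 1L, teCv)
  observed <- rowCv(te_matrix)

  degenerate <- sd(as.vector(te_matrix)) == 0
  set.seed(seed)
  permuted <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    pm <- if (scheme == "within_column") {
      apply(te_matrix, 2L, sample)
    } else {
      matrix(sample(as.vector(te_matrix)), nrow = nrow(te_matrix))
    }
    ## invariant: each replicate preserves every column's value multiset
    if (scheme == "within_column") {
      stopifnot(all(apply(pm, 2L, sort) == apply(te_matrix, 2L, sort)))
    } else {
      stopifnot(all(sort(as.vector(pm)) == sort(as.vector(te_matrix))))
    }
    permuted[[r]] <- rowCv(pm)
  }
  permuted <- unlist(permuted, use.names = FALSE)

  if (is.null(cv_threshold)) {
    cv_threshold <- unname(quantile(observed, 0.2, na.rm = TRUE))
  }
  tt <- if (degenerate) NULL else t.test(observed, permuted)
  structure(list(
    observed_cvs = unname(observed),
    permuted_cvs = permuted,
    n_perm = n_perm,
    t_statistic = if (degenerate) NA_real_ else unname(tt$statistic),
    p_value = if (degenerate) NA_real_ else tt$p.value,
    cv_threshold = cv_threshold,
    frac_observed_below_threshold = mean(observed < cv_threshold, na.rm = TRUE),
    frac_permuted_below_threshold = mean(permuted < cv_threshold, na.rm = TRUE),
    degenerate = degenerate
  ), class = "PermutationResult")
}

#' Assign genes to quintiles by a ranked value
#'
#' Rank-based split into five near-equal groups: group sizes differ by at
#' most one, with any remainder assigned to the *lower* quintiles; ties are
#' broken deterministically by lexicographic gene-id order.  Quintile 1 holds
#' the lowest values.
#'
#' @param values Named numeric vector (names are gene ids) or a `data.frame`
#'   with columns `gene_id` and a single value column.
#' @return Named integer vector of quintiles (1..5), in the input gene order.
#' @export
assignQuintiles <- function(values) {
  if (is.data.frame(values)) {
    stopIfNot("gene_id" %in% names(values) && ncol(values) == 2L,
              "data.frame input needs columns gene_id and one value column")
    v <- values[[setdiff(names(values), "gene_id")]]
    names(v) <- values$gene_id
    values <- v
  }
  stopIfNot(is.numeric(values) && !is.null(names(values)) &&
              !anyNA(values) && !anyDuplicated(names(values)),
            "'values' must be named, non-NA, with unique gene ids")
  n <- length(values)
  stopIfNot(n >= 5L, "need at least 5 genes to form quintiles")
  sizes <- rep(n %/% 5L, 5L)
  r <- n %% 5L
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ord <- order(values, names(values))
  q <- rep.int(seq_len(5L), times = sizes)
  out <- integer(n)
  out[ord] <- q
  names(out) <- names(values)
  out
}

#' Intersect upper/lower quintiles of two gene rankings
#'
#' Forms the four corner groups between the extreme quintiles of two
#' rankings (typically TE and protein stability): high/high, high/low,
#' low/high and low/low.
#'
#' @param q_a,q_b Named integer quintile vectors (1..5) as returned by
#'   [assignQuintiles()], over a shared gene universe.
#' @param labels Length-2 character vector naming the two rankings (default
#'   `c("TE", "stability")`), used to build group labels.
#' @return A named list of four character vectors of gene ids, with names
#'   like `"highTE_highstability"`.  A warning is issued when the universes
#'   are disjoint.
#' @export
intersectQuintiles <- function(q_a, q_b, labels = c("TE", "stability")) {
  stopIfNot(!is.null(names(q_a)) && !is.null(names(q_b)),
            "quintile vectors must be named by gene id")
  shared <- intersect(names(q_a), names(q_b))
  if (length(shared) == 0L) {
    warning("gene universes of the two rankings are disjoint; groups are empty")
  }
  hi_a <- names(q_a)[q_a == 5L]; lo_a <- names(q_a)[q_a == 1L]
  hi_b <- names(q_b)[q_b == 5L]; lo_b <- names(q_b)[q_b == 1L]
  out <- list(
    intersect(hi_a, hi_b),
    intersect(hi_a, lo_b),
    intersect(lo_a, hi_b),
    intersect(lo_a, lo_b)
  )
  names(out) <- c(
    sprintf("high%s_high%s", labels[1], labels[2]),
    sprintf("high%s_low%s", labels[1], labels[2]),
    sprintf("low%s_high%s", labels[1], labels[2]),
    sprintf("low%s_low%s", labels[1], labels[2])
  )
  out
}
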