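## Local annotation-term enrichment: EASE-adjusted Fisher statistic with
## Benjamini-Hochberg correction, applied to quintile and intersection groups.

#' Upper-tail Fisher exact probability of a 2x2 table
#'
#' Probability, under the hypergeometric null, of observing at least `a`
#' group genes carrying the term, given the table margins:
#' `a` = genes in the group with the term, `b` = in the group without it,
#' `c` = with the term outside the group, `d` = without it outside the group.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return One-sided (enrichment) p-value in (0, 1\].
#' @export
fisherUpperTail <- function(a, b, c, d) {
  for (v in list(a = a, b = b, c = c, d = d)) {
    stopIfNot(is.numeric(v) && length(v) == 1L && is.finite(v) &&
                v >= 0 && v == as.integer(v),
              "counts must be single non-negative integers")
  }
  ## P(X >= a) for X ~ Hypergeometric(white = a+c, black = b+d, drawn = a+b)
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' EASE score (jackknifed Fisher exact p-value)
#'
#' A conservative modification of the one-sided Fisher exact test in which
#' one gene is removed from the overlap cell before the test: the table
#' (`a`, `b`, `c`, `d`) becomes (`a`-1, `b`, `c`, `d`) (floored at 0, other
#' cells unchanged) and the upper-tail Fisher probability of that table is
#' returned.  A single-gene overlap therefore carries no evidence:
#' `a` of 0 or 1 both give p = 1.  The EASE score is always greater than or
#' equal to the plain Fisher p-value of the same table.
#'
#' @inheritParams fisherUpperTail
#' @return EASE p-value in (0, 1\].
#' @examples
#' easeScore(5, 5, 5, 5)
#' easeScore(1, 10, 10, 100)  # 1: no evidence after the jackknife
#' @export
easeScore <- function(a, b, c, d) {
  for (v in list(a = a, b = b, c = c, d = d)) {
    stopIfNot(is.numeric(v) && length(v) == 1L && is.finite(v) &&
                v >= 0 && v == as.integer(v),
              "counts must be single non-negative integers")
  }
  fisherUpperTail(max(a - 1, 0), b, c, d)
}

#' Benjamini-Hochberg adjustment of a p-value list
#'
#' Step-up false-discovery-rate adjustment (p(i) * m / i with a running
#' minimum from the largest rank, capped at 1), preserving input order.
#' Delegates to [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(pvalues) {
  stopIfNot(is.numeric(pvalues) && all(is.finite(pvalues)) &&
              all(pvalues >= 0) && all(pvalues <= 1),
            "'pvalues' must be in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Annotation-term enrichment for gene groups
#'
#' For each group (for example a TE quintile or a quintile-intersection
#' corner) and each annotation term, builds the 2x2 contingency table against
#' the background universe, computes the EASE score, and applies
#' Benjamini-Hochberg correction within each group-by-category family (a
#' `global_correction` flag pools all terms of a group instead).  Terms with
#' fewer than `min_genes` group genes are skipped, and results are flagged at
#' the `bh_max` threshold.
#'
#' @param groups Named list of character vectors of gene ids.
#' @param annotation A `data.frame` with columns `gene_id`, `term_id` and
#'   optionally `category` (a single category is assumed when absent).
#' @param background Character vector: the gene universe.  Every group gene
#'   must be in the background.
#' @param min_genes Minimum group genes carrying a term (default 2).
#' @param ease_max Maximum EASE score for a term to be reported (default 1,
#'   i.e. report all tested terms).
#' @param bh_max Benjamini-Hochberg significance threshold used for the
#'   `passes` flag (default 0.05).
#' @param global_correction When TRUE, BH correction pools all categories of
#'   a group (default FALSE: per group x category family).
#' @return A `data.frame` with `group`, `category`, `term_id`, `a`, `b`, `c`,
#'   `d`, `ease_p`, `fisher_p`, `bh_p`, `passes`.
#' @export
enrichGroups <- function(groups, annotation, background, min_genes = 2L,
                         ease_max = 1, bh_max = 0.05,
                         global_correction = FALSE) {
  stopIfNot(is.list(groups) && !is.null(names(groups)),
            "'groups' must be a named list of gene-id vectors")
  stopIfNot(all(c("gene_id", "term_id") %in% names(annotation)),
            "'annotation' needs gene_id and term_id")
  min_genes <- checkCount(min_genes, "min_genes", min = 0L)
  checkScalarNumeric(ease_max, "ease_max", lower = 0, upper = 1)
  checkScalarNumeric(bh_max, "bh_max", lower = 0, upper = 1)
  background <- unique(as.character(background))
  stray <- setdiff(unique(unlist(groups)), background)
  stopIfNot(length(stray) == 0L,
            sprintf("group gene(s) absent from background: %s",
                    paste(head(stray, 5), collapse = ", ")))
  if (!"category" %in% names(annotation)) annotation$category <- "default"
  ## annotation restricted to the universe; duplicate gene-term rows collapse
  annotation <- unique(annotation[annotation$gene_id %in% background,
                                  c("gene_id", "term_id", "category")])
  n_bg <- length(background)
  term_genes <- split(annotation$gene_id,
                      paste(annotation$category, annotation$term_id, sep = "\r"))

  rows <- list()
  for (grp in names(groups)) {
    gset <- unique(groups[[grp]])
    n_grp <- length(gset)
    if (n_grp == 0L) next
    for (key in names(term_genes)) {
      tg <- term_genes[[key]]
      a <- length(intersect(gset, tg))
      if (a < min_genes) next
      b <- n_grp - a
      c_ <- length(tg) - a
      d <- n_bg - n_grp - c_
      ep <- easeScore(a, b, c_, d)
      if (ep > ease_max) next
      cat_term <- strsplit(key, "\r", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, category = cat_term[1], term_id = cat_term[2],
        a = a, b = b, c = c_, d = d,
        ease_p = ep, fisher_p = fisherUpperTail(a, b, c_, d),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(group = character(), category = character(),
                      term_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), ease_p = numeric(),
                      fisher_p = numeric(), bh_p = numeric(),
                      passes = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  fam <- if (global_correction) res$group else paste(res$group, res$category)
  res$bh_p <- NA_real_
  for (f in unique(fam)) {
    idx <- fam == f
    res$bh_p[idx] <- benjaminiHochberg(res$ease_p[idx])
  }
  res$passes <- res$bh_p < bh_max
  rownames(res) <- NULL
  res
}
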