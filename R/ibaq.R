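## iBAQ conversion and between-sample normalization of protein quantifications.

#' Convert mass-spectrometry intensities to iBAQ values
#'
#' iBAQ (intensity-based absolute quantification) divides the summed MS
#' intensity of a protein by the number of theoretically observable tryptic
#' peptides (6--30 residues, see [digestProtein()]), putting proteins of
#' different sizes on a comparable abundance scale.
#'
#' A gene may map to several sequence isoforms.  When the isoforms of a
#' protein yield *different* quantifiable peptide counts the iBAQ denominator
#' is ambiguous and the protein is excluded (reason
#' `"ambiguous_peptide_count"`); proteins whose every isoform has zero
#' quantifiable peptides are excluded as well (reason
#' `"zero_quantifiable_count"`).  Exclusions are reported, never silently
#' dropped.
#'
#' @param records A `data.frame` with columns `protein_id`, `gene_id`,
#'   `cell_line`, `intensity` (non-negative).
#' @param digests A `data.frame` with columns `protein_id`,
#'   `quantifiable_count`, as produced by [digestProteins()]; multiple rows
#'   per `protein_id` are interpreted as isoforms.
#' @return A list with `ibaq` (`data.frame`: `gene_id`, `cell_line`, `ibaq`)
#'   and `exclusions` (`data.frame`: `protein_id`, `reason`).
#' @export
intensityToIbaq <- function(records, digests) {
  stopIfNot(all(c("protein_id", "gene_id", "cell_line", "intensity") %in%
                  names(records)),
            "'records' needs protein_id, gene_id, cell_line, intensity")
  stopIfNot(all(c("protein_id", "quantifiable_count") %in% names(digests)),
            "'digests' needs protein_id, quantifiable_count")
  stopIfNot(all(is.finite(records$intensity)) && all(records$intensity >= 0),
            "intensities must be finite and >= 0")
  missing <- setdiff(records$protein_id, digests$protein_id)
  stopIfNot(length(missing) == 0L,
            sprintf("no digest for protein(s): %s",
                    paste(head(missing, 5), collapse = ", ")))

  counts <- split(digests$quantifiable_count, digests$protein_id)
  n_distinct <- vapply(counts, function(v) length(unique(v)), integer(1))
  the_count <- vapply(counts, function(v) v[1], numeric(1))

  ambiguous <- names(counts)[n_distinct > 1L]
  zero <- names(counts)[n_distinct == 1L & the_count == 0]
  exclusions <- data.frame(
    protein_id = c(ambiguous, zero),
    reason = c(rep("ambiguous_peptide_count", length(ambiguous)),
               rep("zero_quantifiable_count", length(zero))),
    stringsAsFactors = FALSE
  )

  keep <- !(records$protein_id %in% exclusions$protein_id)
  kept <- records[keep, , drop = FALSE]
  kept$ibaq <- kept$intensity / the_count[kept$protein_id]
  list(
    ibaq = data.frame(gene_id = kept$gene_id, cell_line = kept$cell_line,
                      ibaq = kept$ibaq, row.names = NULL,
                      stringsAsFactors = FALSE),
    exclusions = exclusions
  )
}

## Quantile positions for a sorted vector of m detected values; the single
## value of a length-1 column sits at the distribution middle.
.qpos <- function(m) {
  if (m == 1L) 0.5 else (seq_len(m) - 1) / (m - 1)
}

#' Quantile-normalize quantifications between samples
#'
#' Forces every column (cell line) of a gene-by-sample quantification matrix
#' onto a common empirical distribution, preserving within-column rank order:
#' the reference distribution is the mean of the columns' empirical quantile
#' functions, and each column's detected values are replaced by the reference
#' evaluated at their own quantile positions.  Columns with unequal numbers of
#' detected values (missing entries stay `NA`) are supported by linear
#' interpolation of quantile positions.
#'
#' By default averaging happens on the linear scale, so two complete columns
#' of equal length are both replaced by the element-wise mean of their sorted
#' vectors; `scale = "log"` averages log-transformed values (geometric means)
#' instead, which requires strictly positive detected values.
#'
#' @param m Numeric matrix, genes in rows, samples in columns; `NA` marks a
#'   missing observation. At least two columns, each with at least one
#'   detected value.
#' @param scale `"linear"` (default) or `"log"`.
#' @return A matrix of the same shape with detected values replaced; `NA`s
#'   are untouched.
#' @export
normalizeBetweenSamples <- function(m, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopIfNot(is.matrix(m) && is.numeric(m) && ncol(m) >= 2L,
            "'m' must be a numeric matrix with >= 2 columns")
  detected <- lapply(seq_len(ncol(m)), function(j) which(!is.na(m[, j])))
  n_det <- lengths(detected)
  stopIfNot(all(n_det >= 1L), "every column needs at least one detected value")
  if (scale == "log") {
    stopIfNot(all(m > 0, na.rm = TRUE),
              "log-scale normalization requires positive detected values")
  }
  trans <- if (scale == "log") log else identity
  inv <- if (scale == "log") exp else identity

  grid_m <- max(n_det)
  grid <- .qpos(grid_m)
  ## each column's empirical quantile function on the common grid
  qcols <- vapply(seq_len(ncol(m)), function(j) {
    v <- sort(trans(m[detected[[j]], j]))
    if (length(v) == 1L) rep(v, grid_m)
    else approx(.qpos(length(v)), v, xout = grid, rule = 2)$y
  }, numeric(grid_m))
  ref <- rowMeans(qcols)

  out <- m
  for (j in seq_len(ncol(m))) {
    idx <- detected[[j]]
    v <- trans(m[idx, j])
    r <- rank(v, ties.method = "average")
    p <- if (length(v) == 1L) 0.5 else (r - 1) / (length(v) - 1)
    out[idx, j] <- inv(approx(grid, ref, xout = p, rule = 2)$y)
  }
  out
}
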