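## Protein turnover: degradation constants, half-lives and the PSAT factor.

#' Convert a protein half-life to a first-order degradation rate constant
#'
#' Protein turnover is modelled as first-order decay, so the degradation
#' rate constant and the half-life are related by
#' \eqn{k_{deg} = \ln 2 / t_{1/2}}.
#'
#' @param half_life_h Protein half-life in hours; strictly positive, may be a
#'   vector.
#' @return Degradation rate constant(s) in h\eqn{^{-1}}.
#' @seealso [halfLifeFromKdeg()], [psat()]
#' @examples
#' kdegFromHalfLife(log(2))   # 1 per hour
#' kdegFromHalfLife(c(18, 72))
#' @export
kdegFromHalfLife <- function(half_life_h) {
  stopIfNot(is.numeric(half_life_h) && length(half_life_h) >= 1L &&
              all(is.finite(half_life_h)) && all(half_life_h > 0),
            "'half_life_h' must be finite and > 0")
  log(2) / half_life_h
}

#' Convert a degradation rate constant to a half-life
#'
#' @param kdeg_per_h Degradation rate constant in h\eqn{^{-1}}; strictly
#'   positive, may be a vector.
#' @return Half-life in hours.
#' @export
halfLifeFromKdeg <- function(kdeg_per_h) {
  stopIfNot(is.numeric(kdeg_per_h) && length(kdeg_per_h) >= 1L &&
              all(is.finite(kdeg_per_h)) && all(kdeg_per_h > 0),
            "'kdeg_per_h' must be finite and > 0")
  log(2) / kdeg_per_h
}

#' Protein stability accounting term (PSAT)
#'
#' The PSAT is the fraction of a protein pool degraded -- and therefore, at
#' steady state, resynthesised -- in a time window \eqn{\Delta t}:
#' \deqn{PSAT = 1 - e^{-k_{deg}\,\Delta t}.}
#' With \eqn{k_{deg}} in h\eqn{^{-1}} the conventional window is 1 hour; the
#' window is exposed as an argument rather than hard-coded.  PSAT is strictly
#' increasing in \eqn{k_{deg}} and lies in (0, 1): a stable protein
#' (long half-life) has a small PSAT, so a high protein level is compatible
#' with a low synthesis rate.
#'
#' @param kdeg Degradation rate constant(s) in h\eqn{^{-1}}; strictly positive.
#' @param delta_t_h Time window in hours (default 1).
#' @return PSAT value(s) in (0, 1).
#' @examples
#' psat(kdegFromHalfLife(18))   # ~0.038
#' psat(kdegFromHalfLife(72))   # ~0.0096
#' @export
psat <- function(kdeg, delta_t_h = 1) {
  stopIfNot(is.numeric(kdeg) && length(kdeg) >= 1L &&
              all(is.finite(kdeg)) && all(kdeg > 0),
            "'kdeg' must be finite and > 0")
  checkScalarNumeric(delta_t_h, "delta_t_h", lower = 0, strict_lower = TRUE)
  1 - exp(-kdeg * delta_t_h)
}

#' Read a protein stability table
#'
#' Accepts a TSV (or an equivalent `data.frame`) with a `gene_id` column and
#' either `half_life_h` or `kdeg_per_h`; the missing one of the two is derived
#' via \eqn{t_{1/2} = \ln 2 / k_{deg}}.  If both are present their consistency
#' is enforced to 1e-9 relative tolerance.
#'
#' @param x Path to a TSV file, or a `data.frame`.
#' @return A `data.frame` with columns `gene_id`, `half_life_h`, `kdeg_per_h`.
#' @export
readStabilityTable <- function(x) {
  df <- if (is.character(x)) readTsv(x) else as.data.frame(x)
  stopIfNot("gene_id" %in% names(df), "stability table needs a 'gene_id' column")
  has_hl <- "half_life_h" %in% names(df)
  has_kd <- "kdeg_per_h" %in% names(df)
  stopIfNot(has_hl || has_kd,
            "stability table needs 'half_life_h' or 'kdeg_per_h'")
  if (has_hl && !has_kd) df$kdeg_per_h <- kdegFromHalfLife(df$half_life_h)
  if (has_kd && !has_hl) df$half_life_h <- halfLifeFromKdeg(df$kdeg_per_h)
  if (has_hl && has_kd) {
    rel <- abs(df$half_life_h * df$kdeg_per_h - log(2)) / log(2)
    stopIfNot(all(rel < 1e-9),
              "half_life_h and kdeg_per_h are inconsistent (t1/2 != ln2/kdeg)")
  }
  df[, c("gene_id", "half_life_h", "kdeg_per_h")]
}

## Collapse duplicated gene entries to the geometric mean of kdeg.  Returns
## the collapsed table plus the list of collided gene ids for reporting.
collapseStability <- function(stability) {
  stability <- readStabilityTable(stability)
  dup <- unique(stability$gene_id[duplicated(stability$gene_id)])
  if (length(dup)) {
    kd <- tapply(stability$kdeg_per_h, stability$gene_id,
                 function(v) exp(mean(log(v))))
    stability <- data.frame(gene_id = names(kd),
                            kdeg_per_h = as.numeric(kd),
                            stringsAsFactors = FALSE)
    stability$half_life_h <- halfLifeFromKdeg(stability$kdeg_per_h)
    stability <- stability[, c("gene_id", "half_life_h", "kdeg_per_h")]
  }
  list(stability = stability, collisions = dup)
}

#' Compare two protein stability tables over mapped genes
#'
#' Computes the Spearman rank correlation of degradation constants across a
#' gene-to-gene mapping (for example human genes to their orthologs in a
#' second organism), together with the median half-life of each full table.
#'
#' @param a,b Stability tables accepted by [readStabilityTable()].
#' @param mapping A `data.frame` with columns `id_a`, `id_b`, or a named
#'   character vector (names = ids in `a`, values = ids in `b`).
#' @return A list with `n_mapped`, `spearman_r`, `median_half_life_a`,
#'   `median_half_life_b`.
#' @export
compareStabilityTables <- function(a, b, mapping) {
  a <- readStabilityTable(a)
  b <- readStabilityTable(b)
  if (!is.data.frame(mapping)) {
    stopIfNot(length(mapping) > 0 && !is.null(names(mapping)),
              "'mapping' must be a data.frame or a named vector")
    mapping <- data.frame(id_a = names(mapping), id_b = unname(mapping),
                          stringsAsFactors = FALSE)
  }
  stopIfNot(nrow(mapping) > 0, "'mapping' must not be empty")
  ka <- a$kdeg_per_h[match(mapping$id_a, a$gene_id)]
  kb <- b$kdeg_per_h[match(mapping$id_b, b$gene_id)]
  ok <- !is.na(ka) & !is.na(kb)
  stopIfNot(sum(ok) >= 3L, "need at least 3 mapped genes present in both tables")
  list(
    n_mapped = sum(ok),
    spearman_r = cor(ka[ok], kb[ok], method = "spearman"),
    median_half_life_a = median(a$half_life_h),
    median_half_life_b = median(b$half_life_h)
  )
}
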