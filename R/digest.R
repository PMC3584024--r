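## In-silico tryptic digestion used to count quantifiable peptides for iBAQ.

.KEIL_CLEAVE_DESPITE_P <- c("WKP", "MRP")
.KEIL_BLOCKED <- c("CKD", "DKD", "CKH", "CKY", "KKR",
                   "RRH", "RRR", "CRK", "DRD")

## Decide, per internal position i (1..n-1), whether the bond after residue i
## is cleaved.  `prev` is the residue before i ("" at the N-terminus).
.cleaveAfter <- function(prev, res, nxt, rule) {
  if (res != "K" && res != "R") return(FALSE)
  if (rule == "trypsin-simple") return(nxt != "P")
  ## trypsin-keil
  triple <- paste0(prev, res, nxt)
  if (nxt == "P") return(triple %in% .KEIL_CLEAVE_DESPITE_P)
  !(triple %in% .KEIL_BLOCKED)
}

#' Predict tryptic peptides of a protein sequence
#'
#' Performs complete (no missed cleavage) in-silico trypsin digestion and
#' counts the peptides of length 6--30 residues inclusive -- the
#' "quantifiable" peptides that form the iBAQ denominator.
#'
#' Two cleavage rules are available:
#' \describe{
#'   \item{`trypsin-simple`}{cleave C-terminal of K or R except when the next
#'     residue is P. This is the default and the rule assumed throughout the
#'     pipeline unless stated otherwise.}
#'   \item{`trypsin-keil`}{the Keil-style exception model used by
#'     PeptideCutter-like predictors: the proline block is overridden for the
#'     contexts `WKP` and `MRP` (cleavage occurs), and cleavage is additionally
#'     suppressed for the contexts `CKD`, `DKD`, `CKH`, `CKY`, `KKR`, `RRH`,
#'     `RRR`, `CRK` and `DRD` (each triple is previous residue, cleavage-site
#'     residue, following residue).}
#' }
#' Nonstandard residues (X, B, Z, U, ...) never cleave and count toward
#' peptide length, so arbitrary FASTA input digests deterministically.
#'
#' @param sequence A single non-empty residue string (or length-1
#'   `Biostrings::AAStringSet` element coerced via `as.character`).
#' @param rule Cleavage rule, `"trypsin-simple"` (default) or
#'   `"trypsin-keil"`.
#' @return A list of class `DigestResult` with elements `peptides` (character
#'   vector; concatenating them restores the input), `quantifiable_count`
#'   (peptides with length in \[6, 30\]) and `rule`.
#' @examples
#' digestProtein("MKPGRSAAQLLR")
#' digestProtein("RRRRRR")$quantifiable_count  # 0
#' @export
digestProtein <- function(sequence, rule = c("trypsin-simple", "trypsin-keil")) {
  rule <- match.arg(rule)
  sequence <- toupper(as.character(sequence))
  stopIfNot(length(sequence) == 1L && !is.na(sequence) && nzchar(sequence),
            "'sequence' must be a single non-empty residue string")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut <- logical(n - 1L)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      prev <- if (i > 1L) res[i - 1L] else ""
      cut[i] <- .cleaveAfter(prev, res[i], res[i + 1L], rule)
    }
  }
  ends <- c(which(cut), n)
  starts <- c(1L, head(ends, -1L) + 1L)
  peptides <- substring(sequence, starts, ends)
  structure(
    list(peptides = peptides,
         quantifiable_count = sum(nchar(peptides) >= 6L & nchar(peptides) <= 30L),
         rule = rule),
    class = "DigestResult"
  )
}

#' Digest many protein sequences and tabulate quantifiable peptide counts
#'
#' @param sequences A named character vector or a `Biostrings::AAStringSet`;
#'   names are protein identifiers.
#' @param rule Cleavage rule passed to [digestProtein()].
#' @return A `data.frame` with columns `protein_id`, `n_peptides`,
#'   `quantifiable_count`, `rule`.
#' @export
digestProteins <- function(sequences, rule = c("trypsin-simple", "trypsin-keil")) {
  rule <- match.arg(rule)
  seqs <- as.character(sequences)
  names(seqs) <- names(sequences)
  stopIfNot(length(seqs) >= 1L && !is.null(names(seqs)) && all(nzchar(names(seqs))),
            "'sequences' must be named (protein identifiers)")
  counts <- vapply(seqs, function(s) {
    d <- digestProtein(s, rule)
    c(length(d$peptides), d$quantifiable_count)
  }, numeric(2))
  data.frame(
    protein_id = names(seqs),
    n_peptides = as.integer(counts[1, ]),
    quantifiable_count = as.integer(counts[2, ]),
    rule = rule,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
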