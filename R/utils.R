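#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats approx coef cor lm median p.adjust phyper quantile
#'   rlnorm rnorm runif sd setNames t.test
#' @importFrom utils head read.delim write.table
NULL

## Argument checks -----------------------------------------------------------

stopIfNot <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

checkScalarNumeric <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  stopIfNot(is.numeric(x) && length(x) == 1L && is.finite(x),
            sprintf("'%s' must be a single finite number", name))
  if (strict_lower) {
    stopIfNot(x > lower, sprintf("'%s' must be > %s", name, lower))
  } else {
    stopIfNot(x >= lower, sprintf("'%s' must be >= %s", name, lower))
  }
  stopIfNot(x <= upper, sprintf("'%s' must be <= %s", name, upper))
  invisible(x)
}

checkCount <- function(x, name, min = 1L) {
  stopIfNot(is.numeric(x) && length(x) == 1L && is.finite(x) &&
              x == as.integer(x) && x >= min,
            sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}

## Seed substreams ------------------------------------------------------------
##
## A single user-facing seed is expanded into independent per-table seeds so
## that adding a new table to a simulation never shifts the draws of existing
## tables.  All randomness uses R's default Mersenne-Twister generator.

substreamSeeds <- function(seed, n) {
  seed <- checkCount(seed, "seed", min = 0L)
  n <- checkCount(n, "n")
  runif(1) # force RNG initialisation so .Random.seed exists
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## TSV / JSON io --------------------------------------------------------------

#' Read a tab-separated table with a header
#'
#' Thin wrapper around [utils::read.delim()] used for all tabular inputs
#' (expression tables, stability tables, annotation tables).
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame`.
#' @export
readTsv <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a table as TSV
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Matrix <-> long-table reshaping used throughout the pipeline ---------------

longToMatrix <- function(df, value_col) {
  genes <- sort(unique(df$gene_id))
  lines <- sort(unique(df$cell_line))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(lines),
              dimnames = list(genes, lines))
  m[cbind(match(df$gene_id, genes), match(df$cell_line, lines))] <-
    df[[value_col]]
  m
}

matrixToLong <- function(m, value_col) {
  df <- data.frame(
    gene_id = rep(rownames(m), times = ncol(m)),
    cell_line = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    stringsAsFactors = FALSE
  )
  names(df)[3] <- value_col
  df <- df[!is.na(df[[value_col]]), , drop = FALSE]
  rownames(df) <- NULL
  df
}
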