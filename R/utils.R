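#' @import data.table
#' @importFrom methods is
NULL

# Classed error helpers so callers can distinguish bad input from bugs.
tx_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "teconsex_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

validation_error <- function(msg, ...) tx_error("teconsex_validation_error", msg, ...)
parse_error      <- function(msg, ...) tx_error("teconsex_parse_error", msg, ...)
config_error     <- function(msg, ...) tx_error("teconsex_config_error", msg, ...)

#' Convert a 0-based half-open interval table to GRanges
#'
#' All tabular coordinates in this package are 0-based half-open (BED
#' convention); GRanges is 1-based closed, so the conversion is
#' `start + 1` on the left edge only.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `strand`.
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
as_granges0 <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else rep("*", nrow(df))
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# Count >=1 bp overlaps of `query` rows against `subject` rows, strand-blind.
overlap_any <- function(query, subject) {
  if (nrow(subject) == 0L || nrow(query) == 0L) return(rep(FALSE, nrow(query)))
  GenomicRanges::countOverlaps(as_granges0(query), as_granges0(subject),
                               ignore.strand = TRUE) > 0L
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    validation_error("'%s' must be a single number", name)
  }
  if (integer && x != as.integer(x)) {
    validation_error("'%s' must be an integer (got %s)", name, format(x))
  }
  if (x < lower || x > upper) {
    validation_error("'%s' must be in [%s, %s] (got %s)",
                     name, format(lower), format(upper), format(x))
  }
  invisible(x)
}

# round(x, 2) reported as a plain number; used for Table-style proportions.
round2 <- function(x) round(x, 2)

#' Percentage of a count relative to a denominator
#'
#' Report-formatting helper used for conservation tables: `100 * k / n`
#' rounded to `digits` decimals.
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @param digits decimals to keep (default 2).
#' @return Numeric percentage.
#' @examples
#' pct_of(5175, 7479)  # 69.19
#' @export
pct_of <- function(k, n, digits = 2) {
  check_number(n, "n", lower = 1)
  round(100 * k / n, digits)
}
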