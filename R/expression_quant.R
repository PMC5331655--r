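#' Count reads overlapping each feature
#'
#' coverageBed-style counting: a read interval is counted for every
#' feature it overlaps by at least one base (so a read straddling two
#' features increments both), strand-blind, on 0-based half-open
#' coordinates.
#'
#' @param features data.frame with `chrom`, `start`, `end`.
#' @param reads data.frame of read intervals with `chrom`, `start`, `end`.
#' @param ignore_strand Count regardless of strand (default), as the
#'   unstranded coverage step this mirrors; set `FALSE` for strand-aware
#'   counting when both inputs carry strands.
#' @return Integer vector of counts, one per feature row.
#' @export
count_overlapping_reads <- function(features, reads, ignore_strand = TRUE) {
  if (nrow(features) == 0L) return(integer())
  if (nrow(reads) == 0L) return(integer(nrow(features)))
  # disjoint chromosome sets are legitimate (count is then 0), so the
  # GenomicRanges "no sequence levels in common" warning is noise here
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges0(features), as_granges0(reads),
                                 ignore.strand = ignore_strand))
}

#' Reads per kilobase of feature per million mapped reads
#'
#' `RPKM = count / ((length/1000) * (librarySize/1e6))`, i.e. the read
#' count normalised by feature length and sequencing depth.
#'
#' @param count Read count(s), >= 0.
#' @param length_bp Feature length in bp, > 0.
#' @param library_size Mapped reads in the library, > 0.
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) validation_error("length_bp must be > 0")
  if (any(library_size <= 0)) validation_error("library_size must be > 0")
  count / ((length_bp / 1000) * (library_size / 1e6))
}

#' Expressed-feature rules
#'
#' Two distinct thresholding rules, both against an inclusive RPKM
#' cutoff of 1: TEs are called expressed when the *mean* RPKM over
#' replicates reaches the cutoff; transcripts require the cutoff in
#' *every* replicate. The all-replicates rule is strictly stricter, so
#' `transcript_expressed()` implies `te_expressed()`.
#'
#' @param rpkms Numeric vector of per-replicate RPKM values (>= 1 value).
#' @param cutoff RPKM threshold (default 1, inclusive).
#' @return Logical scalar.
#' @examples
#' te_expressed(c(0.5, 1.6))          # TRUE  (mean 1.05)
#' transcript_expressed(c(0.5, 1.6))  # FALSE
#' @export
te_expressed <- function(rpkms, cutoff = 1) {
  if (length(rpkms) < 1L) validation_error("need >= 1 replicate RPKM")
  mean(rpkms) >= cutoff
}

#' @rdname te_expressed
#' @export
transcript_expressed <- function(rpkms, cutoff = 1) {
  if (length(rpkms) < 1L) validation_error("need >= 1 replicate RPKM")
  all(rpkms >= cutoff)
}

#' Per-feature expression table over replicates
#'
#' Combines counts, library sizes and feature lengths into per-replicate
#' RPKMs, the mean RPKM, and the expressed flag under the chosen rule.
#'
#' @param feature_id Character vector of feature ids.
#' @param length_bp Feature lengths (bp).
#' @param counts Integer matrix, features x replicates.
#' @param library_sizes Integer vector of per-replicate library sizes.
#' @param mode `"te"` (mean-over-replicates rule) or `"transcript"`
#'   (all-replicates rule).
#' @param cutoff RPKM threshold (default 1).
#' @return data.frame with `feature_id`, `length_bp`, per-replicate
#'   `rpkm_<i>` columns, `mean_rpkm`, `expressed`.
#' @export
expression_table <- function(feature_id, length_bp, counts, library_sizes,
                             mode = c("te", "transcript"), cutoff = 1) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (ncol(counts) != length(library_sizes)) {
    validation_error("counts has %d columns but %d library sizes given",
                     ncol(counts), length(library_sizes))
  }
  if (nrow(counts) != length(feature_id)) {
    validation_error("counts has %d rows but %d feature ids given",
                     nrow(counts), length(feature_id))
  }
  r <- sweep(counts, 2L, library_sizes / 1e6, "/") / (length_bp / 1000)
  expressed <- if (mode == "te") rowMeans(r) >= cutoff else
    apply(r >= cutoff, 1L, all)
  out <- data.frame(feature_id = feature_id, length_bp = length_bp,
                    stringsAsFactors = FALSE)
  colnames(r) <- paste0("rpkm_", seq_len(ncol(r)))
  out <- cbind(out, as.data.frame(r))
  out$mean_rpkm <- rowMeans(r)
  out$expressed <- expressed
  out
}

#' Write / read a counts matrix with library sizes
#'
#' Plain TSV with a `#library_sizes:` comment header carrying the
#' per-replicate library sizes, then `feature_id`, `length_bp` and one
#' count column per replicate.
#'
#' @param feature_id,length_bp,counts,library_sizes As in
#'   [expression_table()].
#' @param path File path.
#' @return `write_counts_tsv()` returns `path` invisibly;
#'   `read_counts_tsv()` returns a list with `feature_id`, `length_bp`,
#'   `counts` (matrix) and `library_sizes`.
#' @export
write_counts_tsv <- function(feature_id, length_bp, counts, library_sizes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_sizes: ", paste(library_sizes, collapse = ",")), con)
  df <- data.frame(feature_id = feature_id, length_bp = length_bp, counts)
  colnames(df) <- c("feature_id", "length_bp",
                    paste0("rep", seq_len(ncol(as.matrix(counts)))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#library_sizes:")) {
    parse_error("counts TSV missing '#library_sizes:' header line")
  }
  lib <- as.integer(strsplit(trimws(sub("^#library_sizes:", "", first)), ",")[[1L]])
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  if (ncol(counts) != length(lib)) {
    parse_error("counts TSV: %d count columns but %d library sizes",
                ncol(counts), length(lib))
  }
  list(feature_id = df$feature_id, length_bp = df$length_bp,
       counts = counts, library_sizes = lib)
}
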