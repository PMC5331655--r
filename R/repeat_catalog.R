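#' Parse a RepeatMasker `.out` repeat table
#'
#' Reads the classic RepeatMasker output dialect: three header lines
#' followed by whitespace-delimited columns (Smith-Waterman score, percent
#' divergence, percent deleted, percent inserted, query sequence, query
#' begin, query end, query left, strand, repeat name, repeat class/family,
#' repeat begin, repeat end, repeat left, ID, and an optional `*` marker
#' for overlapping annotations). Query coordinates are 1-based inclusive
#' in the file and are converted to 0-based half-open. A strand token of
#' `C` (complement) becomes `-`.
#'
#' The repeat name column is kept whole as the family name (e.g. `AluYa5`);
#' the class/family column is split on `/` and its first component becomes
#' the TE class (e.g. `SINE`).
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return data.frame of fragments with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `family`, `te_class`, `perc_div`,
#'   `sw_score`, `rm_id`.
#' @seealso [join_nested_repeats()] to merge fragments sharing an ID into
#'   insertions.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) parse_error("repeatmasker file has fewer than 3 header lines")
  body_idx <- seq.int(4L, length.out = max(0L, length(lines) - 3L))
  keep <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(keep) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), family = character(),
                      te_class = character(), perc_div = numeric(),
                      sw_score = integer(), rm_id = integer(),
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nt <- lengths(toks)
  bad <- which(nt < 15L)
  if (length(bad)) {
    parse_error("malformed repeatmasker line %d: expected >= 15 fields, got %d",
                keep[bad[1L]], nt[bad[1L]])
  }
  field <- function(i) vapply(toks, `[[`, character(1L), i)
  num <- function(i, name) {
    v <- suppressWarnings(as.numeric(field(i)))
    if (anyNA(v)) {
      parse_error("malformed repeatmasker line %d: non-numeric '%s' column",
                  keep[which(is.na(v))[1L]], name)
    }
    v
  }
  sw      <- num(1L, "swScore")
  percdiv <- num(2L, "percDiv")
  qbegin  <- num(6L, "qBegin")
  qend    <- num(7L, "qEnd")
  strand  <- field(9L)
  rm_id   <- num(15L, "ID")
  if (any(percdiv < 0 | percdiv > 100)) {
    parse_error("malformed repeatmasker line %d: percDiv outside [0,100]",
                keep[which(percdiv < 0 | percdiv > 100)[1L]])
  }
  if (any(qbegin > qend)) {
    parse_error("malformed repeatmasker line %d: qBegin > qEnd",
                keep[which(qbegin > qend)[1L]])
  }
  if (!all(strand %in% c("+", "C"))) {
    parse_error("malformed repeatmasker line %d: strand must be '+' or 'C'",
                keep[which(!strand %in% c("+", "C"))[1L]])
  }
  class_family <- field(11L)
  data.frame(
    chrom = field(5L),
    start = as.integer(qbegin - 1),
    end = as.integer(qend),
    strand = ifelse(strand == "C", "-", "+"),
    family = field(10L),
    te_class = sub("/.*$", "", class_family),
    perc_div = percdiv,
    sw_score = as.integer(sw),
    rm_id = as.integer(rm_id),
    stringsAsFactors = FALSE
  )
}

#' Scale percent divergence to a 0-1000 similarity score
#'
#' Linear transform `round(1000 * (1 - percDiv/100))`: identity to the
#' family consensus maps to 1000 and complete divergence to 0, so higher
#' scores mean younger insertions. The scaled score is used ordinally as
#' an age surrogate throughout, so any strictly monotone transform would
#' preserve downstream conclusions; the linear one is adopted and
#' documented as the package's choice.
#'
#' @param perc_div Percent divergence from consensus, in `[0, 100]`.
#' @return Integer vector of scores in `[0, 1000]`.
#' @examples
#' scale_similarity(c(0, 12.5, 100))  # 1000 875 0
#' @export
scale_similarity <- function(perc_div) {
  if (!is.numeric(perc_div) || anyNA(perc_div)) {
    validation_error("perc_div must be numeric with no NA")
  }
  if (any(perc_div < 0 | perc_div > 100)) {
    validation_error("perc_div outside [0,100]: %s",
                     format(perc_div[perc_div < 0 | perc_div > 100][1L]))
  }
  as.integer(round(1000 * (1 - perc_div / 100)))
}

#' Join nested repeat fragments into insertions
#'
#' RepeatMasker assigns the same ID to fragments of a single insertion that
#' was split by a younger interloping element. Fragments sharing
#' `(chrom, rm_id)` are merged into one instance whose span runs from the
#' first fragment start to the last fragment end; singleton fragments pass
#' through unmodified. The instance similarity score is the
#' length-weighted mean of the fragment scaled scores and `length_bp` is
#' the sum of fragment lengths (the span minus any interloper).
#'
#' Fragments sharing an ID on different chromosomes are never merged; a
#' warning is emitted and they become separate instances.
#'
#' @param fragments data.frame from [parse_repeatmasker_out()].
#' @return data.frame of instances: `instance_id`, `chrom`, `start`, `end`
#'   (span, half-open), `strand`, `family`, `te_class`, `scaled_score`,
#'   `length_bp`, `n_fragments`.
#' @export
join_nested_repeats <- function(fragments) {
  dt <- data.table::as.data.table(fragments)
  if (nrow(dt) == 0L) {
    return(data.frame(instance_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      family = character(), te_class = character(),
                      scaled_score = integer(), length_bp = integer(),
                      n_fragments = integer(), stringsAsFactors = FALSE))
  }
  multi_chrom <- dt[, data.table::uniqueN(chrom), by = rm_id][V1 > 1L]
  if (nrow(multi_chrom)) {
    warning(sprintf("rm_id(s) %s span multiple chromosomes; kept as separate instances",
                    paste(utils::head(multi_chrom$rm_id, 5L), collapse = ", ")))
  }
  dt[, frag_len := end - start]
  dt[, frag_score := scale_similarity(perc_div)]
  inst <- dt[, {
    longest <- which.max(frag_len)
    list(
      start = min(start),
      end = max(end),
      strand = strand[longest],
      family = family[longest],
      te_class = te_class[longest],
      scaled_score = as.integer(round(sum(frag_score * frag_len) / sum(frag_len))),
      length_bp = as.integer(sum(frag_len)),
      n_fragments = .N
    )
  }, by = .(chrom, rm_id)]
  inst[, instance_id := paste0(chrom, "_", rm_id)]
  data.table::setcolorder(inst, c("instance_id", "chrom", "start", "end",
                                  "strand", "family", "te_class",
                                  "scaled_score", "length_bp", "n_fragments"))
  data.table::setorder(inst, chrom, start)
  inst[, rm_id := NULL]
  as.data.frame(inst)
}

#' Mean family similarity score (family age surrogate)
#'
#' The age of a family is summarised as the arithmetic mean of the scaled
#' similarity scores of its member instances: high mean score = young
#' family.
#'
#' @param instances data.frame from [join_nested_repeats()].
#' @return data.frame with `family`, `te_class`, `mean_scaled_score`,
#'   `n_instances`.
#' @export
family_ages <- function(instances) {
  dt <- data.table::as.data.table(instances)
  if (nrow(dt) == 0L) {
    return(data.frame(family = character(), te_class = character(),
                      mean_scaled_score = numeric(), n_instances = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- dt[, .(mean_scaled_score = mean(scaled_score), n_instances = .N),
            by = .(family, te_class)]
  data.table::setorder(out, family)
  as.data.frame(out)
}

#' Remove TE instances that overlap coding regions
#'
#' Expression analysis of TEs is restricted to instances whose span does
#' not overlap any coding interval by even one base; overlap is computed
#' on half-open coordinates, so an instance touching a coding interval
#' end-to-start is kept.
#'
#' @param instances data.frame of TE instances.
#' @param coding data.frame of coding intervals (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return The subset of `instances` with no coding overlap.
#' @export
filter_coding_overlap <- function(instances, coding) {
  if (nrow(instances) == 0L) return(instances)
  instances[!overlap_any(instances, coding), , drop = FALSE]
}

#' Write / read TE instances as BED6
#'
#' BED name encodes `family|instance_id`, score is the scaled similarity
#' score. Reading back reproduces span, strand, family and score exactly.
#'
#' @param instances data.frame of TE instances.
#' @param path Output file path.
#' @return `write_instances_bed()` returns `path` invisibly;
#'   `read_instances_bed()` returns an instance data.frame (without
#'   fragment-level columns).
#' @export
write_instances_bed <- function(instances, path) {
  gr <- as_granges0(instances)
  gr$name <- paste0(instances$family, "|", instances$instance_id)
  gr$score <- instances$scaled_score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_instances_bed
#' @export
read_instances_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  name <- as.character(gr$name)
  bar <- regexpr("|", name, fixed = TRUE)
  data.frame(
    instance_id = substring(name, bar + 1L),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family = substring(name, 1L, bar - 1L),
    scaled_score = as.integer(gr$score),
    stringsAsFactors = FALSE
  )
}
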