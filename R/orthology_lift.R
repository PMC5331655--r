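#' Parse a UCSC chain alignment file
#'
#' A chain file describes a gapped pairwise genome alignment as a header
#' line (`chain score sChrom sSize sStrand sStart sEnd tChrom tSize
#' tStrand tStart tEnd id`) followed by block lines `alignedSize
#' sourceGap targetGap` and a final bare `alignedSize`. Coordinates are
#' 0-based half-open; on a `-` strand they count from the far end of the
#' sequence (UCSC convention). The first coordinate triple is the *source*
#' assembly (the one intervals are lifted from), the second the *target*.
#'
#' Block sums are verified at parse time:
#' `sum(size) + sum(sourceGap) == sourceEnd - sourceStart` and the
#' analogous identity on the target side; a mismatch is a parse error
#' naming the chain id.
#'
#' @param path Path to a chain file.
#' @return List of chain objects (class `te_chain`), each a list with the
#'   header fields and a `blocks` data.frame (`size`, `s_gap`, `t_gap`).
#' @export
parse_chain <- function(path) {
  lines <- trimws(readLines(path))
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], "chain")) {
      parse_error("expected 'chain' header at line %d", i)
    }
    h <- strsplit(lines[i], "\\s+")[[1L]]
    if (length(h) < 13L) parse_error("chain header at line %d has %d fields, expected 13", i, length(h))
    ch <- list(
      score = as.numeric(h[2L]),
      s_chrom = h[3L], s_size = as.integer(h[4L]), s_strand = h[5L],
      s_start = as.integer(h[6L]), s_end = as.integer(h[7L]),
      t_chrom = h[8L], t_size = as.integer(h[9L]), t_strand = h[10L],
      t_start = as.integer(h[11L]), t_end = as.integer(h[12L]),
      id = h[13L]
    )
    if (ch$s_strand != "+") {
      parse_error("chain %s: source strand must be '+'", ch$id)
    }
    i <- i + 1L
    size <- integer(); s_gap <- integer(); t_gap <- integer()
    repeat {
      if (i > n || !nzchar(lines[i])) parse_error("chain %s: truncated block list", ch$id)
      tok <- strsplit(lines[i], "\\s+")[[1L]]
      v <- suppressWarnings(as.integer(tok))
      if (anyNA(v)) parse_error("chain %s: malformed block line %d", ch$id, i)
      if (length(v) == 3L) {
        size <- c(size, v[1L]); s_gap <- c(s_gap, v[2L]); t_gap <- c(t_gap, v[3L])
        i <- i + 1L
      } else if (length(v) == 1L) {
        size <- c(size, v[1L]); s_gap <- c(s_gap, 0L); t_gap <- c(t_gap, 0L)
        i <- i + 1L
        break
      } else {
        parse_error("chain %s: block line %d must have 1 or 3 fields", ch$id, i)
      }
    }
    if (any(size < 1L) || any(s_gap < 0L) || any(t_gap < 0L)) {
      parse_error("chain %s: block sizes must be >= 1 and gaps >= 0", ch$id)
    }
    if (sum(size) + sum(s_gap) != ch$s_end - ch$s_start) {
      parse_error("chain %s: source block sums do not match span", ch$id)
    }
    if (sum(size) + sum(t_gap) != ch$t_end - ch$t_start) {
      parse_error("chain %s: target block sums do not match span", ch$id)
    }
    ch$blocks <- data.frame(size = size, s_gap = s_gap, t_gap = t_gap)
    class(ch) <- "te_chain"
    out[[length(out) + 1L]] <- ch
  }
  out
}

#' Write chains in UCSC chain format
#'
#' @param chains List of `te_chain` objects (see [parse_chain()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %s",
                       format(ch$score, scientific = FALSE), ch$s_chrom, ch$s_size,
                       ch$s_strand, ch$s_start, ch$s_end, ch$t_chrom, ch$t_size,
                       ch$t_strand, ch$t_start, ch$t_end, ch$id), con)
    b <- ch$blocks
    k <- nrow(b)
    if (k > 1L) {
      writeLines(sprintf("%d %d %d", b$size[-k], b$s_gap[-k], b$t_gap[-k]), con)
    }
    writeLines(c(sprintf("%d", b$size[k]), ""), con)
  }
  invisible(path)
}

# Flatten a chain list into per-block and per-chain tables with absolute
# source coordinates and strand-local target block starts.
chain_block_table <- function(chains) {
  blk <- data.table::rbindlist(lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    b <- ch$blocks
    adv_s <- cumsum(c(0L, (b$size + b$s_gap)[-nrow(b)]))
    adv_t <- cumsum(c(0L, (b$size + b$t_gap)[-nrow(b)]))
    data.table::data.table(
      ci = ci,
      chrom = ch$s_chrom,
      bs = ch$s_start + adv_s,
      be = ch$s_start + adv_s + b$size,
      ts = ch$t_start + adv_t
    )
  }))
  meta <- data.table::rbindlist(lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    data.table::data.table(ci = ci, chrom = ch$s_chrom,
                           s_start = ch$s_start, s_end = ch$s_end,
                           score = ch$score, chain_id = ch$id,
                           t_chrom = ch$t_chrom, t_size = ch$t_size,
                           t_strand = ch$t_strand)
  }))
  list(blocks = blk, meta = meta)
}

#' Lift intervals to another assembly through alignment chains
#'
#' For each interval, every overlapping chain is scored by the number of
#' interval bases that fall inside its aligned blocks (`mappedBases`).
#' The chain maximising `mappedBases` wins, with the chain score breaking
#' ties; if the top two chains still tie and map to different target
#' loci the result is `ambiguous`. A lift succeeds when
#' `mappedBases / width >= min_match` (the LiftOver `-minMatch` rule);
#' the target interval then spans the target positions of the first
#' through last mapped source base, reported on the forward strand of the
#' target (with `t_strand` recording a flip).
#'
#' Statuses: `mapped`, `unmapped_below_minMatch`, `unmapped_no_chain`,
#' `ambiguous`.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `id`.
#' @param chains List of chains from [parse_chain()].
#' @param min_match Minimum fraction of bases that must remap (default
#'   0.1, the cross-species LiftOver default).
#' @return data.frame with one row per input interval: `status`,
#'   `mapped_bases`, `mapped_ratio`, `chain_id`, `t_chrom`, `t_start`,
#'   `t_end`, `t_strand`.
#' @export
lift_intervals <- function(intervals, chains, min_match = 0.1) {
  check_number(min_match, "min_match", lower = 0, upper = 1)
  nq <- nrow(intervals)
  width <- intervals$end - intervals$start
  if (any(width <= 0)) {
    validation_error("zero-length interval at row %d", which(width <= 0)[1L])
  }
  res <- data.frame(
    status = rep("unmapped_no_chain", nq),
    mapped_bases = 0L, mapped_ratio = 0,
    chain_id = NA_character_, t_chrom = NA_character_,
    t_start = NA_integer_, t_end = NA_integer_, t_strand = NA_character_,
    stringsAsFactors = FALSE
  )
  if (length(chains) == 0L || nq == 0L) return(res)

  tab <- chain_block_table(chains)
  qgr <- as_granges0(intervals[, c("chrom", "start", "end")])

  # Any chain whose span overlaps marks the interval as at least "below".
  span_gr <- GenomicRanges::GRanges(tab$meta$chrom,
                                    IRanges::IRanges(tab$meta$s_start + 1L, tab$meta$s_end))
  has_chain <- GenomicRanges::countOverlaps(qgr, span_gr, ignore.strand = TRUE) > 0L
  res$status[has_chain] <- "unmapped_below_minMatch"

  bgr <- GenomicRanges::GRanges(tab$blocks$chrom,
                                IRanges::IRanges(tab$blocks$bs + 1L, tab$blocks$be))
  hits <- GenomicRanges::findOverlaps(qgr, bgr, ignore.strand = TRUE)
  if (length(hits) == 0L) return(res)

  qi <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  dt <- data.table::data.table(
    qi = qi, ci = tab$blocks$ci[bi],
    ov_s = pmax(intervals$start[qi], tab$blocks$bs[bi]),
    ov_e = pmin(intervals$end[qi], tab$blocks$be[bi]),
    bs = tab$blocks$bs[bi], ts = tab$blocks$ts[bi]
  )
  dt[, `:=`(w = ov_e - ov_s, tf = ts + (ov_s - bs), tl = ts + (ov_e - bs))]
  agg <- dt[, .(mapped = sum(w), tmin = min(tf), tmax = max(tl)), by = .(qi, ci)]
  agg <- merge(agg, tab$meta[, .(ci, score, chain_id, t_chrom, t_size, t_strand)],
               by = "ci")
  data.table::setorder(agg, qi, -mapped, -score)
  best <- agg[, {
    amb <- .N >= 2L && mapped[2L] == mapped[1L] && score[2L] == score[1L] &&
      (t_chrom[2L] != t_chrom[1L] || tmin[2L] != tmin[1L] || tmax[2L] != tmax[1L])
    .SD[1L, .(mapped, tmin, tmax, chain_id, t_chrom, t_size, t_strand,
              ambiguous = amb)]
  }, by = qi]

  idx <- best$qi
  ratio <- best$mapped / width[idx]
  res$mapped_bases[idx] <- as.integer(best$mapped)
  res$mapped_ratio[idx] <- ratio
  ok <- ratio >= min_match & !best$ambiguous
  res$status[idx[best$ambiguous & ratio >= min_match]] <- "ambiguous"
  oi <- idx[ok]
  res$status[oi] <- "mapped"
  res$chain_id[oi] <- best$chain_id[ok]
  res$t_chrom[oi] <- best$t_chrom[ok]
  neg <- best$t_strand == "-"
  res$t_start[oi] <- as.integer(ifelse(neg[ok], best$t_size[ok] - best$tmax[ok], best$tmin[ok]))
  res$t_end[oi]   <- as.integer(ifelse(neg[ok], best$t_size[ok] - best$tmin[ok], best$tmax[ok]))
  res$t_strand[oi] <- ifelse(neg[ok], "-", "+")
  res
}

#' Lift a single interval
#'
#' Convenience wrapper around [lift_intervals()] for one interval.
#'
#' @param chrom,start,end Source interval (0-based half-open).
#' @param chains List of chains from [parse_chain()].
#' @param min_match Minimum remap ratio.
#' @return A one-row list with the fields of [lift_intervals()].
#' @export
lift_interval <- function(chrom, start, end, chains, min_match = 0.1) {
  df <- data.frame(chrom = chrom, start = start, end = end)
  as.list(lift_intervals(df, chains, min_match)[1L, ])
}

#' Classify TE instances as sequence-conserved in a target species
#'
#' Lifts each instance span to the target assembly and overlays the
#' result on the target species' own repeat catalog. `lifted` records a
#' successful lift; `te_annotated_in_target` requires >= 1 bp overlap
#' with any target TE instance; `same_family_in_target` additionally
#' requires that the maximally overlapping target instance carry the
#' same family name. Expression conservation downstream uses the any-TE
#' flag; the same-family flag is kept for re-annotation concordance
#' checks.
#'
#' @param instances Query-species TE instance data.frame.
#' @param chains Chains from query to target assembly.
#' @param target_instances TE instance data.frame of the target species.
#' @param min_match Minimum remap ratio for the lift.
#' @param target_species Optional label stored in the result.
#' @return data.frame with `instance_id`, `family`, `te_class`,
#'   `target_species`, `status`, `lifted`, `te_annotated_in_target`,
#'   `same_family_in_target`, `t_chrom`, `t_start`, `t_end`,
#'   `target_instance_id`.
#' @export
classify_conservation <- function(instances, chains, target_instances,
                                  min_match = 0.1, target_species = NA_character_) {
  lifted <- lift_intervals(instances, chains, min_match)
  rec <- data.frame(
    instance_id = instances$instance_id,
    family = instances$family,
    te_class = instances$te_class,
    target_species = target_species,
    status = lifted$status,
    lifted = lifted$status == "mapped",
    te_annotated_in_target = FALSE,
    same_family_in_target = FALSE,
    t_chrom = lifted$t_chrom, t_start = lifted$t_start, t_end = lifted$t_end,
    target_instance_id = NA_character_,
    stringsAsFactors = FALSE
  )
  ok <- which(rec$lifted)
  if (length(ok) && nrow(target_instances)) {
    q <- data.frame(chrom = rec$t_chrom[ok], start = rec$t_start[ok], end = rec$t_end[ok])
    hits <- GenomicRanges::findOverlaps(as_granges0(q), as_granges0(target_instances),
                                        ignore.strand = TRUE)
    if (length(hits)) {
      hi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- pmin(q$end[hi], target_instances$end[si]) -
        pmax(q$start[hi], target_instances$start[si])
      dt <- data.table::data.table(hi = hi, si = si, ov = ov)
      data.table::setorder(dt, hi, -ov, si)
      topdt <- dt[, .SD[1L], by = hi]
      rows <- ok[topdt$hi]
      rec$te_annotated_in_target[rows] <- TRUE
      rec$target_instance_id[rows] <- target_instances$instance_id[topdt$si]
      rec$same_family_in_target[rows] <-
        target_instances$family[topdt$si] == rec$family[rows]
    }
  }
  rec
}

#' Fraction of lifted instances independently re-annotated to the same family
#'
#' Validation statistic for the lifting strategy: among instances of one
#' family that lift successfully, the fraction whose best-overlapping
#' target annotation carries the same family name.
#'
#' @param records Conservation records for a single family
#'   (from [classify_conservation()]).
#' @return A value in `[0, 1]`.
#' @export
reannotation_concordance <- function(records) {
  lifted <- records[records$lifted, , drop = FALSE]
  if (nrow(lifted) == 0L) {
    tx_error("teconsex_undefined_error",
             "concordance undefined: no lifted instances for this family")
  }
  mean(lifted$same_family_in_target)
}
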