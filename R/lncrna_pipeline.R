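#' Transcript set container
#'
#' A light container for multi-exon transcript models: a `transcripts`
#' table (`transcript_id`, `chrom`, `strand`, `biotype`,
#' `coding_potential`) and an `exons` table (`transcript_id`,
#' `exon_index`, `chrom`, `start`, `end`, `strand`; 0-based half-open,
#' sorted and disjoint within a transcript), plus an optional named
#' character vector of nucleotide `sequences` for the ORF-based coding
#' score.
#'
#' @param transcripts,exons data.frames as described above.
#' @param sequences Optional named character vector (names =
#'   transcript ids).
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons, sequences = NULL) {
  ord <- order(exons$transcript_id, exons$start)
  exons <- exons[ord, , drop = FALSE]
  if (!"exon_index" %in% names(exons)) {
    exons$exon_index <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                                   FUN = seq_along)
  }
  bad <- exons$start >= exons$end
  if (any(bad)) validation_error("exon with start >= end (transcript %s)",
                                 exons$transcript_id[bad][1L])
  structure(list(transcripts = transcripts, exons = exons,
                 sequences = sequences),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d exons\n",
              nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

n_exons_per_transcript <- function(ts) {
  tab <- table(ts$exons$transcript_id)
  as.integer(tab[ts$transcripts$transcript_id])
}

subset_transcripts <- function(ts, keep_ids) {
  transcript_set(
    ts$transcripts[ts$transcripts$transcript_id %in% keep_ids, , drop = FALSE],
    ts$exons[ts$exons$transcript_id %in% keep_ids, , drop = FALSE],
    if (!is.null(ts$sequences)) ts$sequences[names(ts$sequences) %in% keep_ids]
  )
}

#' Read transcript models from a GTF file
#'
#' Uses rtracklayer to parse GTF2.2; exon records are grouped by
#' `transcript_id`, and the optional `transcript_biotype` and
#' `coding_potential` attributes are carried into the transcript table.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_set()].
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  exons <- data.frame(
    transcript_id = as.character(ex$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE
  )
  meta <- S4Vectors::mcols(ex)
  biotype <- if ("transcript_biotype" %in% colnames(meta))
    as.character(meta$transcript_biotype) else rep(NA_character_, length(ex))
  cp <- if ("coding_potential" %in% colnames(meta))
    suppressWarnings(as.numeric(meta$coding_potential)) else rep(NA_real_, length(ex))
  first <- !duplicated(exons$transcript_id)
  transcripts <- data.frame(
    transcript_id = exons$transcript_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    biotype = biotype[first],
    coding_potential = cp[first],
    stringsAsFactors = FALSE
  )
  transcript_set(transcripts, exons)
}

#' Write transcript models as GTF
#'
#' Emits one `transcript` and per-exon `exon` records with `gene_id`,
#' `transcript_id`, and (when present) `transcript_biotype` and
#' `coding_potential` attributes.
#'
#' @param ts A [transcript_set()].
#' @param path Output path.
#' @param source Value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(ts, path, source = "teconsex") {
  tx <- ts$transcripts
  ex <- ts$exons
  if (nrow(tx) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  attr_of <- function(i) {
    a <- sprintf('gene_id "%s"; transcript_id "%s";', tx$transcript_id[i],
                 tx$transcript_id[i])
    if (!is.na(tx$biotype[i])) {
      a <- paste0(a, sprintf(' transcript_biotype "%s";', tx$biotype[i]))
    }
    if (!is.na(tx$coding_potential[i])) {
      a <- paste0(a, sprintf(' coding_potential "%s";',
                             formatC(tx$coding_potential[i], format = "f", digits = 4)))
    }
    a
  }
  span <- data.table::as.data.table(ex)[, .(start = min(start), end = max(end)),
                                        by = transcript_id]
  span <- span[match(tx$transcript_id, transcript_id)]
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    a <- attr_of(i)
    lines <- c(lines, sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom[i], source, span$start[i] + 1L, span$end[i],
                              tx$strand[i], a))
    exi <- ex[ex$transcript_id == tx$transcript_id[i], , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
                              exi$chrom, source, exi$start + 1L, exi$end,
                              exi$strand, a, exi$exon_index))
  }
  writeLines(lines, path)
  invisible(path)
}

#' ORF-based coding potential score
#'
#' Stand-in coding-potential score in `[0, 1]`: the length of the longest
#' open reading frame (ATG through an in-frame stop codon, inclusive,
#' scanned over the three forward frames) divided by the sequence length.
#'
#' @param sequence Nucleotide string over `A, C, G, T, N`.
#' @return Score in `[0, 1]`; 0 when no complete ORF exists.
#' @examples
#' orf_coding_score("ATGAAATAA")  # 1
#' @export
orf_coding_score <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    validation_error("sequence must be a single non-empty string")
  }
  s <- toupper(sequence)
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L || starts[1L] > n - 2L) next
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    for (a in atg) {
      k <- stp[stp >= a]
      if (length(k)) {
        best <- max(best, (k[1L] - a + 1L) * 3L)
      }
    }
  }
  best / n
}

#' Default biotype blacklist for lncRNA catalog construction
#'
#' Known non-lncRNA biotypes removed in the first filtering step:
#' protein-coding genes, all pseudogene subtypes, and classic short
#' non-coding RNA classes.
#'
#' @return Character vector of biotype names (pseudogene subtypes are
#'   matched by substring).
#' @export
default_biotype_blacklist <- function() {
  c("protein_coding", "pseudogene", "tRNA", "rRNA", "snRNA", "snoRNA",
    "miRNA", "misc_RNA")
}

#' Build an lncRNA catalog by cascade filtering
#'
#' Three ordered, logged filtering steps on an assembled transcriptome:
#' (1) remove transcripts whose biotype is blacklisted (pseudogene
#' subtypes match by substring); (2) remove mono-exonic transcripts;
#' (3) remove transcripts with coding potential at or above the cutoff,
#' scoring from the `coding_potential` attribute when present, otherwise
#' from [orf_coding_score()] on the attached sequence. Transcripts with
#' neither a score nor a sequence cannot be cleared and are removed with
#' a warning.
#'
#' @param ts A [transcript_set()].
#' @param biotype_blacklist Biotypes to remove (default
#'   [default_biotype_blacklist()]).
#' @param coding_cutoff Coding-potential cutoff (default 0.364, a widely
#'   used human cutoff for CPAT-style scores; arbitrary here and meant to
#'   be set per dataset).
#' @return A `transcript_set` of retained transcripts with a
#'   `filter_log` attribute: data.frame of per-step removal counts.
#' @export
build_lncrna_catalog <- function(ts, biotype_blacklist = default_biotype_blacklist(),
                                 coding_cutoff = 0.364) {
  check_number(coding_cutoff, "coding_cutoff", lower = 0, upper = 1)
  tx <- ts$transcripts
  n0 <- nrow(tx)

  bt <- tx$biotype
  bad_biotype <- !is.na(bt) &
    (bt %in% biotype_blacklist |
       ("pseudogene" %in% biotype_blacklist & grepl("pseudogene", bt)))
  tx1 <- tx[!bad_biotype, , drop = FALSE]

  ne <- table(ts$exons$transcript_id)
  mono <- as.integer(ne[tx1$transcript_id]) < 2L
  tx2 <- tx1[!mono, , drop = FALSE]

  score <- tx2$coding_potential
  need <- is.na(score)
  if (any(need) && !is.null(ts$sequences)) {
    have_seq <- tx2$transcript_id %in% names(ts$sequences)
    idx <- which(need & have_seq)
    score[idx] <- vapply(ts$sequences[tx2$transcript_id[idx]],
                         orf_coding_score, numeric(1))
  }
  unscored <- is.na(score)
  if (any(unscored)) {
    warning(sprintf("%d transcript(s) had neither coding_potential nor sequence; removed",
                    sum(unscored)))
  }
  keep <- !unscored & score < coding_cutoff
  tx3 <- tx2[keep, , drop = FALSE]

  log <- data.frame(
    step = c("biotype_blacklist", "mono_exonic", "coding_potential"),
    removed = c(sum(bad_biotype), sum(mono), sum(!keep)),
    remaining = c(nrow(tx1), nrow(tx2), nrow(tx3)),
    stringsAsFactors = FALSE
  )
  message(paste(sprintf("lncRNA filter %s: removed %d, %d remaining",
                        log$step, log$removed, log$remaining), collapse = "\n"))
  out <- subset_transcripts(ts, tx3$transcript_id)
  attr(out, "filter_log") <- log
  out
}

#' Fraction of catalog transcripts overlapping a reference catalog
#'
#' A transcript counts as overlapping when any of its exons has >= 1 bp
#' same-strand overlap with any exon of the reference.
#'
#' @param catalog,reference [transcript_set()] objects on the same
#'   assembly.
#' @return Fraction in `[0, 1]`.
#' @export
reference_overlap <- function(catalog, reference) {
  if (nrow(catalog$transcripts) == 0L) {
    tx_error("teconsex_undefined_error", "reference overlap undefined: empty catalog")
  }
  qh <- GenomicRanges::findOverlaps(as_granges0(catalog$exons),
                                    as_granges0(reference$exons),
                                    ignore.strand = FALSE)
  hit_tx <- unique(catalog$exons$transcript_id[S4Vectors::queryHits(qh)])
  length(hit_tx) / nrow(catalog$transcripts)
}

#' Annotate lncRNAs with overlapping TE instances
#'
#' An exon-TE intersection counts only when the overlap covers at least
#' `min_exon_fraction` of the exon's length (default 10%). Each
#' transcript gets a `has_te` flag and a dominant TE: the instance with
#' the largest total overlap summed over the transcript's exons, ties
#' broken by the largest single-exon overlap, then lexicographic family
#' name.
#'
#' @param catalog A [transcript_set()].
#' @param te_instances TE instance data.frame.
#' @param min_exon_fraction Minimum exon fraction covered (default 0.1;
#'   0 reduces to plain >= 1 bp intersection).
#' @return List with `overlaps` (per exon x TE rows: `transcript_id`,
#'   `exon_index`, `instance_id`, `family`, `te_class`, `overlap_bp`,
#'   `exon_length`, segment coordinates) and `transcripts`
#'   (`transcript_id`, `has_te`, `dominant_family`,
#'   `dominant_instance_id`).
#' @export
annotate_te_overlap <- function(catalog, te_instances, min_exon_fraction = 0.1) {
  check_number(min_exon_fraction, "min_exon_fraction", lower = 0, upper = 1)
  ex <- catalog$exons
  empty <- data.frame(transcript_id = character(), exon_index = integer(),
                      instance_id = character(), family = character(),
                      te_class = character(), overlap_bp = integer(),
                      exon_length = integer(), seg_start = integer(),
                      seg_end = integer(), stringsAsFactors = FALSE)
  tx_out <- data.frame(transcript_id = catalog$transcripts$transcript_id,
                       has_te = FALSE, dominant_family = NA_character_,
                       dominant_instance_id = NA_character_,
                       stringsAsFactors = FALSE)
  if (nrow(ex) == 0L || nrow(te_instances) == 0L) {
    return(list(overlaps = empty, transcripts = tx_out))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(ex), as_granges0(te_instances),
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(list(overlaps = empty, transcripts = tx_out))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- data.frame(
    transcript_id = ex$transcript_id[qi],
    exon_index = ex$exon_index[qi],
    instance_id = te_instances$instance_id[si],
    family = te_instances$family[si],
    te_class = te_instances$te_class[si],
    seg_start = pmax(ex$start[qi], te_instances$start[si]),
    seg_end = pmin(ex$end[qi], te_instances$end[si]),
    exon_length = ex$end[qi] - ex$start[qi],
    stringsAsFactors = FALSE
  )
  ov$overlap_bp <- ov$seg_end - ov$seg_start
  ov <- ov[ov$overlap_bp >= min_exon_fraction * ov$exon_length &
             ov$overlap_bp >= 1L, , drop = FALSE]
  if (nrow(ov)) {
    dt <- data.table::as.data.table(ov)
    dom <- dt[, .(total_bp = sum(overlap_bp), max_single = max(overlap_bp),
                  family = family[1L]),
              by = .(transcript_id, instance_id)]
    data.table::setorder(dom, transcript_id, -total_bp, -max_single, family,
                         instance_id)
    top <- dom[, .SD[1L], by = transcript_id]
    m <- match(tx_out$transcript_id, top$transcript_id)
    tx_out$has_te <- !is.na(m)
    tx_out$dominant_family <- top$family[m]
    tx_out$dominant_instance_id <- top$instance_id[m]
  }
  rownames(ov) <- NULL
  list(overlaps = ov[, names(empty)], transcripts = tx_out)
}

# Resolve overlapping TE segments within exons so no exon base is counted
# twice: bases contested by several instances go to the instance with the
# longest local overlap in that exon.
dedup_overlap_segments <- function(ov) {
  if (nrow(ov) == 0L) return(ov)
  dt <- data.table::as.data.table(ov)
  dt[, row_id := .I]
  data.table::setorder(dt, transcript_id, exon_index, -overlap_bp, family,
                       instance_id)
  parts <- vector("list", nrow(dt))
  grp <- dt[, .(rows = list(row_id)), by = .(transcript_id, exon_index)]
  out <- list()
  for (g in seq_len(nrow(grp))) {
    rows <- match(grp$rows[[g]], dt$row_id)
    taken <- IRanges::IRanges()
    for (r in rows) {
      seg <- IRanges::IRanges(dt$seg_start[r] + 1L, dt$seg_end[r])
      free <- IRanges::setdiff(seg, taken)
      w <- sum(IRanges::width(free))
      taken <- IRanges::union(taken, seg)
      if (w > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = dt$transcript_id[r], exon_index = dt$exon_index[r],
          instance_id = dt$instance_id[r], family = dt$family[r],
          te_class = dt$te_class[r], overlap_bp = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(ov[0, c("transcript_id", "exon_index",
                                        "instance_id", "family", "te_class",
                                        "overlap_bp")])
  do.call(rbind, out)
}

#' TE contribution statistics for an lncRNA catalog
#'
#' Computes, over the TE-overlapping transcripts of the catalog:
#' per-class lncRNA sequence proportions (class overlap bp / total exon
#' bp of TE-overlapping transcripts), per-class and per-family genomic
#' proportions (instance bp / genome length), the normalised family
#' contribution (lncRNA bp proportion / genomic proportion), and the
#' per-family lncRNA frequency normalised by family instance count
#' (families with more than `min_family_size` members).
#'
#' By default each exon base is assigned to at most one TE instance (the
#' one with the longest local overlap), so class proportions never
#' double-count a base; `allow_double_count = TRUE` restores raw
#' intersectBed `-wao`-style summation.
#'
#' @param annotations Result of [annotate_te_overlap()].
#' @param catalog The annotated [transcript_set()].
#' @param te_instances TE instance data.frame (for genomic proportions).
#' @param genome_length Genome size in bp.
#' @param allow_double_count Keep overlapping TE segments as-is.
#' @param min_family_size Family-size floor for the frequency table.
#' @return List of data.frames: `class_stats` (`te_class`, `lncrna_bp`,
#'   `lncrna_proportion`, `genomic_bp`, `genomic_proportion`),
#'   `family_stats` (adds `normalized_contribution`), `family_frequency`
#'   (`family`, `n_transcripts`, `n_instances`, `frequency`).
#' @export
contribution_stats <- function(annotations, catalog, te_instances, genome_length,
                               allow_double_count = FALSE, min_family_size = 10) {
  check_number(genome_length, "genome_length", lower = 1)
  ov <- annotations$overlaps
  te_tx <- annotations$transcripts$transcript_id[annotations$transcripts$has_te]
  if (length(te_tx) == 0L) {
    tx_error("teconsex_undefined_error",
             "contribution undefined: no TE-overlapping transcripts")
  }
  ex <- catalog$exons
  total_exon_bp <- sum((ex$end - ex$start)[ex$transcript_id %in% te_tx])
  seg <- if (allow_double_count) ov else dedup_overlap_segments(ov)
  segdt <- data.table::as.data.table(seg)

  inst <- data.table::as.data.table(te_instances)
  gen_class <- inst[, .(genomic_bp = sum(length_bp)), by = te_class]
  gen_family <- inst[, .(genomic_bp = sum(length_bp), n_instances = .N),
                     by = .(family, te_class)]

  cls <- segdt[, .(lncrna_bp = sum(overlap_bp)), by = te_class]
  cls <- merge(cls, gen_class, by = "te_class", all.x = TRUE)
  cls[, `:=`(lncrna_proportion = lncrna_bp / total_exon_bp,
             genomic_proportion = genomic_bp / genome_length)]
  data.table::setorder(cls, -lncrna_bp)

  fam <- segdt[, .(lncrna_bp = sum(overlap_bp)), by = family]
  fam <- merge(fam, gen_family, by = "family", all.x = TRUE)
  fam[, `:=`(lncrna_proportion = lncrna_bp / total_exon_bp,
             genomic_proportion = genomic_bp / genome_length)]
  fam[, normalized_contribution := lncrna_proportion / genomic_proportion]
  data.table::setorder(fam, -normalized_contribution)

  freq <- data.table::as.data.table(ov)[, .(n_transcripts = data.table::uniqueN(transcript_id)),
                                        by = family]
  freq <- merge(freq, gen_family[, .(family, n_instances)], by = "family")
  freq <- freq[n_instances > min_family_size]
  freq[, frequency := n_transcripts / n_instances]
  data.table::setorder(freq, -frequency)

  list(class_stats = as.data.frame(cls),
       family_stats = as.data.frame(fam),
       family_frequency = as.data.frame(freq))
}

#' Lift an lncRNA catalog across species and tier by conservation
#'
#' For each target species the transcript span is lifted as one interval
#' (`n_lifted`); lifted transcripts are re-annotated with TEs in target
#' coordinates by per-exon lifting and the >= 10%-of-exon rule
#' (`n_lifted_te`); expression over the lifted span is quantified from
#' target reads and thresholded with the all-replicates rule
#' (`n_lifted_expressed`), combining into `n_lifted_expressed_te`.
#' Percentages are reported relative to the lifted count, 2 decimals.
#' Transcripts are tiered: `all_species` (lifted and expressed in every
#' target), `some_nhp` (>= 1 target), `query_only`.
#'
#' @param catalog A [transcript_set()] in query coordinates.
#' @param targets Named list; each element a list with `chains`
#'   (query-to-target), `te_instances` (target repeat catalog), `reads`
#'   (list of per-replicate read data.frames) and optionally
#'   `library_sizes` (defaults to read counts).
#' @param min_match Minimum remap ratio (default 0.1).
#' @param min_exon_fraction TE-overlap exon fraction rule (default 0.1).
#' @param rpkm_cutoff Expression threshold (default 1).
#' @return List with `table` (one row per target: counts and
#'   percentages) and `tiers` (`transcript_id`, `tier`).
#' @export
lncrna_conservation <- function(catalog, targets, min_match = 0.1,
                                min_exon_fraction = 0.1, rpkm_cutoff = 1) {
  tx <- catalog$transcripts
  ex <- catalog$exons
  spans <- data.table::as.data.table(ex)[, .(chrom = chrom[1L],
                                             start = min(start), end = max(end)),
                                         by = transcript_id]
  spans <- spans[match(tx$transcript_id, transcript_id)]
  n_targets <- length(targets)
  lifted_expr <- matrix(FALSE, nrow(tx), n_targets,
                        dimnames = list(tx$transcript_id, names(targets)))
  rows <- list()
  for (tg in names(targets)) {
    t <- targets[[tg]]
    lift <- lift_intervals(as.data.frame(spans[, .(chrom, start, end)]),
                           t$chains, min_match)
    is_lifted <- lift$status == "mapped"
    n_lifted <- sum(is_lifted)

    # Per-exon lift, then the exon-fraction TE rule in target coordinates.
    exl <- lift_intervals(ex[, c("chrom", "start", "end")], t$chains, min_match)
    exon_ok <- exl$status == "mapped"
    te_tx <- character(0)
    if (any(exon_ok) && nrow(t$te_instances)) {
      lex <- data.frame(transcript_id = ex$transcript_id[exon_ok],
                        chrom = exl$t_chrom[exon_ok],
                        start = exl$t_start[exon_ok], end = exl$t_end[exon_ok],
                        stringsAsFactors = FALSE)
      hits <- GenomicRanges::findOverlaps(as_granges0(lex),
                                          as_granges0(t$te_instances),
                                          ignore.strand = TRUE)
      if (length(hits)) {
        qi <- S4Vectors::queryHits(hits)
        si <- S4Vectors::subjectHits(hits)
        obp <- pmin(lex$end[qi], t$te_instances$end[si]) -
          pmax(lex$start[qi], t$te_instances$start[si])
        elen <- lex$end[qi] - lex$start[qi]
        qual <- obp >= min_exon_fraction * elen & obp >= 1L
        te_tx <- unique(lex$transcript_id[qi[qual]])
      }
    }
    has_te <- tx$transcript_id %in% te_tx & is_lifted
    n_lifted_te <- sum(has_te)

    expressed <- rep(FALSE, nrow(tx))
    if (n_lifted > 0L && length(t$reads)) {
      feat <- data.frame(chrom = lift$t_chrom[is_lifted],
                         start = lift$t_start[is_lifted],
                         end = lift$t_end[is_lifted], stringsAsFactors = FALSE)
      libs <- if (!is.null(t$library_sizes)) t$library_sizes else
        vapply(t$reads, nrow, integer(1))
      counts <- vapply(t$reads, function(r) count_overlapping_reads(feat, r),
                       integer(nrow(feat)))
      counts <- matrix(counts, nrow = nrow(feat))
      r <- sweep(counts, 2L, libs / 1e6, "/") / ((feat$end - feat$start) / 1000)
      expressed[is_lifted] <- apply(r >= rpkm_cutoff, 1L, all)
    }
    n_expr <- sum(expressed)
    n_expr_te <- sum(expressed & has_te)
    lifted_expr[, tg] <- is_lifted & expressed
    rows[[tg]] <- data.frame(
      target_species = tg,
      n_catalog = nrow(tx), n_lifted = n_lifted, n_lifted_te = n_lifted_te,
      n_lifted_expressed = n_expr, n_lifted_expressed_te = n_expr_te,
      pct_lifted_te = pct_of(n_lifted_te, max(n_lifted, 1)),
      pct_lifted_expressed = pct_of(n_expr, max(n_lifted, 1)),
      pct_lifted_expressed_te = pct_of(n_expr_te, max(n_lifted, 1)),
      stringsAsFactors = FALSE
    )
  }
  n_ok <- rowSums(lifted_expr)
  tiers <- data.frame(
    transcript_id = tx$transcript_id,
    tier = ifelse(n_ok == n_targets, "all_species",
                  ifelse(n_ok >= 1L, "some_nhp", "query_only")),
    stringsAsFactors = FALSE
  )
  list(table = do.call(rbind, rows), tiers = tiers)
}

#' Format a conservation report row from transcript counts
#'
#' Report formatting used for the cross-species lncRNA table: given the
#' lifted count and the lifted-and-TE / lifted-and-expressed /
#' lifted-expressed-TE counts, returns the three percentages relative to
#' the lifted count at 2 decimals.
#'
#' @param n_lifted Lifted transcripts.
#' @param n_lifted_te Lifted transcripts overlapping a TE in the target.
#' @param n_lifted_expressed Lifted transcripts expressed in the target.
#' @param n_lifted_expressed_te Lifted, expressed, TE-overlapping.
#' @return Named list of counts and percentages.
#' @examples
#' conservation_report_row(7479, n_lifted_te = 5175)$pct_lifted_te  # 69.19
#' @export
conservation_report_row <- function(n_lifted, n_lifted_te = NA,
                                    n_lifted_expressed = NA,
                                    n_lifted_expressed_te = NA) {
  check_number(n_lifted, "n_lifted", lower = 1)
  list(n_lifted = n_lifted,
       pct_lifted_te = if (is.na(n_lifted_te)) NA else pct_of(n_lifted_te, n_lifted),
       pct_lifted_expressed = if (is.na(n_lifted_expressed)) NA else
         pct_of(n_lifted_expressed, n_lifted),
       pct_lifted_expressed_te = if (is.na(n_lifted_expressed_te)) NA else
         pct_of(n_lifted_expressed_te, n_lifted))
}
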