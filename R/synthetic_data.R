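#' Specification of one simulated TE family
#'
#' Parameters controlling a family in the synthetic multi-species
#' dataset. `mean_perc_div` is the age surrogate (younger families have
#' lower divergence); `loss_prob_per_branch` is the probability an
#' instance is absent from a derived species, so recent families can be
#' given high loss to reproduce the age-conservation trend.
#' `expr_prob_query` is the marginal probability an instance is expressed
#' in the query species; `expr_correlation` is the probability that a
#' retained ortholog of a query-expressed instance is expressed in the
#' target species. Retained orthologs of non-expressed instances are
#' expressed with probability `expr_prob_query`, so setting
#' `expr_correlation == expr_prob_query` yields independence (a null
#' family) while larger values plant conserved expression.
#'
#' @param name Family name.
#' @param te_class One of `DNA`, `LTR`, `LINE`, `SINE`, `Other` (plus the
#'   filtered classes `Simple_repeat`, `Low_complexity` for testing).
#' @param n_instances Number of instances in the query genome.
#' @param mean_perc_div Mean percent divergence from consensus.
#' @param loss_prob_per_branch Per-target-species loss probability.
#' @param expr_prob_query Query expression probability.
#' @param expr_correlation Target expression probability for retained,
#'   query-expressed instances.
#' @param length_range Instance length range in bp (min 200).
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, te_class, n_instances, mean_perc_div,
                        loss_prob_per_branch, expr_prob_query,
                        expr_correlation, length_range = c(200L, 800L)) {
  if (!is.character(name) || !nzchar(name)) config_error("invalid 'name' in family spec")
  if (!te_class %in% c("DNA", "LTR", "LINE", "SINE", "Other",
                       "Simple_repeat", "Low_complexity")) {
    config_error("invalid 'te_class' for family %s", name)
  }
  for (f in c("loss_prob_per_branch", "expr_prob_query", "expr_correlation")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) config_error("invalid '%s' for family %s", f, name)
  }
  if (n_instances < 0) config_error("invalid 'n_instances' for family %s", name)
  if (mean_perc_div < 0 || mean_perc_div > 100) {
    config_error("invalid 'mean_perc_div' for family %s", name)
  }
  if (length_range[1] < 200) config_error("invalid 'length_range' for family %s (min 200)", name)
  structure(list(name = name, te_class = te_class,
                 n_instances = as.integer(n_instances),
                 mean_perc_div = mean_perc_div,
                 loss_prob_per_branch = loss_prob_per_branch,
                 expr_prob_query = expr_prob_query,
                 expr_correlation = expr_correlation,
                 length_range = as.integer(length_range)),
            class = "family_spec")
}

#' Default family set for the simulated dataset
#'
#' Eight families spanning the four main classes with divergence/loss
#' pairs that reproduce the age-conservation trend (younger = higher
#' loss), two planted expression-conserved families (correlation 0.8)
#' and one planted depleted family (0.05) against a 0.3 background.
#'
#' @param n_instances Instances per family.
#' @return List of [family_spec()] objects.
#' @export
default_family_set <- function(n_instances = 250) {
  list(
    family_spec("AluYs",   "SINE", n_instances,  5, 0.40, 0.3, 0.30),
    family_spec("AluSxs",  "SINE", n_instances, 12, 0.15, 0.3, 0.30),
    family_spec("L1Ms",    "LINE", n_instances, 25, 0.05, 0.3, 0.30),
    family_spec("L2s",     "LINE", n_instances, 30, 0.03, 0.3, 0.30),
    family_spec("MER53s",  "DNA",  n_instances, 20, 0.08, 0.3, 0.80),
    family_spec("HERVHs",  "LTR",  n_instances, 15, 0.10, 0.3, 0.80),
    family_spec("MLT1s",   "LTR",  n_instances, 28, 0.05, 0.3, 0.30),
    family_spec("Tiggers", "DNA",  n_instances, 22, 0.08, 0.3, 0.05)
  )
}

#' Configuration for the synthetic multi-species dataset
#'
#' The defaults mirror the study design the package targets: four
#' species (the first is the query) with 3, 1, 2 and 1 biological
#' replicates, 100 bp read intervals, and the [default_family_set()].
#'
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   outputs.
#' @param species Character vector of species names (>= 2; first =
#'   query).
#' @param genome_length Genome size (bp) of each species' single
#'   chromosome coordinate space.
#' @param families List of [family_spec()] objects.
#' @param n_reads_per_replicate Reference library size per replicate.
#' @param replicates_per_species Integer vector, one entry per species.
#' @param lncrna_count Number of true multi-exon lncRNA transcripts.
#' @param coding_gene_count Number of coding genes (their CDS forms the
#'   coding BED).
#' @param target_rpkm Planted expression level for expressed features.
#' @param background_rpkm Background level for non-expressed TEs.
#' @param te_lnc_fraction Fraction of lncRNAs built over a TE instance.
#' @param lnc_expr_prob_target Probability a true lncRNA is expressed in
#'   each target species.
#' @param split_fragment_fraction Fraction of TE instances emitted as two
#'   RepeatMasker fragments sharing an ID (nested-repeat emulation).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       species = c("human", "chimp", "gorilla", "rhesus"),
                       genome_length = 6e6,
                       families = default_family_set(),
                       n_reads_per_replicate = 3e5,
                       replicates_per_species = c(3L, 1L, 2L, 1L),
                       lncrna_count = 150L,
                       coding_gene_count = 40L,
                       target_rpkm = 50,
                       background_rpkm = 0.05,
                       te_lnc_fraction = 0.75,
                       lnc_expr_prob_target = 0.5,
                       split_fragment_fraction = 0.05) {
  cfg <- list(seed = as.integer(seed), species = species,
              genome_length = genome_length, families = families,
              n_reads_per_replicate = n_reads_per_replicate,
              replicates_per_species = as.integer(replicates_per_species),
              lncrna_count = as.integer(lncrna_count),
              coding_gene_count = as.integer(coding_gene_count),
              target_rpkm = target_rpkm, background_rpkm = background_rpkm,
              te_lnc_fraction = te_lnc_fraction,
              lnc_expr_prob_target = lnc_expr_prob_target,
              split_fragment_fraction = split_fragment_fraction)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (length(cfg$species) < 2L) config_error("invalid 'species': need >= 2 species")
  if (anyDuplicated(cfg$species)) config_error("invalid 'species': duplicated names")
  if (!is.numeric(cfg$genome_length) || cfg$genome_length <= 0) {
    config_error("invalid 'genome_length': must be > 0")
  }
  if (length(cfg$replicates_per_species) != length(cfg$species)) {
    config_error("invalid 'replicates_per_species': need one entry per species")
  }
  if (any(cfg$replicates_per_species < 1L)) {
    config_error("invalid 'replicates_per_species': must be >= 1")
  }
  for (f in c("n_reads_per_replicate", "lncrna_count", "coding_gene_count")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) config_error("invalid '%s': must be >= 0", f)
  }
  if (!length(cfg$families)) config_error("invalid 'families': need >= 1 family")
  for (fm in cfg$families) {
    if (!inherits(fm, "family_spec")) config_error("invalid 'families': use family_spec()")
  }
  if (anyDuplicated(vapply(cfg$families, `[[`, "", "name"))) {
    config_error("invalid 'families': duplicated family names")
  }
  structure(cfg, class = "sim_config")
}

# Expected read count for a feature at a planted RPKM.
#' Invert the RPKM formula to an expected read count
#'
#' @param rpkm_value Planted RPKM.
#' @param length_bp Feature length.
#' @param library_size Library size.
#' @return Expected count `rpkm * (length/1000) * (lib/1e6)`.
#' @examples
#' expected_read_count(10, 1000, 1e6)  # 10
#' @export
expected_read_count <- function(rpkm_value, length_bp, library_size) {
  rpkm_value * (length_bp / 1000) * (library_size / 1e6)
}

# ---- internal helpers -------------------------------------------------------

NOISE_REGION <- 50000L   # reserved TE-free region at the chromosome start
READ_LEN <- 100L         # matches 100 bp sequencing reads

write_repeatmasker_out <- function(frags, genome_length, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching repeat          position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat   class/family  begin end   (left)  ID",
    "")
  body <- sprintf("%6d %5s  0.5  0.3  %s %8d %8d (%d) %s %-12s %-16s %6d %6d (0) %6d",
                  frags$sw_score, formatC(frags$perc_div, format = "f", digits = 1),
                  frags$chrom, frags$start + 1L, frags$end,
                  as.integer(genome_length) - frags$end,
                  ifelse(frags$strand == "-", "C", "+"),
                  frags$family, frags$class_family,
                  1L, frags$end - frags$start, frags$rm_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_reads_bed <- function(reads, path) {
  gr <- as_granges0(reads)
  gr$name <- paste0("read", seq_along(gr))
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read BED intervals into a 0-based half-open data.frame
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end` (plus `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- as.character(gr$name)
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

write_bed3 <- function(df, path) {
  rtracklayer::export(as_granges0(df), path, format = "BED")
  invisible(path)
}

# Map source positions through the generator's own gap list.  `bs`, `be`
# are aligned block bounds on the source; `ts` the target block starts.
make_coord_map <- function(bs, be, ts) {
  force(bs); force(be); force(ts)
  pos <- function(p) {
    i <- findInterval(p, bs)
    bad <- i == 0L | p >= be[pmax(i, 1L)]
    if (any(bad)) stop("internal: mapping unaligned position")
    ts[i] + (p - bs[i])
  }
  # Span map: target span of the mapped portion of [a, b).
  span <- function(a, b) {
    ia <- findInterval(a, bs) ; ia[ia == 0L] <- 1L
    in_gap_a <- a >= be[ia] | a < bs[ia]
    ia[in_gap_a] <- ia[in_gap_a] + 1L
    a2 <- pmax(a, bs[ia])
    ib <- findInterval(b - 1L, bs)
    b2 <- pmin(b, be[ib])
    t_start <- ts[ia] + (a2 - bs[ia])
    t_end <- ts[ib] + (b2 - bs[ib])
    cbind(t_start, t_end)
  }
  list(pos = pos, span = span)
}

# Draw per-feature Poisson counts and uniform read placements.
draw_reads <- function(feat, n_reads_ref, target_rpkm, background_rpkm) {
  lam <- expected_read_count(
    ifelse(feat$expressed, target_rpkm, background_rpkm),
    feat$end - feat$start, n_reads_ref)
  counts <- stats::rpois(nrow(feat), lam)
  idx <- rep.int(seq_len(nrow(feat)), counts)
  span <- feat$end[idx] - feat$start[idx] - READ_LEN
  start <- feat$start[idx] + floor(stats::runif(length(idx)) * (span + 1L))
  n_fill <- max(0L, as.integer(n_reads_ref) - length(idx))
  fill_start <- floor(stats::runif(n_fill) * (NOISE_REGION - READ_LEN))
  reads <- data.frame(chrom = "chr1",
                      start = as.integer(c(start, fill_start)),
                      end = as.integer(c(start, fill_start)) + READ_LEN)
  reads[order(reads$start), , drop = FALSE]
}

random_orf_sequence <- function(n_codons = 100L) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste0, collapse = "")
  safe <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  paste0("ATG", paste(sample(safe, n_codons - 2L, replace = TRUE), collapse = ""), "TAA")
}

# ---- the generator ----------------------------------------------------------

#' Simulate a multi-species TE/lncRNA dataset with planted ground truth
#'
#' Generates, for every species, a RepeatMasker-style repeat table,
#' per-replicate 100 bp read intervals (BED), a transcript GTF and a
#' coding-region BED, plus a UCSC chain file from the query species to
#' every target. Species genomes are pure coordinate spaces (one
#' chromosome `chr1`); no nucleotide sequence is simulated except short
#' synthetic sequences attached to coding-potential decoy transcripts.
#'
#' Instances lost on a branch fall inside chain gaps; retained instances
#' keep a small unaligned trim at each edge (~5%, max 20 bp) and a small
#' target-side insertion, so lifts succeed with a mapped-base ratio well
#' above 0.1 but below 1. Expressed features receive Poisson read counts
#' calibrated to `target_rpkm`; non-expressed TEs receive
#' `background_rpkm`. A TE-free noise region at the chromosome start is
#' topped up with filler reads so each replicate's library is at least
#' `n_reads_per_replicate`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, all files are
#'   written there (deterministically for a fixed config).
#' @return A `te_sim` list: per-species `instances`, `fragments`,
#'   `reads`, `transcripts`, `coding`, per-target `chains`, the query
#'   `sequences`, and `ground_truth` (retention and expression flags,
#'   per-transcript type/host/tier). When `dir` is given, a `files`
#'   element lists every path written.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  config <- validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  species <- config$species
  query <- species[1L]
  targets <- species[-1L]
  glen <- as.integer(config$genome_length)

  ## --- query TE layout -------------------------------------------------
  inst <- data.table::rbindlist(lapply(config$families, function(fm) {
    n <- fm$n_instances
    data.table::data.table(
      family = fm$name, te_class = fm$te_class,
      len = sample(seq.int(fm$length_range[1L], fm$length_range[2L]), n, TRUE),
      perc_div = round(pmin(pmax(stats::rnorm(n, fm$mean_perc_div, 2), 0.1), 95), 1),
      loss = fm$loss_prob_per_branch, expr_prob = fm$expr_prob_query,
      corr = fm$expr_correlation)
  }))
  n_te <- nrow(inst)
  inst <- inst[sample(n_te)]

  n_te_lnc <- round(config$te_lnc_fraction * config$lncrna_count)
  n_te_lnc <- min(n_te_lnc, n_te)
  n_slot_lnc <- config$lncrna_count - n_te_lnc
  n_mono <- if (config$lncrna_count > 0) max(2L, round(0.08 * config$lncrna_count)) else 0L
  n_hcp  <- if (config$lncrna_count > 0) max(2L, round(0.04 * config$lncrna_count)) else 0L
  n_slots <- n_slot_lnc + n_mono + n_hcp

  elem <- data.table::data.table(
    type = c(rep("te", n_te), rep("slot", n_slots)),
    idx = c(seq_len(n_te), seq_len(max(n_slots, 0L))),
    width = c(inst$len, rep(800L, n_slots)))
  elem <- elem[sample(.N)]
  gap <- sample(200:600, nrow(elem), TRUE)
  gap[1L] <- gap[1L] + NOISE_REGION
  elem[, start := cumsum(gap + c(0L, width[-.N]))]
  elem[, end := start + width]

  coding_base <- max(elem$end) + 5000L
  coding <- if (config$coding_gene_count > 0L) {
    data.frame(chrom = "chr1",
               start = coding_base + (seq_len(config$coding_gene_count) - 1L) * 1200L,
               end = coding_base + (seq_len(config$coding_gene_count) - 1L) * 1200L + 900L)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  used <- if (nrow(coding)) max(coding$end) + 1000L else max(elem$end) + 1000L
  if (used > glen) {
    config_error("invalid 'genome_length': layout needs %d bp but genome_length is %d",
                 used, glen)
  }

  te_rows <- elem[type == "te"]
  inst[te_rows$idx, `:=`(start = te_rows$start, end = te_rows$end)]
  data.table::setorder(inst, start)
  inst[, rm_id := .I]
  inst[, instance_id := paste0("chr1_", rm_id)]
  inst[, chrom := "chr1"]
  inst[, strand := sample(c("+", "-"), n_te, TRUE)]
  slot_rows <- elem[type == "slot"][order(start)]

  ## --- query fragments (nested-repeat splits) --------------------------
  split <- stats::runif(n_te) < config$split_fragment_fraction & inst$len >= 400L
  frag_one <- inst[!split]
  frag_sp <- inst[split]
  l1 <- (frag_sp$len - 120L) %/% 2L
  frags <- rbind(
    data.frame(chrom = rep("chr1", nrow(frag_one)), start = frag_one$start,
               end = frag_one$end, strand = frag_one$strand,
               family = frag_one$family,
               class_family = sprintf("%s/%s", frag_one$te_class, frag_one$family),
               perc_div = frag_one$perc_div, rm_id = frag_one$rm_id),
    if (nrow(frag_sp)) data.frame(
      chrom = rep("chr1", 2L * nrow(frag_sp)),
      start = c(frag_sp$start, frag_sp$start + l1 + 120L),
      end = c(frag_sp$start + l1, frag_sp$end),
      strand = rep(frag_sp$strand, 2L), family = rep(frag_sp$family, 2L),
      class_family = rep(paste0(frag_sp$te_class, "/", frag_sp$family), 2L),
      perc_div = rep(frag_sp$perc_div, 2L), rm_id = rep(frag_sp$rm_id, 2L))
  )
  frags <- frags[order(frags$start), , drop = FALSE]
  frags$sw_score <- as.integer(round((frags$end - frags$start) * 10 *
                                       (1 - frags$perc_div / 100)))

  ## --- expression in the query -----------------------------------------
  inst[, expr_q := stats::runif(n_te) < expr_prob]

  ## --- per-target retention, chains, coordinates, expression -----------
  tr <- pmin(20L, inst$len %/% 20L)
  per_target <- list()
  for (tg in targets) {
    retained <- stats::runif(n_te) < (1 - inst$loss)
    dq <- sample(0:5, n_te, TRUE)
    # gaps on the source: whole span for lost, edge trims for retained
    gs <- c(inst$start[!retained],
            inst$start[retained], inst$end[retained] - tr[retained])
    ge <- c(inst$end[!retained],
            inst$start[retained] + tr[retained], inst$end[retained])
    gq <- c(integer(sum(!retained)), integer(sum(retained)), dq[retained])
    og <- order(gs)
    gs <- gs[og]; ge <- ge[og]; gq <- gq[og]
    dt_gap <- ge - gs
    bs <- c(0L, ge)
    be <- c(gs, glen)
    ts <- as.integer(bs - c(0L, cumsum(dt_gap)) + c(0L, cumsum(gq)))
    t_size <- glen - sum(dt_gap) + sum(gq)
    blocks <- data.frame(size = be - bs,
                         s_gap = c(dt_gap, 0L),
                         t_gap = c(gq, 0L))
    chain <- structure(list(score = 1e6, s_chrom = "chr1", s_size = glen,
                            s_strand = "+", s_start = 0L, s_end = glen,
                            t_chrom = "chr1", t_size = as.integer(t_size),
                            t_strand = "+", t_start = 0L,
                            t_end = as.integer(t_size), id = "1",
                            blocks = blocks), class = "te_chain")
    cmap <- make_coord_map(bs, be, ts)
    t_start_i <- rep(NA_integer_, n_te)
    t_end_i <- rep(NA_integer_, n_te)
    ridx <- which(retained)
    if (length(ridx)) {
      t_start_i[ridx] <- cmap$pos(inst$start[ridx] + tr[ridx])
      t_end_i[ridx] <- t_start_i[ridx] + (inst$len[ridx] - 2L * tr[ridx])
    }
    expr_t <- rep(NA, n_te)
    expr_t[retained] <- stats::runif(sum(retained)) <
      ifelse(inst$expr_q[retained], inst$corr[retained], inst$expr_prob[retained])
    per_target[[tg]] <- list(retained = retained, chain = chain, map = cmap,
                             t_start = t_start_i, t_end = t_end_i,
                             expr_t = expr_t, t_size = as.integer(t_size))
  }

  ## --- transcripts -------------------------------------------------------
  tx_list <- list(); exon_list <- list(); sequences <- character(0)
  host_of <- integer(0)
  if (config$lncrna_count > 0 || config$coding_gene_count > 0) {
    if (n_te_lnc > 0) {
      w <- c(LTR = 8, LINE = 6, DNA = 4, SINE = 1, Other = 1,
             Simple_repeat = 1, Low_complexity = 1)[inst$te_class]
      hosts <- sample(n_te, n_te_lnc, prob = w)
      host_of <- hosts
      ids <- sprintf("lnc%04d", seq_len(n_te_lnc))
      s <- inst$start[hosts]; e <- inst$end[hosts]
      tx_list$te_lnc <- data.frame(
        transcript_id = ids, type = "lncrna", chrom = "chr1", strand = "+",
        biotype = NA_character_,
        coding_potential = round(stats::runif(n_te_lnc, 0, 0.3), 4),
        host = hosts, stringsAsFactors = FALSE)
      exon_list$te_lnc <- data.frame(
        transcript_id = rep(ids, 2L), chrom = "chr1",
        start = c(s - 80L, e + 50L), end = c(s + 120L, e + 180L),
        strand = "+", stringsAsFactors = FALSE)
    }
    slot_i <- 0L
    take_slot <- function() {
      slot_i <<- slot_i + 1L
      if (slot_i > nrow(slot_rows)) stop("internal: out of slots")
      c(slot_rows$start[slot_i], slot_rows$end[slot_i])
    }
    if (n_slot_lnc > 0) {
      ids <- sprintf("lnc%04d", n_te_lnc + seq_len(n_slot_lnc))
      ss <- t(vapply(seq_len(n_slot_lnc), function(i) take_slot(), numeric(2)))
      tx_list$slot_lnc <- data.frame(
        transcript_id = ids, type = "lncrna", chrom = "chr1", strand = "+",
        biotype = NA_character_,
        coding_potential = round(stats::runif(n_slot_lnc, 0, 0.3), 4),
        host = NA_integer_, stringsAsFactors = FALSE)
      exon_list$slot_lnc <- data.frame(
        transcript_id = rep(ids, 2L), chrom = "chr1",
        start = c(ss[, 1L] + 50L, ss[, 1L] + 350L),
        end = c(ss[, 1L] + 250L, ss[, 1L] + 500L),
        strand = "+", stringsAsFactors = FALSE)
    }
    if (n_mono > 0) {
      ids <- sprintf("mono%03d", seq_len(n_mono))
      ss <- t(vapply(seq_len(n_mono), function(i) take_slot(), numeric(2)))
      tx_list$mono <- data.frame(
        transcript_id = ids, type = "mono_exonic", chrom = "chr1", strand = "+",
        biotype = NA_character_,
        coding_potential = round(stats::runif(n_mono, 0, 0.3), 4),
        host = NA_integer_, stringsAsFactors = FALSE)
      exon_list$mono <- data.frame(
        transcript_id = ids, chrom = "chr1",
        start = ss[, 1L] + 100L, end = ss[, 1L] + 500L,
        strand = "+", stringsAsFactors = FALSE)
    }
    if (n_hcp > 0) {
      ids <- sprintf("hcp%03d", seq_len(n_hcp))
      ss <- t(vapply(seq_len(n_hcp), function(i) take_slot(), numeric(2)))
      seq_path <- seq_len(n_hcp) > n_hcp / 2   # latter half scored from sequence
      cp <- ifelse(seq_path, NA_real_, round(stats::runif(n_hcp, 0.5, 0.9), 4))
      tx_list$hcp <- data.frame(
        transcript_id = ids, type = "high_coding_potential", chrom = "chr1",
        strand = "+", biotype = NA_character_, coding_potential = cp,
        host = NA_integer_, stringsAsFactors = FALSE)
      exon_list$hcp <- data.frame(
        transcript_id = rep(ids, 2L), chrom = "chr1",
        start = c(ss[, 1L] + 50L, ss[, 1L] + 350L),
        end = c(ss[, 1L] + 250L, ss[, 1L] + 500L),
        strand = "+", stringsAsFactors = FALSE)
      for (i in which(seq_path)) {
        sequences[ids[i]] <- random_orf_sequence(100L)
      }
    }
    if (config$coding_gene_count > 0) {
      ids <- sprintf("cds%03d", seq_len(config$coding_gene_count))
      tx_list$cds <- data.frame(
        transcript_id = ids, type = "coding", chrom = "chr1", strand = "+",
        biotype = "protein_coding", coding_potential = 0.9, host = NA_integer_,
        stringsAsFactors = FALSE)
      exon_list$cds <- data.frame(
        transcript_id = rep(ids, 2L), chrom = "chr1",
        start = c(coding$start, coding$start + 500L),
        end = c(coding$start + 400L, coding$start + 900L),
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  tx <- if (length(tx_list)) do.call(rbind, tx_list) else
    data.frame(transcript_id = character(), type = character(), chrom = character(),
               strand = character(), biotype = character(),
               coding_potential = numeric(), host = integer(),
               stringsAsFactors = FALSE)
  exons <- if (length(exon_list)) do.call(rbind, exon_list) else
    data.frame(transcript_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  rownames(tx) <- rownames(exons) <- NULL

  spans <- if (nrow(exons)) {
    data.table::as.data.table(exons)[, .(start = min(start), end = max(end)),
                                     by = transcript_id]
  } else data.table::data.table(transcript_id = character(),
                                start = integer(), end = integer())
  spans <- spans[match(tx$transcript_id, transcript_id)]

  ## transcript lift/expression per target + tiers
  is_lnc <- tx$type == "lncrna"
  tx_lift <- matrix(TRUE, nrow(tx), length(targets),
                    dimnames = list(tx$transcript_id, targets))
  tx_expr <- matrix(FALSE, nrow(tx), length(targets),
                    dimnames = list(tx$transcript_id, targets))
  for (tg in targets) {
    pt <- per_target[[tg]]
    if (nrow(tx)) {
      host_lost <- !is.na(tx$host) & !pt$retained[ifelse(is.na(tx$host), 1L, tx$host)]
      span_len <- spans$end - spans$start
      unaligned <- ifelse(is.na(tx$host), 0L,
                          ifelse(host_lost, inst$len[ifelse(is.na(tx$host), 1L, tx$host)],
                                 2L * tr[ifelse(is.na(tx$host), 1L, tx$host)]))
      ratio <- (span_len - unaligned) / span_len
      tx_lift[, tg] <- ratio >= 0.1
      # the target locus is transcribed if the lncRNA itself is expressed
      # there, or if a retained host TE is expressed (its reads cover the
      # transcript span either way)
      host_expressed <- !is.na(tx$host) & !host_lost &
        !is.na(pt$expr_t[ifelse(is.na(tx$host), 1L, tx$host)]) &
        pt$expr_t[ifelse(is.na(tx$host), 1L, tx$host)] %in% TRUE
      tx_expr[, tg] <- tx_lift[, tg] &
        ((is_lnc & stats::runif(nrow(tx)) < config$lnc_expr_prob_target) |
           tx$type == "coding" | (is_lnc & host_expressed))
    }
  }
  n_ok <- if (nrow(tx)) rowSums(tx_lift & tx_expr) else integer(0)
  tier <- ifelse(n_ok == length(targets), "all_species",
                 ifelse(n_ok >= 1L, "some_nhp", "query_only"))

  ## --- per-species read generation and repeat tables --------------------
  datasets <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    n_rep <- config$replicates_per_species[si]
    if (si == 1L) {
      sp_inst <- data.frame(instance_id = inst$instance_id, chrom = "chr1",
                            start = inst$start, end = inst$end,
                            strand = inst$strand, family = inst$family,
                            te_class = inst$te_class, perc_div = inst$perc_div,
                            expressed = inst$expr_q, stringsAsFactors = FALSE)
      sp_frags <- frags
      sp_tx_keep <- rep(TRUE, nrow(tx))
      sp_tx_expr <- rep(TRUE, nrow(tx))
      sp_spans <- spans
      sp_exons <- exons
      sp_coding <- coding
    } else {
      pt <- per_target[[sp]]
      ridx <- which(pt$retained)
      sp_inst <- data.frame(instance_id = sprintf("t%d", seq_along(ridx)),
                            chrom = rep("chr1", length(ridx)),
                            start = pt$t_start[ridx],
                            end = pt$t_end[ridx], strand = inst$strand[ridx],
                            family = inst$family[ridx],
                            te_class = inst$te_class[ridx],
                            perc_div = round(pmin(pmax(
                              inst$perc_div[ridx] + stats::rnorm(length(ridx), 0, 0.5),
                              0.1), 95), 1),
                            expressed = pt$expr_t[ridx], stringsAsFactors = FALSE)
      ord <- order(sp_inst$start)
      sp_inst <- sp_inst[ord, , drop = FALSE]
      sp_inst$instance_id <- sprintf("chr1_%d", seq_len(nrow(sp_inst)))
      sp_frags <- data.frame(chrom = rep("chr1", nrow(sp_inst)),
                             start = sp_inst$start,
                             end = sp_inst$end, strand = sp_inst$strand,
                             family = sp_inst$family,
                             class_family = sprintf("%s/%s", sp_inst$te_class, sp_inst$family),
                             perc_div = sp_inst$perc_div,
                             rm_id = seq_len(nrow(sp_inst)))
      sp_frags$sw_score <- as.integer(round((sp_frags$end - sp_frags$start) * 10 *
                                              (1 - sp_frags$perc_div / 100)))
      sp_tx_keep <- tx_lift[, sp] & (tx_expr[, sp] | tx$type == "coding")
      sp_tx_expr <- tx_expr[, sp]
      if (nrow(tx)) {
        m <- pt$map$span(spans$start, spans$end)
        sp_spans <- data.table::data.table(transcript_id = tx$transcript_id,
                                           start = as.integer(m[, 1L]),
                                           end = as.integer(m[, 2L]))
        em <- pt$map$span(exons$start, exons$end)
        sp_exons <- data.frame(transcript_id = exons$transcript_id, chrom = "chr1",
                               start = as.integer(em[, 1L]),
                               end = as.integer(em[, 2L]), strand = "+",
                               stringsAsFactors = FALSE)
      } else {
        sp_spans <- spans; sp_exons <- exons
      }
      sp_coding <- if (nrow(coding)) {
        m <- pt$map$span(coding$start, coding$end)
        data.frame(chrom = "chr1", start = as.integer(m[, 1L]),
                   end = as.integer(m[, 2L]))
      } else coding
    }
    feat <- rbind(
      data.frame(start = sp_inst$start, end = sp_inst$end,
                 expressed = sp_inst$expressed),
      if (nrow(tx)) data.frame(start = sp_spans$start, end = sp_spans$end,
                               expressed = sp_tx_expr | (si == 1L))[sp_tx_keep, ] else NULL
    )
    reads <- lapply(seq_len(n_rep), function(r) {
      draw_reads(feat, config$n_reads_per_replicate,
                 config$target_rpkm, config$background_rpkm)
    })
    keep_ids <- tx$transcript_id[sp_tx_keep]
    sp_ts <- transcript_set(
      data.frame(transcript_id = tx$transcript_id, chrom = tx$chrom,
                 strand = tx$strand, biotype = tx$biotype,
                 coding_potential = tx$coding_potential,
                 stringsAsFactors = FALSE)[sp_tx_keep, , drop = FALSE],
      sp_exons[sp_exons$transcript_id %in% keep_ids, , drop = FALSE],
      if (si == 1L && length(sequences)) sequences else NULL
    )
    datasets[[sp]] <- list(instances = sp_inst, fragments = sp_frags,
                           reads = reads,
                           library_sizes = vapply(reads, nrow, integer(1)),
                           transcripts = sp_ts, coding = sp_coding)
  }

  ground_truth <- list(
    query = query, species = species,
    instances = as.data.frame(inst[, .(instance_id, family, te_class, start, end,
                                       len, perc_div, expr_q)]),
    retention = vapply(targets, function(tg) per_target[[tg]]$retained,
                       logical(n_te)),
    expr_target = vapply(targets, function(tg) per_target[[tg]]$expr_t,
                         logical(n_te)),
    target_coords = lapply(per_target, function(pt) {
      data.frame(instance_id = inst$instance_id, t_start = pt$t_start,
                 t_end = pt$t_end, stringsAsFactors = FALSE)
    }),
    transcripts = if (nrow(tx)) data.frame(
      transcript_id = tx$transcript_id, type = tx$type,
      host_instance_id = ifelse(is.na(tx$host), NA_character_,
                                inst$instance_id[ifelse(is.na(tx$host), 1L, tx$host)]),
      host_family = ifelse(is.na(tx$host), NA_character_,
                           inst$family[ifelse(is.na(tx$host), 1L, tx$host)]),
      tier = tier, stringsAsFactors = FALSE) else NULL,
    tx_lift = tx_lift, tx_expr = tx_expr
  )

  out <- list(config = config, query = query, targets = targets,
              species_data = datasets,
              chains = lapply(per_target, function(pt) list(pt$chain)),
              sequences = sequences, ground_truth = ground_truth)
  class(out) <- "te_sim"
  if (!is.null(dir)) out$files <- write_sim_files(out, dir)
  out
}

write_sim_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$config
  files <- list()
  for (sp in cfg$species) {
    d <- sim$species_data[[sp]]
    p <- file.path(dir, sprintf("repeats_%s.out", sp))
    write_repeatmasker_out(d$fragments, cfg$genome_length, p)
    files[[sprintf("repeats_%s", sp)]] <- p
    for (r in seq_along(d$reads)) {
      p <- file.path(dir, sprintf("reads_%s_rep%d.bed", sp, r))
      write_reads_bed(d$reads[[r]], p)
      files[[sprintf("reads_%s_rep%d", sp, r)]] <- p
    }
    p <- file.path(dir, sprintf("transcripts_%s.gtf", sp))
    write_transcripts_gtf(d$transcripts, p)
    files[[sprintf("transcripts_%s", sp)]] <- p
    p <- file.path(dir, sprintf("coding_%s.bed", sp))
    write_bed3(d$coding, p)
    files[[sprintf("coding_%s", sp)]] <- p
  }
  for (tg in sim$targets) {
    p <- file.path(dir, sprintf("chain_%s_to_%s.chain", sim$query, tg))
    write_chain(sim$chains[[tg]], p)
    files[[sprintf("chain_%s", tg)]] <- p
  }
  if (length(sim$sequences)) {
    p <- file.path(dir, sprintf("sequences_%s.fasta", sim$query))
    writeLines(paste0(">", names(sim$sequences), "\n", sim$sequences), p)
    files[["sequences"]] <- p
  }
  gt <- sim$ground_truth
  gt$retention <- as.data.frame(gt$retention)
  gt$expr_target <- as.data.frame(gt$expr_target)
  gt$tx_lift <- as.data.frame(gt$tx_lift)
  gt$tx_expr <- as.data.frame(gt$tx_expr)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, p, auto_unbox = TRUE, digits = NA, na = "null")
  files[["ground_truth"]] <- p
  p <- file.path(dir, "config.yaml")
  cfg_plain <- cfg
  cfg_plain$families <- lapply(cfg$families, unclass)
  yaml::write_yaml(unclass(cfg_plain), p)
  files[["config"]] <- p
  files
}

#' Draw per-replicate count tables for a species' TE instances
#'
#' Alternative to read placement: Poisson counts at the planted RPKM for
#' expressed features and the background RPKM otherwise, with an
#' optional negative-binomial dispersion. Library size per replicate is
#' the reference library size topped up by any excess planted mass,
#' mirroring the read-based path where filler reads bring the library to
#' at least the reference size.
#'
#' @param instances data.frame with `instance_id`, `start`, `end`.
#' @param expressed Logical vector of planted expression flags.
#' @param config A [sim_config()] (uses `target_rpkm`, `background_rpkm`,
#'   `n_reads_per_replicate`).
#' @param n_replicates Number of replicates to draw.
#' @param dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) keeps pure Poisson noise.
#' @return List with `counts` (matrix), `library_sizes`, `length_bp`.
#' @export
simulate_expression_counts <- function(instances, expressed, config,
                                       n_replicates = 1L, dispersion = NULL) {
  len <- instances$end - instances$start
  lam <- expected_read_count(
    ifelse(expressed, config$target_rpkm, config$background_rpkm),
    len, config$n_reads_per_replicate)
  counts <- vapply(seq_len(n_replicates), function(r) {
    if (is.null(dispersion)) stats::rpois(length(lam), lam)
    else stats::rnbinom(length(lam), size = dispersion, mu = lam)
  }, integer(length(lam)))
  counts <- matrix(counts, nrow = length(lam))
  libs <- pmax(as.integer(config$n_reads_per_replicate), colSums(counts))
  list(counts = counts, library_sizes = libs, length_bp = len)
}

#' Conservation/expression records for a simulated species pair
#'
#' Measurement path used for statistical checks on simulated data:
#' draws per-replicate count tables for the query and target species
#' ([simulate_expression_counts()]), thresholds them with the TE
#' expression rule, lifts query instances through the simulated chain
#' and classifies conservation, and joins the measured target-ortholog
#' expression flags. The result feeds [family_summaries()] /
#' [family_enrichment_table()] directly.
#'
#' @param sim A `te_sim` from [simulate_dataset()].
#' @param target Target species name.
#' @param counts_config Config whose `target_rpkm`, `background_rpkm`
#'   and `n_reads_per_replicate` calibrate the drawn counts (defaults to
#'   the simulation's own config).
#' @param min_match Minimum remap ratio for the lift.
#' @return Per-instance records data.frame (see
#'   [classify_conservation()]) with `expressed_query` and
#'   `expressed_in_target` added.
#' @export
sim_te_records <- function(sim, target, counts_config = sim$config,
                           min_match = 0.1) {
  q <- sim$species_data[[sim$query]]$instances
  t <- sim$species_data[[target]]$instances
  qi <- match(sim$query, sim$config$species)
  ti <- match(target, sim$config$species)
  qc <- simulate_expression_counts(q, q$expressed, counts_config,
                                   sim$config$replicates_per_species[qi])
  tc <- simulate_expression_counts(t, t$expressed, counts_config,
                                   sim$config$replicates_per_species[ti])
  qe <- expression_table(q$instance_id, qc$length_bp, qc$counts,
                         qc$library_sizes, mode = "te")
  te <- expression_table(t$instance_id, tc$length_bp, tc$counts,
                         tc$library_sizes, mode = "te")
  rec <- classify_conservation(q, sim$chains[[target]], t, min_match,
                               target_species = target)
  rec$expressed_query <- qe$expressed[match(rec$instance_id, qe$feature_id)]
  tex <- te$expressed[match(rec$target_instance_id, te$feature_id)]
  rec$expressed_in_target <- !is.na(tex) & tex
  rec
}

#' Read a simulation configuration from YAML
#'
#' Inverse of the `config.yaml` echo written by [simulate_dataset()]:
#' rebuilds a validated [sim_config()] (family specs included) from a
#' YAML file.
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$families <- lapply(y$families, function(fm) {
    family_spec(fm$name, fm$te_class, fm$n_instances, fm$mean_perc_div,
                fm$loss_prob_per_branch, fm$expr_prob_query,
                fm$expr_correlation, unlist(fm$length_range))
  })
  do.call(sim_config, y[intersect(names(y), names(formals(sim_config)))])
}
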