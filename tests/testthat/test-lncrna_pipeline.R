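test_that("the filter cascade removes biotypes, mono-exonics and coding potential in order", {
  ts <- ten_transcript_fixture()
  suppressMessages(cat <- build_lncrna_catalog(ts, coding_cutoff = 0.5))
  expect_setequal(cat$transcripts$transcript_id, c("lnc1", "lnc2", "lnc3", "lnc4"))
  log <- attr(cat, "filter_log")
  expect_equal(log$removed, c(3L, 2L, 1L))
  expect_equal(log$remaining, c(7L, 5L, 4L))
  # removal counts sum to input minus output
  expect_equal(sum(log$removed), nrow(ts$transcripts) - nrow(cat$transcripts))
  # a mono-exonic transcript is removed even with zero coding potential
  expect_false("mono1" %in% cat$transcripts$transcript_id)
  # catalog size is non-increasing across steps
  expect_true(all(diff(c(nrow(ts$transcripts), log$remaining)) <= 0))
})

test_that("unscored transcripts cannot be cleared and are removed with a warning", {
  ts <- ten_transcript_fixture()
  ts$transcripts$coding_potential[ts$transcripts$transcript_id == "lnc4"] <- NA
  suppressMessages(expect_warning(
    cat <- build_lncrna_catalog(ts, coding_cutoff = 0.5), "neither"))
  expect_false("lnc4" %in% cat$transcripts$transcript_id)
  # ... unless a sequence is attached, in which case the ORF score is used
  ts$sequences <- c(lnc4 = paste(rep("ACCCGA", 100), collapse = ""))  # no ATG
  suppressMessages(cat2 <- build_lncrna_catalog(ts, coding_cutoff = 0.5))
  expect_true("lnc4" %in% cat2$transcripts$transcript_id)
})

test_that("ORF coding score is the longest start-to-stop frame fraction", {
  expect_equal(orf_coding_score("CCCAAACCCAAA"), 0)     # no ATG
  expect_equal(orf_coding_score("ATGAAATAA"), 1.0)      # full-length ORF
  expect_equal(orf_coding_score("ATGAAACCC"), 0)        # start but no stop
  expect_equal(orf_coding_score("ccATGAAATAGcc"), 9 / 13)  # offset frame, lowercase
  expect_error(orf_coding_score(""), class = "teconsex_validation_error")
  withr::with_seed(17, {
    for (i in 1:25) {
      s <- random_dna(sample(60:300, 1))
      expect_equal(orf_coding_score(s), oracle_orf_score(s))
    }
  })
})

test_that("GTF round-trip preserves exons, biotype and coding potential", {
  ts <- ten_transcript_fixture()
  p <- tempfile(fileext = ".gtf")
  write_transcripts_gtf(ts, p)
  back <- read_transcripts_gtf(p)
  m <- match(ts$transcripts$transcript_id, back$transcripts$transcript_id)
  expect_equal(back$transcripts$biotype[m], ts$transcripts$biotype)
  expect_equal(back$transcripts$coding_potential[m], ts$transcripts$coding_potential,
               tolerance = 1e-4)
  b_ex <- back$exons[order(back$exons$transcript_id, back$exons$start), ]
  t_ex <- ts$exons[order(ts$exons$transcript_id, ts$exons$start), ]
  expect_equal(b_ex$start, t_ex$start)
  expect_equal(b_ex$end, t_ex$end)
})

test_that("reference overlap is the same-strand exonic hit fraction", {
  ts <- ten_transcript_fixture()
  suppressMessages(cat <- build_lncrna_catalog(ts, coding_cutoff = 0.5))
  expect_equal(reference_overlap(cat, ts), 1.0)  # catalog is a subset
  shifted <- ts
  shifted$exons$start <- shifted$exons$start + 5e6
  shifted$exons$end <- shifted$exons$end + 5e6
  expect_equal(reference_overlap(cat, shifted), 0.0)
  # opposite strand does not count
  flipped <- ts
  flipped$exons$strand <- "-"
  expect_equal(reference_overlap(cat, flipped), 0.0)
  empty <- subset_transcripts <- transcript_set(ts$transcripts[0, ], ts$exons[0, ])
  expect_error(reference_overlap(empty, ts), class = "teconsex_undefined_error")
  # planted: 9 of 10 transcripts moved away
  part <- ts
  keep9 <- ts$transcripts$transcript_id[1:9]
  part$exons$start <- ifelse(part$exons$transcript_id %in% keep9,
                             part$exons$start, part$exons$start + 5e6)
  part$exons$end <- part$exons$start + 300L
  full <- transcript_set(ts$transcripts, ts$exons)
  expect_equal(reference_overlap(full, part), 0.9)
})

te_fixture <- function(rows) {
  data.frame(instance_id = paste0("te", seq_len(nrow(rows))),
             chrom = "chr1", start = rows$start, end = rows$end, strand = "+",
             family = rows$family, te_class = rows$te_class,
             scaled_score = 500L, length_bp = rows$end - rows$start,
             n_fragments = 1L, stringsAsFactors = FALSE)
}

test_that("TE annotation applies the 10%-of-exon rule inclusively", {
  ts <- transcript_set(
    data.frame(transcript_id = "t1", chrom = "chr1", strand = "+",
               biotype = NA, coding_potential = 0.1),
    data.frame(transcript_id = "t1", chrom = "chr1", start = 0L, end = 100L,
               strand = "+"))
  te10 <- te_fixture(data.frame(start = 90L, end = 200L, family = "A", te_class = "LTR"))
  te9 <- te_fixture(data.frame(start = 91L, end = 200L, family = "A", te_class = "LTR"))
  expect_true(annotate_te_overlap(ts, te10)$transcripts$has_te)   # exactly 10 bp
  expect_false(annotate_te_overlap(ts, te9)$transcripts$has_te)   # 9 bp < 10%
})

test_that("the dominant TE maximises total overlap with documented tie-breaks", {
  ts <- transcript_set(
    data.frame(transcript_id = "t1", chrom = "chr1", strand = "+",
               biotype = NA, coding_potential = 0.1),
    data.frame(transcript_id = rep("t1", 2), chrom = "chr1",
               start = c(0L, 1000L), end = c(400L, 1400L), strand = "+"))
  te <- te_fixture(data.frame(start = c(0L, 1000L), end = c(120L, 1080L),
                              family = c("A", "B"), te_class = "LTR"))
  a <- annotate_te_overlap(ts, te)
  expect_equal(a$transcripts$dominant_family, "A")  # 120 bp beats 80 bp
  # equal totals: the larger single-exon overlap wins
  te2 <- te_fixture(data.frame(start = c(0L, 1000L, 1200L),
                               end = c(100L, 1060L, 1260L),
                               family = c("A", "B", "B"), te_class = "LTR"))
  a2 <- annotate_te_overlap(ts, te2)
  expect_equal(a2$transcripts$dominant_family, "A")  # 100 vs max-single 60
  # full tie: lexicographically smaller family name
  te3 <- te_fixture(data.frame(start = c(0L, 1000L), end = c(100L, 1100L),
                               family = c("B", "A"), te_class = "LTR"))
  a3 <- annotate_te_overlap(ts, te3)
  expect_equal(a3$transcripts$dominant_family, "A")
})

test_that("a zero exon-fraction threshold reduces to plain intersection", {
  withr::with_seed(23, {
    n_tx <- 15L
    base <- seq(0, by = 5000, length.out = n_tx)
    ts <- transcript_set(
      data.frame(transcript_id = paste0("t", 1:n_tx), chrom = "chr1",
                 strand = "+", biotype = NA, coding_potential = 0.1),
      data.frame(transcript_id = rep(paste0("t", 1:n_tx), each = 2),
                 chrom = "chr1",
                 start = rep(base, each = 2) + c(0L, 1000L),
                 end = rep(base, each = 2) + c(300L, 1600L), strand = "+"))
    s <- sort(sample(0:70000, 40))
    te <- te_fixture(data.frame(start = s, end = s + sample(20:500, 40, TRUE),
                                family = sample(LETTERS[1:5], 40, TRUE),
                                te_class = "LINE"))
    a <- annotate_te_overlap(ts, te, min_exon_fraction = 0)
    # brute force: all exon x TE pairs with >= 1bp overlap
    brute <- 0L
    for (i in seq_len(nrow(ts$exons))) for (j in seq_len(nrow(te))) {
      ov <- min(ts$exons$end[i], te$end[j]) - max(ts$exons$start[i], te$start[j])
      if (ov >= 1) brute <- brute + 1L
    }
    expect_equal(nrow(a$overlaps), brute)
  })
})

test_that("contribution statistics normalise by exon bp and genomic bp", {
  ts <- transcript_set(
    data.frame(transcript_id = "t1", chrom = "chr1", strand = "+",
               biotype = NA, coding_potential = 0.1),
    data.frame(transcript_id = rep("t1", 2), chrom = "chr1",
               start = c(0L, 2000L), end = c(500L, 2500L), strand = "+"))
  # one LTR overlapping 400 bp of the 1000 exon bp
  te <- te_fixture(data.frame(start = 100L, end = 500L, family = "HERVX",
                              te_class = "LTR"))
  a <- annotate_te_overlap(ts, te)
  cs <- contribution_stats(a, ts, te, genome_length = 40000)
  expect_equal(cs$class_stats$lncrna_proportion[cs$class_stats$te_class == "LTR"], 0.4)
  # genomic proportion 400/40000 = 1%, lncRNA proportion 40% -> normalised 40
  expect_equal(cs$family_stats$normalized_contribution[1], 0.4 / 0.01)
  expect_error(contribution_stats(annotate_te_overlap(ts, te_fixture(
    data.frame(start = 30000L, end = 30100L, family = "X", te_class = "DNA"))),
    ts, te, 40000), class = "teconsex_undefined_error")
})

test_that("overlapping TE annotations never double-count a base by default", {
  ts <- transcript_set(
    data.frame(transcript_id = "t1", chrom = "chr1", strand = "+",
               biotype = NA, coding_potential = 0.1),
    data.frame(transcript_id = "t1", chrom = "chr1", start = c(0L, 2000L),
               end = c(1000L, 2100L), strand = "+"))
  # two instances overlapping each other inside the exon
  te <- te_fixture(data.frame(start = c(0L, 300L), end = c(600L, 900L),
                              family = c("A", "B"), te_class = c("LTR", "LTR")))
  a <- annotate_te_overlap(ts, te)
  dedup <- contribution_stats(a, ts, te, 10000)
  raw <- contribution_stats(a, ts, te, 10000, allow_double_count = TRUE)
  expect_equal(dedup$class_stats$lncrna_bp, 900)        # union of [0,600)+[300,900)
  expect_equal(raw$class_stats$lncrna_bp, 1200)         # -wao style sum
  expect_lte(sum(dedup$class_stats$lncrna_proportion), 1)
})

test_that("lncRNA conservation lifts spans, re-annotates TEs and tiers transcripts", {
  cfg <- small_sim_config(seed = 41, species = c("human", "chimp", "gorilla"),
                          replicates = c(2L, 1L, 1L), lncrna_count = 40L)
  sim <- simulate_dataset(cfg)
  suppressMessages(cat <- build_lncrna_catalog(sim$species_data$human$transcripts))
  targets <- lapply(stats::setNames(sim$targets, sim$targets), function(tg) {
    list(chains = sim$chains[[tg]],
         te_instances = sim$species_data[[tg]]$instances,
         reads = sim$species_data[[tg]]$reads)
  })
  res <- lncrna_conservation(cat, targets)
  expect_equal(nrow(res$table), 2L)
  expect_true(all(res$table$n_lifted <= res$table$n_catalog))
  expect_true(all(res$table$n_lifted_expressed_te <=
                    pmin(res$table$n_lifted_te, res$table$n_lifted_expressed)))
  # percentages are relative to the lifted count
  expect_equal(res$table$pct_lifted_te,
               round(100 * res$table$n_lifted_te / res$table$n_lifted, 2))
  # tier partition: every transcript gets exactly one tier
  expect_equal(nrow(res$tiers), nrow(cat$transcripts))
  expect_equal(sum(table(res$tiers$tier)), nrow(cat$transcripts))
  expect_true(all(res$tiers$tier %in% c("all_species", "some_nhp", "query_only")))
})

test_that("report rows reproduce percentages from raw counts", {
  r <- conservation_report_row(7479, 5175, 2981, 2103)
  expect_equal(r$pct_lifted_te, 69.19)
  expect_equal(r$pct_lifted_expressed, 39.86)
  expect_equal(r$pct_lifted_expressed_te, 28.12)
  expect_equal(conservation_report_row(100, 70, 40, 30)$pct_lifted_te, 70.00)
})
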