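test_that("invalid configurations raise errors naming the offending field", {
  expect_error(sim_config(species = "human"), "species",
               class = "teconsex_config_error")
  expect_error(sim_config(genome_length = -1), "genome_length",
               class = "teconsex_config_error")
  expect_error(sim_config(replicates_per_species = c(1L, 1L)),
               "replicates_per_species", class = "teconsex_config_error")
  expect_error(family_spec("f", "LTR", 10, 10, 1.5, 0.5, 0.5),
               "loss_prob_per_branch", class = "teconsex_config_error")
  expect_error(family_spec("f", "BAD", 10, 10, 0.5, 0.5, 0.5),
               "te_class", class = "teconsex_config_error")
  # layout that cannot fit the genome
  expect_error(simulate_dataset(small_sim_config() |>
    (\(cfg) { cfg$genome_length <- 1e4; cfg })()),
    "genome_length", class = "teconsex_config_error")
})

test_that("zero loss retains every instance and total loss retains none", {
  cfg0 <- small_sim_config(seed = 3, families = list(
    family_spec("F", "DNA", 50, 10, 0, 0.5, 0.5)),
    lncrna_count = 0L, coding_gene_count = 0L)
  sim0 <- simulate_dataset(cfg0)
  lift0 <- lift_intervals(sim0$species_data$human$instances, sim0$chains$chimp)
  expect_true(all(lift0$status == "mapped"))

  cfg1 <- small_sim_config(seed = 3, families = list(
    family_spec("F", "DNA", 50, 10, 1, 0.5, 0.5)),
    lncrna_count = 0L, coding_gene_count = 0L)
  sim1 <- simulate_dataset(cfg1)
  lift1 <- lift_intervals(sim1$species_data$human$instances, sim1$chains$chimp)
  expect_true(all(lift1$status != "mapped"))
  expect_equal(nrow(sim1$species_data$chimp$instances), 0L)
})

test_that("planted expression correlation is recovered from the ground truth", {
  cfg <- sim_config(seed = 19, species = c("q", "t1", "t2", "t3"),
                    genome_length = 2e6,
                    families = list(family_spec("F", "LTR", 400, 10, 0.05, 0.5, 0.5)),
                    replicates_per_species = c(2L, 1L, 1L, 1L),
                    n_reads_per_replicate = 5e4,
                    lncrna_count = 0L, coding_gene_count = 0L)
  sim <- simulate_dataset(cfg)
  gt <- sim$ground_truth
  for (tg in c("t1", "t2", "t3")) {
    sel <- gt$retention[, tg] & gt$instances$expr_q
    prop <- mean(gt$expr_target[sel, tg])
    se <- sqrt(0.5 * 0.5 / sum(sel))
    expect_lt(abs(prop - 0.5), 3 * se)
  }
})

test_that("count draws invert the RPKM formula and recover planted expression", {
  expect_equal(expected_read_count(10, 1000, 1e6), 10)
  expect_equal(expected_read_count(0, 1000, 1e6), 0)
  cfg <- small_sim_config(seed = 29, families = list(
    family_spec("F", "DNA", 200, 10, 0, 1, 0.5)),
    lncrna_count = 0L, coding_gene_count = 0L)
  sim <- simulate_dataset(cfg)
  q <- sim$species_data$human$instances
  expect_true(all(q$expressed))
  withr::with_seed(30, {
    sc <- simulate_expression_counts(q, q$expressed, cfg, n_replicates = 2L)
    tab <- expression_table(q$instance_id, sc$length_bp, sc$counts,
                            sc$library_sizes, mode = "te")
    # oracle: per-instance Poisson tail for mean RPKM >= 1 over 2 replicates
    lam <- expected_read_count(cfg$target_rpkm, sc$length_bp,
                               cfg$n_reads_per_replicate)
    thr <- 2 * sc$length_bp / 1000 * sc$library_sizes[1] / 1e6  # total count for mean RPKM 1
    p_detect <- stats::ppois(ceiling(thr) - 1, 2 * lam, lower.tail = FALSE)
    expect_gte(mean(tab$expressed), 0.95)
    expect_gte(mean(p_detect), 0.95)  # the planted parameters imply the bound
    expect_lt(abs(mean(tab$expressed) - mean(p_detect)), 0.05)
  })
  # a zero-background non-expressed instance stays at zero RPKM
  cfg0 <- cfg; cfg0$background_rpkm <- 0
  sc0 <- simulate_expression_counts(q[1, ], FALSE, cfg0, n_replicates = 1L)
  expect_equal(sc0$counts[1, 1], 0L)
})

test_that("lifted fractions decrease with planted loss probability", {
  cfg <- small_sim_config(seed = 37, families = list(
    family_spec("low",  "DNA", 220, 10, 0.05, 0.4, 0.4),
    family_spec("mid",  "DNA", 220, 10, 0.20, 0.4, 0.4),
    family_spec("high", "DNA", 220, 10, 0.50, 0.4, 0.4)),
    lncrna_count = 0L, coding_gene_count = 0L)
  sim <- simulate_dataset(cfg)
  rec <- classify_conservation(sim$species_data$human$instances,
                               sim$chains$chimp,
                               sim$species_data$chimp$instances)
  frac <- tapply(rec$lifted, rec$family, mean)
  expect_gt(frac["low"], frac["mid"])
  expect_gt(frac["mid"], frac["high"])
})

test_that("identical configurations produce byte-identical files", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- small_sim_config(seed = 101, lncrna_count = 20L, coding_gene_count = 5L,
                          n_reads = 2e4)
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1)); h2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(h1), unname(h2))
  # and a different seed changes them
  cfg2 <- cfg; cfg2$seed <- 102L
  d3 <- file.path(tempdir(), "simC"); unlink(d3, recursive = TRUE)
  simulate_dataset(cfg2, dir = d3)
  h3 <- tools::md5sum(file.path(d3, sort(list.files(d3))))
  expect_false(all(unname(h1) == unname(h3)))
})

test_that("emitted files parse with the corresponding readers", {
  d <- file.path(tempdir(), "simParse"); unlink(d, recursive = TRUE)
  cfg <- small_sim_config(seed = 51, lncrna_count = 20L, coding_gene_count = 5L,
                          n_reads = 2e4)
  sim <- simulate_dataset(cfg, dir = d)
  frags <- parse_repeatmasker_out(file.path(d, "repeats_human.out"))
  inst <- join_nested_repeats(frags)
  expect_equal(nrow(inst), nrow(sim$species_data$human$instances))
  expect_equal(sort(inst$start), sort(sim$species_data$human$instances$start))
  chains <- parse_chain(file.path(d, "chain_human_to_chimp.chain"))
  expect_equal(chains[[1]]$blocks, sim$chains$chimp[[1]]$blocks)
  reads <- read_bed(file.path(d, "reads_human_rep1.bed"))
  expect_equal(nrow(reads), sim$species_data$human$library_sizes[1])
  ts <- read_transcripts_gtf(file.path(d, "transcripts_human.gtf"))
  expect_equal(nrow(ts$transcripts),
               nrow(sim$species_data$human$transcripts$transcripts))
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_equal(gt$query, "human")
  # the YAML config echo round-trips into an equivalent configuration
  cfg_back <- read_sim_config(file.path(d, "config.yaml"))
  expect_equal(cfg_back$seed, cfg$seed)
  expect_equal(cfg_back$species, cfg$species)
  expect_equal(vapply(cfg_back$families, `[[`, "", "name"),
               vapply(cfg$families, `[[`, "", "name"))
  expect_equal(cfg_back$target_rpkm, cfg$target_rpkm)
})

test_that("planted expressed instances reach RPKM 1 through the read path", {
  cfg <- small_sim_config(seed = 61, families = list(
    family_spec("F", "LINE", 150, 10, 0.1, 0.5, 0.5)),
    lncrna_count = 0L, coding_gene_count = 0L)
  sim <- simulate_dataset(cfg)
  q <- sim$species_data$human$instances
  reads <- sim$species_data$human$reads
  libs <- sim$species_data$human$library_sizes
  counts <- vapply(reads, function(r) count_overlapping_reads(q, r),
                   integer(nrow(q)))
  tab <- expression_table(q$instance_id, q$end - q$start, counts, libs, "te")
  expect_gte(mean(tab$expressed[q$expressed]), 0.95)
  expect_lte(mean(tab$expressed[!q$expressed]), 0.05)
})
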