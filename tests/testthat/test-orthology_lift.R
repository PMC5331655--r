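test_that("chain files round-trip through write and parse with invariants checked", {
  ch <- make_chain(data.frame(size = c(400L, 300L, 300L),
                              s_gap = c(50L, 20L, 0L), t_gap = c(0L, 35L, 0L)),
                   s_start = 10L, t_start = 5L, id = "42")
  p <- tempfile(fileext = ".chain")
  write_chain(list(ch, identity_chain(1000L)), p)
  back <- parse_chain(p)
  expect_length(back, 2L)
  expect_equal(back[[1]]$blocks, ch$blocks)
  expect_equal(back[[1]]$s_end, 10L + 1000L + 70L)
  expect_equal(back[[1]]$t_end, 5L + 1000L + 35L)
  expect_equal(back[[1]]$id, "42")
  expect_equal(back[[2]]$blocks$size, 1000L)

  # empty file -> empty list
  empty <- tempfile(); writeLines(character(0), empty)
  expect_length(parse_chain(empty), 0L)
})

test_that("block-sum mismatches are parse errors naming the chain id", {
  p <- tempfile()
  writeLines(c("chain 100 chr1 2000 + 0 1000 chrA 2000 + 0 950 7",
               "500 100 50", "300", ""), p)  # source: 500+100+300 = 900 != 1000
  expect_error(parse_chain(p), "chain 7", class = "teconsex_parse_error")
})

test_that("identity chains lift intervals unchanged with ratio 1", {
  ch <- list(identity_chain(10000L))
  r <- lift_interval("chr1", 100L, 200L, ch)
  expect_equal(r$status, "mapped")
  expect_equal(c(r$t_start, r$t_end), c(100L, 200L))
  expect_equal(r$mapped_ratio, 1.0)
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- sample(0:9000, 1); w <- sample(1:999, 1)
      r <- lift_interval("chr1", s, s + w, ch)
      expect_equal(c(r$t_start, r$t_end), c(s, s + w))
      expect_equal(r$mapped_ratio, 1.0)
    }
  })
})

test_that("the minMatch threshold separates mapped from unmapped_below_minMatch", {
  # aligned block covers only [195, 200) of the interval [100, 200)
  ch <- list(make_chain(data.frame(size = 5L, s_gap = 0L, t_gap = 0L),
                        s_start = 195L, t_start = 700L))
  r <- lift_interval("chr1", 100L, 200L, ch, min_match = 0.1)
  expect_equal(r$status, "unmapped_below_minMatch")
  expect_equal(r$mapped_ratio, 0.05)
  # the same interval maps once minMatch drops to its ratio
  r2 <- lift_interval("chr1", 100L, 200L, ch, min_match = 0.05)
  expect_equal(r2$status, "mapped")
  expect_equal(c(r2$t_start, r2$t_end), c(700L, 705L))
  # no chain anywhere near -> unmapped_no_chain
  r3 <- lift_interval("chr1", 5000L, 5100L, ch)
  expect_equal(r3$status, "unmapped_no_chain")
  # zero-length interval is a validation error
  expect_error(lift_interval("chr1", 10L, 10L, ch),
               class = "teconsex_validation_error")
})

test_that("a target-side gap stretches the lifted interval (hand-traced case)", {
  # blocks cover [100,150) then a 30 bp target insertion then [150,200)
  ch <- make_chain(data.frame(size = c(50L, 50L), s_gap = c(0L, 0L),
                              t_gap = c(30L, 0L)),
                   s_start = 100L, t_start = 1000L)
  r <- lift_interval("chr1", 100L, 200L, list(ch))
  expect_equal(r$status, "mapped")
  expect_equal(r$mapped_bases, 100L)
  expect_equal(r$t_end - r$t_start, 130L)
  o <- oracle_lift(100L, 200L, ch)
  expect_equal(r$mapped_bases, o$mapped)
  expect_equal(c(r$t_start, r$t_end), c(o$t_start, o$t_end))
})

test_that("negative-strand chains report forward-strand target coordinates", {
  ch <- make_chain(data.frame(size = c(60L, 40L), s_gap = c(10L, 0L),
                              t_gap = c(5L, 0L)),
                   s_start = 200L, t_start = 50L, t_strand = "-", t_size = 500L)
  r <- lift_interval("chr1", 200L, 310L, list(ch))
  o <- oracle_lift(200L, 310L, ch)
  expect_equal(r$status, "mapped")
  expect_equal(r$t_strand, "-")
  expect_equal(r$mapped_bases, o$mapped)
  expect_equal(c(r$t_start, r$t_end), c(o$t_start, o$t_end))
  expect_true(r$t_start >= 0 && r$t_end <= 500)
})

test_that("lift agrees with the brute-force per-base map on random chains", {
  withr::with_seed(101, {
    for (i in 1:60) {
      ch <- random_chain(max_aligned = 2000)
      lo <- ch$s_start; hi <- ch$s_end
      s <- sample(max(0, lo - 50):(hi + 20), 1)
      w <- sample(1:400, 1)
      r <- lift_interval("chr1", s, s + w, list(ch), min_match = 0)
      o <- oracle_lift(s, s + w, ch)
      expect_equal(r$mapped_bases, o$mapped)
      if (o$mapped > 0) {
        expect_equal(c(r$t_start, r$t_end), c(o$t_start, o$t_end))
      }
    }
  })
})

test_that("decreasing minMatch never unmaps a mapped interval", {
  withr::with_seed(55, {
    chains <- lapply(1:5, function(i) random_chain(2000, id = as.character(i)))
    for (i in 1:40) {
      s <- sample(0:3000, 1); w <- sample(1:500, 1)
      statuses <- vapply(c(0.9, 0.5, 0.1, 0.01), function(mm) {
        lift_interval("chr1", s, s + w, chains, min_match = mm)$status
      }, character(1))
      mapped <- statuses == "mapped"
      # once mapped at a high threshold, mapped at every lower one
      if (any(mapped)) expect_true(all(mapped[which(mapped)[1]:length(mapped)]))
    }
  })
})

test_that("tied chains mapping to different loci are flagged ambiguous", {
  b <- data.frame(size = 100L, s_gap = 0L, t_gap = 0L)
  ch1 <- make_chain(b, s_start = 0L, t_start = 1000L, score = 500, id = "1")
  ch2 <- make_chain(b, s_start = 0L, t_start = 5000L, score = 500, id = "2")
  r <- lift_interval("chr1", 0L, 100L, list(ch1, ch2))
  expect_equal(r$status, "ambiguous")
  # a higher score breaks the tie
  ch2$score <- 900
  r2 <- lift_interval("chr1", 0L, 100L, list(ch1, ch2))
  expect_equal(r2$status, "mapped")
  expect_equal(r2$t_start, 5000L)
  # same target locus is not ambiguous
  ch3 <- make_chain(b, s_start = 0L, t_start = 1000L, score = 500, id = "3")
  r3 <- lift_interval("chr1", 0L, 100L, list(ch1, ch3))
  expect_equal(r3$status, "mapped")
})

test_that("planted retention drives conservation classification", {
  cfg <- small_sim_config(seed = 21, families = list(
    family_spec("FamA", "LTR", 400, 15, 0.1, 0.4, 0.5)),
    lncrna_count = 0L, coding_gene_count = 0L)
  sim <- simulate_dataset(cfg)
  q <- sim$species_data$human$instances
  t <- sim$species_data$chimp$instances
  rec <- classify_conservation(q, sim$chains$chimp, t, target_species = "chimp")
  retained <- sim$ground_truth$retention[, "chimp"]
  # planted truth: retained instances lift and are TE-annotated, lost do not lift
  expect_equal(rec$lifted, unname(retained))
  expect_true(all(rec$te_annotated_in_target[rec$lifted]))
  expect_true(all(rec$same_family_in_target[rec$lifted]))
  # conservation-flag implications
  expect_true(all(rec$lifted[rec$te_annotated_in_target]))
  expect_true(all(rec$te_annotated_in_target[rec$same_family_in_target]))
  # lifted fraction within 3 binomial SE of 1 - loss
  p <- 0.9; se <- sqrt(p * (1 - p) / nrow(q))
  expect_lt(abs(mean(rec$lifted) - p), 3 * se)
  # no family mislabeling planted -> concordance exactly 1
  expect_equal(reannotation_concordance(rec), 1.0)
})

test_that("reannotation concordance counts same-family fractions", {
  rec <- data.frame(lifted = c(rep(TRUE, 10), FALSE),
                    same_family_in_target = c(rep(TRUE, 9), FALSE, FALSE))
  expect_equal(reannotation_concordance(rec), 0.9)
  expect_equal(reannotation_concordance(rec[rec$same_family_in_target, ]), 1.0)
  none <- rec[rec$lifted == FALSE, ]
  expect_error(reannotation_concordance(none), class = "teconsex_undefined_error")
})
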