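# Fixtures and independent oracles used across test files.

# A 10-fragment RepeatMasker .out fixture with 8 distinct IDs (IDs 3 and
# 7 each split into two fragments).  Values chosen for hand computation.
rm_fixture_lines <- function() {
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat  class/family  begin end (left)  ID",
    "")
  body <- c(
    "500 10.0 0.5 0.3 chr1 101 200 (9800) + AluYa5 SINE/Alu 1 100 (0) 1",
    "400 12.5 0.5 0.3 chr1 301 400 (9600) C L1PA3 LINE/L1 1 100 (0) 2",
    "450  8.0 0.5 0.3 chr1 501 600 (9400) + HERVH LTR/ERV1 1 100 (0) 3",
    "300  8.0 0.5 0.3 chr1 701 760 (9240) + HERVH LTR/ERV1 101 160 (0) 3",
    "350 20.0 0.5 0.3 chr2 101 220 (9780) + MER53 DNA/hAT 1 120 (0) 4",
    "600  5.0 0.5 0.3 chr2 401 500 (9500) C AluYa5 SINE/Alu 1 100 (0) 5",
    "250 30.0 0.5 0.3 chr2 801 900 (9100) + L2 LINE/L2 1 100 (0) 6",
    "200 18.0 0.5 0.3 chr3 101 300 (9700) + Tigger1 DNA/TcMar 1 200 (0) 7",
    "150 18.0 0.5 0.3 chr3 401 500 (9500) + Tigger1 DNA/TcMar 201 300 (0) 7",
    "100 40.0 0.5 0.3 chr3 701 800 (9200) + MIR SINE/MIR 1 100 (0) 8")
  c(hdr, body)
}

write_rm_fixture <- function(path = tempfile(fileext = ".out")) {
  writeLines(rm_fixture_lines(), path)
  path
}

# Construct a chain object directly from a block table; header spans are
# derived so the parse-time invariants hold by construction.
make_chain <- function(blocks, s_start = 0, t_start = 0, s_chrom = "chr1",
                       t_chrom = "chrA", t_strand = "+", s_size = NULL,
                       t_size = NULL, score = 1000, id = "1") {
  s_end <- s_start + sum(blocks$size) + sum(blocks$s_gap)
  t_end <- t_start + sum(blocks$size) + sum(blocks$t_gap)
  if (is.null(s_size)) s_size <- s_end + 100L
  if (is.null(t_size)) t_size <- t_end + 100L
  structure(list(score = score, s_chrom = s_chrom, s_size = as.integer(s_size),
                 s_strand = "+", s_start = as.integer(s_start),
                 s_end = as.integer(s_end), t_chrom = t_chrom,
                 t_size = as.integer(t_size), t_strand = t_strand,
                 t_start = as.integer(t_start), t_end = as.integer(t_end),
                 id = id, blocks = blocks), class = "te_chain")
}

identity_chain <- function(len = 1000L, chrom = "chr1") {
  make_chain(data.frame(size = len, s_gap = 0L, t_gap = 0L),
             s_chrom = chrom, t_chrom = chrom, s_size = len, t_size = len)
}

# Brute-force per-base coordinate map for a chain: one row per aligned
# base, with target positions already on the forward strand.
chain_base_map <- function(ch) {
  b <- ch$blocks
  sp <- integer(0); tp <- integer(0)
  s <- ch$s_start; t <- ch$t_start
  for (k in seq_len(nrow(b))) {
    sp <- c(sp, s + seq_len(b$size[k]) - 1L)
    tp <- c(tp, t + seq_len(b$size[k]) - 1L)
    s <- s + b$size[k] + b$s_gap[k]
    t <- t + b$size[k] + b$t_gap[k]
  }
  if (ch$t_strand == "-") tp <- ch$t_size - tp - 1L
  data.frame(sp = sp, tp = tp)
}

oracle_lift <- function(start, end, ch) {
  m <- chain_base_map(ch)
  hit <- m$sp >= start & m$sp < end
  if (!any(hit)) return(list(mapped = 0L, t_start = NA, t_end = NA))
  list(mapped = sum(hit), t_start = min(m$tp[hit]), t_end = max(m$tp[hit]) + 1L)
}

random_chain <- function(max_aligned = 1e4, id = "1") {
  k <- sample(1:15, 1)
  size <- sample(1:600, k, replace = TRUE)
  while (sum(size) > max_aligned) size <- pmax(1L, size %/% 2L)
  s_gap <- if (k > 1) c(sample(0:200, k - 1, TRUE), 0L) else 0L
  t_gap <- if (k > 1) c(sample(0:200, k - 1, TRUE), 0L) else 0L
  make_chain(data.frame(size = as.integer(size), s_gap = as.integer(s_gap),
                        t_gap = as.integer(t_gap)),
             s_start = sample(0:500, 1), t_start = sample(0:500, 1),
             t_strand = sample(c("+", "-"), 1), score = sample(1:1e6, 1),
             id = id)
}

# Exact rational-arithmetic hypergeometric tail oracle (python fractions).
py_hypergeom_sf <- function(params) {
  tf <- tempfile(); sf <- tempfile(fileext = ".py")
  utils::write.table(params, tf, row.names = FALSE, col.names = FALSE)
  writeLines(c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in open(sys.argv[1]):",
    "    N, K, n, j = map(int, line.split())",
    "    tot = comb(N, n)",
    "    s = sum(comb(K, k) * comb(N - K, n - k) for k in range(j, min(K, n) + 1))",
    "    print(repr(float(Fraction(s, tot))))"), sf)
  as.numeric(system2("python", c(sf, tf), stdout = TRUE))
}

# Independent all-substrings ORF scan (O(n^2)); oracle for orf_coding_score.
oracle_orf_score <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  for (i in seq_len(max(0, n - 2))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(s, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2L - i + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best / n
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Small fast simulation config shared by several tests.  The planted
# RPKM scales inversely with the library size so the Poisson rate of the
# shortest instances stays >= 3 per replicate (reliable detection), as
# in the default configuration.
small_sim_config <- function(seed = 11, species = c("human", "chimp"),
                             replicates = c(2L, 1L), families = NULL,
                             lncrna_count = 30L, coding_gene_count = 10L,
                             n_reads = 1e5) {
  if (is.null(families)) {
    families <- list(
      family_spec("FamA", "LTR", 80, 15, 0.1, 0.4, 0.8),
      family_spec("FamB", "LINE", 80, 25, 0.05, 0.4, 0.4),
      family_spec("FamC", "SINE", 80, 5, 0.4, 0.4, 0.05))
  }
  sim_config(seed = seed, species = species, genome_length = 2e6,
             families = families, n_reads_per_replicate = n_reads,
             replicates_per_species = replicates, lncrna_count = lncrna_count,
             coding_gene_count = coding_gene_count,
             target_rpkm = 15e6 / n_reads)
}

# 10-transcript fixture: 3 coding-biotype, 2 mono-exonic, 1 with high
# coding potential, 4 genuine lncRNA candidates.
ten_transcript_fixture <- function() {
  mk_tx <- function(id, biotype, cp) {
    data.frame(transcript_id = id, chrom = "chr1", strand = "+",
               biotype = biotype, coding_potential = cp,
               stringsAsFactors = FALSE)
  }
  mk_ex <- function(id, starts, ends) {
    data.frame(transcript_id = id, chrom = "chr1", start = starts, end = ends,
               strand = "+", stringsAsFactors = FALSE)
  }
  tx <- rbind(
    mk_tx("pc1", "protein_coding", 0.9),
    mk_tx("ps1", "processed_pseudogene", 0.1),
    mk_tx("tr1", "tRNA", 0.0),
    mk_tx("mono1", NA, 0.1),
    mk_tx("mono2", NA, 0.2),
    mk_tx("hot1", NA, 0.8),
    mk_tx("lnc1", NA, 0.05),
    mk_tx("lnc2", NA, 0.10),
    mk_tx("lnc3", "lincRNA", 0.20),
    mk_tx("lnc4", NA, 0.30))
  base <- seq(0, by = 10000, length.out = 10)
  ex <- do.call(rbind, lapply(seq_len(10), function(i) {
    id <- tx$transcript_id[i]
    if (id %in% c("mono1", "mono2")) {
      mk_ex(id, base[i] + 100L, base[i] + 600L)
    } else {
      mk_ex(id, base[i] + c(100L, 1000L), base[i] + c(400L, 1500L))
    }
  }))
  transcript_set(tx, ex)
}

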