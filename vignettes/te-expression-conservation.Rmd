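---
title: "Cross-species conservation of TE expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species conservation of TE expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teconsex)
```

## The analysis

Transposable elements (TEs) supply a large fraction of the sequence of
long non-coding RNAs, and a handful of families — HERVH most famously —
produce non-coding transcripts that matter for pluripotency. A natural
way to look for more such families without functional assays is
comparative: a TE instance whose genomic locus is retained in related
species *and* whose transcription is observed in those species too has a
better claim to function than a private, silent insertion.

`teconsex` implements that comparison as a reusable pipeline over
standard file formats. Its stages are:

1. **Repeat catalog.** RepeatMasker-style `.out` tables are parsed;
   fragments sharing a RepeatMasker ID on one chromosome are joined into
   single insertions (a young element frequently interrupts an older
   one, splitting it into fragments). Percent divergence from the family
   consensus is rescaled to a 0–1000 similarity score, and the mean
   score over a family's members serves as the family's age surrogate
   (higher = younger). Instances overlapping coding regions by even one
   base are excluded from all expression analysis, since the object of
   interest is non-coding transcription.
2. **Orthology lifting.** Intervals are mapped between assemblies
   through UCSC chain alignments. A lift succeeds when at least
   `minMatch` (default 0.1, the standard cross-species value) of the
   interval's bases fall inside aligned blocks of the best chain; the
   lifted interval spans the target positions of the first through last
   mapped base, matching region-mode LiftOver behaviour. An instance is
   *sequence-conserved* when it lifts and overlaps any TE annotation in
   the target's own repeat catalog; requiring the *same family* in the
   target is kept as a separate flag and used only as a concordance
   check of the lifting strategy.
3. **Expression.** Read intervals are counted over features with
   >= 1 bp overlap (coverageBed semantics, strand-blind) and normalised
   to RPKM. Two thresholding rules are used deliberately: TEs are
   expressed when the *mean* RPKM over replicates is >= 1; transcripts
   require RPKM >= 1 in *every* replicate. The all-replicates rule is
   strictly stricter; both comparisons are inclusive.
4. **Family enrichment.** Per family and target species the pipeline
   counts total instances, query-expressed instances, conserved
   instances, and conserved instances expressed on each side. The
   headline statistic is the proportion of query-expressed instances
   whose ortholog is also expressed. Association is tested with the
   hypergeometric tail P(X >= j).
5. **lncRNA catalog and TE annotation.** Assembled transcripts are
   filtered in three logged steps — blacklisted biotypes, mono-exonic
   transcripts, coding potential above a cutoff — and the surviving
   multi-exon transcripts are annotated with TEs under the
   10%-of-an-exon overlap rule. Each TE-overlapping transcript is
   labelled with its dominant TE (largest total overlap). Contribution
   statistics compare each class/family's share of lncRNA sequence with
   its share of the genome. Finally the catalog is lifted to every
   target species, re-annotated there, re-quantified over the lifted
   spans, and each transcript is tiered `all_species` / `some_nhp` /
   `query_only`.

## The hypergeometric parameterisation

The test asks whether, among a family's conserved instances, expression
in the query and expression in the target co-occur more often than
chance. The default parameterisation is therefore restricted to the
conserved instances: population `N` = conserved instances, successes
`K` = conserved instances expressed in the target, draws `n` =
conserved instances expressed in the query, observed `j` = instances
expressed in both. Conditional on the margins, `j` is exactly
hypergeometric under independence, which is what makes the null
p-values uniform (see below). An alternative reading — population = the
whole family, successes = conserved, draws = query-expressed — is
available via `family_enrichment_table(..., population = "all")`; since
published per-family p-values do not disclose their population and
success definitions, neither parameterisation is asserted to reproduce
them, and p-values are treated as internal ranking statistics.

No multiple-testing correction is applied by default (an optional
Benjamini–Hochberg column exists) because the tables are used as ranked
shortlists, not as significance claims.

Family filters follow the conventions of repeat-family screens: only
families with >= 100 instances from the four main classes (DNA, SINE,
LINE, LTR), >= 30 query-expressed instances, and — for conservation
scatter tables — >= 10 conserved instances. Simple repeats and
low-complexity annotations are excluded outright; their GC-driven
detection biases make both their expression calls and their small-family
p-values untrustworthy.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_match` | 0.1 | minimum fraction of interval bases that must remap for a lift |
| `rpkm_cutoff` | 1 | inclusive expression threshold, both rules |
| `min_exon_fraction` | 0.1 | minimum fraction of an exon a TE must cover to count |
| `min_total` / `min_expressed_query` / `min_conserved` | 100 / 30 / 10 | family filters |
| `coding_cutoff` | 0.364 | coding-potential cutoff; a widely used human CPAT-style value, documented as arbitrary and meant to be recalibrated per dataset |

The coding-potential score itself is pluggable: a `coding_potential`
transcript attribute is used when present; otherwise
`orf_coding_score()` supplies a deliberately simple stand-in — the
longest forward-frame start-to-stop ORF divided by transcript length.
It is *not* a trained classifier and is documented as such; the cascade
is designed so a CPAT-like score can be dropped in via the attribute.

## The synthetic dataset generator

Real multi-species iPSC data cannot be bundled or re-processed at desk
scale, so the package carries a first-class generator
(`simulate_dataset()`) whose outputs exercise every reader and every
stage. Genomes are pure coordinate spaces (a single `chr1` per
species): no downstream stage reads nucleotide sequence, except the
coding-score stand-in, which gets short synthetic sequences attached to
decoy transcripts.

What is emulated, and how:

* **Study design.** Four species, the first being the query, with 3, 1,
  2 and 1 replicates by default — the replicate structure of a typical
  multi-primate iPSC comparison. Reads are fixed-length 100 bp
  intervals; paired-end structure is not simulated because coverage
  counting only consumes intervals.
* **Retention and chains.** Each instance survives to each target with
  probability `1 - loss_prob_per_branch`, independently per branch.
  Retained instances keep a small unaligned trim at each edge (5%, max
  20 bp) plus a small target-side insertion, so their lift ratios land
  well above 0.1 but below 1 and the `minMatch` logic is genuinely
  exercised; lost instances fall wholly inside chain gaps. Giving young
  (low-divergence) families high loss probabilities reproduces the
  age-versus-conservation trend by construction.
* **Expression.** An instance is expressed in the query with
  probability `expr_prob_query`. A retained ortholog is expressed in
  the target with probability `expr_correlation` if the query copy is
  expressed, and `expr_prob_query` otherwise. Setting
  `expr_correlation == expr_prob_query` therefore yields exact
  independence (null families); larger values plant conserved
  expression, smaller values plant depletion.
* **Counts.** Expressed features draw Poisson counts calibrated to
  `target_rpkm` (default 50) at the reference library size;
  non-expressed TEs draw `background_rpkm` (default 0.05). The planted
  level is chosen so that the shortest instances (200 bp) still have a
  Poisson rate >= 3 per replicate at the default library size of
  3e5 — strong, stem-cell-HERVH-like expression — which keeps planted
  flags recoverable through the thresholding rules rather than hovering
  at the detection boundary. An optional negative-binomial dispersion is
  available in the count path; Poisson is the default because no noise
  model is asserted by the analysis itself. A TE-free region at the
  chromosome start absorbs filler reads so each library reaches its
  reference size, keeping RPKM calibration honest.
* **Transcripts.** True lncRNAs are two-exon transcripts; 75% are built
  over a host TE (first exon overlapping it well beyond the 10% rule),
  with host classes drawn with LTR/LINE-heavy, SINE-light weights so the
  class enrichment/depletion pattern is planted. Decoys for the filter
  cascade are generated alongside: protein-coding-biotype genes (whose
  CDS intervals form the coding BED), mono-exonic transcripts, and
  high-coding-potential transcripts — half flagged via the attribute,
  half via an attached synthetic sequence containing a designed
  full-length ORF. A transcript's target locus counts as transcribed if
  the lncRNA itself is expressed there *or* its retained host TE is,
  since either way reads cover the span; the recorded conservation tier
  reflects that.

What is *not* emulated — and hence what passing tests do not show about
real data: multi-mapping reads and mappability, GC and amplification
bias, assembly errors and missing repeat annotations in non-reference
genomes, transcript assembly artefacts, strand-specific signal, genuine
nested-insertion sequence structure (fragment splits are positional
only), and inter-chromosomal or rearranged orthology (one chain per
species pair).

## Numerical and design choices

* The 0–1000 similarity scale is `round(1000 * (1 - percDiv/100))`.
  The printed analyses use this scale only ordinally, so any strictly
  monotone transform would do; linear is the obvious choice and is
  asserted (with strict monotonicity) in the tests.
* Joined-instance scores are *length-weighted* means of fragment scores,
  so a 10 bp sliver cannot dominate an insertion's age; RPKM length for
  a joined instance is the sum of fragment lengths, not the span, since
  reads cannot map to the interloper (a span-based switch exists).
* Best-chain selection: most mapped bases, then chain score; a residual
  tie mapping to different loci is reported `ambiguous` rather than
  resolved arbitrarily.
* Ties for the dominant TE go to the larger single-exon overlap, then
  the lexicographically smaller family name — deterministic output for
  fixed input.
* Overlapping TE annotations inside one exon are resolved
  longest-local-overlap-first before base counting, so contribution
  proportions never double-count a base; `allow_double_count = TRUE`
  restores raw `-wao`-style sums for comparability with
  intersectBed-based workflows.
* lncRNA lifting uses the whole transcript span for the conservation
  counts (matching transcript-level published tables) and per-exon
  lifting only to re-apply the exon-fraction TE rule in target
  coordinates; expression of a lifted transcript is quantified over its
  lifted span. Conservation percentages are reported relative to the
  number of lifted transcripts, which is the convention of the printed
  tables this mirrors.
* Degenerate inputs are signalled, not silently absorbed: zero-length
  intervals, empty catalogs for reference overlap, zero lifted instances
  for concordance, and zero TE-overlapping transcripts for contribution
  statistics all raise classed errors; proportions with zero
  query-expressed instances are reported as `NA`.

## Test problem sizes

The bundled tests run the generator at deliberately modest sizes: unit
and property tests use 2–3 species with 80–400 instances per family;
the end-to-end planted-recovery check uses 4 species and 12 families of
300 instances through the full file-based pipeline; the null-uniformity
check uses 200 independence families of 400 instances (the top of the
generator's recommended 200–400 range, which minimises the discreteness
of the hypergeometric p-values that a Kolmogorov–Smirnov check is
sensitive to) measured through the count-table path on a two-species
dataset. These sizes give the statistical checks adequate power while
keeping a full test run in the low minutes on one CPU.

## Known limitations

* The generator's expression probabilities are chosen for test power,
  not biological realism; no published per-family expression rates
  exist to calibrate against.
* Published per-family p-values are not reproduction targets (their
  exact test population is not disclosed); printed proportions and
  percentages are.
* The ORF-based coding score is a stand-in; treat catalog composition
  near the cutoff with suspicion unless a real coding-potential score
  is supplied.
* Strand-aware counting is available as an option but unstranded
  counting is the default, mirroring the coverageBed-style step the
  pipeline reproduces.
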