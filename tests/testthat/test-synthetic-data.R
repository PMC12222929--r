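# The simulator is first-class code: its manifest is the oracle for the
# rest of the suite, so its own guarantees are tested here.

test_that("LTR element has identical terminal repeats and ordered domains", {
  tpl <- fix_ltr()
  L <- nchar(tpl$sequence)
  expect_identical(substring(tpl$sequence, 1, 300),
                   substring(tpl$sequence, L - 299, L))
  f <- tpl$features
  pos <- function(nm) f$start[f$feature == nm][1]
  expect_true(pos("GAG") < pos("PR"))
  expect_true(pos("PR") < pos("RT"))
  expect_true(pos("RT") < pos("RH"))
  expect_true(pos("RH") < pos("INT"))
  # PBS immediately downstream of LTR5, PPT immediately upstream of LTR3
  expect_equal(pos("PBS"), f$end[f$feature == "LTR5"])
  expect_equal(f$end[f$feature == "PPT"], pos("LTR3"))
  # same seed twice is byte-identical
  expect_identical(build_ltr_element(4000, 300, seed = 101, name = "LTR1"),
                   tpl)
})

test_that("LTR builder errors name the limiting feature", {
  expect_error(build_ltr_element(internal_length = 1200, ltr_length = 150),
               "RT|GAG|PR")
  expect_error(build_ltr_element(internal_length = 500, ltr_length = 150),
               "internal_length")
})

test_that("TIR element carries inverted terminal repeats", {
  tpl <- fix_tir()
  L <- nchar(tpl$sequence)
  expect_identical(substring(tpl$sequence, 1, 25),
                   revcomp(substring(tpl$sequence, L - 24, L)))
  expect_true("transposase" %in% tpl$features$feature)
})

test_that("5S arrays have the documented geometry per mode", {
  t5 <- fix_5s()
  gene <- substring(t5$sequence, 1, 121)
  nts <- substring(t5$sequence, 122)
  arr <- build_5s_array(gene, nts, 6, "regular", seed = 1)
  expect_equal(nchar(arr$sequence), 6 * 1098)
  expect_true(all(arr$nts_lengths == 977))
  # single monomer at zero divergence is the monomer itself
  one <- build_5s_array(gene, nts, 1, "regular", seed = 2, divergence = 0)
  expect_identical(one$sequence, paste0(gene, nts))
  # pseudogenic arrays show at least one inter-monomer gap > one monomer,
  # recomputed from the emitted coordinates
  ps <- build_5s_array(gene, nts, 6, "pseudogenic", seed = 3)
  gaps <- diff(ps$monomers$start) - 1098
  expect_true(any(gaps > 1098))
  # long-NTS arrays elongate at least one spacer
  ln <- build_5s_array(gene, nts, 6, "long_nts", seed = 4)
  expect_true(any(ln$nts_lengths > 977))
  expect_error(build_5s_array("", nts, 3, "regular"), "non-empty")
})

test_that("build_genome realizes target proportions and a faithful manifest", {
  sim <- fix_small_sim()
  gt <- sim$gt
  expect_equal(nchar(gt$genome), 1.5e6)
  p <- gt$truth$proportions
  expect_true(abs(p[["LTR1"]] - 0.06) / 0.06 <= 0.10)
  expect_true(abs(p[["SAT1"]] - 0.02) / 0.02 <= 0.10)
  # proportion conservation: planted bp + background bp = genome length
  planted <- sum(gt$truth$copies$end - gt$truth$copies$start)
  expect_equal(planted + gt$truth$background_bp, nchar(gt$genome))
  # manifest/realization consistency: re-reading the genome at manifest
  # coordinates recovers the planted copies at the stated divergence
  ltr <- fix_ltr()
  cp <- gt$truth$copies[gt$truth$copies$family == "LTR1", ]
  set.seed(1)
  for (i in sample(nrow(cp), 5)) {
    s <- substring(gt$genome, cp$start[i] + 1, cp$end[i])
    if (cp$strand[i] == "-") s <- revcomp(s)
    al <- local_align(s, ltr$sequence)
    expect_equal(al$identity, 1 - cp$divergence[i], tolerance = 0.02)
    expect_gte(al$span, 0.98 * nchar(ltr$sequence))
  }
})

test_that("a 10% family in a 1-Mb genome lands within 10% of target", {
  sat <- build_satellite(500, seed = 9)
  gt <- build_genome(genome_spec(1e6, families = list(
    list(template = sat, target_proportion = 0.10,
         per_copy_divergence = 0.02, arrangement = "dispersed")),
    seed = 10))
  expect_true(gt$truth$proportions[[1]] >= 0.09 &&
                gt$truth$proportions[[1]] <= 0.11)
})

test_that("zero families gives pure background and an empty manifest", {
  gt <- build_genome(genome_spec(50000, seed = 3))
  expect_equal(nchar(gt$genome), 50000)
  expect_equal(nrow(gt$truth$copies), 0)
  expect_equal(gt$truth$background_bp, 50000)
})

test_that("genome construction is seed-deterministic", {
  spec <- genome_spec(2e5, families = list(
    list(template = fix_tir(), target_proportion = 0.05,
         per_copy_divergence = 0.02, arrangement = "dispersed")), seed = 77)
  g1 <- build_genome(spec)
  g2 <- build_genome(spec)
  expect_identical(seq_digest(g1$genome), seq_digest(g2$genome))
  expect_identical(g1$truth$copies, g2$truth$copies)
})

test_that("genome_spec validates proportions and divergence", {
  sat <- build_satellite(100, seed = 1)
  expect_error(genome_spec(1e5, families = list(
    list(template = sat, target_proportion = 0.7,
         per_copy_divergence = 0.02, arrangement = "dispersed"),
    list(template = sat, target_proportion = 0.4,
         per_copy_divergence = 0.02, arrangement = "dispersed"))),
    "target_proportions")
  expect_error(genome_spec(1e5, families = list(
    list(template = sat, target_proportion = 0.1,
         per_copy_divergence = 0.5, arrangement = "dispersed"))),
    "per_copy_divergence")
})

test_that("error-free short reads are exact genome substrings, properly paired", {
  gt <- build_genome(genome_spec(1e5, seed = 5))
  rs <- simulate_short_reads(gt, n_pairs = 50, error_rate = 0, seed = 6)
  expect_equal(nrow(rs$reads), 100)
  expect_true(all(nchar(rs$reads$seq) == 100))
  g <- gt$genome
  for (i in seq_len(nrow(rs$reads))) {
    r <- rs$reads[i, ]
    src <- substring(g, r$src_start + 1, r$src_end)
    expect_identical(r$seq, if (r$src_strand == "+") src else revcomp(src))
  }
  # pairing is symmetric
  expect_identical(rs$reads$mate[match(rs$reads$mate, rs$reads$id)],
                   rs$reads$id)
  expect_error(simulate_short_reads(gt, n_pairs = 0), "positive")
})

test_that("family read share matches genome proportion (law of large numbers)", {
  sim <- fix_small_sim()
  fam <- read_family(sim$rs, sim$gt$truth)
  share <- sum(fam == "LTR1", na.rm = TRUE) / length(fam)
  truep <- sim$gt$truth$proportions[["LTR1"]]
  expect_lt(abs(share - truep) / truep, 0.15)
})

test_that("short-read simulation is seed-deterministic", {
  gt <- build_genome(genome_spec(1e5, seed = 5))
  r1 <- simulate_short_reads(gt, 100, error_rate = 0.02, seed = 9)
  r2 <- simulate_short_reads(gt, 100, error_rate = 0.02, seed = 9)
  expect_identical(r1$reads, r2$reads)
})

test_that("long reads respect the length range and seed determinism", {
  gt <- build_genome(genome_spec(3e5, seed = 5))
  lr <- simulate_long_reads(gt, 300, length_range = c(500, 72000), seed = 7)
  L <- nchar(lr$reads$seq)
  # indel errors perturb lengths slightly around the drawn value
  expect_true(all(L >= 400 & L <= 80000))
  expect_true(all(lr$reads$src_end - lr$reads$src_start >= 500))
  l2 <- simulate_long_reads(gt, 300, length_range = c(500, 72000), seed = 7)
  expect_identical(lr$reads, l2$reads)
  expect_error(simulate_long_reads(gt, 0), "positive")
})

test_that("an error-free long read over a regular array carries the manifest monomer count", {
  t5 <- fix_5s()
  spec <- genome_spec(6e4, array_specs = list(
    list(template = t5, n_monomers = 6, mode = "regular")), seed = 31)
  gt <- build_genome(spec)
  arr <- gt$truth$arrays[1, ]
  lr <- simulate_long_reads(gt, 60, length_range = c(5000, 30000),
                            error_rate = 0, meanlog = log(15000),
                            sdlog = 0.3, seed = 32)
  cover <- which(lr$reads$src_start <= arr$start & lr$reads$src_end >= arr$end)
  expect_gt(length(cover), 0)
  am <- gt$truth$array_monomers
  for (i in cover[1]) {
    inside <- sum(am$start >= lr$reads$src_start[i] &
                    am$end <= lr$reads$src_end[i])
    expect_equal(inside, arr$n_monomers)
  }
})

test_that("genome, reads and manifest writers produce readable files", {
  sim <- fix_small_sim()
  td <- withr::local_tempdir()
  f <- write_genome_fasta(sim$gt$genome, file.path(td, "g.fasta"))
  g2 <- Biostrings::readDNAStringSet(f)
  expect_equal(nchar(as.character(g2[[1]])), nchar(sim$gt$genome))
  rs_small <- subset_rs <- simulate_short_reads(sim$gt, 25, seed = 1)
  paths <- write_reads(rs_small, file.path(td, "reads"))
  expect_length(paths, 2)
  back <- read_reads(paths, species = "SP1")
  expect_equal(nrow(back$reads), 50)
  expect_setequal(back$reads$seq, rs_small$reads$seq)
  write_manifest(sim$gt$truth, file.path(td, "truth"))
  tsv <- read.table(file.path(td, "truth_copies.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(nrow(tsv), nrow(sim$gt$truth$copies))
})
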