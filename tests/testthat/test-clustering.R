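test_that("the reporting floor is 0.01% of the analyzed reads", {
  expect_equal(reporting_floor(1e7), 1000)
  expect_equal(reporting_floor(200000), 20)
  expect_equal(reporting_floor(5999), 1)
})

test_that("clusters partition the reads and proportions sum to one", {
  sim <- fix_small_sim()
  cl <- sim$cl
  expect_equal(sum(cl$clusters$size), cl$total_reads)
  expect_equal(sum(cl$clusters$genome_proportion), 1)
  expect_equal(nrow(cl$members), cl$total_reads)
  expect_false(anyDuplicated(cl$members$id) > 0)
  expect_equal(unname(rowSums(cl$per_species)), cl$clusters$size)
  expect_error(build_clusters(character(0)))
})

test_that("minimizer-seeded clustering equals the brute-force similar() oracle", {
  set.seed(51)
  tA <- random_dna(600, 0.4); tB <- random_dna(400, 0.4)
  mk <- function(tpl, n, div) vapply(seq_len(n), function(i) {
    s <- sample.int(nchar(tpl) - 100, 1)
    mutate_dna(substring(tpl, s, s + 99), div)
  }, "")
  seqs <- c(mk(tA, 80, 0.02), mk(tB, 60, 0.02), random_reads(100, seed = 52))
  # randomize order and strands
  seqs <- seqs[sample(length(seqs))]
  flip <- sample(length(seqs), 60)
  seqs[flip] <- revcomp(seqs[flip])
  cl <- build_clusters(seqs)
  lab_fast <- integer(length(seqs))
  m <- match(cl$members$id, sprintf("r%06d", seq_along(seqs)))
  lab_fast[m] <- as.integer(factor(cl$members$cluster_id))
  lab_oracle <- brute_force_clusters(seqs)
  expect_identical(partition_signature(lab_fast),
                   partition_signature(lab_oracle))
})

test_that("the partition is invariant to reverse-complementing input reads", {
  set.seed(53)
  tpl <- random_dna(500, 0.4)
  seqs <- c(vapply(1:50, function(i) {
    s <- sample.int(400, 1); mutate_dna(substring(tpl, s, s + 99), 0.02)
  }, ""), random_reads(50, seed = 54))
  cl1 <- build_clusters(seqs)
  seqs2 <- seqs
  flip <- seq(1, 100, by = 3)
  seqs2[flip] <- revcomp(seqs2[flip])
  cl2 <- build_clusters(seqs2)
  sig <- function(cl) partition_signature(as.integer(factor(
    cl$members$cluster_id[order(cl$members$id)])))
  expect_identical(sig(cl1), sig(cl2))
})

test_that("background-only low-coverage reads form no substantial cluster", {
  gt <- build_genome(genome_spec(2e6, seed = 55))
  rs <- simulate_short_reads(gt, n_pairs = 2000, error_rate = 0.01, seed = 56)
  cl <- build_clusters(rs)
  # only chance doublets from read overlaps; nothing approaches the 0.01%
  # floor of a study-scale analysis (>= 20 reads at 200k analyzed reads)
  expect_lt(max(cl$clusters$size), reporting_floor(200000))
  expect_gt(mean(cl$clusters$size == 1), 0.9)
})

test_that("superclusters join clusters straddled by mate pairs", {
  set.seed(57)
  tA <- random_dna(400, 0.4); tB <- random_dna(400, 0.4)
  tile <- function(tpl, tag, n = 40) {
    starts <- round(seq(1, nchar(tpl) - 100, length.out = n))
    data.frame(id = sprintf("%s_%03d", tag, seq_len(n)),
               seq = substring(tpl, starts, starts + 99),
               mate = NA_character_, species = "SP1",
               stringsAsFactors = FALSE)
  }
  a <- tile(tA, "A"); b <- tile(tB, "B")
  # five mate pairs straddle the two templates
  a$mate[1:5] <- b$id[1:5]; b$mate[1:5] <- a$id[1:5]
  # the rest pair within their template
  ev <- seq(6, 38, by = 2)
  a$mate[ev] <- a$id[ev + 1]
  a$mate[ev + 1] <- a$id[ev]
  rs <- read_set(rbind(a, b))
  cl <- build_clusters(rs)
  expect_gte(nrow(cl$clusters), 2)
  linked <- link_superclusters(cl, rs, min_links = 3)
  big2 <- linked$clusters[order(-linked$clusters$size), ][1:2, ]
  expect_equal(big2$supercluster_id[1], big2$supercluster_id[2])
  # min_links = Inf never merges
  un <- link_superclusters(cl, rs, min_links = Inf)
  expect_equal(length(unique(un$clusters$supercluster_id)),
               nrow(un$clusters))
  # without straddling pairs, superclusters equal clusters
  a2 <- tile(tA, "A"); b2 <- tile(tB, "B")
  rs2 <- read_set(rbind(a2, b2))
  cl2 <- link_superclusters(build_clusters(rs2), rs2)
  expect_equal(length(unique(cl2$clusters$supercluster_id)),
               nrow(cl2$clusters))
  st <- supercluster_table(linked)
  expect_equal(sum(st$size), linked$total_reads)
})

test_that("cluster_representative rebuilds a template from tiled reads", {
  set.seed(58)
  tpl <- random_dna(1000, 0.4)
  starts <- seq(1, 900, by = 10)
  reads <- substring(tpl, starts, starts + 99)
  rep <- cluster_representative(reads)
  expect_gte(nchar(rep$contig), 0.9 * 1000)
  al <- local_align(rep$contig, tpl)
  expect_gte(al$identity, 0.99)
  # identical reads: the contig is the read
  same <- rep("ACGTACGTAC", 0)
  reads2 <- rep(substring(tpl, 1, 100), 10)
  expect_identical(cluster_representative(reads2)$contig, reads2[1])
  # deterministic under fixed input order
  rep2 <- cluster_representative(reads)
  expect_identical(rep$contig, rep2$contig)
})

test_that("annotate_cluster labels contigs by repeat and domain databases", {
  set.seed(59)
  db <- c(REP_A = random_dna(2000, 0.4), REP_B = random_dna(1500, 0.4))
  contig <- substring(db[["REP_A"]], 301, 1500)
  ann <- annotate_cluster(contig, repeat_db = db)
  expect_equal(ann$label, "REP_A")
  expect_equal(ann$evidence, "nucleotide")
  rnd <- random_dna(800, 0.5)
  ann2 <- annotate_cluster(rnd, repeat_db = db)
  expect_equal(ann2$label, "unclassified")
  expect_warning(ann3 <- annotate_cluster(contig), "empty")
  expect_equal(ann3$label, "unclassified")
  # translated search: an RT domain at 10% amino-acid divergence is still
  # assigned to its family
  ltr <- fix_ltr()
  doms <- attr(ltr, "domain_proteins")
  rt <- strsplit(doms[["RT"]], "")[[1]]
  pos <- sample(length(rt), round(0.1 * length(rt)))
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  rt[pos] <- vapply(rt[pos], function(a) sample(setdiff(aas, a), 1), "")
  orf <- reverse_translate_test(paste(rt, collapse = ""))
  contig2 <- paste0(random_dna(300, 0.4), orf, random_dna(300, 0.4))
  ann4 <- annotate_cluster(contig2, domain_db = doms)
  expect_equal(ann4$label, "RT")
  expect_equal(ann4$evidence, "domain")
  # cross-check with an independent protein alignment: the mutated RT must
  # align to the original far better than to the other domains
  fr <- Biostrings::translate(Biostrings::DNAString(orf))
  sc <- vapply(doms, function(d) Biostrings::score(
    Biostrings::pairwiseAlignment(Biostrings::AAString(d), fr,
                                  type = "local",
                                  substitutionMatrix = "BLOSUM80",
                                  gapOpening = 10, gapExtension = 1)), 1.0)
  expect_equal(names(which.max(sc)), "RT")
})
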