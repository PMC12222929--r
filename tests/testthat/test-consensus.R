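make_copy_reads <- function(tpl, n_full, n_trunc = 0, div = 0.05,
                            flank = 2500, seed = 61) {
  with_seed(seed, {
    reads <- character(0); truth <- list()
    for (i in seq_len(n_full + n_trunc)) {
      cp <- mutate_dna(tpl, div)
      if (i > n_full) cp <- substring(cp, round(nchar(cp) / 2))  # 5' truncated
      left <- random_dna(flank, 0.4)
      reads <- c(reads, paste0(left, cp, random_dna(flank, 0.4)))
      truth[[i]] <- c(start = nchar(left), end = nchar(left) + nchar(cp))
    }
    names(reads) <- sprintf("LR%03d", seq_along(reads))
    list(reads = reads, truth = do.call(rbind, truth))
  })
}

test_that("search_long_reads returns the 20 most significant hits, rank-stably", {
  set.seed(62)
  tpl <- fix_ltr()$sequence
  cr <- make_copy_reads(tpl, n_full = 30, seed = 63)
  reads <- c(cr$reads, stats::setNames(
    vapply(1:20, function(i) random_dna(6000, 0.5), ""),
    sprintf("BG%03d", 1:20)))
  contig <- substring(tpl, 1, 2500)
  hits <- search_long_reads(contig, reads)
  expect_equal(nrow(hits), 20)
  expect_true(all(hits$read_id %in% names(cr$reads)))
  # hit intervals overlap the planted locus
  for (k in seq_len(nrow(hits))) {
    tr <- cr$truth[match(hits$read_id[k], names(cr$reads)), ]
    expect_true(hits$start[k] < tr["end"] && hits$end[k] > tr["start"])
  }
  # rank stability under input permutation
  perm <- sample(length(reads))
  hits2 <- search_long_reads(contig, reads[perm])
  expect_identical(hits$read_id, hits2$read_id)
  # absent query: empty result
  expect_equal(nrow(search_long_reads(random_dna(800, 0.5), reads)), 0)
})

test_that("detect_copies recovers element boundaries and flags fragments", {
  tpl <- fix_ltr()$sequence
  cr <- make_copy_reads(tpl, n_full = 8, n_trunc = 4, seed = 64)
  contig <- substring(tpl, 1, 2500)
  hits <- search_long_reads(contig, cr$reads, top = 12)
  det <- detect_copies(hits, cr$reads, contig)
  tab <- det$table
  m <- match(tab$read_id, rownames(cr$truth))
  m <- match(tab$read_id, names(cr$reads))
  full_reads <- names(cr$reads)[1:8]
  for (k in seq_len(nrow(tab))) {
    tr <- cr$truth[m[k], ]
    if (tab$read_id[k] %in% full_reads) {
      expect_lte(abs(tab$start[k] - tr[["start"]]), 60)
      expect_lte(abs(tab$end[k] - tr[["end"]]), 60)
      expect_true(tab$full[k])
    } else {
      expect_false(tab$full[k])
    }
  }
})

test_that("msa_consensus takes per-column majorities, order-invariantly", {
  set.seed(65)
  # identical copies reproduce the copy
  cp <- random_dna(600, 0.4)
  expect_identical(suppressWarnings(msa_consensus(rep(cp, 3))), cp)
  # 20 copies at 5% divergence: consensus >= 99% identical to the template
  tpl <- random_dna(2000, 0.4)
  copies <- vapply(1:20, function(i) mutate_dna(tpl, 0.05), "")
  cons <- msa_consensus(copies)
  al <- local_align(cons, tpl)
  expect_gte(al$matches / nchar(tpl), 0.99)
  # order invariance
  cons2 <- msa_consensus(rev(copies))
  expect_identical(cons, cons2)
  # 3 copies with one disagreeing column: majority base wins
  v <- strsplit(cp, "")[[1]]
  v[100] <- setdiff(c("A", "C", "G", "T"), v[100])[1]
  dis <- paste(v, collapse = "")
  expect_identical(suppressWarnings(msa_consensus(c(cp, dis, cp))), cp)
  expect_error(msa_consensus(character(0)), "at least")
  expect_warning(msa_consensus(c(cp, dis)), "only")
})

test_that("map_refine corrects a corrupted consensus and is idempotent", {
  set.seed(66)
  tpl <- random_dna(1500, 0.4)
  starts <- seq(1, 1400, by = 7)
  reads <- substring(tpl, starts, starts + 99)
  v <- strsplit(tpl, "")[[1]]
  bad_pos <- sample(100:1300, 10)
  v[bad_pos] <- vapply(v[bad_pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  corrupt <- paste(v, collapse = "")
  fixed <- map_refine(corrupt, reads)
  expect_identical(fixed, tpl)
  expect_identical(map_refine(tpl, reads), tpl)
  # zero-coverage positions are never changed
  tail100 <- random_dna(100, 0.5)
  ext <- paste0(tpl, tail100)
  fixed2 <- map_refine(ext, reads)
  expect_identical(substring(fixed2, 1501, 1600), tail100)
})

test_that("annotate_domains recovers planted domains in order, both strands", {
  ltr <- fix_ltr()
  doms <- annotate_domains(ltr$sequence, attr(ltr, "domain_proteins"))
  expect_identical(doms$domain, c("GAG", "PR", "RT", "RH", "INT", "CD"))
  expect_true(all(doms$strand == "+"))
  # feature coordinates agree with the template's manifest within a codon
  f <- ltr$features
  for (d in c("GAG", "RT", "INT")) {
    expect_lte(abs(doms$start[doms$domain == d] - f$start[f$feature == d]), 3)
  }
  rcd <- annotate_domains(revcomp(ltr$sequence), attr(ltr, "domain_proteins"))
  expect_identical(rcd$domain, rev(doms$domain))
  expect_true(all(rcd$strand == "-"))
  set.seed(67)
  none <- annotate_domains(random_dna(3000, 0.5), attr(ltr, "domain_proteins"))
  expect_equal(nrow(none), 0)
})

test_that("terminal repeat detection distinguishes LTR, TIR and none", {
  ltr <- fix_ltr()
  tr <- detect_terminal_repeats(ltr$sequence)
  expect_equal(tr$kind, "LTR")
  expect_lte(abs(tr$five[1] - 0), 20)
  expect_lte(abs(tr$five[2] - 300), 20)
  expect_lte(abs(tr$three[1] - 4300), 20)
  expect_lte(abs(tr$three[2] - 4600), 20)
  tir <- fix_tir()
  tr2 <- detect_terminal_repeats(tir$sequence)
  expect_equal(tr2$kind, "TIR")
  set.seed(68)
  tr3 <- detect_terminal_repeats(random_dna(2000, 0.5))
  expect_equal(tr3$kind, "none")
})

test_that("35S annotation finds the three rRNA genes in order, with flips", {
  u <- fix_35s()
  refs <- attr(u, "rRNA_genes")
  ann <- annotate_35s(u$sequence, refs)
  genes <- ann$features[ann$features$feature %in% c("18S", "5.8S", "26S"), ]
  expect_identical(genes$feature, c("18S", "5.8S", "26S"))
  expect_true(all(c("ITS1", "ITS2", "IGS") %in% ann$features$feature))
  f <- u$features
  expect_lte(abs(genes$start[1] - f$start[f$feature == "18S"]), 20)
  # reverse-complement input is flipped back
  ann2 <- annotate_35s(revcomp(u$sequence), refs)
  expect_true(ann2$flipped)
  g2 <- ann2$features[ann2$features$feature %in% c("18S", "5.8S", "26S"), ]
  expect_identical(g2$feature, c("18S", "5.8S", "26S"))
  # a unit without 5.8S gives a partial annotation with a warning
  broken <- paste0(substring(u$sequence, 1, f$start[f$feature == "5.8S"]),
                   random_dna(160, 0.5),
                   substring(u$sequence, f$end[f$feature == "5.8S"] + 1))
  expect_warning(ann3 <- annotate_35s(broken, refs), "partial")
  expect_equal(sum(ann3$features$feature %in% c("18S", "26S")), 2)
})

test_that("reconstruct_element runs the full path and annotates the result", {
  tpl <- fix_ltr()
  cr <- make_copy_reads(tpl$sequence, n_full = 12, seed = 69)
  contig <- substring(tpl$sequence, 1, 2500)
  rc <- reconstruct_element(contig, cr$reads, top = 12,
                            domain_db = attr(tpl, "domain_proteins"))
  expect_s3_class(rc, "repeat_consensus")
  expect_equal(rc$terminal_repeats$kind, "LTR")
  al <- local_align(rc$sequence, tpl$sequence)
  expect_gte(al$matches / nchar(tpl$sequence), 0.98)
  expect_identical(rc$domains$domain, c("GAG", "PR", "RT", "RH", "INT", "CD"))
  expect_error(reconstruct_element(random_dna(500, 0.5), cr$reads),
               "aborted")
})
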