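# Simulation studies used to validate the pipeline against the simulator's
# ground truth. These are exported so the same study definitions drive both
# the test suite and the acceptance script.

#' Assign simulated reads to planted families via the manifest
#'
#' A read belongs to the family whose planted copy contains its source
#' midpoint.
#'
#' @param rs A simulated [read_set()] (with `src_start`/`src_end`).
#' @param truth The manifest from [build_genome()].
#' @return Character vector (family name or NA) per read.
#' @export
read_family <- function(rs, truth) {
  cp <- truth$copies[order(truth$copies$start), , drop = FALSE]
  mid <- (rs$reads$src_start + rs$reads$src_end) / 2
  idx <- findInterval(mid, cp$start)
  fam <- rep(NA_character_, length(mid))
  ok <- idx >= 1 & idx <= nrow(cp)
  inside <- ok & mid < cp$end[pmax(idx, 1)]
  fam[inside] <- cp$family[idx[inside]]
  fam
}

#' Clustering recovery study
#'
#' Plants three repeat families at 10%, 5% and 1% of a synthetic genome,
#' simulates low-coverage paired short reads, clusters them, assigns each
#' reported cluster to its source family by the manifest (majority of
#' member reads), and compares the estimated against the realized
#' proportions. Family proportions are estimated as the summed read
#' proportion of the clusters assigned to each family, the same
#' aggregation used when clusters of one repeat are grouped by annotation.
#'
#' @param seed Integer seed.
#' @param genome_length Genome size, bp (default 1e8, giving ~0.2x
#'   coverage at the default read number — the low-coverage regime the
#'   clustering method assumes).
#' @param n_pairs Read pairs (default 1e5).
#' @param targets Named target proportions of the three families.
#' @param per_copy_divergence Divergence of planted copies.
#' @param error_rate Read error rate.
#' @return `data.frame`: family, true (realized) and estimated proportion,
#'   relative error.
#' @export
sim_cluster_recovery <- function(seed, genome_length = 1e8, n_pairs = 1e5,
                                 targets = c(FAM_A = 0.10, FAM_B = 0.05,
                                             FAM_C = 0.01),
                                 per_copy_divergence = 0.03,
                                 error_rate = 0.01) {
  tpls <- list(
    build_ltr_element(4000, 300, seed = seed + 1, name = names(targets)[1]),
    build_tir_element(3000, 25, seed = seed + 2, name = names(targets)[2]),
    build_satellite(500, seed = seed + 3, name = names(targets)[3]))
  fams <- lapply(seq_along(tpls), function(i) list(
    template = tpls[[i]], target_proportion = unname(targets[i]),
    per_copy_divergence = per_copy_divergence,
    arrangement = if (tpls[[i]]$repeat_class == "satellite") "tandem"
                  else "dispersed"))
  gt <- build_genome(genome_spec(genome_length, families = fams, seed = seed))
  rs <- simulate_short_reads(gt, n_pairs = n_pairs, error_rate = error_rate,
                             seed = seed + 10)
  cl <- build_clusters(rs)
  fam_of_read <- read_family(rs, gt$truth)
  names(fam_of_read) <- rs$reads$id
  rep_cl <- cl$clusters$cluster_id[cl$clusters$reported]
  est <- stats::setNames(numeric(length(targets)), names(targets))
  for (cid in rep_cl) {
    ids <- cl$members$id[cl$members$cluster_id == cid]
    f <- fam_of_read[ids]
    f <- f[!is.na(f)]
    if (!length(f)) next
    maj <- names(sort(table(f), decreasing = TRUE))[1]
    if (length(f) >= 0.5 * length(ids))
      est[maj] <- est[maj] + length(ids) / cl$total_reads
  }
  truep <- gt$truth$proportions[names(targets)]
  data.frame(family = names(targets), true = unname(truep),
             estimated = unname(est),
             rel_error = unname((est - truep) / truep),
             stringsAsFactors = FALSE)
}

#' Consensus fidelity study
#'
#' Plants an LTR retrotransposon (30 copies at 5% per-copy divergence) in
#' a synthetic genome, runs the full reconstruction path — short-read
#' clustering, contig assembly, long-read search, copy detection,
#' multiple-alignment consensus, short-read refinement — and measures the
#' consensus against the planted template. Long reads carry no sequencing
#' error here so the study isolates biological copy divergence (the
#' quantity the consensus must average out).
#'
#' @param seed Integer seed.
#' @return List: `identity` (consensus matches / template length),
#'   `ltr_found`, `domain_order_ok` (GAG-PR-RT-RH-INT recovered in
#'   order), `n_copies`, `consensus_length`, `template_length`.
#' @export
sim_consensus_fidelity <- function(seed) {
  ltr <- build_ltr_element(4000, 300, seed = seed + 1, name = "LTR1")
  G <- 2.3e6
  gt <- build_genome(genome_spec(G, families = list(
    list(template = ltr, target_proportion = 0.06,
         per_copy_divergence = 0.05, arrangement = "dispersed")),
    seed = seed))
  rs <- simulate_short_reads(gt, n_pairs = round(0.5 * G / 200),
                             error_rate = 0.01, seed = seed + 2)
  cl <- build_clusters(rs)
  contig <- cluster_representative(
    unname(cluster_reads(cl, rs, cl$clusters$cluster_id[1])))$contig
  lr <- simulate_long_reads(gt, n_reads = 600, error_rate = 0,
                            meanlog = log(12000), sdlog = 0.5,
                            seed = seed + 3)
  hits <- search_long_reads(contig, lr)
  det <- detect_copies(hits, lr, contig)
  cons <- msa_consensus(det$copies)
  cons <- map_refine(cons, rs)
  ori <- orient_by_domains(cons, attr(ltr, "domain_proteins"))
  cons <- ori$sequence
  doms <- ori$domains
  al <- local_align(cons, ltr$sequence)
  tr <- detect_terminal_repeats(cons)
  want <- c("GAG", "PR", "RT", "RH", "INT")
  got <- doms$domain[doms$domain %in% want]
  list(identity = al$matches / nchar(ltr$sequence),
       ltr_found = identical(tr$kind, "LTR"),
       domain_order_ok = identical(got, want),
       n_copies = length(det$copies),
       consensus_length = nchar(cons),
       template_length = nchar(ltr$sequence))
}

#' Array-classifier recovery study
#'
#' Simulates long reads each carrying one 5S array of known organization
#' (`n_per_class` per class: regular / potentially regular / pseudogenic,
#' well-separated parameters), classifies them from monomer hit geometry,
#' and reports the per-class confusion counts plus label
#' re-derivability.
#'
#' @param seed Integer seed.
#' @param n_per_class Reads per class (default 50).
#' @return List: `confusion` (true x called table), `precision`, `recall`
#'   (named by class), `rederivable` (all emitted labels reproduce from
#'   stored geometry).
#' @export
sim_array_classification <- function(seed, n_per_class = 50) {
  with_seed(seed, {
    t5 <- build_5s_template(seed = seed + 1)
    gene <- subseq0(t5$sequence, 0, 121)
    nts <- subseq0(t5$sequence, 121, nchar(t5$sequence))
    monomer <- list(monomer = t5$sequence, gene = gene)
    make_read <- function(mode) {
      if (mode == "regular") {
        arr <- build_5s_array(gene, nts, 8, "regular")
        fl <- 600
      } else if (mode == "potentially_regular") {
        arr <- build_5s_array(gene, nts, 3, "regular")
        fl <- 350
      } else {
        arr <- build_5s_array(gene, nts, 8, "pseudogenic")
        fl <- 600
      }
      paste0(random_dna(fl), arr$sequence, random_dna(fl))
    }
    truth <- rep(c("regular", "potentially_regular", "pseudogenic"),
                 each = n_per_class)
    reads <- vapply(truth, make_read, "")
    names(reads) <- sprintf("R%03d", seq_along(reads))
    res <- classify_arrays(reads, monomer)
    called <- vapply(res$calls, `[[`, "", "label")
    names(called) <- vapply(res$calls, `[[`, "", "read_id")
    called <- called[names(reads)]
    classes <- c("regular", "potentially_regular", "pseudogenic")
    conf <- table(factor(truth, classes), factor(called, classes))
    prec <- diag(conf) / pmax(colSums(conf), 1)
    rec <- diag(conf) / pmax(rowSums(conf), 1)
    ml <- nchar(t5$sequence)
    rederivable <- all(vapply(res$calls, function(cc)
      identical(rederive_label(cc, ml), cc$label), TRUE))
    list(confusion = conf, precision = prec, recall = rec,
         rederivable = rederivable)
  })
}

#' K2P estimator bias study
#'
#' Simulates sequence pairs at a known total divergence and measures the
#' mean K2P estimate.
#'
#' @param seed Integer seed.
#' @param reps Replicates (default 200).
#' @param n Sites (default 1000).
#' @param d True distance (default 0.1).
#' @return List: `mean_estimate`, `bias`.
#' @export
k2p_bias <- function(seed, reps = 200, n = 1000, d = 0.1) {
  with_seed(seed, {
    est <- vapply(seq_len(reps), function(i) {
      p <- simulate_k2p_pair(n, d)
      k2p_distance(p$a, p$b)
    }, 1.0)
    list(mean_estimate = mean(est), bias = mean(est) - d)
  })
}

#' Tajima relative-rate test calibration study
#'
#' Under equal-rates simulation (both ingroup lineages at the same
#' divergence from their common ancestor), the test's type-I error at
#' alpha should match the nominal level.
#'
#' @param seed Integer seed.
#' @param reps Replicates (default 1000).
#' @param n Sites (default 600).
#' @param d_lineage Per-lineage divergence (default 0.05).
#' @param d_outgroup Extra outgroup divergence (default 0.08).
#' @param alpha Nominal level (default 0.05).
#' @return List: `rejection_rate`, `alpha`.
#' @export
tajima_type1 <- function(seed, reps = 1000, n = 600, d_lineage = 0.05,
                         d_outgroup = 0.08, alpha = 0.05) {
  with_seed(seed, {
    rej <- vapply(seq_len(reps), function(i) {
      anc <- random_dna(n, 0.5)
      a <- mutate_dna(anc, d_lineage)
      b <- mutate_dna(anc, d_lineage)
      o <- mutate_dna(anc, d_outgroup)
      tajima_rrt(a, b, o)$p_value < alpha
    }, TRUE)
    list(rejection_rate = mean(rej), alpha = alpha)
  })
}
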