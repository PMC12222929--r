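# Similarity-graph read clustering with abundance accounting.
#
# The published repeat-clustering pipeline's internal graph-community
# algorithm is deliberately NOT re-implemented; clusters here are connected
# components of the read-similarity graph under the stated thresholds (90%
# identity over 55% of the read length), with minimizer candidate pairing
# to avoid the quadratic all-vs-all comparison. This is a documented,
# parameter-compatible simplification.

#' Cluster reads into repeat families
#'
#' Edges come from shared-minimizer candidate pairs verified by the
#' [similar()] contract; clusters are the connected components. A cluster's
#' genome proportion is its read count divided by the total analyzed reads
#' (the coverage-based abundance proxy). Reported ("top") clusters are
#' those at proportion >= `report_threshold` (default 0.01% of the analyzed
#' reads) with at least 2 reads; contig building is attempted only for
#' clusters with >= `min_assembly` reads.
#'
#' @param rs A [read_set()] (or character vector of read sequences).
#' @param params [similarity_params()].
#' @param report_threshold Reporting floor as a fraction of analyzed reads
#'   (default 1e-4, i.e. 0.01%).
#' @param min_assembly Minimal cluster size for assembly (default 5).
#' @param max_attempts Alignment attempts per read per minimizer bucket.
#' @return Object of class `repeat_clusters`: `clusters` (table with size,
#'   genome_proportion, flags), `members` (read -> cluster), `per_species`
#'   (cluster x species count matrix), `total_reads`, `params`.
#' @export
build_clusters <- function(rs, params = similarity_params(),
                           report_threshold = 1e-4, min_assembly = 5,
                           max_attempts = 12) {
  if (is.character(rs)) {
    rs <- read_set(data.frame(id = sprintf("r%06d", seq_along(rs)), seq = rs,
                              stringsAsFactors = FALSE))
  }
  df <- rs$reads
  if (nrow(df) == 0) stop("empty read set")
  if (length(unique(nchar(df$seq))) > 1)
    warning("reads are not length-homogeneous; trim first")
  lab <- cpp_cluster_reads(df$seq, k = params$kmer_seed_size,
                           w = params$window,
                           min_ident = params$min_identity,
                           min_cov = params$min_coverage,
                           max_attempts = max_attempts,
                           match = params$match, mismatch = params$mismatch,
                           gap = params$gap)
  total <- nrow(df)
  sizes <- tabulate(lab)
  ord <- order(-sizes, seq_along(sizes))
  new_id <- integer(length(sizes))
  new_id[ord] <- seq_along(ord)
  cl_of_read <- new_id[lab]
  sizes <- sizes[ord]
  ids <- sprintf("CL%d", seq_along(sizes))
  sp_tab <- table(factor(cl_of_read, levels = seq_along(sizes)), df$species)
  per_species <- matrix(as.integer(sp_tab), nrow = nrow(sp_tab),
                        dimnames = list(ids, colnames(sp_tab)))
  clusters <- data.frame(
    cluster_id = ids, size = sizes,
    genome_proportion = sizes / total,
    reported = sizes / total >= report_threshold & sizes >= 2,
    small = sizes < max(2, min_assembly),
    assembly_eligible = sizes >= min_assembly,
    annotation = NA_character_, supercluster_id = NA_character_,
    stringsAsFactors = FALSE)
  members <- data.frame(id = df$id, cluster_id = ids[cl_of_read],
                        species = df$species, stringsAsFactors = FALSE)
  structure(list(clusters = clusters, members = members,
                 per_species = per_species, total_reads = total,
                 params = params,
                 report_threshold = report_threshold,
                 min_assembly = min_assembly),
            class = "repeat_clusters")
}

#' @export
print.repeat_clusters <- function(x, ...) {
  cat(sprintf("<repeat_clusters> %d reads in %d clusters (%d reported)\n",
              x$total_reads, nrow(x$clusters), sum(x$clusters$reported)))
  print(head(x$clusters[x$clusters$reported, c("cluster_id", "size",
                                               "genome_proportion",
                                               "supercluster_id")], 10))
  invisible(x)
}

#' Reporting floor in reads for a given total
#'
#' The cluster size threshold: 0.01% of the analyzed reads by default.
#'
#' @param total_reads Total analyzed reads.
#' @param threshold Fraction (default 1e-4).
#' @return Minimum cluster size (reads) to be reported.
#' @export
reporting_floor <- function(total_reads, threshold = 1e-4) {
  ceiling(total_reads * threshold)
}

#' Read sequences of one cluster
#' @param cl A `repeat_clusters` object.
#' @param rs The [read_set()] it was built from.
#' @param cluster_id Cluster id, e.g. `"CL1"`.
#' @return Character vector of member read sequences (named by id).
#' @export
cluster_reads <- function(cl, rs, cluster_id) {
  ids <- cl$members$id[cl$members$cluster_id == cluster_id]
  s <- read_seqs(rs)
  s[ids]
}

#' Join clusters into superclusters via mate-pair links
#'
#' Clusters are joined when at least `min_links` read pairs straddle them
#' (one mate in each); superclusters are the transitive closure. An LTR
#' family whose LTR and internal regions split into separate clusters is
#' the typical case this re-joins.
#'
#' @param cl A `repeat_clusters` object.
#' @param rs The [read_set()] with mate information.
#' @param min_links Minimum straddling pairs to join (default 3;
#'   `Inf` disables merging).
#' @return The `repeat_clusters` object with `supercluster_id` filled in
#'   and a `links` table attached.
#' @export
link_superclusters <- function(cl, rs, min_links = 3) {
  df <- rs$reads
  m <- cl$members
  clu <- stats::setNames(m$cluster_id, m$id)
  paired <- !is.na(df$mate) & df$id < df$mate &
    df$id %in% names(clu) & df$mate %in% names(clu)
  a <- clu[df$id[paired]]; b <- clu[df$mate[paired]]
  cross <- a != b
  links <- data.frame(cluster_a = pmin(a[cross], b[cross]),
                      cluster_b = pmax(a[cross], b[cross]),
                      stringsAsFactors = FALSE)
  if (nrow(links)) {
    agg <- stats::aggregate(list(n_links = rep(1L, nrow(links))),
                            links, FUN = sum)
  } else {
    agg <- data.frame(cluster_a = character(), cluster_b = character(),
                      n_links = integer())
  }
  strong <- agg[is.finite(min_links) & agg$n_links >= min_links, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    strong[, c("cluster_a", "cluster_b")], directed = FALSE,
    vertices = cl$clusters$cluster_id)
  comp <- igraph::components(g)$membership
  # supercluster ids ordered by total read count
  tot <- tapply(cl$clusters$size, comp[cl$clusters$cluster_id], sum)
  rk <- rank(-tot, ties.method = "first")
  sc <- sprintf("SC%d", rk[as.character(comp[cl$clusters$cluster_id])])
  cl$clusters$supercluster_id <- sc
  cl$links <- agg
  cl
}

#' Supercluster summary table
#' @param cl A `repeat_clusters` object after [link_superclusters()].
#' @return `data.frame` with supercluster id, member clusters, read count
#'   and genome proportion.
#' @export
supercluster_table <- function(cl) {
  stopifnot(!all(is.na(cl$clusters$supercluster_id)))
  sp <- split(cl$clusters, cl$clusters$supercluster_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    supercluster_id = d$supercluster_id[1],
    n_clusters = nrow(d), size = sum(d$size),
    genome_proportion = sum(d$genome_proportion),
    clusters = paste(d$cluster_id, collapse = ","),
    stringsAsFactors = FALSE)))
  out[order(-out$size), ]
}

#' Build the highest-depth contig of a read cluster
#'
#' Greedy overlap layout by iterative mapping: starting from the most
#' k-mer-central member read, all member reads are mapped back to the
#' growing reference (relaxed identity so diverged copies of one family
#' still stack), the per-column majority is called, and ends are extended
#' by read overhangs while at least `min_extend_depth` reads support the
#' extension — which stops contig growth at the element boundary, where
#' each copy runs into different flanking sequence.
#'
#' @param seqs Character vector of member read sequences (>= min cluster
#'   size for assembly, i.e. 5).
#' @param min_identity Mapping identity (relaxed below the clustering
#'   threshold so a family's diverged copies assemble together).
#' @param min_coverage Minimum aligned fraction of a read to use it.
#' @param k Mapping seed size.
#' @param band Alignment band half-width.
#' @param min_extend_depth Reads required to support an end extension.
#' @param max_reads Cap on member reads used (first `max_reads` kept).
#' @param max_iter Iteration cap.
#' @return List with `contig`, `depth` (mean coverage), `n_mapped`,
#'   `iterations`.
#' @export
cluster_representative <- function(seqs, min_identity = 0.75,
                                   min_coverage = 0.5, k = 11, band = 40,
                                   min_extend_depth = 2, max_reads = 1500,
                                   max_iter = 600) {
  stopifnot(length(seqs) >= 5)
  seqs <- unname(seqs)
  if (length(seqs) > max_reads) seqs <- seqs[seq_len(max_reads)]
  if (length(unique(seqs)) == 1)
    return(list(contig = seqs[1], depth = length(seqs), n_mapped = length(seqs),
                iterations = 0L))
  ref <- seqs[seed_read_index(seqs)]
  bases5 <- c("A", "C", "G", "T", "-")
  n_mapped <- 0L
  for (it in seq_len(max_iter)) {
    L <- nchar(ref)
    mp <- cpp_map_reads(ref, seqs, k = k, min_ident = min_identity,
                        min_cov = min_coverage, band = band)
    n_mapped <- sum(mp$mapped)
    if (n_mapped == 0) break
    counts <- cpp_pileup(L, mp$ref_start, mp$aligned)
    cov <- colSums(counts)
    top <- max.col(t(counts), ties.method = "first")
    cons <- bases5[top]
    refv <- strsplit(ref, "", fixed = TRUE)[[1]]
    cons[cov == 0] <- refv[cov == 0]
    drop <- cons == "-" & cov > 0
    new_ref <- paste(cons[!drop], collapse = "")
    # end extensions from read overhangs
    oriented <- ifelse(!is.na(mp$strand) & mp$strand == "-", revcomp(seqs),
                       seqs)
    right <- which(mp$mapped & mp$ref_end >= L - 3)
    left <- which(mp$mapped & mp$ref_start <= 3)
    ext_r <- overhang_consensus(
      substring(oriented[right], mp$q_end[right] + (L - mp$ref_end[right]) + 1),
      min_extend_depth)
    ext_l_rev <- overhang_consensus(
      stringi::stri_reverse(
        substring(oriented[left], 1, mp$q_start[left] - mp$ref_start[left])),
      min_extend_depth)
    ext_l <- stringi::stri_reverse(ext_l_rev)
    cand <- paste0(ext_l, new_ref, ext_r)
    if (cand == ref) break
    ref <- cand
  }
  mp <- cpp_map_reads(ref, seqs, k = k, min_ident = min_identity,
                      min_cov = min_coverage, band = band)
  depth <- sum(mp$span[mp$mapped]) / nchar(ref)
  list(contig = ref, depth = depth, n_mapped = sum(mp$mapped),
       iterations = it)
}

# read whose k-mers are most frequent across the cluster (a central read)
seed_read_index <- function(seqs, k = 13) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  tab <- table(unlist(km))
  scores <- vapply(km, function(x) sum(tab[x]), 1)
  which.max(scores)
}

# majority consensus of left-aligned overhang strings, up to the first
# column whose majority base has support below min_depth (so extension
# stops where copies disagree, i.e. at the element boundary); capped at
# 80 columns per call
overhang_consensus <- function(ov, min_depth, max_ext = 80) {
  ov <- ov[nchar(ov) > 0]
  if (length(ov) < min_depth) return("")
  width <- min(max(nchar(ov)), max_ext)
  out <- character(0)
  for (j in seq_len(width)) {
    b <- substr(ov, j, j)
    b <- b[b != ""]
    if (length(b) < min_depth) break
    tb <- sort(table(b), decreasing = TRUE)
    if (tb[1] < min_depth) break
    out <- c(out, names(tb)[1])
  }
  paste(out, collapse = "")
}

#' Annotate a cluster contig against repeat and domain databases
#'
#' Nucleotide search of the contig against a repeat reference set plus
#' six-frame translated search against a protein domain set (BLOSUM80).
#' The best label wins by significance, with ties broken by higher
#' identity, then longer span, then lexicographic name; `"unclassified"`
#' when no hit passes the significance threshold.
#'
#' @param contig Contig sequence.
#' @param repeat_db Named character vector / `DNAStringSet` / FASTA path of
#'   repeat references (nucleotide), or NULL.
#' @param domain_db Named character vector / `AAStringSet` / FASTA path of
#'   domain peptides, or NULL.
#' @param max_evalue Significance threshold (default 1e-5).
#' @return List with `label`, `evidence` (`nucleotide`, `domain` or
#'   `unclassified`), `score`, `identity`, `evalue`, and the full `hits`
#'   table.
#' @export
annotate_cluster <- function(contig, repeat_db = NULL, domain_db = NULL,
                             max_evalue = 1e-5) {
  nt_db <- if (!is.null(repeat_db)) as_seq_vector(repeat_db) else character(0)
  aa_db <- if (!is.null(domain_db)) as_aa_vector(domain_db) else character(0)
  if (length(nt_db) == 0 && length(aa_db) == 0) {
    warning("both databases empty; contig left unclassified")
    return(list(label = "unclassified", evidence = "unclassified",
                score = NA_real_, identity = NA_real_, evalue = NA_real_,
                hits = NULL))
  }
  hits <- list()
  for (nm in names(nt_db)) {
    h <- seeded_nt_hit(nt_db[[nm]], contig)
    if (is.null(h)) next
    ev <- alignment_evalue(h$score, nchar(nt_db[[nm]]), nchar(contig),
                           match = 1, mismatch = -2)
    hits[[length(hits) + 1]] <- data.frame(
      name = nm, evidence = "nucleotide", score = h$score,
      identity = h$identity, span = h$span, evalue = ev,
      stringsAsFactors = FALSE)
  }
  if (length(aa_db)) {
    frames <- six_frame(contig)
    for (nm in names(aa_db)) {
      best <- NULL
      for (f in seq_along(frames)) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(aa_db[[nm]]), frames[[f]], type = "local",
          substitutionMatrix = "BLOSUM80", gapOpening = 10, gapExtension = 1)
        sc <- Biostrings::score(pa)
        if (is.null(best) || sc > best$score)
          best <- list(score = sc,
                       identity = Biostrings::pid(pa) / 100,
                       span = Biostrings::nchar(pa))
      }
      ev <- protein_evalue(best$score, nchar(aa_db[[nm]]),
                           nchar(contig) / 3)
      hits[[length(hits) + 1]] <- data.frame(
        name = nm, evidence = "domain", score = best$score,
        identity = best$identity, span = best$span, evalue = ev,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  ok <- hits[!is.na(hits$evalue) & hits$evalue <= max_evalue, , drop = FALSE]
  if (is.null(hits) || nrow(ok) == 0)
    return(list(label = "unclassified", evidence = "unclassified",
                score = NA_real_, identity = NA_real_, evalue = NA_real_,
                hits = hits))
  ok <- ok[order(ok$evalue, -ok$identity, -ok$span, ok$name), , drop = FALSE]
  list(label = ok$name[1], evidence = ok$evidence[1], score = ok$score[1],
       identity = ok$identity[1], evalue = ok$evalue[1], hits = hits)
}

# best seeded + banded local nucleotide alignment of query vs subject
# (either strand); NULL when no word seed exists
seeded_nt_hit <- function(query, subject, word = 12, band = 100,
                          match = 1, mismatch = -2, gap = -2) {
  best <- NULL
  for (st in c("+", "-")) {
    subj <- if (st == "+") subject else revcomp(subject)
    runs <- cpp_word_runs(query, subj, word, both_strands = FALSE)
    if (nrow(runs) == 0) next
    r <- runs[which.max(runs$length), ]
    d0 <- r$b_start - r$a_start
    al <- cpp_banded_align(query, subj, as.integer(d0), as.integer(band),
                           match, mismatch, gap)
    if (is.null(best) || al$score > best$score) {
      best <- al; best$strand <- st
    }
  }
  best
}

as_aa_vector <- function(x) {
  if (inherits(x, "AAStringSet")) return(stats::setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      grepl("\\.(fa|faa|fasta)$", x)) {
    s <- Biostrings::readAAStringSet(x)
    return(stats::setNames(as.character(s), sub("\\s.*", "", names(s))))
  }
  x
}
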