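# Reconstruction of full repeat elements from long reads, seeded by
# cluster contigs: hit search, dotplot-style copy detection, multiple-
# alignment consensus, short-read refinement, domain and terminal-repeat
# annotation.

#' Search long reads for a contig, keeping the best 20 hits
#'
#' Seeded local alignment on both strands; hits are ranked by significance
#' ascending, then score descending, then read id (rank-stable under input
#' permutation), and the top `top` are returned.
#'
#' @param contig Query contig (>= 100 bp).
#' @param long_reads A [read_set()] or named character vector of long
#'   reads.
#' @param top Hits to keep (default 20).
#' @param max_evalue Significance threshold (default 1e-5); no hit above it
#'   means an empty result and downstream reconstruction aborts.
#' @param word Seed word size.
#' @return `data.frame` of hits: read_id, score, evalue, read interval
#'   (0-based half-open, forward-strand coordinates), strand.
#' @export
search_long_reads <- function(contig, long_reads, top = 20,
                              max_evalue = 1e-5, word = 13) {
  stopifnot(nchar(contig) >= 100)
  reads <- if (inherits(long_reads, "read_set")) read_seqs(long_reads)
           else long_reads
  if (is.null(names(reads))) names(reads) <- sprintf("LR%06d", seq_along(reads))
  rows <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    h <- seeded_nt_hit(contig, reads[[i]], word = word, band = 150,
                       match = 1, mismatch = -2, gap = -2)
    if (is.null(h) || h$score <= 0) next
    ev <- alignment_evalue(h$score, nchar(contig), nchar(reads[[i]]),
                           match = 1, mismatch = -2)
    if (ev > max_evalue) next
    # subject interval back to forward coordinates when hit is on '-'
    n <- nchar(reads[[i]])
    b0 <- if (h$strand == "+") h$b_start else n - h$b_end
    b1 <- if (h$strand == "+") h$b_end else n - h$b_start
    rows[[i]] <- data.frame(read_id = names(reads)[i], score = h$score,
                            evalue = ev, start = b0, end = b1,
                            strand = h$strand, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits)) return(data.frame(read_id = character(), score = numeric(),
                                       evalue = numeric(), start = integer(),
                                       end = integer(), strand = character()))
  hits <- hits[order(hits$evalue, -hits$score, hits$read_id), , drop = FALSE]
  rownames(hits) <- NULL
  head(hits, top)
}

#' Detect repeat copies on hit reads and extend to element boundaries
#'
#' For each hit read, the hit interval is extended to the element
#' boundaries by diagonal-run analysis of the word-match matrix between the
#' read and the contig (a dotplot surrogate: word size 10, runs of at least
#' 3 consecutive word matches, chained along the read). A copy is flagged
#' `full` when terminal repeats are detected on it and its length reaches
#' 90% of the modal copy length; otherwise `fragmented`. Reads with no
#' diagonal structure keep the unmodified hit interval.
#'
#' @param hits Hit table from [search_long_reads()].
#' @param long_reads The long reads searched.
#' @param contig The query contig.
#' @param word Dotplot word size (default 10).
#' @param min_run Minimum diagonal run length in bases (default
#'   `word + 2`, i.e. 3 consecutive word matches).
#' @param boundary_window Extension window beyond the outermost runs, bp.
#' @return List with `copies` (oriented copy sequences, named by read id)
#'   and `table` (read_id, start, end, strand, length, full flag).
#' @export
detect_copies <- function(hits, long_reads, contig, word = 10,
                          min_run = word + 2, boundary_window = 50) {
  stopifnot(nrow(hits) >= 1)
  reads <- if (inherits(long_reads, "read_set")) read_seqs(long_reads)
           else long_reads
  res <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    rid <- hits$read_id[i]
    rd <- reads[[rid]]
    n <- nchar(rd)
    oriented <- if (hits$strand[i] == "+") rd else revcomp(rd)
    h0 <- if (hits$strand[i] == "+") hits$start[i] else n - hits$end[i]
    h1 <- if (hits$strand[i] == "+") hits$end[i] else n - hits$start[i]
    runs <- cpp_word_runs(contig, oriented, word, both_strands = FALSE)
    runs <- runs[runs$length >= min_run, , drop = FALSE]
    if (nrow(runs) == 0) {
      s0 <- h0; s1 <- h1
    } else {
      # a partial contig anchored in one part of the element must still
      # chain to the matches of its other occurrences on the read (e.g.
      # the contig's LTR matching the element's far LTR); the 25-bp
      # support filter below keeps chance word matches from exploiting
      # this window
      gap_max <- max(nchar(contig), 5000)
      cls <- chain_runs(runs, gap_max)
      # the chain overlapping the hit interval
      pick <- NULL
      for (cc in cls) {
        lo <- min(cc$b_start); hi <- max(cc$b_start + cc$length)
        if (lo < h1 && hi > h0) pick <- if (is.null(pick)) cc else rbind(pick, cc)
      }
      if (is.null(pick)) { s0 <- h0; s1 <- h1 } else {
        # trim weakly supported terminal run groups (single chance word
        # matches would otherwise drag the boundary outwards)
        pick <- pick[order(pick$b_start), , drop = FALSE]
        grp <- cumsum(c(FALSE, pick$b_start[-1] >
                          (pick$b_start + pick$length)[-nrow(pick)] + 200))
        support <- tapply(pick$length, grp, sum)
        ok_grp <- as.integer(names(support)[support >= 25])
        if (length(ok_grp)) {
          keep <- grp %in% seq(min(ok_grp), max(ok_grp))
          pick <- pick[keep, , drop = FALSE]
        }
        s0 <- max(0, min(pick$b_start) - boundary_window)
        s1 <- min(n, max(pick$b_start + pick$length) + boundary_window)
      }
    }
    copy <- subseq0(oriented, s0, s1)
    res[[i]] <- list(read_id = rid, start = s0, end = s1,
                     strand = hits$strand[i], seq = copy)
  }
  lens <- vapply(res, function(x) nchar(x$seq), 1)
  modal <- as.numeric(names(sort(table(round(lens, -2)), decreasing = TRUE))[1])
  tab <- do.call(rbind, lapply(res, function(x) {
    tr <- if (nchar(x$seq) >= 400) detect_terminal_repeats(x$seq)
          else list(kind = "none")
    data.frame(read_id = x$read_id, start = x$start, end = x$end,
               strand = x$strand, length = nchar(x$seq),
               full = !is.null(tr$kind) && tr$kind != "none" &&
                 nchar(x$seq) >= 0.9 * modal,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  copies <- stats::setNames(vapply(res, `[[`, "", "seq"),
                            vapply(res, `[[`, "", "read_id"))
  list(copies = copies, table = tab)
}

#' Majority consensus of repeat copies
#'
#' `method = "star"` (default): the copy closest to the median length is
#' the scaffold; every other copy is globally aligned to it, copies are
#' stacked in scaffold coordinates, and each column takes the majority
#' base; gap-majority columns are removed and exact ties become IUPAC
#' ambiguity codes. Deterministic and order-invariant. `method = "mafft"`
#' delegates the multiple alignment to the mafft binary (pluggable
#' aligner, better for indel-rich copies), with the same column rule.
#'
#' @param copies Character vector of copy sequences (>= `min_copies`).
#' @param min_copies Minimum copies required (default 2; a warning below
#'   10).
#' @param method `"star"` or `"mafft"`.
#' @return Consensus sequence.
#' @export
msa_consensus <- function(copies, min_copies = 2,
                          method = c("star", "mafft")) {
  method <- match.arg(method)
  copies <- unname(as.character(copies))
  if (length(copies) < min_copies)
    stop("need at least ", min_copies, " copies, got ", length(copies))
  if (length(copies) < 10)
    warning("consensus from only ", length(copies), " copies")
  if (length(unique(copies)) == 1) return(copies[1])
  if (method == "mafft") return(mafft_consensus(copies))
  lens <- nchar(copies)
  # scaffold near the upper length quartile: fragments are subsequences of
  # the full form, so the scaffold must come from the long end, while the
  # quartile still guards against rare over-merged outliers
  target <- stats::quantile(lens, 0.75, type = 1)
  cand <- which(abs(lens - target) == min(abs(lens - target)))
  scaffold <- copies[cand[order(copies[cand])[1]]]
  L <- nchar(scaffold)
  others <- copies[-match(scaffold, copies)]  # drops one scaffold instance
  starts <- integer(0); projs <- character(0)
  for (cp in others) {
    pr <- star_project(cp, scaffold)
    if (is.null(pr)) next
    projs <- c(projs, pr$proj)
    starts <- c(starts, pr$start)
  }
  starts <- c(starts, 0L); projs <- c(projs, scaffold)
  counts <- cpp_pileup(L, starts, projs)
  consensus_from_counts(counts, strsplit(scaffold, "", fixed = TRUE)[[1]])
}

# align one copy to the scaffold (anchored banded alignment; Biostrings
# global-local fallback when no word anchor exists) and project its bases
# into scaffold coordinates
star_project <- function(copy, scaffold, band = 150) {
  runs <- cpp_word_runs(copy, scaffold, 12, both_strands = FALSE)
  if (nrow(runs) > 0) {
    d <- runs$b_start - runs$a_start
    bin <- round(d / 50)
    w <- tapply(runs$length, bin, sum)
    d0 <- round(stats::median(d[bin == as.numeric(names(w)[which.max(w)])]))
    al <- cpp_banded_align(copy, scaffold, as.integer(d0), as.integer(band),
                           1, -1, -2, keep_aln = TRUE)
    if (al$span > 0) {
      pv <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
      sv <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
      keep <- sv != "-"
      return(list(start = al$b_start,
                  proj = paste(pv[keep], collapse = "")))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(copy), Biostrings::DNAString(scaffold),
    type = "global-local", gapOpening = 6, gapExtension = 1)
  pv <- strsplit(as.character(Biostrings::alignedPattern(pa)), "",
                 fixed = TRUE)[[1]]
  sv <- strsplit(as.character(Biostrings::alignedSubject(pa)), "",
                 fixed = TRUE)[[1]]
  keep <- sv != "-"
  list(start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       proj = paste(pv[keep], collapse = ""))
}

consensus_from_counts <- function(counts, fallback) {
  bases5 <- c("A", "C", "G", "T", "-")
  L <- ncol(counts)
  cov <- colSums(counts)
  mx <- apply(counts, 2, max)
  out <- character(L)
  for (j in seq_len(L)) {
    if (cov[j] == 0) { out[j] <- fallback[j]; next }
    winners <- bases5[counts[, j] == mx[j]]
    if ("-" %in% winners && length(winners) == 1) { out[j] <- ""; next }
    winners <- setdiff(winners, "-")
    out[j] <- if (length(winners) == 1) winners else iupac_code(winners)
  }
  paste(out, collapse = "")
}

mafft_consensus <- function(copies) {
  if (Sys.which("mafft") == "") stop("mafft binary not found on PATH")
  td <- tempfile("msa"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  infile <- file.path(td, "in.fasta")
  x <- Biostrings::DNAStringSet(copies)
  names(x) <- sprintf("c%03d", seq_along(copies))
  Biostrings::writeXStringSet(x, infile)
  out <- system2("mafft", c("--auto", "--quiet", infile), stdout = TRUE)
  aln <- Biostrings::readDNAStringSet(textConnection(paste(out, collapse = "\n")),
                                      format = "fasta")
  M <- do.call(rbind, strsplit(toupper(as.character(aln)), "", fixed = TRUE))
  cons <- apply(M, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    winners <- names(tb)[tb == tb[1]]
    if (identical(winners, "-")) return("")
    winners <- setdiff(winners, "-")
    if (length(winners) == 1) winners else iupac_code(winners)
  })
  paste(cons, collapse = "")
}

#' Refine a consensus by iterative short-read mapping
#'
#' Per round, short reads are mapped under the clustering similarity
#' contract, and each position covered by at least `min_depth` reads is set
#' to the majority base among covering reads. Stops on convergence (no
#' change) or after `rounds` rounds. Zero-coverage positions are never
#' changed; no indels are introduced.
#'
#' @param consensus Starting consensus (non-empty).
#' @param short_reads A [read_set()] or character vector.
#' @param rounds Maximum refinement rounds (default 3).
#' @param min_depth Depth required to change a base (default 3).
#' @param params [similarity_params()] giving the mapping contract.
#' @return Refined consensus sequence.
#' @export
map_refine <- function(consensus, short_reads, rounds = 3, min_depth = 3,
                       params = similarity_params()) {
  stopifnot(nchar(consensus) > 0)
  seqs <- if (inherits(short_reads, "read_set")) short_reads$reads$seq
          else short_reads
  bases4 <- c("A", "C", "G", "T")
  for (r in seq_len(rounds)) {
    L <- nchar(consensus)
    mp <- cpp_map_reads(consensus, seqs, k = 11,
                        min_ident = params$min_identity,
                        min_cov = params$min_coverage, band = 30)
    if (!any(mp$mapped)) break
    counts <- cpp_pileup(L, mp$ref_start, mp$aligned)[1:4, , drop = FALSE]
    cov <- colSums(counts)
    top <- max.col(t(counts), ties.method = "first")
    cur <- strsplit(consensus, "", fixed = TRUE)[[1]]
    newv <- ifelse(cov >= min_depth, bases4[top], cur)
    new_cons <- paste(newv, collapse = "")
    if (new_cons == consensus) break
    consensus <- new_cons
  }
  consensus
}

# orient a consensus by its protein domains: when the majority of chained
# domain hits lie on the minus strand, the element was assembled in
# reverse complement and is flipped (with re-annotation)
orient_by_domains <- function(cons, domain_db, max_evalue = 1e-5) {
  doms <- annotate_domains(cons, domain_db, max_evalue = max_evalue)
  flipped <- FALSE
  if (nrow(doms) > 0 && sum(doms$strand == "-") > nrow(doms) / 2) {
    cons <- revcomp(cons)
    doms <- annotate_domains(cons, domain_db, max_evalue = max_evalue)
    flipped <- TRUE
  }
  list(sequence = cons, domains = doms, flipped = flipped)
}

# six-frame translation; returns list of AAString (3 forward, 3 reverse)
six_frame <- function(seq) {
  s <- Biostrings::DNAString(gsub("[^ACGTacgt]", "N", seq))
  rc <- Biostrings::reverseComplement(s)
  frames <- list()
  for (f in 0:2) {
    for (x in list(s, rc)) {
      n <- length(x) - f
      n <- n - n %% 3
      if (n < 3) { frames[[length(frames) + 1]] <- Biostrings::AAString("") ; next }
      frames[[length(frames) + 1]] <-
        suppressWarnings(Biostrings::translate(Biostrings::subseq(x, f + 1, f + n),
                                               if.fuzzy.codon = "solve"))
    }
  }
  # order: +1 -1 +2 -2 +3 -3
  names(frames) <- c("+1", "-1", "+2", "-2", "+3", "-3")
  frames
}

#' Annotate protein domains on a consensus
#'
#' Six-frame translated local alignment against a user-supplied domain
#' peptide set (BLOSUM80 scoring), keeping hits below the significance
#' threshold and chaining them left-to-right without overlap (greedy by
#' score). The reported order (e.g. GAG-PR-RT-RH-INT) is the basis for
#' element classification.
#'
#' @param consensus Consensus sequence.
#' @param domain_db Named peptides (character / `AAStringSet` / FASTA
#'   path); names are domain labels, optionally `family__DOMAIN`.
#' @param max_evalue Significance threshold.
#' @return `data.frame` of chained hits ordered by position: domain, frame,
#'   strand, start, end (nt, 0-based half-open on the consensus), score.
#' @export
annotate_domains <- function(consensus, domain_db, max_evalue = 1e-5) {
  aa_db <- as_aa_vector(domain_db)
  if (length(aa_db) == 0) stop("domain_db must be non-empty")
  frames <- six_frame(consensus)
  L <- nchar(consensus)
  rows <- list()
  for (nm in names(aa_db)) {
    for (fi in seq_along(frames)) {
      fr <- frames[[fi]]
      if (length(fr) == 0) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(aa_db[[nm]]), fr, type = "local",
        substitutionMatrix = "BLOSUM80", gapOpening = 10, gapExtension = 1)
      sc <- Biostrings::score(pa)
      ev <- protein_evalue(sc, nchar(aa_db[[nm]]), L / 3)
      if (ev > max_evalue) next
      fname <- names(frames)[fi]
      off <- as.integer(substr(fname, 2, 2)) - 1L
      aa0 <- Biostrings::start(Biostrings::subject(pa)) - 1L
      aa1 <- Biostrings::end(Biostrings::subject(pa))
      if (startsWith(fname, "+")) {
        nt0 <- off + 3L * aa0; nt1 <- off + 3L * aa1
      } else {
        nt1 <- L - (off + 3L * aa0); nt0 <- L - (off + 3L * aa1)
      }
      rows[[length(rows) + 1]] <- data.frame(
        domain = nm, frame = fname,
        strand = substr(fname, 1, 1), start = nt0, end = nt1,
        score = sc, evalue = ev, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits)) return(data.frame(domain = character(), frame = character(),
                                       strand = character(), start = integer(),
                                       end = integer(), score = numeric(),
                                       evalue = numeric()))
  # greedy collinear chaining: keep best-scoring non-overlapping hits
  hits <- hits[order(-hits$score), , drop = FALSE]
  kept <- hits[0, ]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (nrow(kept) == 0 ||
        all(h$end <= kept$start | h$start >= kept$end))
      kept <- rbind(kept, h)
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Detect terminal repeats on a consensus
#'
#' Direct terminal repeats of at least 100 bp at >= 80% identity are
#' reported as an LTR pair; otherwise terminal inverted repeats of at
#' least 10 bp are reported as a TIR pair; otherwise the element is
#' flagged truncated (`kind = "none"`).
#'
#' @param consensus Sequence (>= 400 bp).
#' @param min_ltr,min_ltr_identity LTR length/identity thresholds.
#' @param min_tir TIR length threshold.
#' @param end_window How far from each end to search, bp.
#' @return List with `kind` (`"LTR"`, `"TIR"` or `"none"`) and, when
#'   found, `five` and `three` intervals (0-based half-open) plus
#'   `identity`.
#' @export
detect_terminal_repeats <- function(consensus, min_ltr = 100,
                                    min_ltr_identity = 0.8, min_tir = 10,
                                    end_window = 3000) {
  L <- nchar(consensus)
  stopifnot(L >= 400)
  W <- min(floor(L / 2), end_window)
  pre <- subseq0(consensus, 0, W)
  suf <- subseq0(consensus, L - W, L)
  al <- cpp_local_align(pre, suf, 1, -1, -2)
  if (al$span >= min_ltr && al$identity >= min_ltr_identity) {
    return(list(kind = "LTR",
                five = c(al$a_start, al$a_end),
                three = c(L - W + al$b_start, L - W + al$b_end),
                identity = al$identity))
  }
  # TIRs: compare element start with reverse complement of element end
  W2 <- min(floor(L / 2), 200)
  pre2 <- subseq0(consensus, 0, W2)
  suf2 <- revcomp(subseq0(consensus, L - W2, L))
  al2 <- cpp_local_align(pre2, suf2, 1, -2, -3)
  near_ends <- al2$a_start <= 20 && al2$b_start <= 20
  if (al2$span >= min_tir && al2$identity >= 0.9 && near_ends) {
    return(list(kind = "TIR",
                five = c(al2$a_start, al2$a_end),
                three = c(L - W2 + (W2 - al2$b_end), L - W2 + (W2 - al2$b_start)),
                identity = al2$identity))
  }
  list(kind = "none")
}

#' Annotate a 35S rDNA consensus
#'
#' Locates the 18S, 5.8S and 26S rRNA genes by seeded local alignment,
#' enforces the order 18S < 5.8S < 26S (retrying on the reverse complement
#' when the genes lie on the minus strand), labels the intervals between
#' genes ITS1/ITS2 and the flanks IGS. Missing genes give a partial
#' annotation with a warning.
#'
#' @param consensus The reconstructed unit.
#' @param rRNA_refs Named references for `18S`, `5.8S`, `26S` (character /
#'   `DNAStringSet` / FASTA path).
#' @param max_evalue Significance threshold.
#' @return List with `features` (data.frame: feature, start, end) and
#'   `flipped` (TRUE if the reverse complement was annotated).
#' @export
annotate_35s <- function(consensus, rRNA_refs, max_evalue = 1e-5) {
  refs <- as_seq_vector(rRNA_refs)
  genes <- c("18S", "5.8S", "26S")
  stopifnot(all(genes %in% names(refs)))
  locate <- function(seqs) {
    out <- list()
    for (g in genes) {
      h <- seeded_nt_hit(refs[[g]], seqs, word = 12, band = 100,
                         match = 1, mismatch = -2)
      if (is.null(h)) next
      ev <- alignment_evalue(h$score, nchar(refs[[g]]), nchar(seqs),
                             match = 1, mismatch = -2)
      if (ev > max_evalue) next
      n <- nchar(seqs)
      b0 <- if (h$strand == "+") h$b_start else n - h$b_end
      b1 <- if (h$strand == "+") h$b_end else n - h$b_start
      out[[g]] <- data.frame(feature = g, start = b0, end = b1,
                             strand = h$strand, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  feats <- locate(consensus)
  flipped <- FALSE
  if (!is.null(feats) && sum(feats$strand == "-") > nrow(feats) / 2) {
    consensus <- revcomp(consensus)
    feats <- locate(consensus)
    flipped <- TRUE
  }
  if (is.null(feats) || nrow(feats) < 3) {
    warning("partial 35S annotation: found ",
            if (is.null(feats)) 0 else nrow(feats), " of 3 rRNA genes")
    if (is.null(feats))
      return(list(features = data.frame(feature = character(),
                                        start = integer(), end = integer()),
                  flipped = flipped))
  }
  feats <- feats[order(feats$start), , drop = FALSE]
  found <- feats$feature
  if (!identical(found, intersect(genes, found)))
    warning("rRNA genes out of order 18S < 5.8S < 26S")
  L <- nchar(consensus)
  spacers <- list()
  add_sp <- function(name, s, e) {
    if (e > s) spacers[[length(spacers) + 1]] <<-
        data.frame(feature = name, start = s, end = e, strand = "+",
                   stringsAsFactors = FALSE)
  }
  if (all(c("18S", "5.8S") %in% found))
    add_sp("ITS1", feats$end[feats$feature == "18S"],
           feats$start[feats$feature == "5.8S"])
  if (all(c("5.8S", "26S") %in% found))
    add_sp("ITS2", feats$end[feats$feature == "5.8S"],
           feats$start[feats$feature == "26S"])
  add_sp("IGS", 0, min(feats$start))
  add_sp("IGS", max(feats$end), L)
  out <- rbind(feats, if (length(spacers)) do.call(rbind, spacers))
  out <- out[order(out$start), c("feature", "start", "end")]
  rownames(out) <- NULL
  list(features = out, flipped = flipped)
}

#' Reconstruct a repeat element end to end
#'
#' contig -> long-read search -> copy detection -> consensus (->
#' optional short-read refinement), the full reconstruction path for one
#' abundant repeat family.
#'
#' @param contig Cluster contig seeding the reconstruction.
#' @param long_reads Long reads.
#' @param short_reads Optional short reads for [map_refine()].
#' @param top Long-read hits to use (default 20).
#' @param min_copies Minimum copies for a consensus.
#' @param domain_db,rRNA_refs Optional databases for annotation.
#' @return Object of class `repeat_consensus`: `sequence`, `copies` table,
#'   `terminal_repeats`, `domains` (if `domain_db` given), `n_copies`.
#' @export
reconstruct_element <- function(contig, long_reads, short_reads = NULL,
                                top = 20, min_copies = 2, domain_db = NULL,
                                rRNA_refs = NULL) {
  hits <- search_long_reads(contig, long_reads, top = top)
  if (nrow(hits) == 0)
    stop("no long-read hit above threshold; reconstruction aborted")
  det <- detect_copies(hits, long_reads, contig)
  cons <- msa_consensus(det$copies, min_copies = min_copies)
  if (!is.null(short_reads)) cons <- map_refine(cons, short_reads)
  doms <- NULL
  if (!is.null(domain_db)) {
    ori <- orient_by_domains(cons, domain_db)
    cons <- ori$sequence
    doms <- ori$domains
  }
  tr <- if (nchar(cons) >= 400) detect_terminal_repeats(cons) else
    list(kind = "none")
  r35 <- if (!is.null(rRNA_refs)) annotate_35s(cons, rRNA_refs) else NULL
  structure(list(sequence = cons, copies = det$table,
                 terminal_repeats = tr, domains = doms, rdna_features = r35,
                 n_copies = length(det$copies)),
            class = "repeat_consensus")
}

#' @export
print.repeat_consensus <- function(x, ...) {
  cat(sprintf("<repeat_consensus> %d bp from %d copies; terminal repeats: %s\n",
              nchar(x$sequence), x$n_copies, x$terminal_repeats$kind))
  if (!is.null(x$domains) && nrow(x$domains))
    cat("domains:", paste(x$domains$domain, collapse = "-"), "\n")
  invisible(x)
}
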