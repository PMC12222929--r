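# 5S rDNA: gene and monomer reconstruction, long-read array scanning,
# organization classification, NTS length variants and region-wise
# divergence.
#
# Array classes follow the hit-geometry rule: "regular" needs at least
# five monomers without major gaps on a read longer than 6000 bp;
# "potentially regular" keeps the gap condition but fails the read-length
# or monomer-count requirement; "pseudogenic" has large inter-monomer gaps
# (sequence fallen below the detection threshold); "sparse" is a single
# monomer. A "major gap" is operationalized as consecutive monomer starts
# more than 1.5 periods apart (gap_frac = 0.5), configurable.

#' Reconstruct the 5S gene by mapping short reads to a seed gene
#'
#' Maps reads at relaxed identity (75%, admitting diverged genes), calls
#' the majority consensus over the seed coordinates, and reports the
#' mapped read fraction of the total (the coverage-based abundance proxy).
#'
#' @param short_reads A [read_set()] or character vector.
#' @param seed_gene Seed gene sequence (80-200 bp).
#' @param min_identity Mapping identity (default 0.75).
#' @param min_coverage Minimum aligned fraction of `min(read, gene)`.
#' @return List with `gene` (consensus) and `mapped_fraction`.
#' @export
reconstruct_gene <- function(short_reads, seed_gene, min_identity = 0.75,
                             min_coverage = 0.5) {
  lg <- nchar(seed_gene)
  stopifnot(lg >= 80, lg <= 200)
  seqs <- if (inherits(short_reads, "read_set")) short_reads$reads$seq
          else short_reads
  mp <- cpp_map_reads(seed_gene, seqs, k = 8, min_ident = min_identity,
                      min_cov = min_coverage, band = 20)
  frac <- mean(mp$mapped)
  if (!any(mp$mapped)) return(list(gene = seed_gene, mapped_fraction = 0))
  counts <- cpp_pileup(lg, mp$ref_start, mp$aligned)
  gene <- consensus_from_counts(counts, strsplit(seed_gene, "", fixed = TRUE)[[1]])
  list(gene = gene, mapped_fraction = frac)
}

# Locate gene copies on one read: seeded banded local alignment, both
# strands, hits thresholded at max_e and overlap-merged (keep the more
# significant; prevents double counting at tandem junctions).
scan_gene_hits <- function(read, gene, max_e = 1e-4, word = 10,
                           match = 1, mismatch = -3, gap = -4) {
  n <- nchar(read)
  lg <- nchar(gene)
  if (n < word) return(empty_hits())
  rows <- list()
  for (st in c("+", "-")) {
    oriented <- if (st == "+") read else revcomp(read)
    runs <- cpp_word_runs(gene, oriented, word, both_strands = FALSE)
    if (nrow(runs) == 0) next
    for (cc in chain_runs(runs, gap_max = lg)) {
      d0 <- round(stats::median(cc$b_start - cc$a_start))
      spread <- diff(range(cc$b_start - cc$a_start))
      al <- cpp_banded_align(gene, oriented, as.integer(d0),
                             as.integer(spread + 30), match, mismatch, gap)
      if (al$score <= 0) next
      ev <- alignment_evalue(al$score, lg, n, match = match,
                             mismatch = mismatch)
      if (ev > max_e) next
      b0 <- if (st == "+") al$b_start else n - al$b_end
      b1 <- if (st == "+") al$b_end else n - al$b_start
      rows[[length(rows) + 1]] <- data.frame(
        start = b0, end = b1, strand = st, evalue = ev,
        identity = al$identity, score = al$score, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else return(empty_hits())
  hits <- hits[order(hits$start), , drop = FALSE]
  # merge overlapping hits, keeping the more significant
  keep <- rep(TRUE, nrow(hits))
  i <- 1
  while (i < nrow(hits)) {
    j <- i + 1
    while (j <= nrow(hits) && keep[i] &&
           hits$start[j] < hits$end[i] - 0.5 * lg) {
      if (hits$evalue[j] < hits$evalue[i]) { keep[i] <- FALSE } else keep[j] <- FALSE
      j <- j + 1
    }
    i <- i + 1
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             evalue = numeric(), identity = numeric(), score = numeric())
}

#' Reconstruct the complete 5S monomer from long reads
#'
#' Reads carrying at least two gene hits define monomer candidates (gene
#' start to next gene start); candidates near the modal length are aligned
#' and majority-called, and the modal spacer defines the NTS length.
#'
#' @param long_reads A [read_set()] or named character vector.
#' @param gene The 5S gene sequence.
#' @param max_e Hit significance threshold (default 1e-4).
#' @param length_tol Relative deviation from the modal monomer length
#'   tolerated in the consensus set.
#' @return Object of class `monomer_5s`: `monomer`, `gene`, `nts`,
#'   `control_regions` (canonical defaults on the gene), `n_reads`,
#'   `n_monomers`.
#' @export
build_monomer <- function(long_reads, gene, max_e = 1e-4, length_tol = 0.2) {
  reads <- if (inherits(long_reads, "read_set")) read_seqs(long_reads)
           else long_reads
  monomers <- character(0)
  used_reads <- 0L
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    hits <- scan_gene_hits(rd, gene, max_e = max_e)
    if (nrow(hits) < 2) next
    by_strand <- split(hits, hits$strand)
    got <- FALSE
    for (st in names(by_strand)) {
      h <- by_strand[[st]]
      if (nrow(h) < 2) next
      oriented <- if (st == "+") rd else revcomp(rd)
      n <- nchar(rd)
      s <- if (st == "+") h$start else n - h$end
      s <- sort(s)
      for (k in seq_len(length(s) - 1)) {
        monomers <- c(monomers, subseq0(oriented, s[k], s[k + 1]))
        got <- TRUE
      }
    }
    if (got) used_reads <- used_reads + 1L
  }
  if (length(monomers) < 3)
    stop("no regular periodicity: found ", length(monomers),
         " monomer candidates on ", used_reads, " reads")
  lens <- vapply(monomers, nchar, 1L, USE.NAMES = FALSE)
  modal <- as.numeric(names(sort(table(round(lens, -1)), decreasing = TRUE))[1])
  ok <- abs(lens - modal) <= length_tol * modal
  if (sum(ok) < 3) stop("no regular periodicity: monomer lengths too variable")
  cons <- msa_consensus(monomers[ok], min_copies = 2)
  al <- cpp_local_align(gene, cons, 1, -2, -3)
  gene_end <- if (al$span >= 0.5 * nchar(gene)) al$b_end else nchar(gene)
  structure(list(monomer = cons,
                 gene = subseq0(cons, 0, gene_end),
                 nts = subseq0(cons, gene_end, nchar(cons)),
                 control_regions = list(A_box = c(49L, 60L), IE = c(66L, 72L),
                                        C_box = c(79L, 97L)),
                 n_reads = used_reads, n_monomers = sum(ok)),
            class = "monomer_5s")
}

#' @export
print.monomer_5s <- function(x, ...) {
  cat(sprintf("<monomer_5s> %d bp (gene %d bp + NTS %d bp) from %d monomers on %d reads\n",
              nchar(x$monomer), nchar(x$gene), nchar(x$nts), x$n_monomers,
              x$n_reads))
  invisible(x)
}

#' Scan one long read for 5S monomer hits
#'
#' Local alignment of the gene region of the monomer against the read on
#' both strands; hits at significance <= `max_e` are reported with a
#' visualization context of `zoom` bp on each side.
#'
#' @param read Read sequence.
#' @param monomer A `monomer_5s` (or list with `gene`) or the gene
#'   sequence itself.
#' @param max_e Significance threshold (default 1e-4).
#' @param zoom Context, bp (default 500).
#' @param read_id Optional read id attached to the hits.
#' @return `data.frame` of hits: start, end, strand, evalue, identity,
#'   zoom_start, zoom_end (0-based half-open on the read).
#' @export
scan_monomers <- function(read, monomer, max_e = 1e-4, zoom = 500,
                          read_id = NA_character_) {
  gene <- if (is.list(monomer)) monomer$gene else monomer
  if (nchar(read) == 0) {
    h <- empty_hits()
    h$zoom_start <- integer(); h$zoom_end <- integer(); h$read_id <- character()
    return(h)
  }
  hits <- scan_gene_hits(read, gene, max_e = max_e)
  hits$zoom_start <- pmax(0L, hits$start - as.integer(zoom))
  hits$zoom_end <- pmin(nchar(read), hits$end + as.integer(zoom))
  hits$read_id <- rep(read_id, nrow(hits))
  hits
}

#' Classify the 5S array organization of one read
#'
#' Applies the hit-geometry rule (see module header). The gap between
#' consecutive monomers is the distance between consecutive hit starts
#' minus the monomer length.
#'
#' @param read_id Read identifier.
#' @param read_length Read length, bp.
#' @param hits Hit table from [scan_monomers()] for this read.
#' @param monomer_length Monomer length, bp.
#' @param gene_length Gene length, bp (for NTS estimates; defaults to
#'   monomer_length minus 977 heuristic is NOT used — pass it when NTS
#'   estimates matter).
#' @param min_monomers Monomers required for "regular" (default 5).
#' @param min_read_len Read length required for "regular", bp (default
#'   6000).
#' @param gap_frac "Major gap" threshold as a fraction of the monomer
#'   length (default 0.5).
#' @return Object of class `array_call` (a one-row list): read_id,
#'   read_length, monomer_count, gaps, nts_lengths, label, subclass; or
#'   NULL when there are no hits (read not reported).
#' @export
classify_array <- function(read_id, read_length, hits, monomer_length,
                           gene_length = NULL, min_monomers = 5,
                           min_read_len = 6000, gap_frac = 0.5) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  starts <- sort(hits$start)
  n <- length(starts)
  gaps <- if (n >= 2) diff(starts) - monomer_length else numeric(0)
  gap_max <- gap_frac * monomer_length
  gaps_ok <- all(gaps <= gap_max)
  label <- if (n == 1) "sparse"
  else if (!gaps_ok) "pseudogenic"
  else if (n >= min_monomers && read_length > min_read_len) "regular"
  else "potentially_regular"
  subclass <- if (label == "potentially_regular") {
    if (n < min_monomers) "few_monomers" else "short_read"
  } else NA_character_
  nts <- if (!is.null(gene_length) && n >= 2) diff(starts) - gene_length
         else numeric(0)
  structure(list(read_id = read_id, read_length = read_length,
                 monomer_count = n, starts = starts, gaps = gaps,
                 nts_lengths = nts, label = label, subclass = subclass),
            class = "array_call")
}

#' Re-derive an array label from the call's stored geometry
#'
#' The label invariant: recomputing the label from (read length, monomer
#' count, gaps) must reproduce the emitted label exactly.
#'
#' @param call An `array_call`.
#' @param monomer_length,min_monomers,min_read_len,gap_frac As in
#'   [classify_array()].
#' @return The re-derived label.
#' @export
rederive_label <- function(call, monomer_length, min_monomers = 5,
                           min_read_len = 6000, gap_frac = 0.5) {
  n <- call$monomer_count
  gaps_ok <- all(call$gaps <= gap_frac * monomer_length)
  if (n == 1) "sparse"
  else if (!gaps_ok) "pseudogenic"
  else if (n >= min_monomers && call$read_length > min_read_len) "regular"
  else "potentially_regular"
}

#' Scan and classify all long reads
#'
#' @param long_reads A [read_set()] or named character vector.
#' @param monomer A `monomer_5s` or list with `gene` and `monomer`.
#' @param max_e,zoom See [scan_monomers()].
#' @param ... Passed to [classify_array()].
#' @return List with `calls` (list of `array_call`), `summary` (label
#'   counts incl. `no_call`), `n_reads`.
#' @export
classify_arrays <- function(long_reads, monomer, max_e = 1e-4, zoom = 500,
                            ...) {
  reads <- if (inherits(long_reads, "read_set")) read_seqs(long_reads)
           else long_reads
  ml <- nchar(if (is.list(monomer)) monomer$monomer else monomer)
  gl <- if (is.list(monomer)) nchar(monomer$gene) else NULL
  calls <- list()
  no_call <- 0L
  for (i in seq_along(reads)) {
    hits <- scan_monomers(reads[[i]], monomer, max_e = max_e, zoom = zoom,
                          read_id = names(reads)[i])
    cl <- classify_array(names(reads)[i], nchar(reads[[i]]), hits, ml,
                         gene_length = gl, ...)
    if (is.null(cl)) no_call <- no_call + 1L else calls[[length(calls) + 1]] <- cl
  }
  labs <- vapply(calls, `[[`, "", "label")
  summary <- c(table(factor(labs, levels = c("regular", "potentially_regular",
                                             "pseudogenic", "sparse"))),
               no_call = no_call)
  list(calls = calls, summary = summary, n_reads = length(reads))
}

#' NTS length-variant report
#'
#' Arrays whose inter-monomer period deviates more than `dev_frac` from
#' the modal period are flagged elongated or shortened; for elongated
#' spacers the internal-repetition signature (off-diagonal word-match
#' runs within the spacer, word size 10) is reported as a boolean.
#'
#' @param calls List of `array_call` objects (regular / potentially
#'   regular arrays are used).
#' @param reads Optional named read sequences for the internal-repetition
#'   check.
#' @param dev_frac Relative deviation threshold (default 0.2).
#' @param word Dotplot word size.
#' @return `data.frame`: read_id, n_periods, min/max period, flag
#'   (`regular`, `elongated`, `shortened`), internal_repetition.
#' @export
nts_variants <- function(calls, reads = NULL, dev_frac = 0.2, word = 10) {
  use <- Filter(function(x) x$label %in% c("regular", "potentially_regular") &&
                  x$monomer_count >= 2, calls)
  if (length(use) == 0) stop("need at least one regular or potentially regular call")
  periods <- unlist(lapply(use, function(x) diff(x$starts)))
  modal <- stats::median(periods)
  rows <- lapply(use, function(x) {
    p <- diff(x$starts)
    flag <- if (any(p > modal * (1 + dev_frac))) "elongated"
    else if (any(p < modal * (1 - dev_frac))) "shortened"
    else "regular"
    rep_found <- NA
    if (flag == "elongated" && !is.null(reads) && x$read_id %in% names(reads)) {
      k <- which.max(p)
      sp <- subseq0(reads[[x$read_id]], x$starts[k], x$starts[k + 1])
      runs <- cpp_word_runs(sp, sp, word, both_strands = FALSE)
      off <- runs[runs$a_start != runs$b_start, , drop = FALSE]
      rep_found <- any(off$length >= 2 * word)
    }
    data.frame(read_id = x$read_id, n_periods = length(p),
               min_period = min(p), max_period = max(p), flag = flag,
               internal_repetition = rep_found, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "modal_period") <- modal
  out
}

#' Per-region substitution proportions from an alignment of 5S genes
#'
#' For each control region (and the remainder of the gene) the proportion
#' of variable alignment columns is reported. Region intervals are 0-based
#' half-open in reference (first sequence) coordinates.
#'
#' @param aln Character vector of aligned sequences (equal lengths, `-`
#'   for gaps); the first sequence is the coordinate reference.
#' @param regions Named list of `c(start, end)` intervals on the
#'   ungapped reference.
#' @return `data.frame`: region, n_columns, prop_variable.
#' @export
region_divergence <- function(aln, regions) {
  stopifnot(length(aln) >= 2, length(unique(nchar(aln))) == 1)
  M <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  refgap <- M[1, ] == "-"
  ref_pos <- cumsum(!refgap) - 1L  # 0-based reference coordinate per column
  variable <- apply(M, 2, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) > 1
  })
  in_region <- rep(FALSE, ncol(M))
  rows <- list()
  for (nm in names(regions)) {
    iv <- regions[[nm]]
    sel <- !refgap & ref_pos >= iv[1] & ref_pos < iv[2]
    in_region <- in_region | sel
    rows[[nm]] <- data.frame(region = nm, n_columns = sum(sel),
                             prop_variable = if (sum(sel)) mean(variable[sel]) else NA_real_,
                             stringsAsFactors = FALSE)
  }
  sel <- !refgap & !in_region
  rows[["remainder"]] <- data.frame(region = "remainder", n_columns = sum(sel),
                                    prop_variable = if (sum(sel)) mean(variable[sel]) else NA_real_,
                                    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
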