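# Pairwise similarity: the read-clustering contract.
# Identity = matches / alignment columns (gaps count as mismatch), making
# the 90%/55% rule unambiguous.

#' Similarity parameters for read clustering
#'
#' Defaults encode the clustering contract: a local alignment (either
#' strand) at >= 90% identity spanning >= 55% of the shorter read.
#'
#' @param min_identity Minimum identity (matches / alignment columns).
#' @param min_coverage Minimum alignment span as a fraction of the shorter
#'   read.
#' @param kmer_seed_size Minimizer k for candidate pairing.
#' @param window Minimizer window (in k-mers); any exact shared substring of
#'   `kmer_seed_size + window - 1` bp guarantees a shared minimizer.
#' @param match,mismatch,gap Alignment scores (linear gap).
#' @return List of class `similarity_params`.
#' @export
similarity_params <- function(min_identity = 0.90, min_coverage = 0.55,
                              kmer_seed_size = 13, window = 5,
                              match = 1, mismatch = -1, gap = -2) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 kmer_seed_size = kmer_seed_size, window = window,
                 match = match, mismatch = mismatch, gap = gap),
            class = "similarity_params")
}

#' Are two reads similar under the clustering thresholds?
#'
#' TRUE iff the best local alignment on either strand reaches
#' `min_identity` over a span of at least `min_coverage` times the shorter
#' read's length. Symmetric in its arguments.
#'
#' @param read_a,read_b Sequences (character).
#' @param params [similarity_params()].
#' @return Logical.
#' @export
similar <- function(read_a, read_b, params = similarity_params()) {
  stopifnot(nchar(read_a) > 0, nchar(read_b) > 0)
  need <- ceiling(params$min_coverage * min(nchar(read_a), nchar(read_b)))
  for (b in c(read_b, revcomp(read_b))) {
    al <- cpp_local_align(read_a, b, params$match, params$mismatch, params$gap)
    if (al$span >= need && al$identity >= params$min_identity) return(TRUE)
  }
  FALSE
}

#' Best local alignment between two sequences
#'
#' Smith-Waterman with linear gap penalty; optionally banded around a
#' diagonal. Intervals are 0-based half-open.
#'
#' @param a,b Sequences.
#' @param match,mismatch,gap Scores.
#' @param d0,band Optional diagonal and band half-width for banded
#'   alignment.
#' @param keep_aln Return the aligned strings.
#' @return List with score, identity, span, matches and intervals.
#' @export
local_align <- function(a, b, match = 1, mismatch = -1, gap = -2,
                        d0 = NULL, band = NULL, keep_aln = FALSE) {
  if (is.null(band))
    cpp_local_align(a, b, match, mismatch, gap, keep_aln)
  else
    cpp_banded_align(a, b, as.integer(d0), as.integer(band),
                     match, mismatch, gap, keep_aln)
}

# Chain word-diagonal runs of one orientation into candidate loci.
# runs: data.frame from cpp_word_runs (single strand); gap_max on the b
# coordinate. Returns list of data.frames (clusters ordered by b_start).
chain_runs <- function(runs, gap_max) {
  if (nrow(runs) == 0) return(list())
  runs <- runs[order(runs$b_start), , drop = FALSE]
  bend <- runs$b_start + runs$length
  brk <- c(FALSE, runs$b_start[-1] > cummax(bend[-nrow(runs)]) + gap_max)
  grp <- cumsum(brk)
  lapply(split(runs, grp), identity)
}
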