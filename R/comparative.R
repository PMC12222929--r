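# Cross-species abundance matrices and sequence-divergence statistics:
# Kimura 2-parameter distances and Tajima's relative-rate test.
# Gap/ambiguity handling is pairwise deletion throughout (it changes n, P
# and Q, so it is stated explicitly).

#' Two-layer cross-species abundance matrix
#'
#' `relative_share`: reads of repeat r in species s divided by the total
#' reads clustered for r across species (rows sum to 1). `within_genome`:
#' the same counts divided by the total analyzed reads of s (the genome
#' proportion of the repeat in that species).
#'
#' @param counts Repeat x species count matrix (repeats as rownames), or a
#'   `data.frame` with columns `repeat_name`, `species`, `count` (clusters
#'   of one repeat are aggregated before division).
#' @param totals Named vector: total analyzed reads per species (every
#'   species in `counts` must be present).
#' @return Object of class `abundance_matrix`: list with `relative_share`
#'   and `within_genome` matrices and `totals`.
#' @export
abundance_matrix <- function(counts, totals) {
  if (is.data.frame(counts)) {
    counts <- stats::xtabs(count ~ repeat_name + species, data = counts)
    counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                     dimnames = dimnames(counts))
  }
  stopifnot(all(colnames(counts) %in% names(totals)))
  totals <- totals[colnames(counts)]
  rs <- rowSums(counts)
  relative_share <- sweep(counts, 1, ifelse(rs > 0, rs, 1), "/")
  within_genome <- sweep(counts, 2, totals, "/")
  structure(list(relative_share = relative_share,
                 within_genome = within_genome, totals = totals),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d repeats x %d species\n",
              nrow(x$relative_share), ncol(x$relative_share)))
  invisible(x)
}

# transition / transversion classification of two base vectors
count_pq <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  diffs <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- diffs & (purine[a] == purine[b])
  list(n = length(a), transitions = sum(ts), transversions = sum(diffs & !ts))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with P and Q the transition
#' and transversion proportions over pairwise-deleted (gapless,
#' unambiguous) columns.
#'
#' @param seq_a,seq_b Aligned sequences (same length; `-` for gaps).
#' @param min_sites Minimum comparable columns (default 20; error below).
#' @return The distance (substitutions per site).
#' @export
k2p_distance <- function(seq_a, seq_b, min_sites = 20) {
  stopifnot(nchar(seq_a) == nchar(seq_b))
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  pq <- count_pq(a, b)
  if (pq$n < min_sites)
    stop("only ", pq$n, " comparable columns (< ", min_sites, ")")
  k2p_from_pq(pq$transitions / pq$n, pq$transversions / pq$n)
}

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' The closed form, exposed so the estimator can be checked against direct
#' evaluation.
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return The distance.
#' @export
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturation: K2P distance undefined for P = ", P, ", Q = ", Q)
  -0.5 * log(w1 * sqrt(w2))
}

#' K2P distance matrix with heatmap-ready ordering
#'
#' Symmetric zero-diagonal matrix over an aligned sequence set; the
#' returned ordering comes from average-linkage hierarchical clustering on
#' the distances (presentational only).
#'
#' @param seqs Named character vector of aligned sequences (>= 2, equal
#'   lengths).
#' @param min_sites Passed to [k2p_distance()].
#' @return List with `matrix` and `order` (taxa ordered for plotting).
#' @export
distance_matrix <- function(seqs, min_sites = 20) {
  stopifnot(length(seqs) >= 2)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- k2p_distance(seqs[[i]], seqs[[j]], min_sites)
  }
  ord <- if (n > 2) {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    names(seqs)[hc$order]
  } else names(seqs)
  list(matrix = D, order = ord)
}

#' Tajima's relative-rate test
#'
#' For a three-way alignment (two ingroup lineages and an outgroup),
#' counts the pairwise-deleted columns where only lineage 1 differs (m1)
#' and where only lineage 2 differs (m2), and tests m1 = m2 with
#' `chi2 = (m1 - m2)^2 / (m1 + m2)` on 1 degree of freedom.
#'
#' @param seq1,seq2,outgroup Aligned sequences (equal lengths).
#' @param min_sites Minimum three-way comparable columns (default 20).
#' @return List of class `rrt_result`: m1, m2, chi2, p_value, df = 1, n.
#' @export
tajima_rrt <- function(seq1, seq2, outgroup, min_sites = 20) {
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) == nchar(outgroup))
  a <- strsplit(toupper(seq1), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq2), "", fixed = TRUE)[[1]]
  o <- strsplit(toupper(outgroup), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  ok <- a %in% bases & b %in% bases & o %in% bases
  a <- a[ok]; b <- b[ok]; o <- o[ok]
  if (length(a) < min_sites)
    stop("only ", length(a), " comparable columns (< ", min_sites, ")")
  m1 <- sum(a != o & b == o)
  m2 <- sum(b != o & a == o)
  chi2 <- if (m1 + m2 > 0) (m1 - m2)^2 / (m1 + m2) else 0
  p <- if (m1 + m2 > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  structure(list(m1 = m1, m2 = m2, chi2 = chi2, p_value = p, df = 1,
                 n = length(a)),
            class = "rrt_result")
}

#' @export
print.rrt_result <- function(x, ...) {
  cat(sprintf("Tajima relative-rate test: m1 = %d, m2 = %d, chi2 = %.4g, p = %.4g\n",
              x$m1, x$m2, x$chi2, x$p_value))
  invisible(x)
}

#' Simulate a pair of sequences diverged under the K2P model
#'
#' Used to validate the estimator: an ancestor of length `n` accumulates
#' substitutions on both lineages for a total expected distance `d`, with
#' the generator's 2:1 transition:transversion ratio.
#'
#' @param n Sites.
#' @param d Total expected distance between the pair.
#' @param ts_tv Transition:transversion ratio.
#' @return List with `a` and `b`.
#' @export
simulate_k2p_pair <- function(n, d, ts_tv = 2) {
  anc <- random_dna(n, gc = 0.5)
  list(a = mutate_dna(anc, d / 2, ts_tv), b = mutate_dna(anc, d / 2, ts_tv))
}
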