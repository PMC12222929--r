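# Shared helpers: sequence generation, mutation, coordinates, significance.
# Interval convention: 0-based half-open throughout the package (BED-style).

#' Random DNA sequence
#'
#' I.i.d. nucleotides at a given GC content (default 0.38, plant-like).
#'
#' @param n Sequence length in bp.
#' @param gc GC content in `[0, 1]`.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.38) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE, prob = p)])
}

#' Mutate a DNA sequence by random substitutions
#'
#' Substitutions are drawn at the given per-site rate with a
#' transition:transversion ratio (default 2:1), so distance estimators that
#' separate the two substitution classes are properly exercised.
#'
#' @param seq Character string (ACGT).
#' @param divergence Expected substitutions per site in `[0, 1]`.
#' @param ts_tv Transition:transversion ratio.
#' @return Mutated sequence.
#' @export
mutate_dna <- function(seq, divergence, ts_tv = 2) {
  if (divergence <= 0 || nchar(seq) == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  nmut <- rbinom(1, n, divergence)
  if (nmut == 0) return(seq)
  pos <- sample.int(n, nmut)
  TS <- c(A = "G", G = "A", C = "T", T = "C")
  TV1 <- c(A = "C", G = "C", C = "A", T = "A")
  TV2 <- c(A = "T", G = "T", C = "G", T = "G")
  cur <- v[pos]
  is_ts <- runif(nmut) < ts_tv / (ts_tv + 1)
  pick2 <- runif(nmut) < 0.5
  new <- ifelse(is_ts, TS[cur], ifelse(pick2, TV1[cur], TV2[cur]))
  keep <- is.na(new)  # non-ACGT positions left untouched
  new[keep] <- cur[keep]
  v[pos] <- new
  paste(v, collapse = "")
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTRYKMacgtrykm", "TGCAYRMKtgcayrmk", stringi::stri_reverse(x))
}

#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T); IUPAC ambiguity codes and gaps are excluded
#' from the denominator.
#'
#' @param sequence Character string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  s <- toupper(sequence)
  gcn <- stringi::stri_count_regex(s, "[GC]")
  acgt <- stringi::stri_count_regex(s, "[ACGT]")
  if (acgt == 0) return(NA_real_)
  gcn / acgt
}

# substring with 0-based half-open coordinates
subseq0 <- function(x, start, end) substring(x, start + 1, end)

# run code with a temporary RNG state seeded by `seed` (NULL = use current)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Karlin-Altschul-style significance for ungapped-ish local DNA alignment.
# lambda solves sum_ij p_i p_j exp(lambda * s_ij) = 1 for uniform base
# composition; K is a fixed calibration constant (documented approximation).
ka_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10 / max(match, 1e-9)))$root
}

#' E-value-like significance for a local alignment score
#'
#' Karlin-Altschul form `E = K m n exp(-lambda S)` with lambda solved from
#' the scoring scheme under uniform base composition and a fixed calibration
#' constant K. Used to rank and threshold hits; it approximates, but is not
#' identical to, BLAST E-values.
#'
#' @param score Alignment raw score.
#' @param m,n Query and subject lengths (search space).
#' @param match,mismatch Match/mismatch scores of the alignment.
#' @param K Calibration constant.
#' @return Numeric significance (smaller = more significant).
#' @export
alignment_evalue <- function(score, m, n, match = 1, mismatch = -3, K = 0.5) {
  lambda <- ka_lambda(match, mismatch)
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

# significance for protein local alignment under BLOSUM80 (approximate
# ungapped parameters)
protein_evalue <- function(score, m, n, lambda = 0.32, K = 0.14) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

#' Percentage as printed in summary tables
#'
#' `100 * count / total`, rounded half-to-even to a fixed number of decimals
#' (the convention of the summary statistics this package reports).
#'
#' @param count,total Non-negative counts.
#' @param digits Decimals to keep.
#' @return Rounded percentage.
#' @export
percent_printed <- function(count, total, digits = 3) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}

# IUPAC code for a set of bases
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  out <- codes[[key]]
  if (is.null(out)) "N" else out
}

# stable file-content digest used in determinism tests (no external deps)
seq_digest <- function(x) {
  v <- utf8ToInt(x)
  n <- length(v)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%d-%d", n, h)
}
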