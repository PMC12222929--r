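# Read preparation: filter -> subsample -> trim -> pool.
# The stage order is fixed; each stage records in/out counts in the
# `prep_log` attribute so the full pre-processing is auditable.

log_stage <- function(rs, stage, n_in, n_out, extra = list(), prev = NULL) {
  lg <- attr(if (is.null(prev)) rs else prev, "prep_log")
  if (is.null(lg)) lg <- list()
  lg[[length(lg) + 1]] <- c(list(stage = stage, n_in = n_in, n_out = n_out), extra)
  attr(rs, "prep_log") <- lg
  rs
}

#' Filter reads matching contaminant references
#'
#' Removes any read (and its mate) that aligns to a contaminant reference
#' (e.g. plastome, adapters) at >= `min_identity` over >= `min_coverage` of
#' the read length. Matching uses a k-mer prefilter (k = 15) plus banded
#' local alignment; the contract is stated purely in identity/coverage
#' terms.
#'
#' @param rs A [read_set()].
#' @param contaminant_refs Named character vector of reference sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param min_identity,min_coverage Removal thresholds (defaults 0.90 /
#'   0.80 of the read length).
#' @return Filtered [read_set()] with attribute `removed_count`.
#' @export
filter_by_reference <- function(rs, contaminant_refs, min_identity = 0.90,
                                min_coverage = 0.80) {
  refs <- as_seq_vector(contaminant_refs)
  if (length(refs) == 0) stop("contaminant references must be non-empty")
  n_in <- nrow(rs$reads)
  if (n_in == 0) {
    warning("empty read set; nothing to filter")
    out <- rs
    attr(out, "removed_count") <- 0L
    return(log_stage(out, "filter", 0L, 0L))
  }
  hit <- rep(FALSE, n_in)
  for (ref in refs) {
    todo <- which(!hit)
    if (!length(todo)) break
    mp <- cpp_map_reads(ref, rs$reads$seq[todo], k = 15,
                        min_ident = min_identity, min_cov = min_coverage,
                        band = 20)
    hit[todo[mp$mapped]] <- TRUE
  }
  # remove mates of hit reads too
  hit_ids <- rs$reads$id[hit]
  hit <- hit | (!is.na(rs$reads$mate) & rs$reads$mate %in% hit_ids)
  out <- subset_read_set(rs, !hit)
  attr(out, "removed_count") <- sum(hit)
  log_stage(out, "filter", n_in, nrow(out$reads),
            list(removed = sum(hit)), prev = rs)
}

#' Randomly subsample read pairs
#'
#' Uniform sampling without replacement, pair-preserving and
#' seed-reproducible. Unpaired reads count as single-read units.
#'
#' @param rs A [read_set()].
#' @param n_pairs Number of pair units to keep (<= available; error
#'   otherwise, no silent truncation).
#' @param seed Integer seed.
#' @return Subsampled [read_set()].
#' @export
subsample <- function(rs, n_pairs, seed = NULL) {
  df <- rs$reads
  # pair units: keyed by the lexicographically smaller id of each pair
  unit <- ifelse(is.na(df$mate), df$id, pmin(df$id, df$mate))
  units <- unique(unit)
  if (n_pairs > length(units))
    stop("n_pairs (", n_pairs, ") exceeds available pair units (",
         length(units), ")")
  keep_units <- with_seed(seed, sample(units, n_pairs))
  out <- subset_read_set(rs, unit %in% keep_units)
  log_stage(out, "subsample", nrow(df), nrow(out$reads), prev = rs)
}

#' Trim reads to a fixed length
#'
#' Reads longer than `L` are truncated to their first `L` bases; reads
#' shorter than `L` are dropped together with their mates (downstream
#' clustering assumes length-homogeneous reads).
#'
#' @param rs A [read_set()].
#' @param L Target length, nt (default 100).
#' @return Trimmed [read_set()] with attribute `dropped_pairs`.
#' @export
trim_to_length <- function(rs, L = 100) {
  stopifnot(L >= 1)
  df <- rs$reads
  short <- nchar(df$seq) < L
  short_ids <- df$id[short]
  drop <- short | (!is.na(df$mate) & df$mate %in% short_ids)
  out <- subset_read_set(rs, !drop)
  out$reads$seq <- substr(out$reads$seq, 1, L)
  attr(out, "dropped_pairs") <- sum(drop)
  log_stage(out, "trim", nrow(df), nrow(out$reads),
            list(dropped = sum(drop)), prev = rs)
}

#' Pool per-species subsamples into one comparative read set
#'
#' Concatenates a random subsample of `per_species_n` reads from each
#' species' read set; ids keep their species-code prefixes so per-species
#' counts remain retrievable with [species_counts()].
#'
#' @param readsets List of [read_set()] objects (one per species).
#' @param per_species_n Reads sampled per species.
#' @param seed Integer seed.
#' @return Pooled [read_set()].
#' @export
pool_species <- function(readsets, per_species_n, seed = NULL) {
  with_seed(seed, {
    parts <- lapply(readsets, function(rs) {
      n <- nrow(rs$reads)
      if (n < per_species_n)
        stop("read set for species ", rs$reads$species[1], " has ", n,
             " reads < per_species_n")
      rs$reads[sample.int(n, per_species_n), , drop = FALSE]
    })
    df <- do.call(rbind, parts)
    df$mate[!is.na(df$mate) & !(df$mate %in% df$id)] <- NA_character_
    rownames(df) <- NULL
    out <- read_set(df)
    log_stage(out, "pool", sum(vapply(readsets, length, 1L)), nrow(df))
  })
}

#' Run the full pre-processing pipeline
#'
#' filter -> subsample -> trim, in that order, with a stage report.
#'
#' @param rs A [read_set()].
#' @param contaminants Optional contaminant references (see
#'   [filter_by_reference()]).
#' @param n_pairs Pairs to subsample (NULL = keep all).
#' @param trim_len Trim length, nt.
#' @param seed Integer seed.
#' @return Prepared [read_set()]; the stage report is in attribute
#'   `prep_log` and retrievable with [prep_report()].
#' @export
prep_reads <- function(rs, contaminants = NULL, n_pairs = NULL,
                       trim_len = 100, seed = NULL) {
  if (!is.null(contaminants)) rs <- filter_by_reference(rs, contaminants)
  if (!is.null(n_pairs)) rs <- subsample(rs, n_pairs, seed = seed)
  trim_to_length(rs, trim_len)
}

#' Stage report of the preparation pipeline
#' @param rs A [read_set()] that went through prep stages.
#' @return `data.frame` with one row per stage.
#' @export
prep_report <- function(rs) {
  lg <- attr(rs, "prep_log")
  if (is.null(lg)) return(data.frame(stage = character(), n_in = integer(),
                                     n_out = integer()))
  do.call(rbind, lapply(lg, function(x)
    data.frame(stage = x$stage, n_in = x$n_in, n_out = x$n_out)))
}

# accept character vector / DNAStringSet / FASTA path
as_seq_vector <- function(x) {
  if (inherits(x, "DNAStringSet")) return(stats::setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      grepl("\\.(fa|fasta|fna)$", x)) {
    s <- Biostrings::readDNAStringSet(x)
    return(stats::setNames(as.character(s), sub("\\s.*", "", names(s))))
  }
  x
}
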