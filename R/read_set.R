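# ReadSet: the unit flowing through preparation and clustering.
# A thin S3 wrapper around a data.frame with columns id, seq, mate,
# species (plus optional simulator provenance columns src_start, src_end,
# src_strand). Mate pairs are symmetric; ids are unique.

#' Read set constructor
#'
#' @param reads `data.frame` with at least columns `id` (unique), `seq`,
#'   `mate` (mate id or `NA`), `species`.
#' @param species Default species code (used when the column is absent).
#' @param provenance Optional character vector of source files.
#' @return Object of class `read_set`.
#' @export
read_set <- function(reads, species = "SP1", provenance = character()) {
  if (is.null(reads$species)) reads$species <- rep(species, nrow(reads))
  if (is.null(reads$mate)) reads$mate <- rep(NA_character_, nrow(reads))
  stopifnot(!anyDuplicated(reads$id))
  paired <- !is.na(reads$mate)
  if (any(paired)) {
    back <- reads$mate[match(reads$mate[paired], reads$id)]
    if (!all(back == reads$id[paired], na.rm = TRUE))
      stop("mate pairing is not symmetric")
  }
  structure(list(reads = reads, provenance = provenance), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  n <- nrow(x$reads)
  np <- sum(!is.na(x$reads$mate)) / 2
  cat(sprintf("<read_set> %d reads (%d pairs), species: %s\n", n, np,
              paste(unique(x$reads$species), collapse = ", ")))
  invisible(x)
}

#' @export
length.read_set <- function(x) nrow(x$reads)

#' Read sequences as a character vector (named by read id)
#' @param rs A [read_set()].
#' @export
read_seqs <- function(rs) {
  stats::setNames(rs$reads$seq, rs$reads$id)
}

#' Per-species read counts parsed from the read set
#' @param rs A [read_set()].
#' @return Named integer vector.
#' @export
species_counts <- function(rs) {
  tab <- table(rs$reads$species)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read FASTA/FASTQ files into a read set
#'
#' Paired files are interleaved in order; mate ids get `/1` `/2` suffixes if
#' not already present.
#'
#' @param files One (unpaired/interleaved) or two (R1, R2) paths; format
#'   inferred from extension.
#' @param species Species code prefixed to ids (`<species>_<id>`), unless
#'   ids already carry it.
#' @param paired Treat two files as mates, or one file as interleaved pairs.
#' @return A [read_set()].
#' @export
read_reads <- function(files, species = "SP1", paired = length(files) == 2) {
  fmt <- ifelse(grepl("\\.f(ast)?q$", files), "fastq", "fasta")
  sets <- lapply(seq_along(files), function(i)
    Biostrings::readDNAStringSet(files[i], format = fmt[i]))
  pref <- function(ids) ifelse(startsWith(ids, paste0(species, "_")), ids,
                               paste0(species, "_", ids))
  if (length(sets) == 2) {
    id1 <- pref(sub("\\s.*", "", names(sets[[1]])))
    id2 <- pref(sub("\\s.*", "", names(sets[[2]])))
    if (!any(grepl("/1$", id1))) { id1 <- paste0(id1, "/1"); id2 <- paste0(id2, "/2") }
    df <- data.frame(id = c(rbind(id1, id2)),
                     seq = c(rbind(as.character(sets[[1]]), as.character(sets[[2]]))),
                     mate = c(rbind(id2, id1)), species = species,
                     stringsAsFactors = FALSE)
  } else {
    ids <- pref(sub("\\s.*", "", names(sets[[1]])))
    n <- length(ids)
    mate <- NA_character_
    if (paired && n %% 2 == 0) {
      mate <- ids[rep(seq(1, n, 2), each = 2) + rep(c(1, 0), n / 2)]
    }
    df <- data.frame(id = ids, seq = as.character(sets[[1]]), mate = mate,
                     species = species, stringsAsFactors = FALSE)
  }
  read_set(df, species = species, provenance = files)
}

#' Write a read set to FASTQ (paired) or interleaved FASTA
#'
#' Paired FASTQ output writes `<prefix>_1.fastq` / `<prefix>_2.fastq` with
#' `/1` `/2` id suffixes; FASTA output is a single interleaved file (the
#' clustering input format).
#'
#' @param rs A [read_set()].
#' @param prefix Output path prefix.
#' @param format `"fastq"` or `"fasta"`.
#' @return Paths written, invisibly.
#' @export
write_reads <- function(rs, prefix, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  df <- rs$reads
  if (format == "fasta") {
    x <- Biostrings::DNAStringSet(df$seq)
    names(x) <- df$id
    f <- paste0(prefix, ".fasta")
    Biostrings::writeXStringSet(x, f)
    return(invisible(f))
  }
  is1 <- grepl("/1$", df$id) | is.na(df$mate)
  q <- function(d) {
    x <- Biostrings::DNAStringSet(d$seq)
    names(x) <- d$id
    Biostrings::writeXStringSet(
      x, file_, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(d$seq))))
  }
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  file_ <- f1; q(df[is1, , drop = FALSE])
  out <- f1
  if (any(!is1)) { file_ <- f2; q(df[!is1, , drop = FALSE]); out <- c(f1, f2) }
  invisible(out)
}

subset_read_set <- function(rs, keep) {
  df <- rs$reads[keep, , drop = FALSE]
  # drop dangling mate references
  df$mate[!is.na(df$mate) & !(df$mate %in% df$id)] <- NA_character_
  rownames(df) <- NULL
  structure(list(reads = df, provenance = rs$provenance), class = "read_set")
}
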