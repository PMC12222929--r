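# Synthetic genomes with planted repeat families and simulated reads.
# The ground-truth manifest (copy coordinates, realized proportions, true
# array labels) is the oracle the analysis modules are validated against.
# All coordinates are 0-based half-open; strands are "+"/"-".

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

rev_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  codons <- split(names(gc), unname(gc))
  a <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(a, function(x) sample(codons[[x]], 1), ""), collapse = "")
}

#' Repeat template constructor
#'
#' A named repeat family template: the element sequence plus feature
#' intervals (0-based half-open) such as LTR5/LTR3, PBS, PPT, protein
#' domains, TIRs or rRNA genes.
#'
#' @param name Family label.
#' @param repeat_class One of `LTR_RT`, `TIR_DNA_TE`, `satellite`,
#'   `rDNA_35S`, `rDNA_5S`, `unclassified`.
#' @param sequence Nucleotide string.
#' @param features `data.frame` with columns `feature`, `start`, `end`.
#' @return Object of class `repeat_template`.
#' @export
repeat_template <- function(name, repeat_class, sequence, features = NULL) {
  repeat_class <- match.arg(repeat_class, c("LTR_RT", "TIR_DNA_TE", "satellite",
                                            "rDNA_35S", "rDNA_5S", "unclassified"))
  if (is.null(features))
    features <- data.frame(feature = character(), start = integer(), end = integer())
  stopifnot(all(features$start >= 0), all(features$end <= nchar(sequence)),
            all(features$start < features$end))
  structure(list(name = name, repeat_class = repeat_class,
                 sequence = sequence, features = features),
            class = "repeat_template")
}

#' @export
print.repeat_template <- function(x, ...) {
  cat(sprintf("<repeat_template> %s (%s), %d bp, %d features\n",
              x$name, x$repeat_class, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

feature_interval <- function(template, feature) {
  f <- template$features[template$features$feature == feature, , drop = FALSE]
  if (nrow(f) == 0) return(NULL)
  c(f$start[1], f$end[1])
}

#' Build a synthetic LTR retrotransposon template
#'
#' Constructs an LTR retroelement with identical 5' and 3' long terminal
#' repeats, a primer binding site (PBS) immediately downstream of LTR5, a
#' polypurine tract (PPT) immediately upstream of LTR3, and internal protein
#' domains in chromovirus-style order GAG-PR-RT-RH-INT (optional
#' chromodomain CD after INT). The domain peptides are random proteins,
#' reverse-translated into the element; they are attached as the
#' `domain_proteins` attribute so translated-search annotation can be
#' validated against them.
#'
#' @param internal_length Length of the internal region (between LTRs), bp.
#' @param ltr_length LTR length, bp (>= 100).
#' @param seed Integer seed.
#' @param name Family label.
#' @param gc GC content of non-domain sequence.
#' @param domain_aa Named amino-acid lengths for GAG, PR, RT, RH, INT
#'   (and CD when `chromodomain = TRUE`).
#' @param chromodomain Add a chromodomain after INT.
#' @return A [repeat_template()] of class `LTR_RT` with attribute
#'   `domain_proteins` (named character vector of peptides).
#' @export
build_ltr_element <- function(internal_length = 4000, ltr_length = 300,
                              seed = NULL, name = "LTR1", gc = 0.38,
                              domain_aa = c(GAG = 150, PR = 100, RT = 200,
                                            RH = 120, INT = 150, CD = 50),
                              chromodomain = TRUE) {
  stopifnot(ltr_length >= 100, internal_length >= 1000)
  with_seed(seed, {
    doms <- c("GAG", "PR", "RT", "RH", "INT", if (chromodomain) "CD")
    pbs_len <- 18L; ppt_len <- 15L; linker <- 15L
    need <- pbs_len + ppt_len
    for (d in doms) {
      need <- need + linker + 3L * domain_aa[[d]]
      if (need > internal_length)
        stop("internal_length too small to host feature ", d,
             " (needs >= ", need, " bp)")
    }
    ltr <- random_dna(ltr_length, gc)
    proteins <- vapply(doms, function(d) random_protein(domain_aa[[d]]), "")
    feats <- list()
    parts <- character()
    pos <- ltr_length
    add <- function(name, s) {
      feats[[length(feats) + 1]] <<- data.frame(feature = name, start = pos,
                                                end = pos + nchar(s))
      parts[[length(parts) + 1]] <<- s
      pos <<- pos + nchar(s)
    }
    feats[[1]] <- data.frame(feature = "LTR5", start = 0L, end = ltr_length)
    parts <- c(parts, ltr)
    add("PBS", random_dna(pbs_len, 0.5))
    filler_total <- internal_length - need
    gaps <- floor(filler_total * seq_len(length(doms) + 1) / (length(doms) + 1))
    gaps <- diff(c(0, gaps))
    for (i in seq_along(doms)) {
      pos <- pos; parts[[length(parts) + 1]] <- random_dna(linker + gaps[i], gc)
      pos <- pos + linker + gaps[i]
      add(doms[i], rev_translate(proteins[[doms[i]]]))
    }
    parts[[length(parts) + 1]] <- random_dna(gaps[length(gaps)], gc)
    pos <- pos + gaps[length(gaps)]
    add("PPT", paste(sample(c("A", "G"), ppt_len, TRUE, prob = c(0.4, 0.6)),
                     collapse = ""))
    feats[[length(feats) + 1]] <- data.frame(feature = "LTR3", start = pos,
                                             end = pos + ltr_length)
    parts[[length(parts) + 1]] <- ltr
    seqs <- paste(unlist(parts), collapse = "")
    tpl <- repeat_template(name, "LTR_RT", seqs, do.call(rbind, feats))
    attr(tpl, "domain_proteins") <- proteins
    tpl
  })
}

#' Build a synthetic TIR DNA transposon template
#'
#' CACTA-style cut-and-paste element: terminal inverted repeats plus a
#' DDE-type transposase ORF (random peptide, attached as
#' `domain_proteins["transposase"]`).
#'
#' @param internal_length Internal length, bp.
#' @param tir_length Terminal inverted repeat length, bp (>= 10).
#' @param seed Integer seed.
#' @param name Family label.
#' @param gc GC content.
#' @param transposase_aa Transposase peptide length.
#' @return A [repeat_template()] of class `TIR_DNA_TE`.
#' @export
build_tir_element <- function(internal_length = 3000, tir_length = 25,
                              seed = NULL, name = "TIR1", gc = 0.38,
                              transposase_aa = 300) {
  stopifnot(tir_length >= 10, internal_length >= 3 * transposase_aa + 40)
  with_seed(seed, {
    tir <- random_dna(tir_length, gc)
    tpase <- random_protein(transposase_aa)
    orf <- rev_translate(tpase)
    pad <- internal_length - nchar(orf)
    left <- random_dna(floor(pad / 2), gc)
    right <- random_dna(pad - nchar(left), gc)
    seqs <- paste0(tir, left, orf, right, revcomp(tir))
    L <- nchar(seqs)
    feats <- data.frame(
      feature = c("TIR", "transposase", "TIR"),
      start = c(0L, tir_length + nchar(left), L - tir_length),
      end = c(tir_length, tir_length + nchar(left) + nchar(orf), L))
    tpl <- repeat_template(name, "TIR_DNA_TE", seqs, feats)
    attr(tpl, "domain_proteins") <- c(transposase = tpase)
    tpl
  })
}

#' Build a satellite monomer template
#'
#' @param monomer_length Monomer length, bp.
#' @param seed Integer seed.
#' @param name Family label.
#' @param gc GC content.
#' @return A [repeat_template()] of class `satellite`.
#' @export
build_satellite <- function(monomer_length = 500, seed = NULL,
                            name = "SAT1", gc = 0.42) {
  with_seed(seed, repeat_template(name, "satellite",
                                  random_dna(monomer_length, gc)))
}

#' Build a synthetic 35S rDNA unit
#'
#' One tandem-repeat unit 18S-ITS1-5.8S-ITS2-26S-IGS. The three rRNA gene
#' sequences are attached as the `rRNA_genes` attribute for use as
#' annotation references.
#'
#' @param seed Integer seed.
#' @param lengths Named lengths of the six parts, bp.
#' @param name Family label.
#' @return A [repeat_template()] of class `rDNA_35S`.
#' @export
build_35s_unit <- function(seed = NULL,
                           lengths = c(`18S` = 1800, ITS1 = 250, `5.8S` = 160,
                                       ITS2 = 230, `26S` = 3400, IGS = 2000),
                           name = "rDNA35S") {
  with_seed(seed, {
    parts <- vapply(lengths, function(n) random_dna(n, 0.52), "")
    ends <- cumsum(nchar(parts))
    feats <- data.frame(feature = names(lengths),
                        start = c(0L, head(ends, -1)), end = ends)
    tpl <- repeat_template(name, "rDNA_35S", paste(parts, collapse = ""), feats)
    attr(tpl, "rRNA_genes") <- parts[c("18S", "5.8S", "26S")]
    tpl
  })
}

#' Build a 5S rDNA monomer template
#'
#' Monomer = 5S gene + non-transcribed spacer (NTS), with canonical internal
#' control-region intervals (A-box, intermediate element, C-box) recorded on
#' the gene. The control-region positions follow canonical plant 5S internal
#' promoter coordinates; they are defaults, not measurements.
#'
#' @param gene_length 5S gene length, bp (default 121).
#' @param nts_length NTS length, bp (default 977).
#' @param seed Integer seed.
#' @param name Family label.
#' @return A [repeat_template()] of class `rDNA_5S` with attribute
#'   `control_regions` (list of 0-based half-open intervals on the gene).
#' @export
build_5s_template <- function(gene_length = 121, nts_length = 977,
                              seed = NULL, name = "rDNA5S") {
  stopifnot(gene_length >= 100, nts_length >= 1)
  with_seed(seed, {
    gene <- random_dna(gene_length, 0.53)
    nts <- random_dna(nts_length, 0.40)
    feats <- data.frame(feature = c("gene_5S", "NTS"),
                        start = c(0L, gene_length),
                        end = c(gene_length, gene_length + nts_length))
    tpl <- repeat_template(name, "rDNA_5S", paste0(gene, nts), feats)
    attr(tpl, "control_regions") <- list(A_box = c(49L, 60L),
                                         IE = c(66L, 72L),
                                         C_box = c(79L, 97L))
    tpl
  })
}

#' Build a 5S rDNA tandem array with a known organization label
#'
#' `regular`: head-to-tail (gene+NTS) x n with low per-copy divergence.
#' `long_nts`: like regular, but one or more NTS copies are elongated by an
#' internal tandem duplication of an NTS segment (the mechanism behind NTS
#' length variants). `pseudogenic`: at least 20% of monomers hyper-mutated
#' far beyond the detection threshold and/or interrupted by inserted
#' non-repeat spacers at least one monomer long.
#'
#' @param gene,nts Gene and NTS sequences.
#' @param n_monomers Number of monomers (>= 1).
#' @param mode `regular`, `long_nts` or `pseudogenic`.
#' @param seed Integer seed.
#' @param divergence Per-copy divergence of normal monomers (<= 0.02 for
#'   regular arrays).
#' @param hyper_divergence Divergence applied to pseudogenized monomers.
#' @param hyper_frac Minimum fraction of hyper-mutated monomers in
#'   pseudogenic mode.
#' @param dup_len Length of the NTS segment duplicated in `long_nts` mode.
#' @param dup_times Extra tandem copies of the duplicated segment.
#' @return List with `sequence`, `monomers` (data.frame of 0-based half-open
#'   monomer and gene coordinates on the array, `nts_length`, `hyper` flag),
#'   `nts_lengths`, `label`.
#' @export
build_5s_array <- function(gene, nts, n_monomers,
                           mode = c("regular", "long_nts", "pseudogenic"),
                           seed = NULL, divergence = 0.02,
                           hyper_divergence = 0.45, hyper_frac = 0.2,
                           dup_len = 200, dup_times = 2) {
  mode <- match.arg(mode)
  if (nchar(gene) == 0 || nchar(nts) == 0) stop("gene and NTS must be non-empty")
  stopifnot(n_monomers >= 1)
  with_seed(seed, {
    lg <- nchar(gene)
    hyper <- rep(FALSE, n_monomers)
    nts_seqs <- rep(nts, n_monomers)
    if (mode == "long_nts") {
      n_long <- max(1L, rbinom(1, n_monomers, 0.3))
      which_long <- sample.int(n_monomers, n_long)
      dl <- min(dup_len, floor(nchar(nts) / 2))
      for (i in which_long) {
        s0 <- sample.int(nchar(nts) - dl, 1)
        seg <- substring(nts, s0, s0 + dl - 1)
        nts_seqs[i] <- paste0(substring(nts, 1, s0 + dl - 1),
                              strrep(seg, dup_times),
                              substring(nts, s0 + dl))
      }
    }
    if (mode == "pseudogenic") {
      n_h <- max(1L, ceiling(hyper_frac * n_monomers))
      hyper[sample.int(n_monomers, n_h)] <- TRUE
    }
    monomer_len <- lg + nchar(nts)
    spacer_after <- rep("", n_monomers)
    if (mode == "pseudogenic" && n_monomers >= 2) {
      n_sp <- max(1L, floor(n_monomers / 3))
      at <- sample.int(n_monomers - 1, min(n_sp, n_monomers - 1))
      # at least one spacer must separate two detectable (non-hyper-mutated)
      # monomers, so the array's hit geometry always shows a major gap
      between_ok <- which(!hyper[-n_monomers] & !hyper[-1])
      if (length(between_ok) && !any(at %in% between_ok))
        at <- c(at, between_ok[sample.int(length(between_ok), 1)])
      for (i in at)
        spacer_after[i] <- random_dna(round(monomer_len * runif(1, 1, 2)), 0.38)
    }
    parts <- character(0)
    rows <- vector("list", n_monomers)
    pos <- 0L
    for (i in seq_len(n_monomers)) {
      div_i <- if (hyper[i]) hyper_divergence else divergence
      g <- mutate_dna(gene, div_i)
      s <- mutate_dna(nts_seqs[i], div_i)
      mono <- paste0(g, s)
      rows[[i]] <- data.frame(monomer = i, start = pos, end = pos + nchar(mono),
                              gene_start = pos, gene_end = pos + lg,
                              nts_length = nchar(s), hyper = hyper[i])
      parts <- c(parts, mono, spacer_after[i])
      pos <- pos + nchar(mono) + nchar(spacer_after[i])
    }
    monomers <- do.call(rbind, rows)
    label <- mode
    list(sequence = paste(parts, collapse = ""), monomers = monomers,
         nts_lengths = monomers$nts_length, label = label)
  })
}

#' Genome specification for the simulator
#'
#' @param genome_length Total genome length, bp.
#' @param families List of family specs, each a list with `template`
#'   ([repeat_template()]), `target_proportion` (fraction of genome),
#'   `per_copy_divergence` (substitutions/site in `[0, 0.3]`) and
#'   `arrangement` (`dispersed` or `tandem`).
#' @param array_specs List of 5S-array specs, each a list with `template`
#'   (a `rDNA_5S` [repeat_template()]), `n_monomers` and `mode`
#'   (see [build_5s_array()]).
#' @param gc Background GC content.
#' @param seed Integer seed.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(genome_length, families = list(), array_specs = list(),
                        gc = 0.38, seed = 1) {
  props <- vapply(families, function(f) f$target_proportion, 1.0)
  divs <- vapply(families, function(f) f$per_copy_divergence, 1.0)
  if (length(props) && sum(props) >= 1)
    stop("sum of target_proportions must be < 1")
  if (length(divs) && any(divs < 0 | divs > 0.3))
    stop("per_copy_divergence must be in [0, 0.3]")
  structure(list(genome_length = genome_length, families = families,
                 array_specs = array_specs, gc = gc, seed = seed),
            class = "genome_spec")
}

#' Build a synthetic genome with a ground-truth manifest
#'
#' The background is i.i.d. random sequence at the spec's GC; each family is
#' planted as independently diverged copies (dispersed, random strand) or
#' tandem monomer arrays until the realized proportion is within 10%
#' relative of its target. 5S array specs are planted as whole arrays with
#' their true labels. The manifest records every planted copy's coordinates,
#' strand and divergence; realized proportions are recomputable from it.
#'
#' @param spec A [genome_spec()].
#' @return List with `genome` (character), and `truth`: `copies`
#'   (per-copy manifest), `arrays` and `array_monomers` (5S array truth),
#'   `proportions` (realized per family), `background_bp`, `genome_length`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    G <- spec$genome_length
    units <- list()   # each: list(seq, rows = copies rows, fam, array info)
    for (f in spec$families) {
      tpl <- f$template
      len <- nchar(tpl$sequence)
      n_copies <- max(1L, round(f$target_proportion * G / len))
      realized <- n_copies * len / G
      if (abs(realized - f$target_proportion) / f$target_proportion > 0.10)
        stop("family ", tpl$name, ": realized proportion ", signif(realized, 3),
             " not within 10% of target (copy length too coarse for genome)")
      if (f$arrangement == "dispersed") {
        for (i in seq_len(n_copies)) {
          s <- mutate_dna(tpl$sequence, f$per_copy_divergence)
          strand <- sample(c("+", "-"), 1)
          if (strand == "-") s <- revcomp(s)
          units[[length(units) + 1]] <- list(
            seq = s, fam = tpl$name, class = tpl$repeat_class,
            strand = strand, divergence = f$per_copy_divergence)
        }
      } else { # tandem: group monomers into arrays of 10-30
        left <- n_copies
        while (left > 0) {
          m <- min(left, sample(10:30, 1))
          left <- left - m
          mono <- vapply(seq_len(m), function(i)
            mutate_dna(tpl$sequence, f$per_copy_divergence), "")
          units[[length(units) + 1]] <- list(
            seq = paste(mono, collapse = ""), fam = tpl$name,
            class = tpl$repeat_class, strand = "+",
            divergence = f$per_copy_divergence, n_monomers = m,
            monomer_len = len)
        }
      }
    }
    for (a in spec$array_specs) {
      tpl <- a$template
      gi <- feature_interval(tpl, "gene_5S")
      gene <- subseq0(tpl$sequence, gi[1], gi[2])
      nts <- subseq0(tpl$sequence, gi[2], nchar(tpl$sequence))
      arr <- build_5s_array(gene, nts, a$n_monomers, a$mode,
                            divergence = if (is.null(a$divergence)) 0.02 else a$divergence)
      units[[length(units) + 1]] <- list(
        seq = arr$sequence, fam = tpl$name, class = "rDNA_5S", strand = "+",
        divergence = NA_real_, array = arr)
    }
    planted_bp <- sum(vapply(units, function(u) nchar(u$seq), 1L))
    B <- G - planted_bp
    if (B < length(units) + 1)
      stop("target proportions unreachable within genome_length")
    bg <- random_dna(B, spec$gc)
    if (length(units)) units <- units[sample.int(length(units))]
    cuts <- sort(sample.int(B - 1, length(units)))
    # assemble genome and assign coordinates
    copies <- list(); arrays <- list(); monos <- list()
    pieces <- character(2 * length(units) + 1)
    prev <- 0L; off <- 0L; arr_id <- 0L
    for (i in seq_along(units)) {
      u <- units[[i]]
      pieces[2 * i - 1] <- subseq0(bg, prev, cuts[i])
      start <- cuts[i] + off
      pieces[2 * i] <- u$seq
      ulen <- nchar(u$seq)
      if (!is.null(u$array)) {
        arr_id <- arr_id + 1L
        arrays[[length(arrays) + 1]] <- data.frame(
          array_id = arr_id, family = u$fam, label = u$array$label,
          start = start, end = start + ulen,
          n_monomers = nrow(u$array$monomers))
        m <- u$array$monomers
        m$array_id <- arr_id
        m$start <- m$start + start; m$end <- m$end + start
        m$gene_start <- m$gene_start + start; m$gene_end <- m$gene_end + start
        monos[[length(monos) + 1]] <- m
      } else if (!is.null(u$n_monomers)) {
        mstart <- start + (seq_len(u$n_monomers) - 1L) * u$monomer_len
        copies[[length(copies) + 1]] <- data.frame(
          family = u$fam, class = u$class, start = mstart,
          end = mstart + u$monomer_len, strand = u$strand,
          divergence = u$divergence)
      } else {
        copies[[length(copies) + 1]] <- data.frame(
          family = u$fam, class = u$class, start = start, end = start + ulen,
          strand = u$strand, divergence = u$divergence)
      }
      prev <- cuts[i]; off <- off + ulen
    }
    pieces[2 * length(units) + 1] <- subseq0(bg, prev, B)
    genome <- paste(pieces, collapse = "")
    copies <- if (length(copies)) do.call(rbind, copies) else
      data.frame(family = character(), class = character(), start = integer(),
                 end = integer(), strand = character(), divergence = numeric())
    if (nrow(copies)) copies$copy_id <- seq_len(nrow(copies))
    arrays <- if (length(arrays)) do.call(rbind, arrays) else NULL
    monos <- if (length(monos)) do.call(rbind, monos) else NULL
    props <- if (nrow(copies))
      tapply(copies$end - copies$start, copies$family, sum) / G else
      numeric(0)
    list(genome = genome,
         truth = list(copies = copies, arrays = arrays, array_monomers = monos,
                      proportions = c(props),
                      background_bp = G - planted_bp, genome_length = G))
  })
}

OTHER_BASE <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                     nrow = 3, dimnames = list(NULL, c("A", "C", "G", "T")))

add_subst_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs)
  if (length(unique(L)) == 1) { # fixed-length fast path
    M <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = L[1])
    ntot <- rbinom(1, length(M), rate)
    if (ntot > 0) {
      pos <- sample.int(length(M), ntot)
      b <- M[pos]
      ok <- b %in% colnames(OTHER_BASE)
      M[pos[ok]] <- OTHER_BASE[cbind(sample.int(3, sum(ok), TRUE),
                                     match(b[ok], colnames(OTHER_BASE)))]
    }
    return(do.call(paste0, as.data.frame(t(M), stringsAsFactors = FALSE)))
  }
  k <- rbinom(length(seqs), L, rate)
  for (i in which(k > 0)) {
    v <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    p <- sample.int(length(v), k[i])
    ok <- v[p] %in% colnames(OTHER_BASE)
    v[p[ok]] <- OTHER_BASE[cbind(sample.int(3, sum(ok), TRUE),
                                 match(v[p[ok]], colnames(OTHER_BASE)))]
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

#' Simulate paired short reads from a genome
#'
#' Uniformly positioned insert pairs; the forward read is the insert's first
#' `read_length` bases and the mate is the reverse complement of its last
#' `read_length` bases. Substitution errors only. Reads are exactly
#' `read_length` nt. Source intervals are kept (`src_start`, `src_end` of
#' the insert) so reads can be assigned to planted copies via the manifest.
#'
#' @param genome Genome sequence (character) or the list from
#'   [build_genome()].
#' @param n_pairs Number of read pairs (> 0).
#' @param read_length Read length, nt (default 100).
#' @param insert_mean,insert_sd Insert size distribution, bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param species Species code prefixed to read ids.
#' @return A [read_set()] of paired reads.
#' @export
simulate_short_reads <- function(genome, n_pairs, read_length = 100,
                                 insert_mean = 300, insert_sd = 30,
                                 error_rate = 0.01, seed = NULL,
                                 species = "SP1") {
  if (is.list(genome)) genome <- genome$genome
  if (n_pairs <= 0) stop("n_pairs must be positive")
  G <- nchar(genome)
  stopifnot(read_length <= insert_mean, G > insert_mean)
  with_seed(seed, {
    ins <- pmax(read_length, pmin(round(rnorm(n_pairs, insert_mean, insert_sd)),
                                  G - 1))
    start <- floor(runif(n_pairs) * (G - ins))  # 0-based insert start
    r1 <- substring(genome, start + 1, start + read_length)
    r2 <- revcomp(substring(genome, start + ins - read_length + 1, start + ins))
    r1 <- add_subst_errors(r1, error_rate)
    r2 <- add_subst_errors(r2, error_rate)
    id1 <- sprintf("%s_%07d/1", species, seq_len(n_pairs))
    id2 <- sprintf("%s_%07d/2", species, seq_len(n_pairs))
    df <- data.frame(
      id = c(rbind(id1, id2)), seq = c(rbind(r1, r2)),
      mate = c(rbind(id2, id1)), species = species,
      src_start = c(rbind(start, start + ins - read_length)),
      src_end = c(rbind(start + read_length, start + ins)),
      src_strand = c(rbind(rep("+", n_pairs), rep("-", n_pairs))),
      stringsAsFactors = FALSE)
    read_set(df, species = species)
  })
}

add_longread_errors <- function(seqs, rate, sub_frac = 0.2, ins_frac = 0.4) {
  if (rate <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    v <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    ne <- rbinom(1, length(v), rate)
    if (ne == 0) next
    pos <- sample.int(length(v), ne)
    type <- sample(c("s", "i", "d"), ne, TRUE,
                   prob = c(sub_frac, ins_frac, 1 - sub_frac - ins_frac))
    sp <- pos[type == "s"]
    ok <- v[sp] %in% colnames(OTHER_BASE)
    v[sp[ok]] <- OTHER_BASE[cbind(sample.int(3, sum(ok), TRUE),
                                  match(v[sp[ok]], colnames(OTHER_BASE)))]
    v[pos[type == "d"]] <- ""
    ip <- pos[type == "i"]
    if (length(ip))
      v[ip] <- paste0(sample(c("A", "C", "G", "T"), length(ip), TRUE), v[ip])
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

#' Simulate long reads from a genome
#'
#' Log-normal read lengths truncated to `length_range`, uniform positions,
#' random strand, indel-dominated error model (40% insertion, 40% deletion,
#' 20% substitution by default). Source intervals and strands are kept for
#' manifest-based validation.
#'
#' @param genome Genome sequence or [build_genome()] output.
#' @param n_reads Number of reads (> 0).
#' @param length_range Min/max read length, bp (default c(500, 72000)).
#' @param error_rate Per-base error rate (default 0.12, configurable; the
#'   indel-rich profile emulates noisy long-read chemistry).
#' @param meanlog,sdlog Log-normal length parameters.
#' @param seed Integer seed.
#' @param species Species code.
#' @return A [read_set()] of unpaired long reads.
#' @export
simulate_long_reads <- function(genome, n_reads, length_range = c(500, 72000),
                                error_rate = 0.12, meanlog = log(8000),
                                sdlog = 0.7, seed = NULL, species = "SP1") {
  if (is.list(genome)) genome <- genome$genome
  if (n_reads <= 0) stop("n_reads must be positive")
  stopifnot(length_range[1] > 0, length_range[2] >= length_range[1])
  G <- nchar(genome)
  with_seed(seed, {
    L <- rlnorm(n_reads, meanlog, sdlog)
    for (it in 1:20) {
      bad <- L < length_range[1] | L > length_range[2]
      if (!any(bad)) break
      L[bad] <- rlnorm(sum(bad), meanlog, sdlog)
    }
    L <- pmin(pmax(round(L), length_range[1]), min(length_range[2], G - 1))
    start <- floor(runif(n_reads) * (G - L))
    seqs <- substring(genome, start + 1, start + L)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    seqs <- add_longread_errors(seqs, error_rate)
    df <- data.frame(
      id = sprintf("%s_LR%06d", species, seq_len(n_reads)), seq = seqs,
      mate = NA_character_, species = species,
      src_start = start, src_end = start + L, src_strand = strand,
      stringsAsFactors = FALSE)
    read_set(df, species = species)
  })
}

#' Write a genome to FASTA
#' @param genome Genome sequence or [build_genome()] output.
#' @param file Output path.
#' @param name Sequence name.
#' @export
write_genome_fasta <- function(genome, file, name = "genome") {
  if (is.list(genome)) genome <- genome$genome
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- name
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Write the ground-truth manifest as TSV and JSON
#' @param truth The `truth` element of [build_genome()] output.
#' @param prefix Output path prefix; writes `<prefix>_copies.tsv`,
#'   `<prefix>_arrays.tsv` (if any) and `<prefix>.json`.
#' @export
write_manifest <- function(truth, prefix) {
  write.table(truth$copies, paste0(prefix, "_copies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth$arrays))
    write.table(truth$arrays, paste0(prefix, "_arrays.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
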