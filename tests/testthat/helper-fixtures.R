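# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

fix_ltr <- function() fixture("ltr", function()
  build_ltr_element(4000, 300, seed = 101, name = "LTR1"))

fix_tir <- function() fixture("tir", function()
  build_tir_element(3000, 25, seed = 102, name = "TIR1"))

fix_35s <- function() fixture("u35", function() build_35s_unit(seed = 103))

fix_5s <- function() fixture("t5", function() build_5s_template(seed = 104))

# small two-family genome + reads + clusters, reused across modules
fix_small_sim <- function() fixture("small_sim", function() {
  ltr <- fix_ltr()
  sat <- build_satellite(500, seed = 105, name = "SAT1")
  spec <- genome_spec(1.5e6, families = list(
    list(template = ltr, target_proportion = 0.06,
         per_copy_divergence = 0.03, arrangement = "dispersed"),
    list(template = sat, target_proportion = 0.02,
         per_copy_divergence = 0.03, arrangement = "tandem")),
    seed = 106)
  gt <- build_genome(spec)
  rs <- simulate_short_reads(gt, n_pairs = 3000, error_rate = 0.01, seed = 107)
  cl <- build_clusters(rs)
  list(gt = gt, rs = rs, cl = cl)
})

random_reads <- function(n, len = 100, seed = NULL) {
  with_seed(seed, vapply(seq_len(n), function(i) random_dna(len, 0.5), ""))
}

# Brute-force clustering oracle: all-vs-all similar() graph components.
brute_force_clusters <- function(seqs, params = similarity_params()) {
  n <- length(seqs)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (similar(seqs[i], seqs[j], params))
      edges <- rbind(edges, c(i, j))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

# canonical signature of a partition (order-independent)
partition_signature <- function(labels) {
  grp <- split(seq_along(labels), labels)
  grp <- lapply(grp, sort)
  grp <- grp[order(vapply(grp, `[`, 1L, 1))]
  unname(grp)
}

# Biostrings-based local alignment oracle for the similar() contract
oracle_similar <- function(a, b, params = similarity_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch)
  need <- ceiling(params$min_coverage * min(nchar(a), nchar(b)))
  for (bb in c(b, revcomp(b))) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(bb), type = "local",
      substitutionMatrix = mat, gapOpening = 0,
      gapExtension = abs(params$gap))
    cols <- Biostrings::nchar(pa)
    matches <- Biostrings::nmatch(pa)
    if (cols >= need && matches / cols >= params$min_identity) return(TRUE)
  }
  FALSE
}

reverse_translate_test <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  codons <- split(names(gc), unname(gc))
  a <- strsplit(aa, "")[[1]]
  paste(vapply(a, function(x) codons[[x]][1], ""), collapse = "")
}
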