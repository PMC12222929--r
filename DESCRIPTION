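Package: repeatome
Title: Repeatome Profiling from Low-Coverage Reads with Long-Read Repeat
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the repetitive fraction of a genome from
    low-coverage sequencing reads. Short paired reads are filtered,
    subsampled, trimmed and clustered into repeat families by
    similarity-graph connected components (90% identity over 55% of the
    read length), with genome-proportion accounting per cluster and
    supercluster. Cluster contigs seed reconstruction of full repeat
    elements from long reads (top-20 hit search, dotplot-style copy
    detection, multiple-alignment consensus, protein-domain and
    terminal-repeat annotation). 5S rDNA tandem arrays on long reads are
    scanned for monomers and classified as regular, potentially regular
    or pseudogenic from hit geometry. Comparative statistics include
    cross-species abundance matrices, Kimura 2-parameter distances and
    Tajima's relative-rate test. A synthetic-genome simulator with a
    ground-truth manifest supports validation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stringi,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    pheatmap,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
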