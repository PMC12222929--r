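# Publication-style outputs. Every figure is a derived view of a numeric
# twin (TSV/JSON); tests assert the numbers, never pixels.

#' Self-dotplot word-match matrix
#'
#' Exact word matches of a sequence against itself on both strands
#' (reverse-complement matches carry strand `-`), as maximal diagonal
#' runs. Annotation intervals are expanded by `zoom` bp on each side, the
#' convention for marking gene hits on array dotplots.
#'
#' @param sequence Sequence (>= 2 x word size).
#' @param word Word size (>= 4; default 10).
#' @param zoom Annotation context, bp (default 500).
#' @param annotations Optional `data.frame` with `start`, `end` (and
#'   optionally `label`) intervals to box.
#' @return Object of class `dotplot`: `matches` (run table), `annotations`
#'   (zoom-expanded), `length`, `word`.
#' @export
self_dotplot <- function(sequence, word = 10, zoom = 500, annotations = NULL) {
  stopifnot(word >= 4, zoom >= 0, nchar(sequence) >= 2 * word)
  runs <- cpp_word_runs(sequence, sequence, word, both_strands = TRUE)
  if (!is.null(annotations)) {
    annotations$zoom_start <- pmax(0L, annotations$start - as.integer(zoom))
    annotations$zoom_end <- pmin(nchar(sequence),
                                 annotations$end + as.integer(zoom))
  }
  structure(list(matches = runs, annotations = annotations,
                 length = nchar(sequence), word = word, zoom = zoom),
            class = "dotplot")
}

#' @export
print.dotplot <- function(x, ...) {
  off <- x$matches[x$matches$strand == "+" & x$matches$a_start != x$matches$b_start, ]
  cat(sprintf("<dotplot> %d bp, word %d: %d runs (%d off-diagonal forward)\n",
              x$length, x$word, nrow(x$matches), nrow(off)))
  invisible(x)
}

#' @export
plot.dotplot <- function(x, ...) {
  m <- x$matches
  p <- ggplot2::ggplot(m) +
    ggplot2::geom_segment(ggplot2::aes(
      x = a_start, y = b_start,
      xend = a_start + length, yend = ifelse(strand == "+", b_start + length,
                                             b_start - length),
      colour = strand), linewidth = 0.3) +
    ggplot2::coord_fixed(xlim = c(0, x$length), ylim = c(0, x$length)) +
    ggplot2::scale_colour_manual(values = c(`+` = "black", `-` = "red")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(x$annotations)) {
    p <- p + ggplot2::geom_rect(
      data = x$annotations,
      ggplot2::aes(xmin = zoom_start, xmax = zoom_end,
                   ymin = zoom_start, ymax = zoom_end),
      inherit.aes = FALSE, fill = NA, colour = "red", linewidth = 0.4)
  }
  p
}

#' Render run reports: figures plus machine-readable twins
#'
#' Writes, for whichever inputs are given: the supercluster bar chart
#' (bar height = read count, bar width = genome proportion), the
#' comparative bubble layout (bubble size = relative share, label =
#' within-genome percent), and the K2P heatmap — each with a TSV twin
#' carrying exactly the plotted numbers, plus one JSON summary.
#'
#' @param out_dir Output directory (created if needed).
#' @param clusters Optional `repeat_clusters` (after
#'   [link_superclusters()]).
#' @param abundance Optional [abundance_matrix()].
#' @param k2p Optional [distance_matrix()] result.
#' @return Invisible list of written paths and the numeric twins.
#' @export
render_reports <- function(out_dir, clusters = NULL, abundance = NULL,
                           k2p = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(); twins <- list()
  wr <- function(df, name) {
    f <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- f
    twins[[name]] <<- df
  }
  if (!is.null(clusters) && !all(is.na(clusters$clusters$supercluster_id))) {
    sc <- supercluster_table(clusters)
    wr(sc, "superclusters")
    sc$x1 <- cumsum(sc$genome_proportion)
    sc$x0 <- sc$x1 - sc$genome_proportion
    p <- ggplot2::ggplot(sc) +
      ggplot2::geom_rect(ggplot2::aes(xmin = x0, xmax = x1, ymin = 0,
                                      ymax = size), colour = "grey30",
                         fill = "steelblue") +
      ggplot2::labs(x = "genome proportion (cumulative)", y = "reads") +
      ggplot2::theme_classic()
    f <- file.path(out_dir, "superclusters.pdf")
    ggplot2::ggsave(f, p, width = 7, height = 4)
    paths$superclusters_fig <- f
  }
  if (!is.null(abundance)) {
    long <- as.data.frame(as.table(abundance$relative_share),
                          stringsAsFactors = FALSE)
    names(long) <- c("repeat_name", "species", "relative_share")
    wg <- as.data.frame(as.table(abundance$within_genome),
                        stringsAsFactors = FALSE)
    long$within_genome <- wg$Freq
    wr(long, "abundance")
    p <- ggplot2::ggplot(long, ggplot2::aes(species, repeat_name)) +
      ggplot2::geom_point(ggplot2::aes(size = relative_share)) +
      ggplot2::geom_text(ggplot2::aes(
        label = sprintf("%.2g%%", 100 * within_genome)),
        vjust = -1.5, size = 2.5) +
      ggplot2::scale_size_area(max_size = 10) +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "abundance.pdf")
    ggplot2::ggsave(f, p, width = 7, height = 5)
    paths$abundance_fig <- f
  }
  if (!is.null(k2p)) {
    M <- k2p$matrix[k2p$order, k2p$order]
    wr(as.data.frame(M), "k2p_matrix")
    f <- file.path(out_dir, "k2p_heatmap.pdf")
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::pdf(f, width = 7, height = 6)
      pheatmap::pheatmap(k2p$matrix, clustering_method = "average")
      grDevices::dev.off()
    } else {
      long <- as.data.frame(as.table(M), stringsAsFactors = FALSE)
      names(long) <- c("a", "b", "d")
      p <- ggplot2::ggplot(long, ggplot2::aes(a, b, fill = d)) +
        ggplot2::geom_tile() + ggplot2::theme_minimal()
      ggplot2::ggsave(f, p, width = 7, height = 6)
    }
    paths$k2p_fig <- f
  }
  summary_file <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(outputs = lapply(paths, as.character),
         n_superclusters = if (!is.null(clusters))
           length(unique(clusters$clusters$supercluster_id)) else NULL,
         n_repeats = if (!is.null(abundance)) nrow(abundance$relative_share)
           else NULL,
         k2p_max = if (!is.null(k2p)) max(k2p$matrix) else NULL),
    summary_file, auto_unbox = TRUE, digits = NA)
  paths$summary <- summary_file
  invisible(list(paths = paths, twins = twins))
}
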