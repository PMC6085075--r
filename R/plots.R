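# ggplot2 views of the main result types. These are thin: the tested
# artifacts are the underlying tables; plots are for interactive inspection.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_segment
#'   facet_grid labs theme_minimal scale_x_continuous coord_polar geom_col
NULL

#' Plot a genome-wide LOD curve
#'
#' LOD by physical position, faceted by chromosome, with dashed lines at the
#' permutation LOD values matching the significant and suggestive tiers.
#'
#' @param object a `qtl_scan`.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot qtl_scan
autoplot.qtl_scan <- function(object, ...) {
  mk <- object$markers[!is.na(object$markers$lod), ]
  thr <- quantile(object$perm_max, c(0.95, 0.37), names = FALSE)
  ggplot(mk, aes(x = .data$pos_mb, y = .data$lod)) +
    geom_line() +
    geom_hline(yintercept = thr[1], linetype = "dashed", colour = "red") +
    geom_hline(yintercept = thr[2], linetype = "dashed", colour = "grey50") +
    facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    labs(x = "position (Mb)", y = "LOD",
         title = paste0("QTL scan: ", object$trait_id)) +
    theme_minimal()
}

#' Plot integrated prioritization scores across a region
#'
#' Integrated score per gene along the region, the permutation threshold as a
#' dashed line, significant genes highlighted.
#'
#' @param object a `priority_table`.
#' @param genes optional gene annotation tibble supplying positions; without
#'   it genes are plotted by rank.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot priority_table
autoplot.priority_table <- function(object, genes = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(genes)) {
    df <- left_join(df, genes[c("gene_id", "center_mb")], by = "gene_id")
    xvar <- "center_mb"; xlab <- "gene center (Mb)"
  } else {
    df$rank_x <- rev(df$rank); xvar <- "rank_x"; xlab <- "gene (by rank)"
  }
  ggplot(df, aes(x = .data[[xvar]], y = .data$integrated,
                 colour = .data$significant)) +
    geom_point(size = 2) +
    geom_hline(yintercept = attr(object, "threshold"), linetype = "dashed") +
    labs(x = xlab, y = "integrated score",
         title = paste0("Candidate prioritization: ", attr(object, "trait_id")),
         colour = "significant") +
    theme_minimal()
}

#' Plot a hiveplot graph
#'
#' Deterministic hive layout: axes are rays at fixed angles, nodes sit at
#' their radial coordinate, edges are straight chords (a schematic rendering;
#' the graph structure itself is the tested artifact).
#'
#' @param object a `hive_graph`.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot hive_graph
autoplot.hive_graph <- function(object, ...) {
  axes <- sort(unique(object$nodes$axis))
  angle <- setNames(seq(0, 2 * pi, length.out = length(axes) + 1)[seq_along(axes)],
                    axes)
  nd <- object$nodes
  nd$x <- cos(angle[nd$axis]) * nd$radius
  nd$y <- sin(angle[nd$axis]) * nd$radius
  p <- ggplot(nd, aes(x = .data$x, y = .data$y))
  if (nrow(object$edges)) {
    ed <- object$edges
    ed$x0 <- nd$x[match(ed$from, nd$id)]; ed$y0 <- nd$y[match(ed$from, nd$id)]
    ed$x1 <- nd$x[match(ed$to, nd$id)];   ed$y1 <- nd$y[match(ed$to, nd$id)]
    ed <- ed[complete.cases(ed[c("x0", "y0", "x1", "y1")]), ]
    p <- p + geom_segment(data = ed,
                          aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                              yend = .data$y1, colour = .data$kind),
                          alpha = 0.5, inherit.aes = FALSE)
  }
  p + geom_point(aes(shape = .data$axis), size = 2) +
    labs(title = paste0("Hiveplot: ", object$trait_id)) +
    theme_minimal()
}
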