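# Fixed overlap colour scale: 0 -> blue, 0.5 -> yellow, 1 -> red. Anchored,
# never rescaled to the data, so layers are comparable across sizes/methods.
.overlap_fill <- function() {
  ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#FFD92F",
                                high = "#B2182B", midpoint = 0.5,
                                limits = c(0, 1), name = "overlap")
}

.matrix_cells <- function(mat) {
  m <- nrow(mat)
  idx <- which(!is.na(mat), arr.ind = TRUE)
  data.frame(i = idx[, 1L], j = idx[, 2L],
             overlap = mat[idx],
             n = attr(mat, "n") %||% NA_integer_)
}

#' Render a pine plot
#'
#' A pine plot stacks one triangular heat-map layer per sample size, largest
#' n on top: cell (i, j) of a layer shows the Jaccard overlap between the
#' significant calls of replicates i and j at that size, on a fixed
#' blue (0) - yellow (0.5) - red (1) scale; diagonal cells are the constant
#' reference red. Rising overall redness down-to-up is the visual signature
#' of reproducibility improving with sample size.
#'
#' @param layers List of \code{OverlapMatrix}, one per sample size, all with
#'   the same replicate count; drawn with the largest n as the top layer.
#' @param out Output image path (extension selects the device).
#' @param title Optional plot title.
#' @return \code{out}, invisibly.
#' @export
render_pine_plot <- function(layers, out, title = NULL) {
  if (length(layers) == 0L) stop("empty layer list")
  ms <- vapply(layers, nrow, integer(1))
  if (length(unique(ms)) != 1L) stop("all layers must share the replicate count m")
  ns <- vapply(layers, function(l) as.integer(attr(l, "n")), integer(1))
  if (anyNA(ns)) stop("every layer needs its sample size attribute 'n'")
  layers <- layers[order(ns, decreasing = TRUE)]
  cells <- do.call(rbind, lapply(layers, .matrix_cells))
  cells$layer <- factor(paste0("2x", cells$n),
                        levels = paste0("2x", sort(unique(cells$n), decreasing = TRUE)))
  gg <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$j, y = .data$i,
                                            fill = .data$overlap)) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.2) +
    .overlap_fill() +
    ggplot2::scale_y_reverse(breaks = NULL) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$layer), switch = "y") +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
  ggplot2::ggsave(out, gg, width = 5, height = 1.6 * length(layers) + 1,
                  limitsize = FALSE)
  invisible(out)
}

#' Render pairwise and versus-whole overlap box plots
#'
#' Two panels: the left shows the distribution of pairwise overlap scores
#' among same-size replicates, the right the overlaps between each replicate
#' and the whole-dataset analysis; x is the per-group sample size n.
#'
#' @param pairwise,vs_whole Lists of \code{OverlapMultiset} (kinds
#'   \code{pairwise} and \code{vs_whole}), one per sample size.
#' @param out Output image path.
#' @param title Optional title.
#' @return \code{out}, invisibly.
#' @export
render_overlap_boxplots <- function(pairwise, vs_whole, out, title = NULL) {
  if (length(pairwise) == 0L || length(vs_whole) == 0L) stop("empty overlap input")
  as_df <- function(ms, panel) {
    do.call(rbind, lapply(ms, function(v) {
      data.frame(n = attr(v, "n"), overlap = as.numeric(v), panel = panel)
    }))
  }
  df <- rbind(as_df(pairwise, "replicate vs replicate"),
              as_df(vs_whole, "replicate vs whole"))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n), y = .data$overlap)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~panel, nrow = 1L) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "samples per group (n)", y = "overlap score",
                  title = title) +
    ggplot2::theme_bw()
  ggplot2::ggsave(out, gg, width = 8, height = 4)
  invisible(out)
}

#' Render Kendall's W against sample size
#'
#' One series per method; undefined W values (fewer than two gene sets ever
#' called) are omitted with a message.
#'
#' @param df data.frame with columns \code{method}, \code{n}, \code{W}
#'   (NA where undefined).
#' @param out Output image path.
#' @return \code{out}, invisibly.
#' @export
render_concordance_plot <- function(df, out) {
  drop <- is.na(df$W)
  if (any(drop)) {
    message("omitting ", sum(drop), " undefined concordance value(s)")
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no defined concordance values to plot")
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$W,
                                         colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "samples per group (n)", y = "Kendall's W",
                  colour = "method") +
    ggplot2::theme_bw()
  ggplot2::ggsave(out, gg, width = 7, height = 4.5)
  invisible(out)
}

#' Render mean significant-set counts against sample size
#'
#' One series per method plus a horizontal red reference line at the size of
#' the gene set database — the maximum possible count.
#'
#' @param df data.frame with columns \code{method}, \code{n},
#'   \code{mean_count}.
#' @param db_size Number of gene sets in the database.
#' @param out Output image path.
#' @return \code{out}, invisibly.
#' @export
render_count_plot <- function(df, db_size, out) {
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$mean_count,
                                         colour = .data$method)) +
    ggplot2::geom_hline(yintercept = db_size, colour = "red") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "samples per group (n)",
                  y = "mean significant gene sets", colour = "method") +
    ggplot2::theme_bw()
  ggplot2::ggsave(out, gg, width = 7, height = 4.5)
  invisible(out)
}
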