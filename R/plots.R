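#' Manhattan-style plot of a 1D association scan
#'
#' @param object An `episcan_scan1d` result.
#' @param meta Optional per-marker metadata with `marker_id` and `chromosome`
#'   columns to color points by chromosome.
#' @param threshold Optional horizontal significance line on `-log10(p)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episcan_scan1d <- function(object, meta = NULL, threshold = NULL,
                                    ...) {
  df <- tibble::tibble(index = seq_len(nrow(object)),
                       marker_id = object$marker_id,
                       neglog10p = object$neglog10p)
  if (!is.null(meta) && "chromosome" %in% names(meta)) {
    df$chromosome <- meta$chromosome[match(df$marker_id, meta$marker_id)]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$neglog10p,
                                          colour = .data$chromosome))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$neglog10p))
  }
  p <- p + ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "marker index", y = expression(-log[10](p)),
                  title = attr(object, "trait_name")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Heatmap of a 2D association scan
#'
#' Draws the upper-triangular pair-significance matrix as a tile plot, the 2D
#' counterpart of a Manhattan plot. Intended for dense scans of modest size.
#'
#' @param object An `episcan_scan2d` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episcan_scan2d <- function(object, ...) {
  ids <- attr(object, "scan_marker_ids")
  if (is.null(ids)) ids <- unique(c(object$marker_i, object$marker_j))
  df <- tibble::tibble(i = match(object$marker_i, ids),
                       j = match(object$marker_j, ids),
                       neglog10p = object$neglog10p)
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i,
                                   fill = .data$neglog10p)) +
    ggplot2::geom_tile(na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(x = "marker index j", y = "marker index i",
                  title = attr(object, "trait_name")) +
    ggplot2::theme_minimal()
}

#' Variance-component composition plot
#'
#' @param object An `episcan_vc` fit.
#' @param ... Unused.
#' @return A ggplot object (stacked bar of the three variance fractions).
#' @export
autoplot.episcan_vc <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component,
                         levels = c("additive", "interaction", "residual"))
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$ratio,
                                   fill = .data$component)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of phenotypic variance",
                  title = sprintf("%s: H = %.3f", object$trait_name,
                                  object$H)) +
    ggplot2::theme_minimal()
}

#' Heritability vs. predictability-threshold curve plot
#'
#' @param object An `episcan_predcurve` tibble from [pred_threshold_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episcan_predcurve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$H)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_selected), na.rm = TRUE) +
    ggplot2::labs(x = "PRED threshold", y = "broad-sense heritability H",
                  size = "markers kept") +
    ggplot2::theme_minimal()
}

#' Plot a weighted association network
#'
#' Simple circular-layout rendering; for richer layouts convert with
#' [as_igraph()].
#'
#' @param x An `episcan_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_network <- function(x, ...) {
  nodes <- x$nodes
  if (length(nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  ang <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[seq_along(nodes)]
  pos <- tibble::tibble(marker_id = nodes, x = cos(ang), y = sin(ang))
  ed <- x$edges
  ed$x <- pos$x[match(ed$marker_i, nodes)]
  ed$y <- pos$y[match(ed$marker_i, nodes)]
  ed$xend <- pos$x[match(ed$marker_j, nodes)]
  ed$yend <- pos$y[match(ed$marker_j, nodes)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey50") +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y), size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                    label = .data$marker_id), size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2), name = expression(-log[10](p))) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
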