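#' Mean-variance diagnostic plot
#'
#' Plots the voom-style mean-variance relationship: sqrt residual SD against
#' average log2 count, with the fitted LOWESS trend(s). For a
#' `voomByGroup` fit, `mode = "combine"` overlays the per-group curves in a
#' single panel (legend annotated with each group's common BCV to 3
#' decimals); `mode = "separate"` facets one panel per group with that
#' group's training scatter.
#'
#' @param fit A `pbvoom_fit` (any method) or a single `mv_trend`.
#' @param mode `"combine"` or `"separate"`.
#' @param points Draw the training scatter (always on in separate mode).
#' @return A ggplot object.
#' @export
plot_mean_variance <- function(fit, mode = c("combine", "separate"),
                               points = (mode == "separate")) {
  mode <- match.arg(mode)
  if (inherits(fit, "mv_trend")) {
    fit <- structure(list(trend = fit, method = "voom", group_trends = NULL),
                     class = "pbvoom_fit")
  }
  stopifnot(inherits(fit, "pbvoom_fit"))
  trends <- fit$group_trends
  if (is.null(trends)) trends <- list(all = fit$trend)
  labs <- names(trends)
  if (!is.null(fit$group_bcv)) {
    b <- fit$group_bcv[labs]
    labs <- ifelse(is.na(b), labs,
                   sprintf("%s (BCV = %.3f)", labs, b))
  }
  curves <- dplyr::bind_rows(lapply(seq_along(trends), function(i)
    tibble::tibble(group = labs[i], x = trends[[i]]$x, y = trends[[i]]$y)))
  pts <- dplyr::bind_rows(lapply(seq_along(trends), function(i)
    tibble::tibble(group = labs[i], x = trends[[i]]$train_x,
                   y = trends[[i]]$train_y)))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = .data$group))
  if (isTRUE(points) || mode == "separate")
    p <- p + ggplot2::geom_point(data = pts, size = 0.3, alpha = 0.3,
                                 colour = "grey40")
  p <- p + ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Average log2 count",
                  y = expression(sqrt("residual SD")),
                  colour = NULL,
                  title = sprintf("Mean-variance trend (%s)", fit$method)) +
    ggplot2::theme_bw()
  if (mode == "separate")
    p <- p + ggplot2::facet_wrap(~group) +
      ggplot2::theme(legend.position = "none")
  p
}

#' @rdname plot_mean_variance
#' @param object,x A `pbvoom_fit`.
#' @param ... Passed to [plot_mean_variance()].
#' @export
autoplot.pbvoom_fit <- function(object, ...) plot_mean_variance(object, ...)

#' @rdname plot_mean_variance
#' @export
plot.pbvoom_fit <- function(x, ...) print(plot_mean_variance(x, ...))

#' Pairwise sample distances on the leading-logFC scale
#'
#' The distance between two samples is the root-mean-square of the `top`
#' largest absolute log2 fold changes (log-CPM differences) between them.
#'
#' @param E Gene-by-sample log-CPM matrix (or a `log_cpm` object).
#' @param top Number of top genes per pair.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
mds_distances <- function(E, top = 500) {
  if (inherits(E, "log_cpm")) E <- E$values
  n <- ncol(E)
  top <- min(top, nrow(E))
  d <- matrix(0, n, n, dimnames = list(colnames(E), colnames(E)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dif2 <- (E[, i] - E[, j])^2
    d[i, j] <- d[j, i] <-
      sqrt(mean(sort(dif2, decreasing = TRUE)[seq_len(top)]))
  }
  d
}

#' MDS plot of pseudo-bulk samples
#'
#' Classical multidimensional scaling of the leading-logFC pairwise
#' distances ([mds_distances()]), colored by group.
#'
#' @param E Gene-by-sample log-CPM matrix or `log_cpm` object.
#' @param group Group label per sample.
#' @param top Number of top genes per pair for the distance.
#' @return A ggplot object; the coordinates are in
#'   `attr(p$data, "distances")`-free tidy form in `p$data`.
#' @export
plot_mds <- function(E, group, top = 500) {
  if (inherits(E, "log_cpm")) E <- E$values
  if (ncol(E) < 3) stop("need at least 3 samples for an MDS plot")
  d <- mds_distances(E, top = top)
  xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  df <- tibble::tibble(sample_id = colnames(E),
                       dim1 = xy[, 1], dim2 = xy[, 2],
                       group = as.character(group))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$group,
                                   label = .data$sample_id)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Leading logFC dim 1", y = "Leading logFC dim 2",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Save a plot to file
#'
#' Thin wrapper over [ggplot2::ggsave()] used by the command-line interface.
#'
#' @param p A ggplot object.
#' @param path Output path (`.png` or `.svg`).
#' @param width,height Device size in inches.
#' @return Invisibly, the path.
#' @export
save_plot <- function(p, path, width = 7, height = 5) {
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 150)
  invisible(path)
}
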