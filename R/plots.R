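#' Plot a trajectory embedding
#'
#' Scatter plot of the t-SNE map, colored by a per-site covariate (class
#' label, response FDR, or time of maximal binding).
#'
#' @param embedding a `pftc_embedding`.
#' @param color named vector (by site id) or data.frame (`site_id` plus one
#'   column) of per-site values for the color scale; `NULL` for plain points.
#' @return a ggplot object.
#' @export
plot_embedding <- function(embedding, color = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_embedding requires the ggplot2 package")
  }
  df <- as.data.frame(embedding)
  lab <- "value"
  if (!is.null(color)) {
    if (is.data.frame(color)) {
      lab <- setdiff(names(color), "site_id")[1]
      df$value <- color[[lab]][match(df$site_id, color$site_id)]
    } else {
      df$value <- color[df$site_id]
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(
      x = "t-SNE 1", y = "t-SNE 2",
      title = sprintf("Binding-profile embedding (perplexity %g)",
                      attr(embedding, "perplexity"))) +
    ggplot2::theme_minimal()
  if (is.null(color)) {
    p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$value),
                            size = 0.6, alpha = 0.7) +
      ggplot2::labs(color = lab)
  }
}

#' Occupancy heatmap in row-max or absolute normalization
#'
#' Renders the site-by-time occupancy matrix with rows grouped by time of
#' maximal binding (see [order_for_heatmap()]), so the two normalization
#' views can be compared at identical row order.
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @param mode `"row-max"` or `"absolute"`.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_occupancy_heatmap <- function(x, mode = c("row-max", "absolute"), ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_occupancy_heatmap requires the pheatmap package")
  }
  ord <- order_for_heatmap(x, mode = mode)
  invisible(pheatmap::pheatmap(ord$view, cluster_rows = FALSE,
                               cluster_cols = FALSE, show_rownames = FALSE,
                               ...))
}

#' Plot a site or class-average binding profile
#'
#' Mean occupancy over time with a +/- 1 sd ribbon.
#'
#' @param profile a `pftc_profile` from [site_profile()] or
#'   [class_average_profile()].
#' @return a ggplot object.
#' @export
plot_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_profile requires the ggplot2 package")
  }
  df <- as.data.frame(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time after stimulation (min)",
                  y = "normalized occupancy",
                  title = attr(profile, "site_id")) +
    ggplot2::theme_minimal()
}
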