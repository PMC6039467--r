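#' Heatmap of an anchor-centred matrix
#'
#' Rows keep their ranked order (rank 1 at the top). `smooth_rows`
#' applies a rolling mean over ranked rows for display only; the stored
#' matrix is never smoothed.
#'
#' @param object an `anchor_matrix`.
#' @param smooth_rows rolling-window size over ranked rows (display
#'   only); 0 disables smoothing.
#' @param trim upper quantile at which the colour scale saturates.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot anchor_matrix
#' @export
autoplot.anchor_matrix <- function(object, smooth_rows = 50, trim = 0.98,
                                   ...) {
  values <- if (smooth_rows > 1) {
    rolling_row_mean(object$values, smooth_rows)
  } else object$values
  df <- tibble(
    rank = rep(seq_len(nrow(values)), times = ncol(values)),
    offset = rep(object$bin_offsets + object$bin_size / 2,
                 each = nrow(values)),
    value = pmin(as.vector(values),
                 stats::quantile(values, trim, na.rm = TRUE))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$rank,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::labs(x = "distance from anchor centre (bp)",
                  y = "peaks (ranked)")
}

#' @rdname autoplot.anchor_matrix
#' @method autoplot motif_density
#' @export
autoplot.motif_density <- function(object, smooth_rows = 1, trim = 0.98,
                                   ...) {
  p <- autoplot.anchor_matrix(object, smooth_rows = smooth_rows,
                              trim = trim)
  p + ggplot2::labs(fill = "hits/bp/peak", title = object$pwm)
}

#' Average profiles of an anchor matrix by row group
#'
#' @param object an `anchor_matrix` or `motif_density`.
#' @param groups optional named list of row subsets (names or indices);
#'   one profile per subset, whole matrix when NULL.
#' @return a ggplot of per-bin mean signal.
#' @export
plot_average_profile <- function(object, groups = NULL) {
  groups <- groups %||% list(all = NULL)
  df <- purrr::map_dfr(names(groups), function(g) {
    mutate(average_profile(object, groups[[g]]), group = g)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$value,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from anchor centre (bp)",
                  y = "mean signal", colour = NULL)
}

#' Metagene profile plot
#'
#' One line per gene group over scaled gene bodies with fixed-bp flanks;
#' dashed verticals mark the TSS and TES.
#'
#' @param object a `metagene_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  fb <- object$params$flank_bins
  bb <- object$params$body_bins
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(.data$bin, .data$value,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(fb + 0.5, fb + bb + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, fb + 0.5, fb + bb + 0.5, 2 * fb + bb),
      labels = c(sprintf("-%d bp", object$params$flank), "TSS", "TES",
                 sprintf("+%d bp", object$params$flank))) +
    ggplot2::labs(x = NULL, y = "mean signal", colour = "group")
}

#' Fold-difference scatter of a peak comparison
#'
#' @param object a `peak_comparison`.
#' @param ... unused.
#' @return a ggplot of the two samples' log10 CPM coloured by
#'   specificity group.
#' @method autoplot peak_comparison
#' @export
autoplot.peak_comparison <- function(object, ...) {
  pc <- object$params$pseudocount
  ggplot2::ggplot(object$records,
                  ggplot2::aes(log10(.data$cpm_a + pc),
                               log10(.data$cpm_b + pc),
                               colour = .data$group)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::labs(x = sprintf("log10 CPM (%s)", object$params$labels[1]),
                  y = sprintf("log10 CPM (%s)", object$params$labels[2]),
                  colour = NULL)
}

#' Sample-correlation heatmap
#'
#' @param object a `sample_correlation`.
#' @param ... unused.
#' @return a ggplot tile map with samples in dendrogram order.
#' @method autoplot sample_correlation
#' @export
autoplot.sample_correlation <- function(object, ...) {
  ord <- object$order
  df <- tidyr::expand_grid(a = ord, b = ord)
  df$r <- object$correlation[cbind(df$a, df$b)]
  df$a <- factor(df$a, levels = ord)
  df$b <- factor(df$b, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
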