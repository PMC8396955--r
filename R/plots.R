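# ggplot2 figures mirroring the usual presentation of redox-ratio cohorts:
# overlaid per-sample relative-frequency histograms, group mean +/- SD bars
# with the percent difference, and mid-volume ratio slices.

#' Overlaid redox-ratio histograms
#'
#' Plots the relative voxel frequency distribution of RR for one or more
#' samples as step lines, optionally coloured by group.
#'
#' @param histograms An `rr_histogram` or a list of them.
#' @param groups Optional named character vector mapping `sample_id` to a
#'   group label used for colour.
#' @return A ggplot object.
#' @export
plot_rr_histograms <- function(histograms, groups = NULL) {
  if (inherits(histograms, "rr_histogram")) histograms <- list(histograms)
  df <- dplyr::bind_rows(lapply(histograms, tidy))
  df$mid <- (df$bin_left + df$bin_right) / 2
  df$group <- if (!is.null(groups)) unname(groups[df$sample_id]) else df$sample_id
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$rel_freq,
                                   group = .data$sample_id,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Redox ratio (NADH/FAD)", y = "Relative voxel frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_rr_histograms
#' @param object An `rr_histogram`.
#' @param ... Unused.
#' @export
autoplot.rr_histogram <- function(object, ...) plot_rr_histograms(object)

#' Group mean +/- SD bar chart of per-sample mean redox ratios
#'
#' The cohort summary panel: one bar per group at the mean of the per-sample
#' volumetric means, error bars at +/- 1 SD, individual samples overplotted,
#' and the percent difference of each non-reference group annotated.
#'
#' @param summaries Tibble with `group` and `mean_rr` columns (one row per
#'   sample).
#' @param ref_group Reference group for the percent-difference annotation;
#'   default the first group encountered.
#' @return A ggplot object.
#' @export
plot_group_means <- function(summaries, ref_group = NULL) {
  summaries <- tibble::as_tibble(summaries)
  lev <- unique(as.character(summaries$group))
  if (is.null(ref_group)) ref_group <- lev[1]
  gs <- summaries |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$mean_rr),
                     sd = stats::sd(.data$mean_rr), .groups = "drop") |>
    dplyr::mutate(group = factor(.data$group, levels = lev))
  ref_mean <- gs$mean[gs$group == ref_group]
  gs$label <- ifelse(as.character(gs$group) == ref_group, "",
                     sprintf("%+.1f%%", -percent_decrease(ref_mean, gs$mean)))
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$group, y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::geom_jitter(data = summaries,
                         ggplot2::aes(x = .data$group, y = .data$mean_rr),
                         inherit.aes = FALSE, width = 0.08, alpha = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label,
                                    y = .data$mean + .data$sd),
                       vjust = -0.8) +
    ggplot2::labs(x = NULL, y = "Mean redox ratio (NADH/FAD)") +
    ggplot2::theme_minimal()
}

#' Mid-volume slice of a redox-ratio volume
#'
#' @param vol An `rr_volume`.
#' @param z Slice index; default the middle slice.
#' @return A ggplot object (invalid voxels are blank).
#' @export
plot_rr_slice <- function(vol, z = NULL) {
  stopifnot(inherits(vol, "rr_volume"))
  d <- dim(vol$rr)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- vol$rr[, , z]
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$rr <- sl[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$rr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "RR") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s - slice %d", vol$sample_id, z)) +
    ggplot2::theme_minimal()
}
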