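# broom-style accessors and plotting for pipeline results.

#' Tidy a prophage scan
#'
#' Returns the region table with user-facing 1-based inclusive coordinates,
#' one row per predicted prophage.
#'
#' @param x A `prophage_scan` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.prophage_scan <- function(x, ...) {
  summary_table(x)
}

#' One-row summary of a prophage scan
#'
#' @param x A `prophage_scan` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble of run counts (contigs, genes, hits, phage-like
#'   calls, clusters per arm, regions, att pairs, skipped hit rows).
#' @export
glance.prophage_scan <- function(x, ...) {
  x$counts
}

#' Plot a prophage scan as a genome map
#'
#' Genes are drawn as segments along each contig (phage-like calls
#' highlighted); predicted prophage regions are shaded rectangles with att
#' sites as ticks.
#'
#' @param object A `prophage_scan` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prophage_scan <- function(object, ...) {
  g <- mutate(object$genome$genes,
              phage_like = .data$protein_id %in% object$calls$protein_id)
  r <- object$regions
  p <- ggplot2::ggplot(g) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e3, xend = .data$end / 1e3,
                   y = .data$contig_id, yend = .data$contig_id,
                   colour = .data$phage_like),
      linewidth = 3) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "other gene", `TRUE` = "phage-like"),
      name = NULL) +
    ggplot2::labs(x = "position (kb)", y = NULL,
                  title = "Predicted prophage regions") +
    ggplot2::theme_minimal()
  if (nrow(r)) {
    p <- p + ggplot2::geom_rect(
      data = r,
      ggplot2::aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                   ymin = as.numeric(factor(.data$contig_id)) - 0.35,
                   ymax = as.numeric(factor(.data$contig_id)) + 0.35),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2)
    att <- filter(r, !is.na(.data$attL_start))
    if (nrow(att)) {
      ticks <- bind_rows(
        select(att, "contig_id", pos = "attL_start"),
        select(att, "contig_id", pos = "attR_start"))
      p <- p + ggplot2::geom_point(
        data = ticks,
        ggplot2::aes(x = .data$pos / 1e3, y = .data$contig_id),
        inherit.aes = FALSE, shape = 17, colour = "darkgreen", size = 2)
    }
  }
  p
}

#' Plot a tuning grid
#'
#' Heat map of region-level recall over the (minimal cluster size, neighbour
#' density) grid explored by [tune_parameters()].
#'
#' @param grid Tibble returned by [tune_parameters()].
#' @param metric `"recall"` or `"precision"`.
#' @return A ggplot object.
#' @export
plot_tune_grid <- function(grid, metric = c("recall", "precision")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(grid, ggplot2::aes(x = factor(.data$density_bp),
                                     y = factor(.data$min_size),
                                     fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data[[metric]], 2)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = metric) +
    ggplot2::labs(x = "neighbour density (bp)", y = "minimal cluster size") +
    ggplot2::theme_minimal()
}
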