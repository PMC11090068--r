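#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col facet_wrap
#'   facet_grid labs theme_bw geom_rect scale_y_continuous
NULL

#' Plot a threshold-sweep report
#'
#' Error rate and recovery against the GP threshold, faceted by genotype
#' class, one line per INFO threshold — the standard view of the
#' accuracy/recovery trade-off under quality filtering.
#'
#' @param object a `sweep_report` from [sweep_report()].
#' @param site_class,maf_stratum stratum to display.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sweep_report
#' @export
autoplot.sweep_report <- function(object, site_class = "transversion",
                                  maf_stratum = "maf_ge_threshold", ...) {
  d <- object |>
    filter(.data$site_class == !!site_class,
           .data$maf_stratum == !!maf_stratum,
           .data$class %in% c("het", "hom_alt")) |>
    tidyr::pivot_longer(c("error_rate", "recovery"), names_to = "metric")
  ggplot(d, aes(x = .data$min_gp, y = .data$value,
                colour = factor(.data$min_info))) +
    geom_line() + geom_point() +
    facet_grid(metric ~ class, scales = "free_y") +
    labs(x = "GP threshold", y = NULL, colour = "INFO threshold") +
    theme_bw()
}

#' Plot per-window accuracy and recovery along the genome
#'
#' @param windowed tibble from [window_metrics()].
#' @param outliers optional region tibble highlighted as shaded rectangles.
#' @return A ggplot.
#' @export
plot_window_metrics <- function(windowed, outliers = NULL) {
  d <- windowed |>
    tidyr::pivot_longer(c("accuracy", "recovery"), names_to = "metric") |>
    mutate(mid = (.data$start + .data$end) / 2)
  p <- ggplot(d, aes(x = .data$mid / 1e6, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_grid(metric ~ chrom, scales = "free") +
    labs(x = "position (Mb)", y = NULL) +
    theme_bw()
  if (!is.null(outliers) && nrow(outliers) > 0) {
    p <- p + geom_rect(
      data = outliers,
      aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot per-sample ROH totals split at 2 Mb
#'
#' Stacked totals of run-of-homozygosity length below and above the split,
#' the usual summary contrasting recent inbreeding (long runs) with older
#' background homozygosity.
#'
#' @param summary tibble from [roh_summary()].
#' @return A ggplot.
#' @export
plot_roh_summary <- function(summary) {
  d <- summary |>
    tidyr::pivot_longer(c("total_lt_split", "total_ge_split"),
                        names_to = "length_class", values_to = "bp") |>
    mutate(length_class = if_else(.data$length_class == "total_ge_split",
                                  ">= 2 Mb", "< 2 Mb"))
  ggplot(d, aes(x = .data$sample_id, y = .data$bp / 1e6,
                fill = .data$length_class)) +
    geom_col() +
    labs(x = NULL, y = "total ROH (Mb)", fill = "segment length") +
    theme_bw()
}

#' Plot panel PCA with projected samples
#'
#' Panel individuals as points coloured by ancestry; projected test samples
#' (e.g. high-quality vs imputed genotypes of the same individuals) overlaid
#' with shape by projection set.
#'
#' @param object a `panel_pca`.
#' @param projections optional named list of projection tibbles from
#'   [pca_project()].
#' @param pcs the two components to draw (default `c("PC1", "PC2")`).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot panel_pca
#' @export
autoplot.panel_pca <- function(object, projections = NULL,
                               pcs = c("PC1", "PC2"), ...) {
  p <- ggplot(object$coords,
              aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])) +
    geom_point(aes(colour = .data$ancestry), alpha = 0.7) +
    labs(x = pcs[1], y = pcs[2]) +
    theme_bw()
  if (!is.null(projections)) {
    proj <- purrr::imap_dfr(projections, ~ mutate(.x, set = .y))
    p <- p + geom_point(
      data = proj,
      aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]], shape = .data$set),
      size = 3
    )
  }
  p
}
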