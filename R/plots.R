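#' Histogram of library clone abundance
#'
#' The classic library-representation plot: log10 read counts of detected
#' clones, with dashed lines marking the symmetric one-log10 window
#' around the median used by [library_qc()].
#'
#' @param library_counts Integer count vector over clones.
#' @return A ggplot object.
#' @export
plot_library_representation <- function(library_counts) {
  detected <- library_counts[library_counts > 0]
  m <- stats::median(detected)
  df <- tibble::tibble(log_count = log10(detected))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_count)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = log10(c(m / sqrt(10), m * sqrt(10))),
                        linetype = "dashed") +
    ggplot2::labs(x = "log10 read count (detected clones)", y = "clones",
                  title = sprintf("%.1f%% detected, %.1f%% within one log",
                                  100 * length(detected) / length(library_counts),
                                  100 * mean(detected >= m / sqrt(10) &
                                               detected <= m * sqrt(10)))) +
    ggplot2::theme_minimal()
}

#' Replicate (or isotype) concordance scatter plot
#'
#' @param counts_a,counts_b Aligned count vectors.
#' @param label_a,label_b Axis labels.
#' @return A ggplot object annotated with the log-scale R-squared.
#' @export
plot_replicate_scatter <- function(counts_a, counts_b,
                                   label_a = "replicate 1",
                                   label_b = "replicate 2") {
  r2 <- replicate_r2(counts_a, counts_b)
  df <- tibble::tibble(a = log10(counts_a + 1), b = log10(counts_b + 1))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = paste0("log10(", label_a, " + 1)"),
                  y = paste0("log10(", label_b, " + 1)"),
                  title = sprintf("R² = %.3f", r2)) +
    ggplot2::theme_minimal()
}

#' Breadth distributions by group
#'
#' @param breadth_tbl Output of [sample_breadth()] (needs `breadth` and
#'   `group`; facets by `isotype` when present).
#' @return A ggplot object.
#' @export
plot_breadth <- function(breadth_tbl) {
  p <- ggplot2::ggplot(breadth_tbl,
                       ggplot2::aes(.data$group, .data$breadth)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, size = 0.8) +
    ggplot2::labs(x = NULL, y = "repertoire breadth") +
    ggplot2::theme_minimal()
  if ("isotype" %in% names(breadth_tbl)) {
    p <- p + ggplot2::facet_wrap(~isotype)
  }
  p
}

#' Longitudinal pairwise scatter plot
#'
#' @param pairdata Output of [longitudinal_pairplot_data()].
#' @param organism_label Legend label for the flagged organism.
#' @return A ggplot object.
#' @export
plot_pairwise_timepoints <- function(pairdata, organism_label = "wheat") {
  tab <- pairdata$table
  ggplot2::ggplot(tab, ggplot2::aes(.data$log_t0, .data$log_t1,
                                    colour = .data$is_target)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red3"),
                                 labels = c(`FALSE` = "other",
                                            `TRUE` = organism_label),
                                 name = NULL) +
    ggplot2::labs(x = "log10(count + 1), baseline",
                  y = "log10(count + 1), follow-up") +
    ggplot2::theme_minimal()
}

#' Hit heatmap of recognised peptides
#'
#' @param x An `allerscan_hits` object.
#' @param clone_ids Optional peptide subset (e.g. from
#'   [prevalence_filter()]).
#' @param ... Unused.
#' @return A ggplot tile map of log10 hit fold changes.
#' @method autoplot allerscan_hits
#' @export
autoplot.allerscan_hits <- function(x, clone_ids = NULL, ...) {
  long <- tidy(x, hits_only = FALSE)
  if (!is.null(clone_ids)) {
    long <- dplyr::filter(long, .data$clone_id %in% clone_ids)
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$clone_id, .data$sample_id,
                                     fill = log10(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red3",
                                 name = "log10 FC") +
    ggplot2::labs(x = "peptide", y = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
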