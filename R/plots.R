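#' Repeat-number spectrum plot
#'
#' Bar chart of how many loci carry each repeat count, optionally split by
#' motif period.
#'
#' @param loci Locus tibble from [scan_ssrs()].
#' @param by_period Facet-fill by period (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_repeat_histogram <- function(loci, by_period = TRUE) {
  d <- dplyr::mutate(loci, period = factor(.data$period, levels = 2:6,
                                           labels = paste0("p", 2:6)))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n_repeats)) +
    ggplot2::labs(x = "repeat number", y = "loci") +
    ggplot2::theme_minimal()
  if (by_period) {
    p + ggplot2::geom_bar(ggplot2::aes(fill = .data$period)) +
      ggplot2::scale_fill_brewer(palette = "Set2", name = "period")
  } else {
    p + ggplot2::geom_bar()
  }
}

#' Per-chromosome frequency/density plot
#'
#' @param stats Tibble from [chromosome_stats()].
#' @param metric `"frequency"` (loci/Mb) or `"density"` (bp/Mb).
#' @return A ggplot object.
#' @export
plot_chromosome_stats <- function(stats, metric = c("frequency", "density")) {
  metric <- match.arg(metric)
  unit <- if (metric == "frequency") "loci/Mb" else "bp/Mb"
  d <- dplyr::mutate(stats,
                     seq_id = factor(.data$seq_id, levels = stats$seq_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$seq_id, y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = paste0(metric, " (", unit, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Region-distribution plot
#'
#' Stacked proportions of exonic / intronic / intergenic records per repeat
#' type.
#'
#' @param dist Result of [region_distribution()].
#' @return A ggplot object.
#' @export
plot_region_distribution <- function(dist) {
  d <- tidyr::pivot_longer(dist$counts,
                           c("exon", "intergenic", "intron"),
                           names_to = "region", values_to = "n")
  d$type <- factor(d$type, levels = c(paste0("p", 2:6), "c"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$n,
                                  fill = .data$region)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::scale_fill_brewer(palette = "Set1") +
    ggplot2::labs(x = "repeat type", y = "share of records") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ssr_tbl <- function(object, ...) plot_repeat_histogram(object, ...)

#' Tidy an SSR scan
#'
#' Returns the per-locus table as a plain tibble.
#'
#' @param x An `ssr_tbl` from [scan_ssrs()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ssr_tbl <- function(x, ...) {
  out <- x
  attr(out, "seq_lengths") <- NULL
  class(out) <- setdiff(class(out), "ssr_tbl")
  out
}

#' One-row genome summary of an SSR scan
#'
#' @param x An `ssr_tbl` from [scan_ssrs()].
#' @param ... Passed to [genome_stats()] (e.g. `genome_size_bp`).
#' @exportS3Method generics::glance
glance.ssr_tbl <- function(x, ...) genome_stats(x, ...)
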