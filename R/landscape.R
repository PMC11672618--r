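#' Length of a perfect SSR in base pairs
#'
#' The length of a perfect repeat is simply unit length times repeat count:
#' `(AC)12` spans 2 x 12 = 24 bp.
#'
#' @param period Motif length in bp (2--6).
#' @param n_repeats Repeat count (>= 1); vectorized.
#' @return Integer vector of lengths in bp.
#' @examples
#' ssr_length(2, 12) # 24
#' @export
ssr_length <- function(period, n_repeats) {
  stopifnot(all(period %in% 2:6), all(n_repeats >= 1))
  as.integer(period) * as.integer(n_repeats)
}

#' Per-chromosome SSR summary statistics
#'
#' For each scanned sequence, counts loci and summed SSR base pairs and
#' derives frequency (loci per Mb) and density (bp per Mb), with
#' 1 Mb = 10^6 bp exactly.  Sequences with no loci get zero counts.
#' Compound members are counted individually here (landscape convention).
#'
#' @param loci Locus tibble from [scan_ssrs()].
#' @param seq_lengths Named vector of sequence lengths in bp.  Defaults to
#'   the `seq_lengths` attribute carried by `loci`.
#' @return Tibble with columns `seq_id`, `size_bp`, `size_mb`, `n_ssrs`,
#'   `total_ssr_bp`, `frequency` (loci/Mb) and `density` (bp/Mb), one row per
#'   sequence.  Values are unrounded; round only at output
#'   (see [write_report()]).
#' @export
chromosome_stats <- function(loci, seq_lengths = attr(loci, "seq_lengths")) {
  if (is.null(seq_lengths) || is.null(names(seq_lengths))) {
    stop("seq_lengths must be a named vector of sequence sizes in bp",
         call. = FALSE)
  }
  if (any(seq_lengths <= 0)) stop("sequence sizes must be positive", call. = FALSE)
  per <- loci |>
    dplyr::count(.data$seq_id, wt = NULL, name = "n_ssrs") |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(loci, .data$seq_id),
                       total_ssr_bp = sum(.data$length_bp), .groups = "drop"),
      by = "seq_id")
  out <- tibble::tibble(seq_id = names(seq_lengths),
                        size_bp = as.numeric(seq_lengths)) |>
    dplyr::left_join(per, by = "seq_id") |>
    dplyr::mutate(
      n_ssrs = dplyr::coalesce(.data$n_ssrs, 0L),
      total_ssr_bp = dplyr::coalesce(.data$total_ssr_bp, 0L),
      size_mb = .data$size_bp / 1e6,
      frequency = .data$n_ssrs / .data$size_mb,
      density = .data$total_ssr_bp / .data$size_mb
    )
  out[c("seq_id", "size_bp", "size_mb", "n_ssrs", "total_ssr_bp",
        "frequency", "density")]
}

#' Genome-level SSR summary
#'
#' Aggregates a scan into one row: total loci, total SSR bp, genome
#' frequency and density.  The denominator defaults to the summed length of
#' the scanned sequences but can be overridden (assemblies sometimes report
#' statistics over a different denominator, e.g. including unplaced
#' scaffolds).
#'
#' @param loci Locus tibble from [scan_ssrs()].
#' @param seq_lengths Named vector of sequence lengths in bp.
#' @param genome_size_bp Optional denominator override in bp.
#' @return One-row tibble with `n_ssrs`, `total_ssr_bp`, `genome_mb`,
#'   `frequency`, `density`, `pct_of_genome` and `mean_spacing_bp` (mean
#'   distance per locus, genome size / count).
#' @export
genome_stats <- function(loci, seq_lengths = attr(loci, "seq_lengths"),
                         genome_size_bp = NULL) {
  size_bp <- if (!is.null(genome_size_bp)) genome_size_bp else sum(seq_lengths)
  if (is.null(size_bp) || size_bp <= 0) {
    stop("genome size must be positive", call. = FALSE)
  }
  mb <- size_bp / 1e6
  tibble::tibble(
    n_ssrs = nrow(loci),
    total_ssr_bp = sum(loci$length_bp),
    genome_mb = mb,
    frequency = nrow(loci) / mb,
    density = sum(loci$length_bp) / mb,
    pct_of_genome = 100 * sum(loci$length_bp) / size_bp,
    mean_spacing_bp = size_bp / max(nrow(loci), 1L)
  )
}

#' Per-period breakdown of an SSR scan
#'
#' Tabulates loci by motif period (di- through hexanucleotide) with counts,
#' proportions, frequencies and densities, one row per period present plus
#' none dropped; proportions sum to 100%.
#'
#' Accepts either a locus tibble or a pre-tabulated named count vector (and
#' optionally a named bp vector), so published summary tables can be fed
#' straight in.
#'
#' @param loci Locus tibble from [scan_ssrs()], or a named numeric vector of
#'   per-period counts (names `"2"`..`"6"`).
#' @param size_mb Optional genome size in Mb for frequency/density columns.
#' @param total_bp Optional named vector of per-period summed bp (only used
#'   with the count-vector form).
#' @return Tibble with `period`, `n`, `proportion_pct`, and where computable
#'   `frequency`, `total_bp`, `density`.
#' @export
period_breakdown <- function(loci, size_mb = NULL, total_bp = NULL) {
  if (is.data.frame(loci)) {
    tab <- loci |>
      dplyr::count(.data$period, name = "n") |>
      dplyr::left_join(
        dplyr::summarise(dplyr::group_by(loci, .data$period),
                         total_bp = sum(.data$length_bp), .groups = "drop"),
        by = "period")
  } else {
    stopifnot(!is.null(names(loci)))
    tab <- tibble::tibble(period = as.integer(names(loci)), n = as.numeric(loci))
    tab$total_bp <- if (!is.null(total_bp)) {
      as.numeric(total_bp[as.character(tab$period)])
    } else NA_real_
  }
  tab <- dplyr::arrange(tab, .data$period)
  tab$proportion_pct <- 100 * tab$n / sum(tab$n)
  if (!is.null(size_mb)) {
    tab$frequency <- tab$n / size_mb
    tab$density <- tab$total_bp / size_mb
  }
  tab
}

#' Rank canonical motif classes by abundance
#'
#' @param loci Locus tibble from [scan_ssrs()].
#' @param top_n Number of classes to keep (>= 1).
#' @param size_mb Optional genome size in Mb for frequency/density columns.
#' @return Tibble sorted by count descending, ties broken lexicographically
#'   by canonical motif, with columns `motif`, `n`, `total_bp` and, given
#'   `size_mb`, `frequency` and `density`.
#' @export
motif_ranking <- function(loci, top_n = 10L, size_mb = NULL) {
  stopifnot(top_n >= 1)
  tab <- loci |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(n = dplyr::n(), total_bp = sum(.data$length_bp),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$motif) |>
    utils::head(top_n)
  if (!is.null(size_mb)) {
    tab$frequency <- tab$n / size_mb
    tab$density <- tab$total_bp / size_mb
  }
  tab
}

#' Repeat-number spectrum of an SSR scan
#'
#' @param loci Locus tibble from [scan_ssrs()].
#' @return Tibble with `n_repeats` and `count`, sorted by `n_repeats`;
#'   counts sum to the number of loci.
#' @export
repeat_number_histogram <- function(loci) {
  dplyr::arrange(dplyr::count(loci, .data$n_repeats, name = "count"),
                 .data$n_repeats)
}

#' Pearson correlation between chromosome size and an SSR metric
#'
#' Tests whether SSR abundance (count), total length or density scales with
#' chromosome size, using the standard two-sided Pearson test.
#'
#' @param stats Per-chromosome tibble from [chromosome_stats()] (>= 3 rows).
#' @param metric One of `"n_ssrs"`, `"total_ssr_bp"`, `"density"`.
#' @return One-row tibble with `metric`, `pearson_r`, `p_value`, `n`.
#' @export
size_correlation <- function(stats, metric = c("n_ssrs", "total_ssr_bp", "density")) {
  metric <- match.arg(metric)
  if (nrow(stats) < 3L) stop("need >= 3 chromosomes", call. = FALSE)
  x <- stats$size_mb
  y <- stats[[metric]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in size or metric: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(metric = metric, pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = nrow(stats))
}
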