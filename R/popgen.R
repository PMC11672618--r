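#' Allele frequencies per locus
#'
#' Estimates allele frequencies from a diploid genotype table by direct
#' count: each non-missing individual contributes two allele observations,
#' so \eqn{\hat p_i = n_i / 2N}.  Individuals with a missing genotype are
#' dropped from that locus's N (no imputation).
#'
#' @param genotypes Long genotype tibble with columns `locus`, `sample_id`,
#'   `allele_a`, `allele_b` (see [read_genotypes()]).
#' @return Tibble with columns `locus`, `allele`, `count`, `p`;
#'   frequencies sum to 1 within each locus.
#' @export
allele_frequencies <- function(genotypes) {
  g <- complete_genotypes(genotypes)
  if (nrow(g) == 0L) stop("no non-missing genotypes", call. = FALSE)
  long <- tibble::tibble(locus = rep(g$locus, 2L),
                         allele = c(g$allele_a, g$allele_b))
  long |>
    dplyr::count(.data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(p = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Per-locus polymorphism statistics
#'
#' Computes, for every locus in a genotype table, the standard
#' marker-informativeness panel:
#' \itemize{
#'   \item `Na` — observed number of alleles;
#'   \item `Ne` — effective number of alleles, \eqn{1/\sum \hat p_i^2};
#'   \item `Ho` — observed heterozygosity, the fraction of genotyped
#'     individuals whose two alleles differ;
#'   \item `He` — expected heterozygosity with Levene's small-sample
#'     correction, \eqn{\frac{2N}{2N-1}(1 - \sum \hat p_i^2)} (the
#'     convention of classic population-genetics software; set
#'     `unbiased = FALSE` for the uncorrected \eqn{1 - \sum \hat p_i^2});
#'   \item `I` — Shannon's information index, \eqn{-\sum \hat p_i \ln \hat p_i};
#'   \item `PIC` — polymorphism information content (Botstein),
#'     \eqn{1 - \sum \hat p_i^2 - \sum_i \sum_{j>i} 2 \hat p_i^2 \hat p_j^2}.
#' }
#'
#' A monomorphic locus yields `Ne = 1` and `Ho = He = I = PIC = 0`.  The
#' unbiased He requires `N >= 2` genotyped individuals.
#'
#' @param genotypes Long genotype tibble (`locus`, `sample_id`, `allele_a`,
#'   `allele_b`).
#' @param unbiased Apply Levene's correction to He (default `TRUE`).
#' @return Tibble of class `marker_stats_tbl`, one row per locus, columns
#'   `locus`, `N`, `Na`, `Ne`, `Ho`, `He`, `I`, `PIC`.
#' @examples
#' g <- simulate_genotypes(list(L1 = c(`120` = 0.5, `124` = 0.5)),
#'                         n_individuals = 10, seed = 1)
#' marker_stats(g)
#' @export
marker_stats <- function(genotypes, unbiased = TRUE) {
  g <- complete_genotypes(genotypes)
  if (nrow(g) == 0L) stop("no non-missing genotypes", call. = FALSE)
  out <- g |>
    dplyr::group_by(.data$locus) |>
    dplyr::group_map(function(d, key) {
      N <- nrow(d)
      alleles <- c(d$allele_a, d$allele_b)
      p <- as.numeric(table(alleles)) / (2 * N)
      s2 <- sum(p^2)
      s4 <- sum(p^4)
      if (unbiased && N < 2L) {
        stop("locus '", key$locus, "': unbiased He needs N >= 2", call. = FALSE)
      }
      he <- if (unbiased) (2 * N / (2 * N - 1)) * (1 - s2) else 1 - s2
      tibble::tibble(
        locus = key$locus,
        N = N,
        Na = length(p),
        Ne = 1 / s2,
        Ho = mean(d$allele_a != d$allele_b),
        He = he,
        I = -sum(p * log(p)),
        PIC = 1 - s2 - (s2^2 - s4)   # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
      )
    }) |>
    dplyr::bind_rows()
  class(out) <- unique(c("marker_stats_tbl", class(out)))
  out
}

#' Summarize a marker panel
#'
#' Means, sample (n-1) standard deviations and the total allele count over a
#' set of per-locus statistics — the usual closing rows of a diversity
#' table.  With a single marker the standard deviations are reported as 0
#' and flagged.
#'
#' @param stats Tibble with columns `Na`, `Ne`, `Ho`, `He`, `I`, `PIC`
#'   (e.g. from [marker_stats()] or a published table read with
#'   [readr::read_tsv()]).
#' @return A list with `mean` and `st_dev` (one-row tibbles over the six
#'   statistics), `total_alleles` (sum of `Na`), `n_markers`, and
#'   `single_marker` flag.
#' @export
summarize_panel <- function(stats) {
  stopifnot(nrow(stats) >= 1)
  cols <- c("Na", "Ne", "Ho", "He", "I", "PIC")
  stopifnot(all(cols %in% names(stats)))
  single <- nrow(stats) == 1L
  means <- dplyr::summarise(stats, dplyr::across(dplyr::all_of(cols), mean))
  sds <- if (single) {
    tibble::as_tibble(stats::setNames(as.list(rep(0, length(cols))), cols))
  } else {
    dplyr::summarise(stats, dplyr::across(dplyr::all_of(cols), stats::sd))
  }
  list(mean = means, st_dev = sds, total_alleles = sum(stats$Na),
       n_markers = nrow(stats), single_marker = single)
}

#' Count highly informative markers
#'
#' A marker is conventionally called highly informative when its
#' polymorphism information content exceeds 0.5 (strict inequality).
#'
#' @param stats Tibble with a `PIC` column.
#' @param threshold PIC threshold (default 0.5).
#' @return Integer count of markers with `PIC > threshold`.
#' @export
classify_informativeness <- function(stats, threshold = 0.5) {
  if (nrow(stats) == 0L) return(0L)
  sum(stats$PIC > threshold)
}

#' Cross-species transferability percentage
#'
#' The fraction of markers designed in one species that amplify a product of
#' the expected size in a related species, as a percentage rounded to two
#' decimals.
#'
#' @param amplified Logical vector, one element per tested marker.
#' @return Percentage (0--100, 2 dp).
#' @examples
#' transferability(c(rep(TRUE, 33), rep(FALSE, 4))) # 89.19
#' @export
transferability <- function(amplified) {
  stopifnot(is.logical(amplified), length(amplified) >= 1)
  round(100 * mean(amplified), 2)
}

# Drop individuals with any missing allele at a locus (partial genotypes are
# missing); column checks shared by the popgen functions.
complete_genotypes <- function(genotypes) {
  stopifnot(is.data.frame(genotypes),
            all(c("locus", "sample_id", "allele_a", "allele_b") %in%
                  names(genotypes)))
  dplyr::filter(genotypes, !is.na(.data$allele_a) & !is.na(.data$allele_b))
}

#' @exportS3Method generics::glance
glance.marker_stats_tbl <- function(x, ...) {
  s <- summarize_panel(x)
  tibble::tibble(
    n_markers = s$n_markers, total_alleles = s$total_alleles,
    mean_Na = s$mean$Na, mean_Ne = s$mean$Ne, mean_Ho = s$mean$Ho,
    mean_He = s$mean$He, mean_I = s$mean$I, mean_PIC = s$mean$PIC,
    n_high_pic = classify_informativeness(x)
  )
}

#' @exportS3Method generics::tidy
tidy.marker_stats_tbl <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "marker_stats_tbl")
  out
}
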