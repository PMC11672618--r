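#' Default MISA-style repeat-count thresholds
#'
#' Dinucleotide motifs must repeat at least 6 times; tri- through
#' hexanucleotide motifs at least 5 times.  Mononucleotide runs are never
#' reported.
#'
#' @return Named integer vector mapping period (`"2"`..`"6"`) to the minimum
#'   repeat count.
#' @export
default_min_repeats <- function() {
  c(`2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

#' Scan a genome for perfect microsatellites
#'
#' Finds every maximal perfect tandem repeat whose minimal period is 2--6 bp
#' and whose whole-unit repeat count meets its period's threshold.  A run is
#' reported under its minimal period only (so a `(AT)n` stretch is never also
#' reported as `(ATAT)m`), is truncated to whole repeat units, and is broken
#' at `N` residues.  Where runs of different minimal periods still overlap,
#' the leftmost (ties: longest) locus wins, so reported loci never overlap.
#'
#' @param genome Tibble with `seq_id` and `residues` columns, as returned by
#'   [read_genome_fasta()] or [simulate_ssr_genome()].
#' @param min_repeats Named vector of per-period repeat-count thresholds;
#'   see [default_min_repeats()].
#' @return A coordinate-sorted tibble of class `ssr_tbl` with columns
#'   `seq_id`, `start`, `end` (1-based inclusive), `period`, `unit` (the
#'   repeat unit as it occurs on the forward strand), `motif` (canonical
#'   class), `n_repeats` and `length_bp`, carrying the scanned sequence
#'   lengths in attribute `seq_lengths`.
#' @examples
#' g <- tibble::tibble(seq_id = "chr1",
#'                     residues = paste0("TTT", strrep("AC", 6), "GGT"))
#' scan_ssrs(g)
#' @export
scan_ssrs <- function(genome, min_repeats = default_min_repeats()) {
  stopifnot(is.data.frame(genome), all(c("seq_id", "residues") %in% names(genome)))
  min_repeats <- validate_thresholds(min_repeats)
  loci <- purrr::map2_dfr(genome$seq_id, genome$residues,
                          scan_sequence, min_repeats = min_repeats)
  sl <- stats::setNames(nchar(genome$residues), genome$seq_id)
  new_ssr_tbl(loci, seq_lengths = sl)
}

# Scan one sequence.  For each candidate period p the shifted
# element-equality vector marks positions where x[i] == x[i+p]; maximal TRUE
# runs are maximal perfectly periodic stretches, which are truncated to whole
# units and kept when the start unit is primitive and the count meets the
# threshold.
scan_sequence <- function(seq_id, residues, min_repeats = default_min_repeats()) {
  empty <- tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), period = integer(),
                          unit = character(), motif = character(),
                          n_repeats = integer(), length_bp = integer())
  n <- nchar(residues)
  if (n == 0L) return(empty)
  x <- strsplit(residues, NULL, fixed = TRUE)[[1L]]
  is_n <- x == "N"
  out <- list()
  for (p in as.integer(names(min_repeats))) {
    thr <- min_repeats[[as.character(p)]]
    if (n < p * thr) next
    eq <- x[seq_len(n - p)] == x[(p + 1L):n]
    eq[is_n[seq_len(n - p)] | is_n[(p + 1L):n]] <- FALSE
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    cand <- which(r$values & (r$lengths + p) >= p * thr)
    for (j in cand) {
      i <- run_start[j]
      k <- (r$lengths[j] + p) %/% p          # whole repeat units in the stretch
      if (k < thr) next
      unit <- substr(residues, i, i + p - 1L)
      if (nchar(minimal_period(unit)) != p) next   # report under minimal period only
      out[[length(out) + 1L]] <- list(start = i, period = p, unit = unit,
                                      n_repeats = k)
    }
  }
  if (length(out) == 0L) return(empty)
  df <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  df <- dplyr::mutate(df,
    seq_id = seq_id,
    length_bp = .data$period * .data$n_repeats,
    end = .data$start + .data$length_bp - 1L,
    motif = vapply(.data$unit, canonical_motif, character(1), USE.NAMES = FALSE)
  )
  df <- resolve_overlaps(df)
  df[c("seq_id", "start", "end", "period", "unit", "motif",
       "n_repeats", "length_bp")]
}

# Leftmost-longest resolution: sort by start, then length descending, then
# period; greedily keep loci that do not overlap an already-kept locus.
resolve_overlaps <- function(df) {
  df <- df[order(df$start, -df$length_bp, df$period), ]
  keep <- logical(nrow(df))
  last_end <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- df$end[i]
    }
  }
  df[keep, ]
}

validate_thresholds <- function(min_repeats) {
  if (is.null(names(min_repeats)) ||
      !all(names(min_repeats) %in% as.character(2:6)) ||
      any(min_repeats < 1)) {
    stop("min_repeats must be a named vector with names in '2'..'6' and positive values",
         call. = FALSE)
  }
  stats::setNames(as.integer(min_repeats), names(min_repeats))
}

new_ssr_tbl <- function(loci, seq_lengths = NULL) {
  loci <- tibble::as_tibble(loci)
  attr(loci, "seq_lengths") <- seq_lengths
  class(loci) <- unique(c("ssr_tbl", class(loci)))
  loci
}

#' Merge near-adjacent SSR loci into compound records
#'
#' Consecutive loci on the same sequence whose intervening gap
#' (`next start - previous end - 1`) is strictly less than `max_gap` are
#' chained into one compound record; all other loci stay standalone.  Every
#' input locus appears in exactly one output record, so the member multiset
#' is conserved.
#'
#' @param loci Coordinate-sorted, non-overlapping locus tibble from
#'   [scan_ssrs()].
#' @param max_gap Gap threshold in nucleotides (strict `<`; default 100).
#' @return A tibble of records with columns `record_id`, `seq_id`, `start`,
#'   `end`, `type` (`"p2"`..`"p6"` for standalone loci, `"c"` for compounds),
#'   `motif` (canonical class, or member classes joined by `/` for
#'   compounds), `n_members`, `length_bp` (summed member lengths), and
#'   list-columns `members` (the member locus rows) and `gaps`
#'   (inter-member distances in nt).
#' @export
merge_compound_ssrs <- function(loci, max_gap = 100L) {
  stopifnot(is.data.frame(loci), max_gap >= 0)
  if (nrow(loci) == 0L) {
    return(tibble::tibble(record_id = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          type = character(), motif = character(),
                          n_members = integer(), length_bp = integer(),
                          members = list(), gaps = list()))
  }
  recs <- loci |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::group_map(~ merge_one_sequence(.x, .y$seq_id, max_gap)) |>
    dplyr::bind_rows()
  recs <- dplyr::arrange(recs, .data$seq_id, .data$start)
  recs$record_id <- sprintf("%s_ssr%d", recs$seq_id,
                            stats::ave(recs$start, recs$seq_id,
                                       FUN = seq_along))
  recs[c("record_id", "seq_id", "start", "end", "type", "motif",
         "n_members", "length_bp", "members", "gaps")]
}

merge_one_sequence <- function(loci, seq_id, max_gap) {
  loci <- tibble::as_tibble(loci)
  loci$seq_id <- seq_id
  o <- order(loci$start)
  if (any(o != seq_along(o))) {
    stop("loci must be coordinate-sorted within each sequence", call. = FALSE)
  }
  if (nrow(loci) > 1L &&
      any(loci$start[-1L] <= loci$end[-nrow(loci)])) {
    stop("loci must be non-overlapping", call. = FALSE)
  }
  gap <- c(Inf, loci$start[-1L] - loci$end[-nrow(loci)] - 1L)
  chain <- cumsum(gap >= max_gap)   # strict <: gap >= max_gap starts a new chain
  loci |>
    dplyr::mutate(.chain = chain) |>
    dplyr::group_by(.data$.chain) |>
    dplyr::group_map(function(g, key) {
      g <- g[setdiff(names(g), ".chain")]
      tibble::tibble(
        seq_id = seq_id,
        start = min(g$start), end = max(g$end),
        type = if (nrow(g) > 1L) "c" else paste0("p", g$period),
        motif = paste(g$motif, collapse = "/"),
        n_members = nrow(g),
        length_bp = sum(g$length_bp),
        members = list(g),
        gaps = list(if (nrow(g) > 1L) g$start[-1L] - g$end[-nrow(g)] - 1L
                    else integer())
      )
    }) |>
    dplyr::bind_rows()
}
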