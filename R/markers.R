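#' Default primer design constraints
#'
#' Primer length 18--30 nt, melting temperature 50--60 degrees C, GC content
#' 40--60%, PCR product size 100--300 bp; all ranges inclusive.
#'
#' @return Named list of length-2 numeric ranges: `len_range`, `tm_range`,
#'   `gc_range`, `product_range`.
#' @export
default_primer_constraints <- function() {
  list(len_range = c(18, 30), tm_range = c(50, 60),
       gc_range = c(40, 60), product_range = c(100, 300))
}

#' Extract SSR flanking sequences as marker candidates
#'
#' For each locus, takes up to `flank_len` bases immediately left and right
#' of the repeat (clipped at sequence ends).  A candidate is marked not
#' designable when a flank is shorter than the minimum primer length plus a
#' small margin (18 + 2 = 20 nt by default) or contains a run of 10 or more
#' `N`s.
#'
#' @param loci Locus tibble from [scan_ssrs()].
#' @param genome Genome tibble with `seq_id` and `residues`.
#' @param flank_len Flank length in bp (default 250, so a 100--300 bp
#'   product window fits).
#' @param min_flank Minimum usable flank length (default 20).
#' @return The locus tibble with `left_flank`, `right_flank`, `designable`
#'   and `reject_reason` columns appended.
#' @export
extract_flanks <- function(loci, genome, flank_len = 250L, min_flank = 20L) {
  stopifnot(flank_len >= 1)
  seqs <- stats::setNames(genome$residues, genome$seq_id)
  if (!all(loci$seq_id %in% names(seqs))) {
    stop("locus sequence(s) missing from genome", call. = FALSE)
  }
  n <- nrow(loci)
  left <- character(n); right <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- seqs[[loci$seq_id[i]]]
    slen <- nchar(s)
    if (loci$start[i] < 1L || loci$end[i] > slen) {
      stop("locus ", loci$seq_id[i], ":", loci$start[i], "-", loci$end[i],
           " outside sequence", call. = FALSE)
    }
    left[i] <- substr(s, max(1L, loci$start[i] - flank_len), loci$start[i] - 1L)
    right[i] <- substr(s, loci$end[i] + 1L, min(slen, loci$end[i] + flank_len))
    fails <- character()
    if (nchar(left[i]) < min_flank) fails <- c(fails, "left flank too short")
    if (nchar(right[i]) < min_flank) fails <- c(fails, "right flank too short")
    if (grepl("N{10,}", left[i])) fails <- c(fails, "left flank N run >= 10")
    if (grepl("N{10,}", right[i])) fails <- c(fails, "right flank N run >= 10")
    if (length(fails) > 0) reason[i] <- paste(fails, collapse = "; ")
  }
  out <- tibble::as_tibble(loci)
  out$left_flank <- left
  out$right_flank <- right
  out$designable <- is.na(reason)
  out$reject_reason <- reason
  out
}

#' GC content of a DNA string
#'
#' @param seq Non-empty DNA string(s); vectorized.
#' @return Percentage of G + C bases.
#' @examples
#' gc_content("ACGT") # 50
#' @export
gc_content <- function(seq) {
  if (any(nchar(seq) == 0L)) stop("empty sequence", call. = FALSE)
  100 * (stringr::str_count(seq, "[GC]")) / nchar(seq)
}

#' Melting temperature of a primer
#'
#' For oligos of 14 nt or more, the basic GC formula
#' `Tm = 64.9 + 41 * (GC_count - 16.4) / length`; for shorter oligos the
#' Wallace rule `2(A+T) + 4(G+C)`.  This is the standard quick estimate for
#' constraint screening, not a nearest-neighbour thermodynamic model.
#'
#' @param seq DNA string(s); vectorized.
#' @return Estimated Tm in degrees Celsius.
#' @examples
#' melting_temperature(paste(rep("GC", 10), collapse = "")) # 20-mer, 20 GC
#' @export
melting_temperature <- function(seq) {
  if (any(nchar(seq) == 0L)) stop("empty sequence", call. = FALSE)
  len <- nchar(seq)
  gc_n <- stringr::str_count(seq, "[GC]")
  at_n <- stringr::str_count(seq, "[AT]")
  ifelse(len >= 14,
         64.9 + 41 * (gc_n - 16.4) / len,
         2 * at_n + 4 * gc_n)
}

#' Screen a primer pair against design constraints
#'
#' Checks forward and reverse primers against the length / Tm / GC
#' constraints and the product-size window.  Product size is computed from
#' exact string matches: the forward primer and the reverse complement of
#' the reverse primer are located on the template (first, i.e.
#' lowest-coordinate, occurrence, with a warning when a primer binds more
#' than once) and the product spans the forward start through the reverse
#' binding end.  All failing constraints are reported, not just the first.
#'
#' @param fwd,rev Primer sequences (ACGT, given 5'->3'; `rev` on the
#'   opposite strand).
#' @param template Template DNA string containing the amplicon.
#' @param constraints Constraint list, see [default_primer_constraints()].
#' @return List with `pass` (logical), `failures` (character vector),
#'   `product_size` (bp or `NA`), `fwd_tm`, `rev_tm`, `fwd_gc`, `rev_gc`.
#' @export
screen_primer_pair <- function(fwd, rev, template,
                               constraints = default_primer_constraints()) {
  fails <- character()
  check_range <- function(value, range, what) {
    if (value < range[1] || value > range[2]) {
      sprintf("%s %.2f outside %g-%g", what, value, range[1], range[2])
    } else character()
  }
  for (side in c("fwd", "rev")) {
    p <- if (side == "fwd") fwd else rev
    fails <- c(fails,
               check_range(nchar(p), constraints$len_range,
                           paste(side, "length")),
               check_range(melting_temperature(p), constraints$tm_range,
                           paste(side, "Tm")),
               check_range(gc_content(p), constraints$gc_range,
                           paste(side, "GC%")))
  }
  product <- NA_integer_
  fwd_hits <- all_matches(template, fwd)
  rev_hits <- all_matches(template, revcomp(rev))
  if (length(fwd_hits) == 0L) fails <- c(fails, "fwd: no binding site")
  if (length(rev_hits) == 0L) fails <- c(fails, "rev: no binding site")
  if (length(fwd_hits) > 1L || length(rev_hits) > 1L) {
    warning("primer binds template at multiple sites; using first occurrence",
            call. = FALSE)
  }
  if (length(fwd_hits) >= 1L && length(rev_hits) >= 1L) {
    product <- (rev_hits[1L] + nchar(rev) - 1L) - fwd_hits[1L] + 1L
    fails <- c(fails, check_range(product, constraints$product_range,
                                  "product size"))
  }
  list(pass = length(fails) == 0L, failures = fails,
       product_size = product,
       fwd_tm = melting_temperature(fwd), rev_tm = melting_temperature(rev),
       fwd_gc = gc_content(fwd), rev_gc = gc_content(rev))
}

all_matches <- function(template, pattern) {
  m <- gregexpr(pattern, template, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Designable marker counts per chromosome
#'
#' @param candidates Candidate tibble from [extract_flanks()].
#' @param seq_lengths Named vector of sequence lengths in bp.
#' @return Tibble with `seq_id`, `n_designable` and `frequency`
#'   (designable markers per Mb), one row per sequence.
#' @export
markers_per_chromosome <- function(candidates,
                                   seq_lengths = attr(candidates, "seq_lengths")) {
  stopifnot(!is.null(names(seq_lengths)))
  per <- candidates |>
    dplyr::filter(.data$designable) |>
    dplyr::count(.data$seq_id, name = "n_designable")
  tibble::tibble(seq_id = names(seq_lengths),
                 size_mb = as.numeric(seq_lengths) / 1e6) |>
    dplyr::left_join(per, by = "seq_id") |>
    dplyr::mutate(n_designable = dplyr::coalesce(.data$n_designable, 0L),
                  frequency = .data$n_designable / .data$size_mb)
}
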