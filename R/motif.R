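#' Reduce a repeat unit to its minimal period
#'
#' A tandem-repeat unit such as `"ATAT"` is not primitive: it is itself a
#' whole-number repetition of the shorter unit `"AT"`.  Microsatellite
#' conventions treat the shortest basic sequence as the motif, so `(ATAT)8`
#' is the same repeat as `(AT)16`.  This function returns the shortest string
#' `u` such that `unit` equals `u` repeated a whole number of times; a
#' primitive unit is returned unchanged.
#'
#' @param unit A single DNA string (characters in `A`, `C`, `G`, `T`),
#'   1--6 bp long.
#' @return The minimal-period unit as a character scalar.
#' @examples
#' minimal_period("ATAT")   # "AT"
#' minimal_period("ACT")    # "ACT" (already primitive)
#' minimal_period("AAAAAA") # "A"
#' @export
minimal_period <- function(unit) {
  check_dna_unit(unit, max_len = 6L)
  n <- nchar(unit)
  for (d in seq_len(n)) {
    if (n %% d == 0L) {
      u <- substr(unit, 1L, d)
      if (strrep(u, n %/% d) == unit) return(u)
    }
  }
  unit
}

#' Canonical motif class of a primitive repeat unit
#'
#' Repeat units that are circular permutations of one another, or circular
#' permutations of each other's reverse complement, describe the same
#' microsatellite read from a different phase or strand, and are counted as
#' one motif class.  The class is named by its lexicographically smallest
#' member (A < C < G < T), so `"CTA"`, `"TAC"`, `"TGA"`, `"GAT"` and `"ATG"`
#' all belong to class `"ACT"`.
#'
#' The unit must be primitive (apply [minimal_period()] first) and at least
#' 2 bp: mononucleotide runs are outside the 2--6 bp motif range and are
#' rejected.
#'
#' @param unit A primitive DNA unit, 2--6 bp.
#' @return The canonical class representative as a character scalar.
#' @examples
#' canonical_motif("CTA") # "ACT"
#' canonical_motif("TGA") # "ACT" (complementary strand)
#' canonical_motif("TC")  # "AG"
#' @export
canonical_motif <- function(unit) {
  check_dna_unit(unit, max_len = 6L)
  if (nchar(minimal_period(unit)) != nchar(unit)) {
    stop("unit '", unit, "' is not primitive; reduce with minimal_period() first",
         call. = FALSE)
  }
  if (nchar(unit) < 2L) {
    stop("mononucleotide units are out of scope (motif length must be 2-6 bp)",
         call. = FALSE)
  }
  min(c(rotations(unit), rotations(revcomp(unit))))
}

#' Normalize a raw repeat observation to (canonical class, repeat count)
#'
#' Reduces the unit to its minimal period, scales the repeat count by the
#' reduction factor, and canonicalizes the unit, so that e.g. `(TCTC)10`
#' becomes class `"AG"` repeated 20 times.
#'
#' @param unit Raw DNA unit, 1--6 bp (length-2+ after reduction).
#' @param n Observed repeat count of `unit` (positive integer).
#' @return A list with elements `motif` (canonical class) and `n_repeats`.
#' @examples
#' normalize_repeat("TCTC", 10) # motif "AG", n_repeats 20
#' normalize_repeat("ATAT", 8)  # motif "AT", n_repeats 16
#' @export
normalize_repeat <- function(unit, n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == as.integer(n))
  base <- minimal_period(unit)
  factor <- nchar(unit) %/% nchar(base)
  list(motif = canonical_motif(base), n_repeats = as.integer(n) * factor)
}

#' Enumerate the universe of canonical motif classes for one period
#'
#' Brute-forces all `4^period` DNA units of exactly the requested length,
#' discards non-primitive ones, canonicalizes the rest and deduplicates.
#' The resulting universes have sizes 4, 10, 33, 102 and 350 for periods
#' 2 through 6; any observed motif set from a scan is a subset of these.
#'
#' @param period Motif length, an integer in 2--6.
#' @return Sorted character vector of canonical class representatives.
#' @examples
#' enumerate_motif_classes(2) # "AC" "AG" "AT" "CG"
#' length(enumerate_motif_classes(3)) # 10
#' @export
enumerate_motif_classes <- function(period) {
  if (!is.numeric(period) || length(period) != 1L || !period %in% 2:6) {
    stop("period must be a single integer in 2..6", call. = FALSE)
  }
  period <- as.integer(period)
  units <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), period),
                                       stringsAsFactors = FALSE))
  primitive <- vapply(units, function(u) nchar(minimal_period(u)) == period,
                      logical(1), USE.NAMES = FALSE)
  sort(unique(vapply(units[primitive], canonical_motif, character(1),
                     USE.NAMES = FALSE)))
}

# All cyclic rotations of a unit.
rotations <- function(unit) {
  n <- nchar(unit)
  vapply(seq_len(n), function(i) {
    paste0(substr(unit, i, n), substr(unit, 1L, i - 1L))
  }, character(1))
}

# Reverse complement of a plain ACGT(N) string.
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
                character(1)))
}

check_dna_unit <- function(unit, max_len = 6L) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit) ||
      nchar(unit) < 1L || nchar(unit) > max_len) {
    stop("unit must be a single DNA string of length 1-", max_len, call. = FALSE)
  }
  if (grepl("[^ACGT]", unit)) {
    stop("unit '", unit, "' contains characters outside {A,C,G,T}",
         call. = FALSE)
  }
  invisible(unit)
}
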