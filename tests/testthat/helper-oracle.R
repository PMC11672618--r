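# Brute-force reference scanner: tests every (start, period) pair by direct
# substring comparison, checks char-level maximality explicitly, keeps
# threshold-passing primitive runs, and resolves overlaps leftmost-longest.
# Deliberately written without the shifted-equality/rle machinery of the
# package scanner so the two can disagree.
oracle_scan <- function(residues,
                        min_repeats = c(`2` = 6, `3` = 5, `4` = 5,
                                        `5` = 5, `6` = 5)) {
  n <- nchar(residues)
  ch <- function(i) substr(residues, i, i)
  is_primitive <- function(unit) {
    p <- nchar(unit)
    for (d in seq_len(p - 1L)) {
      if (p %% d == 0L && strrep(substr(unit, 1L, d), p %/% d) == unit) {
        return(FALSE)
      }
    }
    TRUE
  }
  cand <- list()
  for (p in as.integer(names(min_repeats))) {
    thr <- min_repeats[[as.character(p)]]
    if (n < p * thr) next
    starts <- seq_len(n - 2L * p + 1L)
    # every start position is tested: does the unit at i repeat immediately?
    units <- substring(residues, starts, starts + p - 1L)
    second <- substring(residues, starts + p, starts + 2L * p - 1L)
    ok <- units == second & !grepl("N", units, fixed = TRUE)
    for (i in starts[ok]) {
      unit <- substr(residues, i, i + p - 1L)
      if (!is_primitive(unit)) next
      # char-level maximal start: the preceding base must not continue the
      # periodicity (N never matches anything)
      if (i > 1L && ch(i - 1L) != "N" && ch(i - 1L) == ch(i - 1L + p)) next
      k <- 2L
      repeat {
        nxt <- substr(residues, i + k * p, i + (k + 1L) * p - 1L)
        if (nchar(nxt) < p || grepl("N", nxt) || nxt != unit) break
        k <- k + 1L
      }
      if (k >= thr) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = i, end = i + k * p - 1L, period = p, unit = unit,
          n_repeats = k, length_bp = k * p, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      unit = character(), n_repeats = integer(),
                      length_bp = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, cand)
  oracle_resolve(df)
}

# Independent re-statement of the leftmost-longest rule.
oracle_resolve <- function(df) {
  df <- df[order(df$start, -df$length_bp, df$period), , drop = FALSE]
  kept <- df[0, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    if (nrow(kept) == 0L || all(row$start > kept$end | row$end < kept$start)) {
      kept <- rbind(kept, row)
    }
  }
  kept[order(kept$start), , drop = FALSE]
}

# Random test sequence with occasional repeat-prone structure: i.i.d.
# background plus a few inserted tandem stretches of random unit and length
# (some below threshold, some above).
random_test_sequence <- function(len, n_inserts = 3) {
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s <- paste(x, collapse = "")
  for (j in seq_len(n_inserts)) {
    p <- sample(1:6, 1)
    unit <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
                  collapse = "")
    k <- sample(2:9, 1)
    ins <- strrep(unit, k)
    pos <- sample.int(max(1L, len - nchar(ins)), 1)
    s <- paste0(substr(s, 1, pos - 1), ins,
                substr(s, pos + nchar(ins), len))
  }
  substr(s, 1, len)
}

locus_key <- function(d) {
  paste(d$start, d$end, d$period, d$unit, d$n_repeats, sep = ":")
}
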