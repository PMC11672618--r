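#' Read a genome FASTA into a tibble
#'
#' Reads a (multi-record) FASTA file via Biostrings, uppercases residues,
#' converts `U` to `T`, and maps IUPAC ambiguity codes other than `N` to `N`
#' with a warning.  Record order is preserved.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A tibble with columns `seq_id`, `residues` (uppercase DNA string
#'   over A/C/G/T/N) and `length_bp`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  res <- toupper(as.character(set))
  res <- chartr("U", "T", res)
  if (any(grepl("[^ACGTN]", res))) {
    warning("IUPAC ambiguity codes other than N found; mapped to N",
            call. = FALSE)
    res <- gsub("[^ACGTN]", "N", res)
  }
  # first whitespace-delimited token of the header is the sequence id
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(seq_id = ids, residues = unname(res),
                 length_bp = nchar(unname(res)))
}

#' Write a genome tibble to FASTA
#'
#' @param genome Tibble with `seq_id` and `residues` columns
#'   (as from [read_genome_fasta()] or [simulate_ssr_genome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$residues)
  names(set) <- genome$seq_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene/mRNA/exon features from a GFF3 file
#'
#' Imports the annotation via rtracklayer and keeps only `gene`, `mRNA` and
#' `exon` features, resolving `Parent=` links.  Exons whose parent cannot be
#' resolved are kept with `parent_id = NA` and a warning.  Records with
#' `start > end` are rejected with a warning (rtracklayer refuses such files
#' outright, which satisfies the same contract).
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `seq_id`, `feature_type`, `start`, `end`
#'   (1-based inclusive), `strand`, `feature_id`, `parent_id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "mRNA", "exon")
  gr <- gr[keep]
  if (length(gr) == 0L) {
    return(tibble::tibble(seq_id = character(), feature_type = character(),
                          start = integer(), end = integer(),
                          strand = character(), feature_id = character(),
                          parent_id = character()))
  }
  parent <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  ann <- tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    feature_type = as.character(gr$type),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    feature_id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent_id = parent
  )
  known <- ann$feature_id[!is.na(ann$feature_id)]
  orphan <- ann$feature_type == "exon" & !is.na(ann$parent_id) &
    !(ann$parent_id %in% known)
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) with unresolvable Parent kept with null parent",
            call. = FALSE)
    ann$parent_id[orphan] <- NA_character_
  }
  ann
}

#' Write a report table as TSV with fixed decimal places
#'
#' All pipeline reports are tab-separated with a header row.  Floating-point
#' columns are rendered with a fixed number of decimals so that reports are
#' byte-stable: frequency/density columns conventionally use 2 decimal
#' places and population-genetics statistics 4.
#'
#' @param rows A data frame of report rows.
#' @param path Output path.
#' @param digits Named integer vector mapping column names to the number of
#'   decimal places, e.g. `c(frequency = 2, density = 2)`.  Unnamed numeric
#'   columns are written as-is.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, digits = NULL) {
  stopifnot(is.data.frame(rows))
  out <- tibble::as_tibble(rows)
  # drop list-columns (e.g. compound members); they are not report material
  out <- out[!vapply(out, is.list, logical(1))]
  if (!is.null(digits)) {
    for (col in intersect(names(digits), names(out))) {
      out[[col]] <- formatC(out[[col]], format = "f", digits = digits[[col]])
    }
  }
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) stop("cannot write report to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Read a genotype table
#'
#' Two layouts are supported.  `"wide"` (the default, matching genotyping
#' software exports): one row per individual, first column `sample_id`, one
#' column per locus holding the two allele fragment lengths as `"a/b"` with
#' `"."` (or empty) for missing.  `"long"`: columns `locus`, `sample_id`,
#' `allele_a`, `allele_b`.
#'
#' Partial genotypes (only one allele called) are treated as missing.
#'
#' @param path Path to a tab-separated genotype file.
#' @param format `"auto"` (detect from the header), `"wide"` or `"long"`.
#' @return A long tibble with columns `locus`, `sample_id`, `allele_a`,
#'   `allele_b` (integers, `NA` for missing).
#' @export
read_genotypes <- function(path, format = c("auto", "wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (format == "auto") {
    format <- if (all(c("locus", "sample_id", "allele_a", "allele_b") %in%
                        names(raw))) "long" else "wide"
  }
  if (format == "long") {
    stopifnot(all(c("locus", "sample_id", "allele_a", "allele_b") %in% names(raw)))
    return(dplyr::mutate(
      raw[c("locus", "sample_id", "allele_a", "allele_b")],
      dplyr::across(c("allele_a", "allele_b"), as.integer)
    ))
  }
  stopifnot(names(raw)[1] == "sample_id")
  long <- tidyr::pivot_longer(raw, -"sample_id", names_to = "locus",
                              values_to = "gt", values_transform = as.character)
  parts <- stringr::str_split_fixed(long$gt, "/", 2L)
  a <- suppressWarnings(as.integer(parts[, 1]))
  b <- suppressWarnings(as.integer(parts[, 2]))
  miss <- is.na(a) | is.na(b)
  a[miss] <- NA_integer_
  b[miss] <- NA_integer_
  tibble::tibble(locus = long$locus, sample_id = long$sample_id,
                 allele_a = a, allele_b = b)
}
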