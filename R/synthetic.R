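#' Simulate a genome with planted microsatellites and a truth table
#'
#' Generates a multi-chromosome genome in which every microsatellite is
#' planted deliberately: the background is i.i.d. random sequence at a given
#' GC fraction, screened and locally regenerated until the scanner finds
#' nothing in it, and perfect repeats of known motif, repeat number and
#' target genomic region (exon / intron / intergenic) are then written in at
#' recorded coordinates.  Planted loci are kept at least `min_spacing` nt
#' apart (default 200, beyond the 100 nt compound window, so they stay
#' standalone records), and junction bases are adjusted so a planted run
#' cannot extend into the background.  The generator finishes with a full
#' scan-and-repair pass, so precision and recall of [scan_ssrs()] against
#' the truth table are exactly measurable and equal to 1 by construction of
#' the background, not by tolerance.
#'
#' Each chromosome also carries a regular lattice of gene models (gene /
#' mRNA / exon features; introns are the gaps between exons) used to define
#' the target regions, emitted as a GFF3-convention annotation tibble.
#'
#' Defaults emulate a desk-scale model of a fish genome assembly: 24
#' chromosomes, region mix and period mix close to what genome-wide scans of
#' teleost genomes report (dinucleotides dominant, most loci intronic or
#' intergenic), repeat counts mostly in the 5--15 range.
#'
#' @param n_chromosomes Number of chromosomes (default 24).
#' @param chromosome_length Length of each chromosome in bp (default 2e5).
#' @param n_loci Total number of planted SSRs (default 2000, spread evenly).
#' @param region_weights Named probabilities for target regions
#'   (exon/intron/intergenic).
#' @param period_weights Named probabilities for motif periods 2--6.
#' @param max_repeats Upper bound for the planted repeat count; the lower
#'   bound is each period's detection threshold.
#' @param gc Background GC fraction (default 0.40).
#' @param min_spacing Minimum gap between planted loci in nt (default 200).
#' @param genes_per_chromosome Number of gene models per chromosome.
#' @param min_repeats Detection thresholds, see [default_min_repeats()].
#' @param seed Integer seed; the single source of randomness.
#' @return A list of class `ssr_sim` with elements `genome` (tibble:
#'   `seq_id`, `residues`, `length_bp`), `annotation` (tibble in
#'   [read_gff3()] layout), `truth` (tibble: `seq_id`, `start`, `end`,
#'   `period`, `unit`, `motif`, `n_repeats`, `length_bp`, `region`) and
#'   `params`.
#' @examples
#' sim <- simulate_ssr_genome(n_chromosomes = 2, chromosome_length = 2e4,
#'                            n_loci = 12, seed = 42)
#' nrow(sim$truth)
#' @export
simulate_ssr_genome <- function(n_chromosomes = 24L,
                                chromosome_length = 200000L,
                                n_loci = 2000L,
                                region_weights = c(exon = 0.0855,
                                                   intron = 0.5691,
                                                   intergenic = 0.3454),
                                period_weights = c(`2` = 0.769, `3` = 0.158,
                                                   `4` = 0.057, `5` = 0.013,
                                                   `6` = 0.003),
                                max_repeats = 15L,
                                gc = 0.40,
                                min_spacing = 200L,
                                genes_per_chromosome = 10L,
                                min_repeats = default_min_repeats(),
                                seed = NULL) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 1000, n_loci >= 0,
            gc > 0, gc < 1, min_spacing >= 0)
  if (!is.null(seed)) set.seed(seed)
  min_repeats <- validate_thresholds(min_repeats)
  region_weights <- region_weights / sum(region_weights)
  period_weights <- period_weights / sum(period_weights)
  universes <- lapply(stats::setNames(2:6, as.character(2:6)),
                      enumerate_motif_classes)

  chrom_ids <- sprintf("chr%d", seq_len(n_chromosomes))
  per_chr <- rep(n_loci %/% n_chromosomes, n_chromosomes)
  extra <- n_loci %% n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L

  genomes <- vector("list", n_chromosomes)
  annotations <- vector("list", n_chromosomes)
  truths <- vector("list", n_chromosomes)
  for (c_i in seq_len(n_chromosomes)) {
    ann <- gene_lattice(chrom_ids[c_i], chromosome_length, genes_per_chromosome)
    plan <- plan_loci(per_chr[c_i], chrom_ids[c_i], chromosome_length, ann,
                      region_weights, period_weights, max_repeats,
                      min_spacing, min_repeats, universes)
    residues <- build_chromosome(chromosome_length, gc, plan, min_repeats)
    genomes[[c_i]] <- tibble::tibble(seq_id = chrom_ids[c_i],
                                     residues = residues,
                                     length_bp = nchar(residues))
    annotations[[c_i]] <- ann
    truths[[c_i]] <- plan
  }
  genome <- dplyr::bind_rows(genomes)
  truth <- dplyr::bind_rows(truths)
  truth <- dplyr::arrange(truth, match(.data$seq_id, chrom_ids), .data$start)
  structure(list(
    genome = genome,
    annotation = dplyr::bind_rows(annotations),
    truth = truth,
    params = list(n_chromosomes = n_chromosomes,
                  chromosome_length = chromosome_length, n_loci = n_loci,
                  region_weights = region_weights,
                  period_weights = period_weights, max_repeats = max_repeats,
                  gc = gc, min_spacing = min_spacing,
                  genes_per_chromosome = genes_per_chromosome,
                  min_repeats = min_repeats, seed = seed)
  ), class = "ssr_sim")
}

# Regular lattice of gene models: each gene has 4 exons of 400 bp separated
# by 600 bp introns (gene span 3400 bp), genes evenly spaced with 5 kb
# margins.  Deterministic given the chromosome length and gene count.
gene_lattice <- function(seq_id, len, n_genes) {
  if (n_genes == 0L) {
    return(tibble::tibble(seq_id = character(), feature_type = character(),
                          start = integer(), end = integer(),
                          strand = character(), feature_id = character(),
                          parent_id = character()))
  }
  len <- as.integer(len)
  exon_len <- 400L; intron_len <- 600L; n_exons <- 4L
  span <- n_exons * exon_len + (n_exons - 1L) * intron_len
  margin <- min(5000L, len %/% 20L)
  # fit as many gene models as the chromosome allows, up to the request
  n_fit <- max(0L, (len - 2L * margin) %/% (span + 200L))
  if (n_fit == 0L) {
    stop("chromosome too short for any gene model; lengthen it or set ",
         "genes_per_chromosome = 0", call. = FALSE)
  }
  n_genes <- min(n_genes, n_fit)
  stride <- (len - 2L * margin) %/% n_genes
  rows <- list()
  for (g in seq_len(n_genes)) {
    gs <- margin + (g - 1L) * stride + 1L
    ge <- gs + span - 1L
    gid <- sprintf("%s_gene%d", seq_id, g)
    mid <- sprintf("%s_mrna%d", seq_id, g)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      seq_id = seq_id, feature_type = c("gene", "mRNA"),
      start = gs, end = ge, strand = "+",
      feature_id = c(gid, mid), parent_id = c(NA_character_, gid))
    for (e in seq_len(n_exons)) {
      es <- gs + (e - 1L) * (exon_len + intron_len)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seq_id = seq_id, feature_type = "exon",
        start = es, end = es + exon_len - 1L, strand = "+",
        feature_id = sprintf("%s_exon%d", mid, e), parent_id = mid)
    }
  }
  dplyr::bind_rows(rows)
}

# Choose motif, repeat count, region and coordinates for each planted locus
# on one chromosome, honouring category membership (whole locus within one
# category interval) and the minimum spacing.
plan_loci <- function(n, seq_id, len, ann, region_weights, period_weights,
                      max_repeats, min_spacing, min_repeats, universes) {
  empty <- tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), period = integer(),
                          unit = character(), motif = character(),
                          n_repeats = integer(), length_bp = integer(),
                          region = character())
  if (n == 0L) return(empty)
  idx <- build_region_index(ann, stats::setNames(len, seq_id))[[seq_id]]
  intervals <- lapply(idx[c("exon", "intron", "intergenic")], function(ir) {
    tibble::tibble(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
  })
  placed_start <- integer(0)
  placed_end <- integer(0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- as.integer(sample(names(period_weights), 1L, prob = period_weights))
    motif <- sample(universes[[as.character(p)]], 1L)
    k <- sample(seq(min_repeats[[as.character(p)]], max_repeats), 1L)
    unit <- sample(c(rotations(motif), rotations(revcomp(motif))), 1L)
    region <- sample(names(region_weights), 1L, prob = region_weights)
    L <- p * k
    iv <- intervals[[region]]
    iv <- iv[iv$end - iv$start + 1L >= L + 2L, , drop = FALSE]
    placed <- FALSE
    for (try in seq_len(400L)) {
      if (nrow(iv) == 0L) break
      j <- sample.int(nrow(iv), 1L,
                      prob = iv$end - iv$start + 1L)
      lo <- iv$start[j] + 1L
      hi <- iv$end[j] - L
      if (hi < lo) next
      s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      e <- s + L - 1L
      if (s <= 1L || e >= len) next
      clash <- any(placed_start - e - 1L < min_spacing &
                     s - placed_end - 1L < min_spacing)
      if (clash) next
      placed_start <- c(placed_start, s)
      placed_end <- c(placed_end, e)
      out[[i]] <- tibble::tibble(seq_id = seq_id, start = s, end = e,
                                 period = p, unit = unit, motif = motif,
                                 n_repeats = k, length_bp = L,
                                 region = region)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("cannot place planted loci under the spacing constraints; ",
           "use longer chromosomes or fewer loci", call. = FALSE)
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

# Assemble one chromosome: SSR-free background, planted repeats written in,
# junction bases repaired, then a full scan-and-repair loop until the
# scanner recovers exactly the truth set.
build_chromosome <- function(len, gc, plan, min_repeats) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(probs), len, replace = TRUE, prob = probs)
  planted_mask <- rep(FALSE, len)
  for (i in seq_len(nrow(plan))) {
    s <- plan$start[i]; e <- plan$end[i]
    x[s:e] <- strsplit(strrep(plan$unit[i], plan$n_repeats[i]), NULL)[[1L]]
    planted_mask[s:e] <- TRUE
  }
  x <- repair_junctions(x, plan, planted_mask)
  for (iter in seq_len(100L)) {
    found <- scan_sequence("chr", paste(x, collapse = ""), min_repeats)
    bad <- locus_mismatches(found, plan)
    if (length(bad) == 0L) break
    if (iter == 100L) {
      stop("could not build an SSR-clean background after 100 repair passes",
           call. = FALSE)
    }
    for (iv in bad) {
      win <- max(1L, iv[1L] - 6L):min(len, iv[2L] + 6L)
      win <- win[!planted_mask[win]]
      x[win] <- sample(names(probs), length(win), replace = TRUE, prob = probs)
    }
    x <- repair_junctions(x, plan, planted_mask)
  }
  paste(x, collapse = "")
}

# A planted run must not extend char-by-char into the background: the base
# left of the locus must differ from the base one period inside it, and the
# base right of it from the base one period before the end.  Junction bases
# that belong to another planted locus (abutting fixtures) are left alone:
# truncation to whole units keeps the reported coordinates exact there.
repair_junctions <- function(x, plan, planted_mask) {
  len <- length(x)
  for (i in seq_len(nrow(plan))) {
    s <- plan$start[i]; e <- plan$end[i]; p <- plan$period[i]
    if (s > 1L && !planted_mask[s - 1L] && x[s - 1L] == x[s - 1L + p]) {
      x[s - 1L] <- sample(setdiff(c("A", "C", "G", "T"), x[s - 1L + p]), 1L)
    }
    if (e < len && !planted_mask[e + 1L] && x[e + 1L] == x[e + 1L - p]) {
      x[e + 1L] <- sample(setdiff(c("A", "C", "G", "T"), x[e + 1L - p]), 1L)
    }
  }
  x
}

# Intervals of scanner hits that do not exactly match a truth row.
locus_mismatches <- function(found, plan) {
  key <- function(d) paste(d$start, d$end, d$period)
  truth_keys <- key(plan)
  bad <- list()
  extra <- which(!key(found) %in% truth_keys)
  for (i in extra) bad[[length(bad) + 1L]] <- c(found$start[i], found$end[i])
  missing <- which(!truth_keys %in% key(found))
  for (i in missing) bad[[length(bad) + 1L]] <- c(plan$start[i], plan$end[i])
  bad
}

#' Write a simulated genome to FASTA / GFF3 / truth TSV
#'
#' @param sim `ssr_sim` object from [simulate_ssr_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulated_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "ssr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  truth <- file.path(dir, "truth.tsv")
  write_genome_fasta(sim$genome, fasta)
  write_gff3(sim$annotation, gff)
  readr::write_tsv(sim$truth, truth, progress = FALSE)
  invisible(c(fasta = fasta, gff3 = gff, truth = truth))
}

# Emit gene/mRNA/exon rows as GFF3 lines (plain formatting of the
# annotation tibble; coordinates are already 1-based inclusive).
write_gff3 <- function(annotation, path) {
  attrs <- ifelse(is.na(annotation$parent_id),
                  sprintf("ID=%s", annotation$feature_id),
                  sprintf("ID=%s;Parent=%s", annotation$feature_id,
                          annotation$parent_id))
  lines <- sprintf("%s\tssrscape\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   annotation$seq_id, annotation$feature_type,
                   annotation$start, annotation$end, annotation$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Simulate diploid genotypes under Hardy--Weinberg equilibrium
#'
#' Each individual's two alleles are drawn independently from the locus
#' allele-frequency vector; missingness is then applied per individual and
#' locus.
#'
#' @param freqs Named list, one element per locus: a named numeric vector of
#'   allele frequencies (names are fragment lengths), each summing to 1.
#' @param n_individuals Number of diploid individuals (default 29, the size
#'   of a typical wild validation panel).
#' @param missing_rate Probability an individual x locus genotype is missing.
#' @param seed Integer seed.
#' @return Long genotype tibble (`locus`, `sample_id`, `allele_a`,
#'   `allele_b`) as consumed by [marker_stats()].
#' @examples
#' g <- simulate_genotypes(list(L1 = c(`100` = 0.5, `104` = 0.5)),
#'                         n_individuals = 29, seed = 7)
#' @export
simulate_genotypes <- function(freqs, n_individuals = 29L, missing_rate = 0,
                               seed = NULL) {
  stopifnot(is.list(freqs), length(freqs) >= 1, n_individuals >= 2,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(names(freqs))) names(freqs) <- sprintf("L%d", seq_along(freqs))
  for (f in freqs) {
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stop("each frequency vector must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  samples <- sprintf("ind%02d", seq_len(n_individuals))
  purrr::imap_dfr(freqs, function(f, locus) {
    alleles <- as.integer(names(f))
    # index-based draw: sample() would misread a single allele as 1:allele
    a <- alleles[sample.int(length(f), n_individuals, replace = TRUE, prob = f)]
    b <- alleles[sample.int(length(f), n_individuals, replace = TRUE, prob = f)]
    miss <- stats::runif(n_individuals) < missing_rate
    a[miss] <- NA_integer_
    b[miss] <- NA_integer_
    tibble::tibble(locus = locus, sample_id = samples,
                   allele_a = a, allele_b = b)
  })
}

#' Two-SSR fixture with an exact inter-locus gap
#'
#' Builds a single sequence containing exactly two threshold-passing SSRs
#' -- `(AC)8` then `(AGG)6` -- separated by exactly `gap` non-repetitive
#' nucleotides, for testing the compound-merging boundary.
#'
#' @param gap Gap between the two loci in nt (>= 0).
#' @param flank_len Clean background on each side (default 300 bp).
#' @param seed Integer seed.
#' @return List with `genome` (one-row tibble) and `truth` (two-row locus
#'   tibble with exact coordinates).
#' @export
simulate_compound_fixture <- function(gap, flank_len = 300L, seed = NULL) {
  stopifnot(gap >= 0, flank_len >= 20)
  if (!is.null(seed)) set.seed(seed)
  unit1 <- "AC"; k1 <- 8L
  unit2 <- "AGG"; k2 <- 6L
  L1 <- nchar(unit1) * k1
  L2 <- nchar(unit2) * k2
  len <- flank_len * 2L + L1 + gap + L2
  s1 <- flank_len + 1L
  e1 <- s1 + L1 - 1L
  s2 <- e1 + gap + 1L
  e2 <- s2 + L2 - 1L
  plan <- tibble::tibble(
    seq_id = "fixture", start = c(s1, s2), end = c(e1, e2),
    period = c(2L, 3L), unit = c(unit1, unit2),
    motif = c(canonical_motif(unit1), canonical_motif(unit2)),
    n_repeats = c(k1, k2), length_bp = c(L1, L2),
    region = "intergenic")
  residues <- build_chromosome(len, 0.4, plan, default_min_repeats())
  list(genome = tibble::tibble(seq_id = "fixture", residues = residues,
                               length_bp = len),
       truth = plan[setdiff(names(plan), "region")])
}
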