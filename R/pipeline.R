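#' Run the full SSR pipeline on a genome
#'
#' Orchestrates the stages in dependency order — scan, compound merge,
#' landscape statistics, region assignment (when an annotation is given),
#' marker-candidate extraction, and polymorphism statistics (when a genotype
#' table is given) — writing every report as TSV plus a JSON run manifest
#' recording the package version, parameters, input checksums and per-stage
#' record counts.  The run is a pure function of its inputs and parameters,
#' so rerunning with the same configuration reproduces identical outputs.
#'
#' @param fasta Path to the genome FASTA (required).
#' @param gff Optional path to a GFF3 annotation.
#' @param genotypes Optional path to a genotype TSV (see [read_genotypes()]).
#' @param out_dir Output directory (created if needed).
#' @param min_repeats Detection thresholds, see [default_min_repeats()].
#' @param max_gap Compound-SSR gap threshold (strict `<`, default 100 nt).
#' @param boundary_rule Region boundary rule, see [assign_regions()].
#' @param flank_len Marker flank length in bp (default 250).
#' @param genome_size_bp Optional genome-size denominator override.
#' @param top_n Motif classes to keep in the ranking report.
#' @return Invisibly, a list with the stage results (`loci`, `records`,
#'   `chrom_stats`, `genome_stats`, `period_breakdown`, `motif_ranking`,
#'   `regions`, `candidates`, `popgen`) and the `manifest`.
#' @export
run_ssr_pipeline <- function(fasta, gff = NULL, genotypes = NULL,
                             out_dir = ".",
                             min_repeats = default_min_repeats(),
                             max_gap = 100L,
                             boundary_rule = "start",
                             flank_len = 250L,
                             genome_size_bp = NULL,
                             top_n = 10L) {
  for (p in c(fasta, gff, genotypes)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_fasta(fasta)
  seq_lengths <- stats::setNames(genome$length_bp, genome$seq_id)

  loci <- scan_ssrs(genome, min_repeats = min_repeats)
  records <- merge_compound_ssrs(loci, max_gap = max_gap)
  cs <- chromosome_stats(loci, seq_lengths)
  gs <- genome_stats(loci, seq_lengths, genome_size_bp = genome_size_bp)
  pb <- period_breakdown(loci, size_mb = gs$genome_mb)
  mr <- motif_ranking(loci, top_n = top_n, size_mb = gs$genome_mb)
  hist <- repeat_number_histogram(loci)

  write_report(loci, file.path(out_dir, "ssr_loci.tsv"))
  write_report(records, file.path(out_dir, "ssr_records.tsv"))
  write_report(cs, file.path(out_dir, "chromosome_stats.tsv"),
               digits = c(size_mb = 2, frequency = 2, density = 2))
  write_report(gs, file.path(out_dir, "genome_stats.tsv"),
               digits = c(genome_mb = 2, frequency = 2, density = 2,
                          pct_of_genome = 2, mean_spacing_bp = 1))
  write_report(pb, file.path(out_dir, "period_breakdown.tsv"),
               digits = c(proportion_pct = 2, frequency = 2, density = 2))
  write_report(mr, file.path(out_dir, "motif_ranking.tsv"),
               digits = c(frequency = 2, density = 2))
  write_report(hist, file.path(out_dir, "repeat_histogram.tsv"))

  regions <- NULL
  if (!is.null(gff)) {
    ann <- read_gff3(gff)
    idx <- build_region_index(ann, seq_lengths)
    assigned <- assign_regions(records, idx, boundary_rule = boundary_rule)
    dist <- region_distribution(assigned)
    write_report(assigned, file.path(out_dir, "region_assignments.tsv"))
    write_report(dist$counts, file.path(out_dir, "region_distribution.tsv"))
    regions <- list(assigned = assigned, distribution = dist)
  }

  candidates <- extract_flanks(loci, genome, flank_len = flank_len)
  attr(candidates, "seq_lengths") <- seq_lengths
  mpc <- markers_per_chromosome(candidates, seq_lengths)
  write_report(candidates[setdiff(names(candidates),
                                  c("left_flank", "right_flank"))],
               file.path(out_dir, "marker_candidates.tsv"))
  write_report(mpc, file.path(out_dir, "markers_per_chromosome.tsv"),
               digits = c(size_mb = 2, frequency = 2))

  popgen <- NULL
  if (!is.null(genotypes)) {
    gt <- read_genotypes(genotypes)
    ms <- marker_stats(gt)
    write_report(ms, file.path(out_dir, "marker_stats.tsv"),
                 digits = c(Ne = 4, Ho = 4, He = 4, I = 4, PIC = 4))
    popgen <- ms
  }

  manifest <- list(
    tool = "ssrscape",
    version = as.character(utils::packageVersion("ssrscape")),
    parameters = list(min_repeats = as.list(min_repeats), max_gap = max_gap,
                      boundary_rule = boundary_rule, flank_len = flank_len,
                      genome_size_bp = genome_size_bp, top_n = top_n),
    counts = list(sequences = nrow(genome), loci = nrow(loci),
                  records = nrow(records),
                  compounds = sum(records$type == "c"),
                  markers = sum(candidates$designable),
                  popgen_loci = if (is.null(popgen)) 0L else nrow(popgen))
  )
  ins <- Filter(Negate(is.null), list(fasta = fasta, gff = gff,
                                      genotypes = genotypes))
  manifest$inputs <- lapply(ins, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(loci = loci, records = records, chrom_stats = cs,
                 genome_stats = gs, period_breakdown = pb,
                 motif_ranking = mr, repeat_histogram = hist,
                 regions = regions, candidates = candidates, popgen = popgen,
                 manifest = manifest))
}
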