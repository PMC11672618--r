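mk_ann <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(seq_id = r[[1]], feature_type = r[[2]],
                   start = as.integer(r[[3]]), end = as.integer(r[[4]]),
                   strand = "+", feature_id = r[[5]],
                   parent_id = if (length(r) > 5) r[[6]] else NA_character_)
  }))
}

simple_gene <- function() {
  mk_ann(list("s", "gene", 101, 400, "g1"),
         list("s", "mRNA", 101, 400, "m1", "g1"),
         list("s", "exon", 101, 200, "e1", "m1"),
         list("s", "exon", 301, 400, "e2", "m1"))
}

part_widths <- function(part) {
  vapply(part[c("exon", "intron", "intergenic")],
         function(ir) sum(IRanges::width(ir)), numeric(1))
}

test_that("a gene with two exons partitions the sequence exactly", {
  idx <- build_region_index(simple_gene(), c(s = 1000))
  w <- part_widths(idx$s)
  expect_equal(unname(w), c(200, 100, 700))
  expect_equal(sum(w), 1000)
})

test_that("without genes everything is intergenic", {
  idx <- build_region_index(mk_ann()[0, ], c(s = 500))
  expect_equal(unname(part_widths(idx$s)), c(0, 0, 500))
})

test_that("exon precedence across isoforms: union of exons is exonic", {
  ann <- dplyr::bind_rows(
    simple_gene(),
    mk_ann(list("s", "mRNA", 101, 400, "m2", "g1"),
           list("s", "exon", 201, 250, "e3", "m2")))   # inside m1's intron
  idx <- build_region_index(ann, c(s = 1000))
  w <- part_widths(idx$s)
  expect_equal(unname(w), c(250, 50, 700))
  # brute-force per-base cross-check of the partition
  base_cat <- rep("intergenic", 1000)
  base_cat[101:400] <- "intron"
  for (e in list(101:200, 301:400, 201:250)) base_cat[e] <- "exon"
  for (cat in c("exon", "intron", "intergenic")) {
    ir <- idx$s[[cat]]
    covered <- as.integer(unlist(
      Map(seq, BiocGenerics::start(ir), BiocGenerics::end(ir))))
    expect_identical(sort(covered), which(base_cat == cat))
  }
})

test_that("features beyond the sequence end are clipped with a warning", {
  ann <- mk_ann(list("s", "gene", 101, 1400, "g1"),
                list("s", "exon", 101, 1400, "e1", "g1"))
  expect_warning(idx <- build_region_index(ann, c(s = 1000)), "clipped")
  expect_equal(sum(part_widths(idx$s)), 1000)
})

test_that("records classify by the category of their start base", {
  idx <- build_region_index(simple_gene(), c(s = 1000))
  recs <- tibble::tibble(
    record_id = c("a", "b", "c", "d"),
    seq_id = "s",
    start = c(110L, 600L, 250L, 95L),
    end = c(130L, 620L, 320L, 120L),
    type = "p2")
  out <- assign_regions(recs, idx)
  # wholly exonic; wholly intergenic; starts in intron ends in exon;
  # starts intergenic ends in exon
  expect_identical(out$region, c("exon", "intergenic", "intron", "intergenic"))
  expect_identical(out$gene_id[1], "g1")
  expect_true(is.na(out$gene_id[2]))
  expect_error(assign_regions(dplyr::mutate(recs, seq_id = "zz"), idx),
               "absent")
})

test_that("majority-overlap rule is available as an alternative", {
  idx <- build_region_index(simple_gene(), c(s = 1000))
  # starts 1 bp inside the intron but lies mostly in the exon
  recs <- tibble::tibble(record_id = "a", seq_id = "s",
                         start = 299L, end = 340L, type = "p2")
  expect_identical(assign_regions(recs, idx)$region, "intron")
  expect_identical(assign_regions(recs, idx, boundary_rule = "majority")$region,
                   "exon")
})

test_that("region distribution reproduces published-style percentages", {
  counts <- tibble::tibble(
    type = c("p2", "p3", "p4", "p5", "p6", "c"),
    exon = c(7909, 6655, 761, 207, 70, 3776),
    intergenic = c(45439, 10027, 4689, 1071, 236, 16794),
    intron = c(78991, 14969, 6308, 1623, 247, 26801))
  dist <- region_distribution(counts)
  expect_equal(dist$grand_total, 226573)
  expect_equal(round(unname(dist$region_pct["intron"]), 2), 56.91)
  expect_equal(round(unname(dist$region_pct["intergenic"]), 2), 34.54)
  expect_equal(round(unname(dist$region_pct["exon"]), 2), 8.55)
  expect_equal(dist$counts$all, dist$counts$exon + dist$counts$intergenic +
                 dist$counts$intron)
})

test_that("all-intergenic records give 100% intergenic", {
  a <- tibble::tibble(type = rep("p2", 5), region = rep("intergenic", 5))
  dist <- region_distribution(a)
  expect_equal(unname(dist$region_pct["intergenic"]), 100)
  expect_equal(dist$grand_total, 5)
})

test_that("planted region labels are recovered exactly on a synthetic genome", {
  sim <- simulate_ssr_genome(n_chromosomes = 3, chromosome_length = 5e4,
                             n_loci = 90, seed = 77)
  seq_lengths <- stats::setNames(sim$genome$length_bp, sim$genome$seq_id)
  idx <- build_region_index(sim$annotation, seq_lengths)
  loci <- scan_ssrs(sim$genome)
  recs <- merge_compound_ssrs(loci)
  expect_true(all(recs$n_members == 1L))  # spacing keeps them standalone
  out <- assign_regions(recs, idx)
  truth <- sim$truth
  m <- match(paste(out$seq_id, out$start), paste(truth$seq_id, truth$start))
  expect_false(anyNA(m))
  expect_identical(out$region, truth$region[m])
  # compounds count once in the distribution
  dist <- region_distribution(out)
  expect_equal(dist$grand_total, nrow(recs))
})
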