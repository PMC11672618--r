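test_that("flanks abut the locus and clip at sequence ends", {
  s <- paste0(strrep("T", 488), strrep("AC", 12), strrep("G", 500))
  g <- tibble::tibble(seq_id = "c", residues = s)
  loci <- scan_ssrs(g)
  cand <- extract_flanks(loci, g, flank_len = 100)
  expect_equal(nchar(cand$left_flank), 100L)
  expect_equal(nchar(cand$right_flank), 100L)
  expect_true(cand$designable)
  # the flanks do not reach into the repeat
  expect_identical(cand$left_flank, strrep("T", 100))
  expect_identical(cand$right_flank, strrep("G", 100))

  s2 <- paste0("TTTT", strrep("AC", 12), strrep("G", 300))
  g2 <- tibble::tibble(seq_id = "c", residues = s2)
  cand2 <- extract_flanks(scan_ssrs(g2), g2, flank_len = 100)
  expect_equal(nchar(cand2$left_flank), 4L)
  expect_false(cand2$designable)
  expect_match(cand2$reject_reason, "left flank too short")
})

test_that("flanks with long N runs are rejected", {
  s <- paste0(strrep("T", 100), strrep("N", 12), strrep("T", 100),
              strrep("AC", 12), strrep("G", 300))
  g <- tibble::tibble(seq_id = "c", residues = s)
  cand <- extract_flanks(scan_ssrs(g), g, flank_len = 250)
  expect_false(cand$designable)
  expect_match(cand$reject_reason, "N run")
})

test_that("GC content and melting temperature follow the stated formulas", {
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(round(gc_content("GCGCAA"), 2), 66.67)
  expect_equal(round(gc_content("GCGCGA"), 2), 83.33)
  expect_error(gc_content(""), "empty")

  # 20-mer with 10 G/C: basic GC formula
  p <- paste0(strrep("GC", 5), strrep("AT", 5))
  expect_equal(melting_temperature(p), 64.9 + 41 * (10 - 16.4) / 20)
  expect_equal(round(melting_temperature(p), 2), 51.78)
  # short oligos use the Wallace rule
  expect_equal(melting_temperature("AAAATTTTAAAA"), 24)
  expect_equal(melting_temperature(strrep("G", 20)), 72.28)
})

test_that("primer pairs are screened against every constraint", {
  # build a template where a well-behaved pair amplifies a 150 bp product
  set.seed(10)
  fwd <- paste0(strrep("GC", 5), strrep("AT", 5))       # 20-mer, 50% GC
  rev_bind <- paste0(strrep("AT", 5), strrep("GC", 5))  # site on fwd strand
  rev <- ssrscape:::revcomp(rev_bind)
  mid <- paste(sample(c("A", "C", "G", "T"), 110, TRUE), collapse = "")
  template <- paste0("TT", fwd, mid, rev_bind, "TT")
  res <- screen_primer_pair(fwd, rev, template)
  expect_true(res$pass)
  expect_equal(res$product_size, 150L)

  # too-short forward primer fails with the length message
  res2 <- screen_primer_pair(substr(fwd, 1, 16), rev, template)
  expect_false(res2$pass)
  expect_true(any(grepl("length", res2$failures)))

  # product outside the window fails
  big_mid <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  res3 <- screen_primer_pair(fwd, rev, paste0(fwd, big_mid, rev_bind))
  expect_false(res3$pass)
  expect_true(any(grepl("product size", res3$failures)))

  # absent binding site is reported, not an error
  res4 <- screen_primer_pair(fwd, rev, strrep("T", 200))
  expect_false(res4$pass)
  expect_true(any(grepl("no binding site", res4$failures)))
})

test_that("all failing constraints are listed, not just the first", {
  fwd <- strrep("G", 35)   # too long, Tm too high, GC too high
  rev <- strrep("G", 35)
  res <- screen_primer_pair(fwd, rev, strrep("T", 100))
  expect_gte(length(res$failures), 5)
})

test_that("relaxing constraint ranges never turns a pass into a fail", {
  set.seed(20)
  fwd <- paste0(strrep("GC", 5), strrep("AT", 5))
  rev_bind <- paste0(strrep("AT", 5), strrep("GC", 5))
  rev <- ssrscape:::revcomp(rev_bind)
  mid <- paste(sample(c("A", "C", "G", "T"), 110, TRUE), collapse = "")
  template <- paste0(fwd, mid, rev_bind)
  tight <- default_primer_constraints()
  loose <- list(len_range = c(10, 40), tm_range = c(30, 90),
                gc_range = c(0, 100), product_range = c(50, 1000))
  r_tight <- screen_primer_pair(fwd, rev, template, tight)
  r_loose <- screen_primer_pair(fwd, rev, template, loose)
  expect_true(r_tight$pass)
  expect_true(r_loose$pass)
})

test_that("product size matches a string-search oracle", {
  set.seed(30)
  for (r in 1:10) {
    left <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), sample(60:200, 1), TRUE),
                 collapse = "")
    fwd <- paste0("ACGTACGTACGTACGTACGT")
    rev_bind <- "TGCATGCATGCATGCATGCA"
    template <- paste0(left, fwd, mid, rev_bind, "GG")
    res <- screen_primer_pair(fwd, ssrscape:::revcomp(rev_bind), template)
    fwd_at <- regexpr(fwd, template, fixed = TRUE)[1]
    rev_end <- regexpr(rev_bind, template, fixed = TRUE)[1] +
      nchar(rev_bind) - 1
    expect_equal(res$product_size, rev_end - fwd_at + 1)
  }
})

test_that("per-chromosome marker counts and frequency", {
  cand <- tibble::tibble(seq_id = c("chr1", "chr1", "chr2"),
                         designable = c(TRUE, TRUE, FALSE))
  mpc <- markers_per_chromosome(cand, c(chr1 = 2e6, chr2 = 1e6))
  expect_equal(mpc$n_designable, c(2L, 0L))
  expect_equal(mpc$frequency, c(1, 0))
})
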