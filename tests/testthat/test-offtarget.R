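test_that("a genome that is exactly spacer+PAM yields one perfect hit", {
  spacer <- "ACGTACGTACGTACGTACGT"
  hits <- scan_offtargets(spacer, c(chr = paste0(spacer, "AGG")))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 0L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$strand, "+")
})

test_that("the Hamming bound is respected", {
  spacer <- "ACGTACGTACGTACGTACGT"
  mutated <- "TCGTACGTACGTACGTACGT"
  genome <- c(chr = paste0(mutated, "AGG"))
  expect_equal(nrow(scan_offtargets(spacer, genome, max_mismatch = 0)), 0L)
  h1 <- scan_offtargets(spacer, genome, max_mismatch = 1)
  expect_equal(h1$mismatches, 1L)
})

test_that("scan matches a naive position-by-position rescan on a random contig", {
  contig <- random_dna(5000, seed = 77)
  spacer <- substr(contig, 1001, 1020)  # guarantees a self-hit when PAM fits
  genome <- c(ctg = contig)
  for (k in 0:2) {
    hits <- scan_offtargets(spacer, genome, max_mismatch = k)
    oracle <- oracle_offtarget(spacer, contig, k)
    expect_identical(
      paste(hits$position, hits$strand, hits$mismatches),
      paste(oracle$position, oracle$strand, oracle$mismatches),
      label = paste("max_mismatch", k))
  }
})

test_that("hit counts are monotone in the mismatch bound", {
  contig <- random_dna(8000, seed = 5)
  spacer <- substr(contig, 501, 520)
  genome <- c(ctg = contig)
  counts <- vapply(0:3, function(k)
    nrow(scan_offtargets(spacer, genome, max_mismatch = k)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("scanning the guide's own locus always yields a 0-mismatch self-hit", {
  fx <- generate_locus(synthetic_locus_spec(80, list(c(30, "CAG")), seed = 21))
  res <- suppressMessages(filter_guides(fx$locus,
                                        enumerate_guides(fx$locus)))
  genome <- stats::setNames(locus_seq(fx$locus), "locus")
  for (sp in res$spacer) {
    hits <- scan_offtargets(sp, genome, max_mismatch = 0)
    expect_gte(sum(hits$mismatches == 0), 1L)
  }
})

test_that("reverse-complementing every contig leaves per-guide tallies unchanged", {
  contig <- random_dna(4000, seed = 13)
  spacer <- substr(contig, 2001, 2020)
  a <- scan_offtargets(spacer, c(ctg = contig))
  b <- scan_offtargets(spacer, c(ctg = revcomp(contig)))
  expect_identical(summarize_offtargets(a), summarize_offtargets(b))
})

test_that("ambiguous genome bases count as mismatches and never match the PAM", {
  spacer <- "ACGTACGTACGTACGTACGT"
  with_n <- paste0("ACGTACGTACNTACGTACGT", "AGG")   # N inside protospacer
  hits <- scan_offtargets(spacer, c(chr = with_n), max_mismatch = 1)
  expect_equal(hits$mismatches, 1L)
  pam_n <- paste0(spacer, "ANG")                    # N inside the PAM GG
  expect_equal(nrow(scan_offtargets(spacer, c(chr = pam_n),
                                    max_mismatch = 3)), 0L)
})

test_that("NAG sites are reported separately only when requested", {
  spacer <- "ACGTACGTACGTACGTACGT"
  genome <- c(chr = paste0(spacer, "AAG", strrep("T", 5), spacer, "AGG"))
  strict <- scan_offtargets(spacer, genome)
  expect_true(all(strict$pam_class == "NGG"))
  relaxed <- scan_offtargets(spacer, genome, include_nag = TRUE)
  expect_setequal(relaxed$pam_class, c("NGG", "NAG"))
})

test_that("summaries recount the hit table", {
  expect_equal(unname(summarize_offtargets(sgstop:::empty_hit_frame())),
               c(0L, 0L, 0L, 0L))
  contig <- random_dna(6000, seed = 31)
  spacer <- substr(contig, 101, 120)
  hits <- scan_offtargets(spacer, c(ctg = contig), max_mismatch = 3)
  s <- summarize_offtargets(hits)
  expect_equal(unname(s), vapply(0:3, function(k)
    sum(hits$mismatches == k), integer(1)))
  expect_true(all(diff(cumsum(s)) >= 0))
})

test_that("contract violations are rejected", {
  expect_error(scan_offtargets("ACGT", c(chr = "ACGTACGT")), "spacer length")
  expect_error(scan_offtargets(strrep("A", 20), character(0)), "empty")
  expect_error(scan_offtargets(strrep("A", 20), c(chr = "ACGT"),
                               max_mismatch = 25), "max_mismatch")
})

test_that("hits export to BED with mismatches in the score column", {
  spacer <- "ACGTACGTACGTACGTACGT"
  hits <- scan_offtargets(spacer, c(chr = paste0(spacer, "AGG")))
  path <- withr::local_tempfile(fileext = ".bed")
  export_offtargets_bed(hits, path)
  bed <- rtracklayer::import(path)
  expect_equal(BiocGenerics::start(bed), 1L)  # 0-based BED -> 1-based GRanges
  expect_equal(BiocGenerics::width(bed), 20L)
  expect_equal(bed$score, 0)
})
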