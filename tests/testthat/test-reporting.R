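make_results <- function(locus) {
  suppressMessages(filter_guides(locus, enumerate_guides(locus)))
}

test_that("earlier stops outrank later ones when off-targets tie", {
  fx <- generate_locus(synthetic_locus_spec(
    150, list(c(30, "CAG"), c(120, "CAA")), seed = 2))
  res <- make_results(fx$locus)
  ot <- data.frame(m0 = rep(1L, nrow(res)), m1 = 0L, m2 = 0L, m3 = 0L)
  rep <- rank_guides(res, ot)
  expect_equal(rep$nonsense_codon_number[1], 30L)
  expect_true(all(diff(rep$truncation_fraction) >= 0))
})

test_that("fewer off-target hits outrank a smaller truncation fraction", {
  fx <- generate_locus(synthetic_locus_spec(
    150, list(c(30, "CAG"), c(120, "CAA")), seed = 2))
  res <- make_results(fx$locus)
  n <- nrow(res)
  expect_gte(n, 2)
  m0 <- rep(1L, n)
  m0[res$nonsense_codon_number == 30L] <- 5L   # early stop has many hits
  rep <- rank_guides(res, data.frame(m0 = m0, m1 = 0L, m2 = 0L, m3 = 0L))
  expect_equal(rep$nonsense_codon_number[1], 120L)
})

test_that("a single guide gets rank 1 and ranks are a permutation", {
  fx <- generate_locus(synthetic_locus_spec(80, list(c(30, "CAG")), seed = 21))
  res <- make_results(fx$locus)
  rep <- rank_guides(res)
  expect_equal(rep$rank, seq_len(nrow(rep)))
})

test_that("ranking equals an independently coded comparator sort", {
  withr::with_seed(8, {
    fx <- generate_locus(synthetic_locus_spec(
      300, list(c(30, "CAG"), c(90, "CAA"), c(150, "CGA"), c(210, "TGG"),
                c(260, "CAG")), seed = 8))
    res <- make_results(fx$locus)
    n <- nrow(res)
    ot <- data.frame(m0 = sample(1:3, n, TRUE), m1 = sample(0:2, n, TRUE),
                     m2 = sample(0:2, n, TRUE), m3 = sample(0:4, n, TRUE))
    scores <- data.frame(spacer = res$spacer,
                         score = round(stats::runif(n), 3))
    scores <- scores[-1, ]  # leave one spacer unmatched
    rep <- suppressWarnings(rank_guides(res, ot, scores))
    df <- cbind(res[, c("locus_start", "truncation_fraction")], ot)
    df$external_score <- scores$score[match(res$spacer, scores$spacer)]
    ord <- oracle_rank_order(df)
    expect_equal(rep$locus_start, res$locus_start[ord])
  })
})

test_that("unknown ranking weight keys are a configuration error", {
  fx <- generate_locus(synthetic_locus_spec(80, list(c(30, "CAG")), seed = 21))
  res <- make_results(fx$locus)
  expect_error(rank_guides(res, weights = c(bogus = 1)), "weight key")
})

test_that("coordinate conventions convert correctly at the export boundary", {
  fx <- generate_locus(synthetic_locus_spec(80, list(c(30, "CAG")), seed = 21))
  res <- make_results(fx$locus)
  rep <- rank_guides(res)
  i <- 1
  bed <- export_annotations(rep, fx$locus, "bed")
  bf <- read.table(text = bed, sep = "\t")
  expect_equal(bf$V2[i], rep$locus_start[i])          # 0-based start
  expect_equal(bf$V3[i], rep$locus_start[i] + 20L)    # half-open end
  path <- withr::local_tempfile(fileext = ".gff3")
  export_annotations(rep, fx$locus, "gff3", path = path)
  gff <- rtracklayer::import(path)
  proto <- gff[gff$type == "protospacer"]
  expect_equal(BiocGenerics::start(proto)[i], rep$locus_start[i] + 1L)
  expect_equal(BiocGenerics::end(proto)[i], rep$locus_start[i] + 20L)
})

test_that("GFF3, BED and TSV exports round-trip through standard parsers", {
  fx <- generate_locus(synthetic_locus_spec(
    150, list(c(30, "CAG"), c(77, "CGA"), c(120, "TGG")), seed = 1))
  res <- make_results(fx$locus)
  rep <- rank_guides(res)

  gff_path <- withr::local_tempfile(fileext = ".gff3")
  export_annotations(rep, fx$locus, "gff3", path = gff_path)
  gff <- rtracklayer::import(gff_path)
  proto <- gff[gff$type == "protospacer"]
  expect_equal(length(proto), nrow(rep))
  ord <- order(as.integer(gff$rank[gff$type == "protospacer"]))
  expect_equal(BiocGenerics::start(proto)[ord], rep$locus_start + 1L)
  expect_equal(as.character(BiocGenerics::strand(proto))[ord], rep$strand)
  expect_equal(proto$protein_change[ord], rep$protein_change)
  stops <- gff[gff$type == "stop_codon"]
  expect_equal(length(stops), nrow(rep))
  b <- sgstop:::cds_bounds(fx$locus)
  sord <- order(as.integer(stops$rank))
  expect_equal(BiocGenerics::start(stops)[sord],
               b[["start"]] + (rep$nonsense_codon_number - 1L) * 3L + 1L)

  bed_path <- withr::local_tempfile(fileext = ".bed")
  export_annotations(rep, fx$locus, "bed", path = bed_path)
  bed <- rtracklayer::import(bed_path)
  bord <- order(bed$score)
  expect_equal(BiocGenerics::start(bed)[bord] - 1L, rep$locus_start)
  expect_equal(bed$name[bord], rep$protein_change)
  expect_equal(as.character(BiocGenerics::strand(bed))[bord], rep$strand)

  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  export_annotations(rep, fx$locus, "tsv", path = tsv_path)
  back <- read_guide_report(tsv_path)
  expect_equal(back$locus_start, rep$locus_start)
  expect_equal(back$protein_change, rep$protein_change)
  expect_equal(back$strand, rep$strand)
  expect_equal(ncol(back), length(sgstop:::REPORT_COLUMNS))
})

test_that("empty report lists export as valid header-only files", {
  fx <- generate_locus(synthetic_locus_spec(60, decoys = 5, seed = 3))
  rep <- rank_guides(make_results(fx$locus))
  expect_equal(nrow(rep), 0L)
  tsv <- export_annotations(rep, fx$locus, "tsv")
  expect_true(any(grepl("^rank\\t", tsv)))
  gff <- export_annotations(rep, fx$locus, "gff3")
  expect_true(all(grepl("^#", gff)))
  bed <- export_annotations(rep, fx$locus, "bed")
  expect_length(bed, 0L)
  # TSV re-parses to a zero-row frame with the full column set
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tsv, path)
  back <- read_guide_report(path)
  expect_equal(nrow(back), 0L)
  expect_equal(ncol(back), length(sgstop:::REPORT_COLUMNS))
})

test_that("TSV keeps a fixed column count with optionals rendered empty", {
  fx <- generate_locus(synthetic_locus_spec(80, list(c(30, "CAG")), seed = 21))
  rep <- rank_guides(make_results(fx$locus))  # no off-targets, no scores
  lines <- export_annotations(rep, fx$locus, "tsv")
  rows <- lines[!startsWith(lines, "#")]
  nfields <- count.fields(textConnection(rows), sep = "\t", quote = "")
  expect_true(all(nfields == length(sgstop:::REPORT_COLUMNS)))
})

test_that("cloning oligos are arm+spacer+arm with the standard 19-nt arms", {
  spacer <- strrep("A", 20)
  oligo <- make_cloning_oligo(spacer, strrep("G", 19), strrep("C", 19))
  expect_equal(nchar(oligo), 58L)
  expect_equal(oligo, paste0(strrep("G", 19), spacer, strrep("C", 19)))
  expect_equal(regexpr(spacer, oligo)[1], 20L)  # spacer at offset 19 (0-based)
  expect_error(make_cloning_oligo(spacer, "", strrep("C", 19)), "non-empty")
  expect_error(make_cloning_oligo(spacer, strrep("G", 10), strrep("C", 19)),
               "15")
  expect_warning(make_cloning_oligo(spacer, strrep("G", 16), strrep("C", 19)),
                 "19")
})
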