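# Build a locus whose window covers a chosen codon: ATG + filler + codon +
# filler + TAA, with an NGG placed so the default window (2-4) covers the
# codon's first base.
planted_locus <- function(codon, n_before = 10, n_after = 10) {
  filler <- "GCT"  # Ala: no C->T stop possible on either strand
  cds <- paste0("ATG", strrep(filler, n_before), codon,
                strrep(filler, n_after), "TAA")
  # codon starts at CDS position (1 + n_before)*3 (0-based)
  suppressMessages(suppressWarnings(coding_sequence(
    cds, upstream = strrep("A", 30), downstream = strrep("A", 30))))
}

guide_over <- function(locus, codon_number, window_pos = 2L,
                       strand = "+") {
  g <- suppressMessages(enumerate_guides(locus))
  b <- sgstop:::cds_bounds(locus)
  target <- b[["start"]] + (codon_number - 1L) * 3L
  hit <- vapply(seq_len(nrow(g)), function(i) {
    any(g$window_locus[[i]] %in% (target + 0:2)) && g$strand[i] == strand
  }, logical(1))
  g[hit, , drop = FALSE]
}

test_that("simulate_edit converts a sense CAG into TAG (nonsense)", {
  fx <- generate_locus(synthetic_locus_spec(40, list(c(12, "CAG")), seed = 4))
  locus <- fx$locus
  g <- suppressMessages(enumerate_guides(locus))
  b <- sgstop:::cds_bounds(locus)
  cpos <- b[["start"]] + 11L * 3L   # the planted CAG's cytosine
  i <- which(vapply(seq_len(nrow(g)), function(i)
    cpos %in% g$editable_positions[[i]], logical(1)))
  expect_gt(length(i), 0)
  sim <- simulate_edit(locus, g[i[1], ], mask = cpos)
  cons <- sim$consequences
  expect_equal(cons$codon_number, 12L)
  expect_equal(cons$ref_codon, "CAG")
  expect_equal(cons$alt_codon, "TAG")
  expect_equal(cons$consequence, "nonsense")
})

test_that("simulate_edit with an empty mask is the identity", {
  locus <- planted_locus("CAG")
  g <- suppressMessages(enumerate_guides(locus))
  sim <- simulate_edit(locus, g[1, ], mask = integer(0))
  expect_identical(sim$cds, locus$cds)
  expect_equal(nrow(sim$consequences), 0L)
})

test_that("simulate_edit rejects masks outside the editable set", {
  locus <- planted_locus("CAG")
  g <- suppressMessages(enumerate_guides(locus))
  expect_error(simulate_edit(locus, g[1, ], mask = c(-5L)), "not editable")
})

test_that("a minus-strand guide knocks out TGG via the opposite-strand CCA", {
  fx <- generate_locus(synthetic_locus_spec(80, list(c(40, "TGG")), seed = 11))
  res <- suppressMessages(filter_guides(fx$locus,
                                        enumerate_guides(fx$locus)))
  expect_true(all(res$nonsense_codon_number == 40L))
  minus <- res[res$strand == "-", ]
  expect_gt(nrow(minus), 0)
  expect_equal(unique(minus$ref_codon), "TGG")
  expect_true(all(minus$alt_codon %in% c("TGA", "TAG", "TAA")))
  expect_equal(unique(minus$protein_change), "W40*")
})

test_that("viability decisions match the exhaustive-mask oracle", {
  n_discrepant <- 0L
  for (seed in 1:30) {
    locus <- random_locus(sample(20:60, 1), seed = seed + 1000)
    g <- suppressMessages(enumerate_guides(locus))
    res <- filter_guides(locus, g)
    viable_keys <- paste(res$locus_start, res$strand)
    b <- sgstop:::cds_bounds(locus)
    for (i in seq_len(nrow(g))) {
      expected <- oracle_viable(locus_seq(locus), b[["start"]],
                                nchar(locus$cds), g$locus_start[i],
                                g$strand[i])
      got <- paste(g$locus_start[i], g$strand[i]) %in% viable_keys
      if (expected != got) n_discrepant <- n_discrepant + 1L
    }
  }
  expect_equal(n_discrepant, 0L)
})

test_that("every reported edit truncates strictly before the native stop", {
  for (seed in c(5, 23)) {
    locus <- random_locus(60, seed = seed)
    res <- suppressMessages(filter_guides(locus, enumerate_guides(locus)))
    if (!nrow(res)) next
    expect_true(all(res$nonsense_codon_number < n_codons(locus)))
    expect_true(all(res$truncation_fraction > 0 & res$truncation_fraction < 1))
    # re-simulate and confirm the premature stop
    for (i in seq_len(nrow(res))) {
      sim <- simulate_edit(locus, sgstop:::as_guide_row(res, i))
      prot <- sim$protein
      first_stop <- regexpr("\\*", prot)[1]
      expect_lt(first_stop, n_codons(locus))
    }
  }
})

test_that("widening the window never removes a viable guide", {
  narrow <- target_aid()
  wide <- editor_architecture(window_start = 1, window_end = 10)
  for (seed in c(2, 9, 31)) {
    locus <- random_locus(50, seed = seed)
    rn <- suppressMessages(filter_guides(locus,
                                         enumerate_guides(locus, narrow),
                                         narrow))
    rw <- suppressMessages(filter_guides(locus,
                                         enumerate_guides(locus, wide),
                                         wide))
    expect_true(all(paste(rn$locus_start, rn$strand) %in%
                      paste(rw$locus_start, rw$strand)))
  }
})

test_that("require_clean selects a subset without changing labels", {
  for (seed in c(4, 12)) {
    locus <- random_locus(60, seed = seed)
    g <- suppressMessages(enumerate_guides(locus))
    all_res <- filter_guides(locus, g)
    clean <- filter_guides(locus, g, require_clean = TRUE)
    expect_true(all(paste(clean$locus_start, clean$strand) %in%
                      paste(all_res$locus_start, all_res$strand)))
    if (nrow(clean)) {
      merged <- merge(clean, all_res,
                      by = c("locus_start", "strand"))
      expect_identical(merged$protein_change.x, merged$protein_change.y)
    }
  }
})

test_that("protein-change labels follow the <ref><number><alt> convention", {
  expect_equal(protein_change_label("CAG", 151, "TAG"), "Q151*")
  expect_equal(protein_change_label("CAA", 178, "TAA"), "Q178*")
  expect_equal(protein_change_label("GCT", 10, "GTT"), "A10V")
  expect_error(protein_change_label("CAX", 5, "TAA"), "invalid codon")
})

test_that("filtering a fixture recovers exactly the planted sites", {
  fx <- generate_locus(synthetic_locus_spec(
    150, list(c(30, "CAA"), c(77, "CGA"), c(120, "TGG")),
    decoys = 5, seed = 1))
  res <- suppressMessages(filter_guides(fx$locus,
                                        enumerate_guides(fx$locus)))
  expect_setequal(unique(res$nonsense_codon_number), c(30L, 77L, 120L))
})

test_that("a locus with no editable window cytosines yields no guides", {
  fx <- generate_locus(synthetic_locus_spec(60, decoys = 10, seed = 3))
  res <- suppressMessages(filter_guides(fx$locus,
                                        enumerate_guides(fx$locus)))
  expect_equal(nrow(res), 0L)
})
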