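# In-code fixtures: random loci (unconstrained codon usage, so amenable
# codons occur naturally) and small file fixtures written on the fly.

random_locus <- function(n_codons, flank = 30L, seed = 1L) {
  withr::with_seed(seed, {
    pool <- setdiff(sgstop:::all_codons(), c("TAA", "TAG", "TGA"))
    cds <- paste(c("ATG", sample(pool, n_codons - 2L, replace = TRUE), "TAA"),
                 collapse = "")
    up <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                collapse = "")
    down <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                  collapse = "")
    suppressWarnings(coding_sequence(cds, upstream = up, downstream = down,
                                     record_id = sprintf("rand%d", seed)))
  })
}

random_dna <- function(n, seed = 1L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# A thyA-like synthetic CDS: 264 codons with one CAG planted at codon 151
# and a supporting PAM, mirroring the Q151* knockout label.
thya_like_locus <- function(seed = 42L) {
  generate_locus(synthetic_locus_spec(264, list(c(151, "CAG")), decoys = 3,
                                      seed = seed))
}

# Minimal GenBank flat file around a given CDS (plus strand unless stated).
write_genbank_fixture <- function(path, full_seq, s, e, strand = "+",
                                  locus_tag = "TESTGENE_0001",
                                  extra_cds = NULL) {
  loc <- if (strand == "+") sprintf("%d..%d", s, e) else
    sprintf("complement(%d..%d)", s, e)
  lines <- c(
    sprintf("LOCUS       TESTREC %d bp    DNA     linear   BCT 01-JAN-2024",
            nchar(full_seq)),
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(full_seq)),
    "                     /organism=\"synthetic construct\"",
    sprintf("     CDS             %s", loc),
    sprintf("                     /locus_tag=\"%s\"", locus_tag),
    "                     /product=\"test protein\""
  )
  if (!is.null(extra_cds)) lines <- c(lines, extra_cds)
  seq_lines <- character()
  chars <- tolower(full_seq)
  for (i in seq(1, nchar(chars), 60)) {
    chunk <- substr(chars, i, min(nchar(chars), i + 59))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    seq_lines <- c(seq_lines, sprintf("%9d %s", i, paste(blocks, collapse = " ")))
  }
  writeLines(c(lines, "ORIGIN", seq_lines, "//"), path)
  path
}

write_fasta_gff_fixture <- function(fa_path, gff_path, full_seq, s, e,
                                    strand = "+", seqid = "TESTREC",
                                    id = "cds1") {
  writeLines(c(paste0(">", seqid), full_seq), fa_path)
  writeLines(c(
    "##gff-version 3",
    paste(seqid, "test", "CDS", s, e, ".", strand, "0",
          paste0("ID=", id, ";locus_tag=", id), sep = "\t")
  ), gff_path)
  invisible(NULL)
}
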