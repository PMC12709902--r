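#' Construct an annotated coding sequence
#'
#' The central container everything else maps into: the in-frame CDS plus
#' optional genomic flanks, held in CDS sense orientation. The concatenated
#' locus (`upstream + cds + downstream`) is the search space for guide
#' enumeration; codon numbering is 1-based from the annotated start codon.
#'
#' Annotation sanity problems (non-standard start codon, internal stop,
#' missing terminal stop) are reported as warnings so that bacterial GTG/TTG
#' starts and partial annotations still load; `strict = TRUE` upgrades them
#' to errors.
#'
#' @param cds In-frame coding sequence (A/C/G/T; length a multiple of 3,
#'   at least 6 nt).
#' @param upstream,downstream Flanking context 5' and 3' of the CDS in sense
#'   orientation (may be empty).
#' @param record_id Identifier of the source record.
#' @param source_offset 0-based start of the CDS within the source record.
#' @param source_strand Orientation of the CDS in the source record
#'   (`"+"` or `"-"`).
#' @param genetic_code_table NCBI translation-table id (default `"11"`,
#'   bacterial).
#' @param strict Upgrade annotation warnings to errors.
#' @return An object of class `coding_sequence`.
#' @export
#' @examples
#' coding_sequence("ATGCAGTAA")
coding_sequence <- function(cds, upstream = "", downstream = "",
                            record_id = "locus", source_offset = 0L,
                            source_strand = "+",
                            genetic_code_table = "11", strict = FALSE) {
  cds <- toupper(cds)
  upstream <- toupper(upstream)
  downstream <- toupper(downstream)
  check_dna(cds, "cds")
  if (nchar(upstream)) check_dna(upstream, "upstream flank")
  if (nchar(downstream)) check_dna(downstream, "downstream flank")
  if (nchar(cds) < 6L || nchar(cds) %% 3L != 0L) {
    stop("cds length must be a multiple of 3 and at least 6 nt (got ",
         nchar(cds), ")", call. = FALSE)
  }
  if (!source_strand %in% c("+", "-")) {
    stop("source_strand must be '+' or '-'", call. = FALSE)
  }
  source_offset <- as.integer(source_offset)
  if (is.na(source_offset) || source_offset < 0L) {
    stop("source_offset must be a non-negative integer", call. = FALSE)
  }

  code <- genetic_code(genetic_code_table)
  codons <- codon_split(cds)
  aa <- codon_aa(codons, code)
  nc <- length(codons)
  complain <- function(msg) {
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (!codons[1] %in% c("ATG", "GTG", "TTG")) {
    complain(sprintf("first codon %s is not a standard bacterial start codon",
                     codons[1]))
  }
  internal <- which(aa[-nc] == "*")
  if (length(internal)) {
    complain(sprintf("internal stop codon(s) at codon %s",
                     paste(internal, collapse = ", ")))
  }
  if (aa[nc] != "*") {
    complain(sprintf("final codon %s is not a stop codon", codons[nc]))
  }

  structure(
    list(record_id = record_id, cds = cds, upstream = upstream,
         downstream = downstream, source_offset = source_offset,
         source_strand = source_strand,
         genetic_code_table = if (is.character(genetic_code_table) ||
                                  is.numeric(genetic_code_table))
           as.character(genetic_code_table) else "custom",
         genetic_code = code),
    class = "coding_sequence"
  )
}

codon_split <- function(cds) {
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

#' Concatenated locus sequence of a coding_sequence
#'
#' @param x A `coding_sequence`.
#' @return `upstream + cds + downstream` as one string.
#' @export
locus_seq <- function(x) paste0(x$upstream, x$cds, x$downstream)

# 0-based half-open CDS bounds within the locus.
cds_bounds <- function(x) {
  s <- nchar(x$upstream)
  c(start = s, end = s + nchar(x$cds))
}

#' Number of codons in the CDS (including the native stop)
#'
#' @param x A `coding_sequence`.
#' @return Integer codon count.
#' @export
n_codons <- function(x) nchar(x$cds) %/% 3L

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt CDS (%d codons), flanks %d/%d nt\n",
              x$record_id, nchar(x$cds), n_codons(x),
              nchar(x$upstream), nchar(x$downstream)))
  cat(sprintf("  source offset %d (%s strand), genetic code table %s\n",
              x$source_offset, x$source_strand, x$genetic_code_table))
  invisible(x)
}

#' Map a CDS position to its codon
#'
#' Converts a 0-based position within the CDS to 1-based codon number and
#' within-codon offset; `codon_position()` is the inverse.
#'
#' @param position 0-based position(s) within the CDS.
#' @param cds_length CDS length in nt, or a `coding_sequence`.
#' @return A data.frame with columns `codon_number` (1-based) and `offset`
#'   (0, 1, or 2), one row per input position.
#' @export
#' @examples
#' codon_of(450, 900)   # codon 151, offset 0
codon_of <- function(position, cds_length) {
  if (inherits(cds_length, "coding_sequence")) {
    cds_length <- nchar(cds_length$cds)
  }
  position <- as.integer(position)
  bad <- position < 0L | position >= cds_length
  if (any(bad)) {
    stop(sprintf("position %s out of range for a CDS of length %d",
                 paste(position[bad], collapse = ", "), cds_length),
         call. = FALSE)
  }
  data.frame(codon_number = position %/% 3L + 1L, offset = position %% 3L)
}

#' @rdname codon_of
#' @param codon_number 1-based codon number.
#' @param offset Within-codon offset (0, 1, or 2).
#' @export
codon_position <- function(codon_number, offset = 0L) {
  (as.integer(codon_number) - 1L) * 3L + as.integer(offset)
}

#' Translate an in-frame nucleotide sequence
#'
#' Standard-code translation through [Biostrings::translate()], with stops
#' rendered as `"*"`. Every codon (including the first) is translated from
#' the plain codon table, so alternative initiators report their bare amino
#' acid.
#'
#' @param seq In-frame A/C/G/T string.
#' @param genetic_code_table NCBI translation-table id or a 64-entry codon
#'   map.
#' @return Amino-acid string of length `nchar(seq)/3`.
#' @export
#' @examples
#' translate_cds("ATGTAA")        # "M*"
#' translate_cds("CAACAGCGATGG")  # "QQRW"
translate_cds <- function(seq, genetic_code_table = "11") {
  seq <- toupper(seq)
  check_dna(seq, "sequence")
  if (nchar(seq) %% 3L != 0L) {
    stop("sequence length ", nchar(seq), " is not a multiple of 3",
         call. = FALSE)
  }
  if (!nchar(seq)) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(seq),
    genetic.code = genetic_code(genetic_code_table),
    no.init.codon = TRUE
  ))
}
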