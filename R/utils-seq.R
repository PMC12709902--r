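## Small sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x A single DNA string (A/C/G/T/IUPAC).
#' @return The reverse complement as a character scalar.
#' @export
#' @examples
#' revcomp("CCAAGG")
revcomp <- function(x) {
  if (!nchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna <- function(x, what = "sequence") {
  if (grepl("[^ACGT]", x)) {
    stop(what, " contains characters other than A/C/G/T", call. = FALSE)
  }
  invisible(x)
}

#' Genetic code lookup
#'
#' Fetches an NCBI translation table as a named codon -> amino-acid vector.
#' Table "11" (bacterial/archaeal/plant plastid) is the package default; its
#' codon assignments match the standard code, differing only in permitted
#' initiators.
#'
#' @param table NCBI translation-table identifier (integer or string).
#' @return Named character vector of length 64 (names are codons, values
#'   one-letter amino acids, `"*"` for stop).
#' @export
genetic_code <- function(table = "11") {
  if (is.numeric(table) && length(table) == 1L) {
    table <- as.character(as.integer(table))
  }
  if (is.character(table) && length(table) == 1L && is.null(names(table))) {
    return(Biostrings::getGeneticCode(table))
  }
  code <- table
  if (!is.character(code) || length(code) != 64L || is.null(names(code)) ||
      !setequal(names(code), all_codons())) {
    stop("genetic code must cover all 64 codons", call. = FALSE)
  }
  code
}

all_codons <- function() {
  as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
}

stop_codons <- function(code) names(code)[code == "*"]

codon_aa <- function(codons, code) unname(code[codons])

# Expand an IUPAC pattern into a literal character-class regex.  N becomes
# [ACGT] (not "."), so ambiguity letters in the *subject* never satisfy a
# PAM letter.
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(chars, names(map))
  if (length(bad)) {
    stop("pattern contains non-IUPAC characters: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  paste0(vapply(chars, function(ch) {
    ex <- map[[ch]]
    if (nchar(ex) == 1L) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

# 1-based start positions where `pattern` (IUPAC) matches `subject_string`
# literally over A/C/G/T.  Overlapping matches are all returned.
pam_match_starts <- function(subject_string, pattern) {
  n <- nchar(subject_string)
  pl <- nchar(pattern)
  if (n < pl) return(integer(0))
  hits <- Biostrings::matchPattern(pattern,
                                   Biostrings::DNAString(subject_string),
                                   fixed = FALSE)
  starts <- BiocGenerics::start(hits)
  if (!length(starts)) return(integer(0))
  obs <- substring(subject_string, starts, starts + pl - 1L)
  rx <- paste0("^", iupac_regex(pattern), "$")
  starts[grepl(rx, obs)]
}
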