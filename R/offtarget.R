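#' Scan a genome for off-target protospacer matches
#'
#' Reports every PAM-adjacent site, on either strand of any contig, whose
#' protospacer lies within a Hamming-distance bound of the query spacer.
#' The PAM must match the architecture pattern exactly (IUPAC-expanded);
#' ambiguity letters (N) in the genome never satisfy a PAM letter and count
#' as mismatches within the protospacer. With `include_nag = TRUE`, sites
#' carrying the weaker NAG PAM are additionally reported and tagged
#' separately in `pam_class`. Scanning the guide's own source sequence
#' always yields its site as a 0-mismatch hit.
#'
#' @param spacer Query spacer (protospacer-strand sequence, 5'->3'), length
#'   `arch$spacer_length`.
#' @param genome A [Biostrings::DNAStringSet], a named character vector of
#'   contigs, or the path to a (optionally gzipped) FASTA file.
#' @param arch An [editor_architecture()].
#' @param max_mismatch Maximum Hamming distance over the spacer
#'   (default 3).
#' @param include_nag Also report NAG-PAM sites (only meaningful for the
#'   NGG architecture).
#' @return Data.frame of hits: `contig`, `position` (0-based half-open
#'   start of the protospacer on the contig's plus strand), `strand`,
#'   `mismatches`, `pam_observed`, `pam_class`; ordered by contig, position,
#'   strand.
#' @export
#' @examples
#' scan_offtargets(strrep("ACGT", 5), c(chr = paste0(strrep("ACGT", 5), "AGG")))
scan_offtargets <- function(spacer, genome, arch = target_aid(),
                            max_mismatch = 3L, include_nag = FALSE) {
  spacer <- toupper(spacer)
  check_dna(spacer, "spacer")
  L <- arch$spacer_length
  if (nchar(spacer) != L) {
    stop("spacer length ", nchar(spacer),
         " does not match the architecture spacer_length ", L, call. = FALSE)
  }
  max_mismatch <- as.integer(max_mismatch)
  if (max_mismatch < 0L || max_mismatch > L) {
    stop("max_mismatch must lie in [0, spacer_length]", call. = FALSE)
  }
  genome <- as_genome(genome)
  if (!length(genome)) stop("genome is empty", call. = FALSE)

  pams <- list(list(pattern = arch$pam, class = arch$pam))
  if (include_nag && identical(arch$pam, "NGG")) {
    pams <- c(pams, list(list(pattern = "NAG", class = "NAG")))
  }

  pat <- Biostrings::DNAString(spacer)
  rows <- list()
  for (ci in seq_along(genome)) {
    contig_name <- names(genome)[ci]
    contig <- genome[[ci]]
    n <- length(contig)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") contig else
        Biostrings::reverseComplement(contig)
      s_chr <- as.character(subj)
      for (pp in pams) {
        pl <- nchar(pp$pattern)
        pam_starts <- pam_match_starts(s_chr, pp$pattern)
        starts <- pam_starts - L
        keep <- starts >= 1L
        starts <- starts[keep]
        pam_starts <- pam_starts[keep]
        if (!length(starts)) next
        mm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                          with.indels = FALSE, fixed = TRUE)
        ok <- mm <= max_mismatch
        if (!any(ok)) next
        starts <- starts[ok]
        position <- if (strand == "+") starts - 1L else n - (starts - 1L) - L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig_name,
          position = as.integer(position),
          strand = strand,
          mismatches = as.integer(mm[ok]),
          pam_observed = substring(s_chr, pam_starts[ok],
                                   pam_starts[ok] + pl - 1L),
          pam_class = pp$class,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(empty_hit_frame())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$contig, hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hit_frame <- function() {
  data.frame(contig = character(), position = integer(), strand = character(),
             mismatches = integer(), pam_observed = character(),
             pam_class = character(), stringsAsFactors = FALSE)
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    gs <- tryCatch(Biostrings::readDNAStringSet(genome),
                   error = function(e) stop("failed to read genome FASTA '",
                                            genome, "': ", conditionMessage(e),
                                            call. = FALSE))
  } else if (is.character(genome)) {
    gs <- Biostrings::DNAStringSet(toupper(genome))
  } else {
    stop("genome must be a DNAStringSet, a character vector, or a FASTA path",
         call. = FALSE)
  }
  if (!length(gs)) stop("genome is empty", call. = FALSE)
  if (is.null(names(gs))) names(gs) <- paste0("contig", seq_along(gs))
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

#' Tally off-target hits by mismatch level
#'
#' @param hits Data.frame from [scan_offtargets()] for one guide.
#' @param max_mismatch Highest mismatch level to tabulate (default 3).
#' @return Named integer vector `m0..m<max_mismatch>`.
#' @export
summarize_offtargets <- function(hits, max_mismatch = 3L) {
  levels <- 0:max_mismatch
  counts <- vapply(levels, function(k) sum(hits$mismatches == k), integer(1))
  stats::setNames(counts, paste0("m", levels))
}

#' Export off-target hits as BED
#'
#' Writes hits in BED6 (0-based half-open) with the mismatch count in the
#' score column.
#'
#' @param hits Data.frame from [scan_offtargets()].
#' @param path Output file.
#' @param spacer_length Protospacer length used for the interval end.
#' @return Invisibly, the path.
#' @export
export_offtargets_bed <- function(hits, path, spacer_length = 20L) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(hits)) hits$contig else character(),
    ranges = IRanges::IRanges(start = hits$position + 1L,
                              width = spacer_length),
    strand = if (nrow(hits)) hits$strand else character()
  )
  gr$name <- if (nrow(hits)) paste0(hits$pam_class, "_mm", hits$mismatches)
             else character()
  gr$score <- hits$mismatches
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
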