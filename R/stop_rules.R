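#' Enumerate codons knockable by C->T editing
#'
#' Exhaustively tests, for every codon of a genetic code, every nonempty
#' subset of its cytosine positions converted to thymine. A codon is
#' *sense-editable* when some subset turns it into a stop codon; it is
#' *antisense-editable* when its reverse complement (the opposite-strand
#' triplet read 5'->3') has a cytosine subset whose conversion makes the
#' sense triplet a stop. Under the bacterial/standard code this recovers the
#' classic knockout set: CAA->TAA, CAG->TAG, CGA->TGA on the sense strand,
#' and TGG (via the opposite-strand CCA) on the antisense strand.
#'
#' Only minimal subsets are reported: a subset is dropped when one of its
#' proper subsets already yields a stop.
#'
#' @param code A 64-entry codon -> amino-acid map, as returned by
#'   [genetic_code()], or an NCBI table id.
#' @param conversion_from,conversion_to The edited base and its product
#'   (default C and T).
#' @return An object of class `stop_rule_table`: a list with data.frames
#'   `sense` (columns `codon`, `edit_offsets`, `resulting_stop`) and
#'   `antisense` (columns `sense_codon`, `opposite_strand_triplet`,
#'   `edit_offsets`, `resulting_stop`). `edit_offsets` are 0-based positions
#'   within the edited triplet, comma-joined for multi-base subsets.
#' @export
#' @examples
#' tbl <- build_stop_rule_table()
#' unique(tbl$sense$codon)            # CAA, CAG, CGA
#' unique(tbl$antisense$sense_codon)  # TGG
build_stop_rule_table <- function(code = genetic_code("11"),
                                  conversion_from = "C",
                                  conversion_to = "T") {
  code <- genetic_code(code)
  stops <- stop_codons(code)
  codons <- all_codons()

  # Every nonempty subset of `conversion_from` positions in `triplet`,
  # with the edited product; subsets ordered by size then position.
  edit_subsets <- function(triplet) {
    chars <- strsplit(triplet, "")[[1]]
    cpos <- which(chars == conversion_from)  # 1-based
    if (!length(cpos)) return(list())
    out <- list()
    for (bits in seq_len(2L^length(cpos) - 1L)) {
      sel <- cpos[bitwAnd(bits, 2L^(seq_along(cpos) - 1L)) > 0L]
      edited <- chars
      edited[sel] <- conversion_to
      out[[length(out) + 1L]] <- list(sel = sel,
                                      alt = paste(edited, collapse = ""))
    }
    out[order(vapply(out, function(h) length(h$sel), integer(1)))]
  }

  # Keep only subsets not containing a smaller qualifying subset.
  minimal_only <- function(hits) {
    if (length(hits) < 2L) return(hits)
    keep <- vapply(hits, function(h) {
      !any(vapply(hits, function(o) {
        length(o$sel) < length(h$sel) && all(o$sel %in% h$sel)
      }, logical(1)))
    }, logical(1))
    hits[keep]
  }

  sense <- list()
  antisense <- list()
  for (codon in codons) {
    if (codon %in% stops) next

    hits <- Filter(function(h) h$alt %in% stops, edit_subsets(codon))
    for (h in minimal_only(hits)) {
      sense[[length(sense) + 1L]] <- data.frame(
        codon = codon,
        edit_offsets = paste(h$sel - 1L, collapse = ","),
        resulting_stop = h$alt
      )
    }

    opp <- revcomp(codon)
    hits <- Filter(function(h) revcomp(h$alt) %in% stops, edit_subsets(opp))
    for (h in minimal_only(hits)) {
      antisense[[length(antisense) + 1L]] <- data.frame(
        sense_codon = codon,
        opposite_strand_triplet = opp,
        edit_offsets = paste(h$sel - 1L, collapse = ","),
        resulting_stop = revcomp(h$alt)
      )
    }
  }
  empty_sense <- data.frame(codon = character(), edit_offsets = character(),
                            resulting_stop = character())
  empty_anti <- data.frame(sense_codon = character(),
                           opposite_strand_triplet = character(),
                           edit_offsets = character(),
                           resulting_stop = character())
  structure(
    list(sense = if (length(sense)) do.call(rbind, sense) else empty_sense,
         antisense = if (length(antisense)) do.call(rbind, antisense)
                     else empty_anti),
    class = "stop_rule_table"
  )
}

#' Codons amenable to stop-codon conversion
#'
#' Convenience accessor over [build_stop_rule_table()]: the set of sense
#' codons knockable from either strand.
#'
#' @inheritParams build_stop_rule_table
#' @return Character vector of sense codons (e.g. CAA, CAG, CGA, TGG for the
#'   standard code).
#' @export
amenable_codons <- function(code = genetic_code("11")) {
  tbl <- build_stop_rule_table(code)
  sort(unique(c(tbl$sense$codon, tbl$antisense$sense_codon)))
}

#' @export
print.stop_rule_table <- function(x, ...) {
  cat("<stop_rule_table>\n  sense-editable codons: ",
      paste(unique(x$sense$codon), collapse = ", "),
      "\n  antisense-editable codons: ",
      paste(unique(x$antisense$sense_codon), collapse = ", "), "\n", sep = "")
  invisible(x)
}
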