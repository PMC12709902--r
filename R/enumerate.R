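#' Enumerate PAM-adjacent guide candidates over a locus
#'
#' Scans both strands of the concatenated locus (upstream flank + CDS +
#' downstream flank) for every position where the architecture's PAM matches
#' immediately 3' of a full-length protospacer. No filtering is applied at
#' this stage: every candidate is returned, including overlapping guides,
#' duplicate spacer sequences at different positions, and guides lying
#' partly or wholly in the flanks.
#'
#' Coordinates are 0-based half-open on the locus, in CDS sense orientation;
#' minus-strand guides report the leftmost sense-strand position of the
#' protospacer. Editing-window positions are mapped onto the locus for each
#' guide, and the subset of window positions carrying the convertible base
#' on the protospacer strand is recorded as `editable_positions`.
#'
#' @param locus A [coding_sequence()].
#' @param arch An [editor_architecture()] (default [target_aid()]).
#' @return A data.frame with one row per candidate: `spacer` (protospacer
#'   strand, 5'->3'), `pam_observed`, `strand`, `locus_start`, and list
#'   columns `window_locus` and `editable_positions` (0-based locus
#'   positions). Sorted by `locus_start` then strand; empty (zero-row) when
#'   no PAM matches.
#' @export
#' @examples
#' locus <- coding_sequence("ATGCAGAAATTTGGATCCAAGCTTGGGTAA")
#' enumerate_guides(locus, target_aid())
enumerate_guides <- function(locus, arch = target_aid()) {
  stopifnot(inherits(locus, "coding_sequence"),
            inherits(arch, "editor_architecture"))
  seq <- locus_seq(locus)
  n <- nchar(seq)
  L <- arch$spacer_length
  pl <- nchar(arch$pam)
  if (nchar(locus$upstream) < L + pl - 1L ||
      nchar(locus$downstream) < L + pl - 1L) {
    message("flanking context is shorter than spacer_length + PAM length - 1 (",
            L + pl - 1L, " nt); guides whose PAM lies outside the available ",
            "sequence will not be seen")
  }

  scan_strand <- function(s, strand) {
    pam_starts <- pam_match_starts(s, arch$pam)       # 1-based
    starts <- pam_starts - L
    keep <- starts >= 1L
    starts <- starts[keep]
    pam_starts <- pam_starts[keep]
    if (!length(starts)) return(NULL)
    data.frame(
      spacer = substring(s, starts, starts + L - 1L),
      pam_observed = substring(s, pam_starts, pam_starts + pl - 1L),
      strand = strand,
      scan_start0 = starts - 1L,
      stringsAsFactors = FALSE
    )
  }

  plus <- scan_strand(seq, "+")
  minus <- scan_strand(revcomp(seq), "-")
  if (!is.null(plus)) plus$locus_start <- plus$scan_start0
  if (!is.null(minus)) minus$locus_start <- n - minus$scan_start0 - L
  g <- rbind(plus, minus)
  if (is.null(g)) {
    message("no guide candidates found")
    return(empty_guide_frame())
  }
  g$scan_start0 <- NULL
  g <- g[order(g$locus_start, g$strand), , drop = FALSE]
  rownames(g) <- NULL

  wpos <- arch$window_start:arch$window_end
  g$window_locus <- lapply(seq_len(nrow(g)), function(i) {
    if (g$strand[i] == "+") {
      g$locus_start[i] + (wpos - 1L)
    } else {
      (g$locus_start[i] + L - 1L) - (wpos - 1L)
    }
  })
  g$editable_positions <- lapply(seq_len(nrow(g)), function(i) {
    proto_base <- substring(g$spacer[i], wpos, wpos)
    g$window_locus[[i]][proto_base == arch$conversion_from]
  })
  g
}

empty_guide_frame <- function() {
  data.frame(spacer = character(), pam_observed = character(),
             strand = character(), locus_start = integer(),
             window_locus = I(list()), editable_positions = I(list()),
             stringsAsFactors = FALSE)
}

# Rebuild the protospacer from the locus and fail loudly on mismatch:
# guards against guides paired with the wrong locus.
check_guide_matches_locus <- function(guide, locus) {
  seq <- locus_seq(locus)
  L <- nchar(guide$spacer)
  sub <- substring(seq, guide$locus_start + 1L, guide$locus_start + L)
  expected <- if (guide$strand == "+") sub else revcomp(sub)
  if (!identical(expected, guide$spacer)) {
    stop("guide/locus integrity error: spacer does not match the locus at ",
         "position ", guide$locus_start, call. = FALSE)
  }
  invisible(TRUE)
}

as_guide_row <- function(guide, i = 1L) {
  if (is.data.frame(guide)) {
    stopifnot(nrow(guide) >= i)
    list(spacer = guide$spacer[i], pam_observed = guide$pam_observed[i],
         strand = guide$strand[i], locus_start = guide$locus_start[i],
         window_locus = guide$window_locus[[i]],
         editable_positions = guide$editable_positions[[i]])
  } else {
    guide
  }
}

#' Codons reachable by a guide's editable window positions
#'
#' Maps each editable position of a guide that falls inside the CDS to its
#' 1-based codon number and within-codon offset. Positions in the flanks are
#' excluded; an empty data.frame means no editable position overlaps the
#' CDS.
#'
#' @param guide One row of the data.frame returned by [enumerate_guides()]
#'   (or an equivalent list).
#' @param locus The [coding_sequence()] the guide was enumerated from.
#' @return Data.frame with columns `codon_number` and `offset`.
#' @export
window_codons <- function(guide, locus) {
  guide <- as_guide_row(guide)
  check_guide_matches_locus(guide, locus)
  b <- cds_bounds(locus)
  ed <- guide$editable_positions
  inside <- ed[ed >= b[["start"]] & ed < b[["end"]]]
  if (!length(inside)) {
    return(data.frame(codon_number = integer(), offset = integer()))
  }
  codon_of(inside - b[["start"]], nchar(locus$cds))
}
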