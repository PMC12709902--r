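#' Simulate the base edit a guide would install
#'
#' Applies the conversion chemistry at a chosen subset of a guide's editable
#' window positions and reports the edited CDS with per-codon consequences.
#' The substitution model is a pure base change (no double-strand break):
#' C->T on the protospacer strand, which reads as G->A on the CDS sense
#' strand for minus-strand guides. Edits landing in the flanks are applied
#' to the locus but have no coding consequence. Inputs are not mutated.
#'
#' @param locus A [coding_sequence()].
#' @param guide One row of [enumerate_guides()] output.
#' @param mask Subset of `guide$editable_positions` (0-based locus
#'   positions) to convert; defaults to all of them (the maximal edit).
#' @param arch The [editor_architecture()] the guide was enumerated under.
#' @return A list: `cds` (edited CDS string), `protein` (its translation),
#'   and `consequences`, a data.frame with one row per affected CDS codon
#'   (`codon_number`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `consequence` in `nonsense`/`missense`/`silent`/`stop_loss`).
#' @export
simulate_edit <- function(locus, guide, mask = NULL, arch = target_aid()) {
  guide <- as_guide_row(guide)
  check_guide_matches_locus(guide, locus)
  ed <- guide$editable_positions
  if (is.null(mask)) mask <- ed
  mask <- as.integer(mask)
  if (length(setdiff(mask, ed))) {
    stop("mask contains positions that are not editable for this guide: ",
         paste(setdiff(mask, ed), collapse = ", "), call. = FALSE)
  }

  chars <- strsplit(locus_seq(locus), "")[[1]]
  from <- arch$conversion_from
  to <- arch$conversion_to
  if (guide$strand == "-") {
    from <- COMPLEMENT[[from]]
    to <- COMPLEMENT[[to]]
  }
  # editable positions were defined on the protospacer strand; on the sense
  # strand they must all carry the complement-adjusted source base
  stopifnot(all(chars[mask + 1L] == from))
  chars[mask + 1L] <- to

  b <- cds_bounds(locus)
  edited_cds <- paste(chars[(b[["start"]] + 1L):b[["end"]]], collapse = "")
  code <- locus$genetic_code

  inside <- mask[mask >= b[["start"]] & mask < b[["end"]]]
  affected <- sort(unique((inside - b[["start"]]) %/% 3L + 1L))
  ref_codons <- codon_split(locus$cds)[affected]
  alt_codons <- codon_split(edited_cds)[affected]
  ref_aa <- codon_aa(ref_codons, code)
  alt_aa <- codon_aa(alt_codons, code)
  consequence <- ifelse(
    ref_aa == alt_aa, "silent",
    ifelse(alt_aa == "*", "nonsense",
           ifelse(ref_aa == "*", "stop_loss", "missense"))
  )
  cons <- data.frame(codon_number = affected,
                     ref_codon = ref_codons, alt_codon = alt_codons,
                     ref_aa = ref_aa, alt_aa = alt_aa,
                     consequence = consequence,
                     stringsAsFactors = FALSE)
  if (!length(affected)) {
    cons <- data.frame(codon_number = integer(), ref_codon = character(),
                       alt_codon = character(), ref_aa = character(),
                       alt_aa = character(), consequence = character(),
                       stringsAsFactors = FALSE)
  }
  list(cds = edited_cds,
       protein = translate_cds(edited_cds, code),
       consequences = cons)
}

#' Decide whether a guide can install a premature stop codon
#'
#' The core filter: a guide is *viable* when some nonempty subset of its
#' editable window positions, converted, turns an in-frame CDS codon into a
#' stop codon strictly before the native stop. The decision is
#' simulation-driven (every subset is tried), so it holds for any genetic
#' code, with the rule table of [build_stop_rule_table()] available as an
#' independent cross-check.
#'
#' The reported representative edit follows the maximal-mask policy:
#' deaminases edit promiscuously within the window, so all editable window
#' positions are converted, except that within the stop-gaining codon the
#' largest stop-yielding subset is used. Consequences at other codons are
#' reported as bystanders, not used to disqualify — unless
#' `require_clean = TRUE`, which additionally demands that the fully maximal
#' edit still yields a stop with no missense bystander.
#'
#' When several codons can be made a stop, the earliest (lowest codon
#' number) is reported, truncating the most protein.
#'
#' @inheritParams simulate_edit
#' @param require_clean Restrict to guides whose maximal edit yields a stop
#'   with no missense bystanders.
#' @return `NULL` when the guide cannot create a premature stop; otherwise a
#'   one-row data.frame with `nonsense_codon_number`, `ref_codon`,
#'   `alt_codon`, `protein_change`, `truncation_fraction`, `n_bystanders`,
#'   `maximal_edit_class`, and list column `bystanders` (the consequence
#'   rows at non-target codons).
#' @export
is_viable <- function(locus, guide, arch = target_aid(),
                      require_clean = FALSE) {
  guide <- as_guide_row(guide)
  check_guide_matches_locus(guide, locus)
  b <- cds_bounds(locus)
  nc <- n_codons(locus)
  code <- locus$genetic_code
  stops <- stop_codons(code)

  ed <- guide$editable_positions
  inside <- ed[ed >= b[["start"]] & ed < b[["end"]]]
  if (!length(inside)) return(NULL)
  cdspos <- inside - b[["start"]]
  cn <- cdspos %/% 3L + 1L

  sense_from <- if (guide$strand == "+") arch$conversion_from else
    COMPLEMENT[[arch$conversion_from]]
  sense_to <- if (guide$strand == "+") arch$conversion_to else
    COMPLEMENT[[arch$conversion_to]]

  ref_codons <- codon_split(locus$cds)

  # Per reachable codon, the subsets of its editable positions that yield a
  # stop; cross-codon edits are independent, so per-codon search is
  # equivalent to searching all masks.
  best_subset <- list()
  for (codon_number in unique(cn)) {
    if (codon_number >= nc) next  # native stop position: never premature
    ref <- ref_codons[codon_number]
    if (ref %in% stops) next
    pos <- cdspos[cn == codon_number]
    chars <- strsplit(ref, "")[[1]]
    off <- pos %% 3L + 1L
    winners <- list()
    for (bits in seq_len(2L^length(pos) - 1L)) {
      sel <- bitwAnd(bits, 2L^(seq_along(pos) - 1L)) > 0L
      edited <- chars
      edited[off[sel]] <- sense_to
      if (paste(edited, collapse = "") %in% stops) {
        winners[[length(winners) + 1L]] <- pos[sel]
      }
    }
    if (length(winners)) {
      sizes <- vapply(winners, length, integer(1))
      ord <- order(-sizes, vapply(winners, function(p)
        paste(sort(p), collapse = ","), character(1)))
      best_subset[[as.character(codon_number)]] <- winners[[ord[1]]]
    }
  }
  if (!length(best_subset)) return(NULL)

  target <- min(as.integer(names(best_subset)))
  target_positions <- cdspos[cn == target] + b[["start"]]
  mask <- sort(c(setdiff(ed, target_positions),
                 best_subset[[as.character(target)]] + b[["start"]]))
  sim <- simulate_edit(locus, guide, mask, arch)
  cons <- sim$consequences
  tgt <- cons[cons$codon_number == target, , drop = FALSE]
  bystanders <- cons[cons$codon_number != target, , drop = FALSE]

  if (require_clean) {
    simmax <- simulate_edit(locus, guide, ed, arch)
    cmax <- simmax$consequences
    if (!any(cmax$consequence == "nonsense") ||
        any(cmax$consequence == "missense")) {
      return(NULL)
    }
  }

  out <- data.frame(
    nonsense_codon_number = target,
    ref_codon = tgt$ref_codon,
    alt_codon = tgt$alt_codon,
    protein_change = protein_change_label(tgt$ref_codon, target,
                                          tgt$alt_codon, code),
    truncation_fraction = (target - 1) / (nc - 1),
    n_bystanders = nrow(bystanders),
    maximal_edit_class = if (nrow(bystanders)) "nonsense_plus_bystanders"
                         else "nonsense",
    stringsAsFactors = FALSE
  )
  out$bystanders <- list(bystanders)
  out
}

#' Filter guide candidates down to stop-installing guides
#'
#' Order-preserving subset of the candidate list: each guide is kept exactly
#' when [is_viable()] finds a premature-stop edit, and its guide fields are
#' joined with the simulated consequence.
#'
#' @param locus A [coding_sequence()].
#' @param guides Data.frame from [enumerate_guides()]; enumerated from
#'   `locus` by default.
#' @inheritParams is_viable
#' @return Data.frame with the guide columns plus the [is_viable()] result
#'   columns; zero rows when no guide is viable.
#' @export
#' @examples
#' locus <- coding_sequence(paste0("ATG", strrep("GCT", 20), "CAG",
#'                                 strrep("GCT", 10), "TAA"))
#' guides <- enumerate_guides(locus)
#' filter_guides(locus, guides)
filter_guides <- function(locus, guides = enumerate_guides(locus, arch),
                          arch = target_aid(), require_clean = FALSE) {
  rows <- lapply(seq_len(nrow(guides)), function(i) {
    res <- is_viable(locus, as_guide_row(guides, i), arch, require_clean)
    if (is.null(res)) return(NULL)
    cbind(guides[i, , drop = FALSE], res)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    g <- empty_guide_frame()
    res <- data.frame(nonsense_codon_number = integer(),
                      ref_codon = character(), alt_codon = character(),
                      protein_change = character(),
                      truncation_fraction = numeric(),
                      n_bystanders = integer(),
                      maximal_edit_class = character(),
                      bystanders = I(list()),
                      stringsAsFactors = FALSE)
    return(cbind(g, res))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Protein-change label in standard short form
#'
#' Formats an edit as `<ref-aa><codon-number><alt-aa>` with stop codons
#' rendered as `*`, the nomenclature used for knockout genotypes such as
#' `Q151*`.
#'
#' @param ref_codon,alt_codon Reference and edited codons (A/C/G/T
#'   triplets).
#' @param codon_number 1-based codon number from the annotated start.
#' @param code A genetic code map or NCBI table id.
#' @return Character label, e.g. `"Q151*"`.
#' @export
#' @examples
#' protein_change_label("CAG", 151, "TAG")  # "Q151*"
protein_change_label <- function(ref_codon, codon_number, alt_codon,
                                 code = genetic_code("11")) {
  code <- genetic_code(code)
  for (x in c(ref_codon, alt_codon)) {
    if (!grepl("^[ACGT]{3}$", x)) {
      stop("invalid codon '", x, "': expected an A/C/G/T triplet",
           call. = FALSE)
    }
  }
  paste0(codon_aa(ref_codon, code), as.integer(codon_number),
         codon_aa(alt_codon, code))
}
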