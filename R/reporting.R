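## Report columns are fixed: every TSV row carries all of them, with empty
## strings for absent optional values, never dropped columns.
REPORT_COLUMNS <- c("rank", "spacer", "pam_observed", "strand",
                    "locus_start", "locus_end", "nonsense_codon_number",
                    "ref_codon", "alt_codon", "protein_change",
                    "truncation_fraction", "n_bystanders",
                    "bystander_changes", "maximal_edit_class",
                    "m0", "m1", "m2", "m3", "external_score")

#' Rank viable guides into a report table
#'
#' Default ordering, most preferred first: fewest off-target hits beyond the
#' guide's own site (lexicographic over `m0 - 1`, `m1`, `m2`, `m3`), then
#' smallest truncation fraction (earlier stop, more protein removed), then
#' highest external on-target score when present, then ascending
#' `locus_start` as the final deterministic tie-break. Alternatively, a
#' named `weights` vector over `c("offtarget", "truncation", "score")`
#' ranks by weighted sum instead of lexicographic ordering.
#'
#' @param results Data.frame from [filter_guides()].
#' @param offtarget_summaries Optional data.frame/matrix with columns
#'   `m0..m3`, one row per result row (e.g. rows of
#'   [summarize_offtargets()]). Absent counts leave off-target rank keys at
#'   zero.
#' @param external_scores Optional data.frame with columns `spacer` and
#'   `score` (externally computed on-target efficiencies); joined by exact
#'   spacer sequence, unmatched spacers get an absent score and a warning.
#' @param weights Optional named numeric vector for weighted-sum ranking;
#'   unknown names are a configuration error.
#' @return Data.frame of flattened guide reports (columns
#'   `REPORT_COLUMNS`), ordered by rank.
#' @export
rank_guides <- function(results, offtarget_summaries = NULL,
                        external_scores = NULL, weights = NULL) {
  n <- nrow(results)
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), c("offtarget", "truncation", "score"))
    if (length(unknown) || is.null(names(weights))) {
      stop("unknown ranking weight key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  ot <- matrix(0L, nrow = n, ncol = 4,
               dimnames = list(NULL, paste0("m", 0:3)))
  have_ot <- !is.null(offtarget_summaries)
  if (have_ot && n) {
    os <- as.data.frame(offtarget_summaries)
    stopifnot(nrow(os) == n)
    for (k in paste0("m", 0:3)) {
      if (k %in% names(os)) ot[, k] <- as.integer(os[[k]])
    }
  }

  score <- rep(NA_real_, n)
  if (!is.null(external_scores) && n) {
    es <- as.data.frame(external_scores)
    stopifnot(all(c("spacer", "score") %in% names(es)))
    idx <- match(results$spacer, toupper(es$spacer))
    score <- as.numeric(es$score)[idx]
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " spacer(s) had no external score",
              call. = FALSE)
    }
  }

  if (n) {
    beyond_self <- ot[, "m0"] - 1L
    score_key <- ifelse(is.na(score), -Inf, score)
    if (is.null(weights)) {
      ord <- order(beyond_self, ot[, "m1"], ot[, "m2"], ot[, "m3"],
                   results$truncation_fraction, -score_key,
                   results$locus_start)
    } else {
      w <- function(k) if (k %in% names(weights)) weights[[k]] else 0
      composite <- w("offtarget") *
        (beyond_self * 1e6 + ot[, "m1"] * 1e4 + ot[, "m2"] * 1e2 +
           ot[, "m3"]) +
        w("truncation") * results$truncation_fraction -
        w("score") * ifelse(is.na(score), 0, score)
      ord <- order(composite, results$locus_start)
    }
  } else {
    ord <- integer(0)
  }

  ranked <- results[ord, , drop = FALSE]
  report <- data.frame(
    rank = seq_len(n),
    spacer = ranked$spacer,
    pam_observed = ranked$pam_observed,
    strand = ranked$strand,
    locus_start = ranked$locus_start,
    locus_end = ranked$locus_start + nchar(ranked$spacer),
    nonsense_codon_number = ranked$nonsense_codon_number,
    ref_codon = ranked$ref_codon,
    alt_codon = ranked$alt_codon,
    protein_change = ranked$protein_change,
    truncation_fraction = ranked$truncation_fraction,
    n_bystanders = ranked$n_bystanders,
    bystander_changes = vapply(ranked$bystanders, format_bystanders,
                               character(1)),
    maximal_edit_class = ranked$maximal_edit_class,
    stringsAsFactors = FALSE
  )
  if (!n) {
    report <- report[0, , drop = FALSE]
  }
  if (have_ot) {
    for (k in paste0("m", 0:3)) report[[k]] <- ot[ord, k]
  } else {
    for (k in paste0("m", 0:3)) report[[k]] <- rep(NA_integer_, n)
  }
  report$external_score <- score[ord]
  report[, REPORT_COLUMNS]
}

format_bystanders <- function(bys) {
  if (is.null(bys) || !nrow(bys)) return("")
  paste0(bys$ref_aa, bys$codon_number, bys$alt_aa,
         "(", bys$consequence, ")", collapse = ";")
}

report_header_lines <- function(locus, arch) {
  c(sprintf("# sgstop %s guide report", as.character(packageVersion("sgstop"))),
    sprintf("# record: %s | CDS %d nt (%d codons) | genetic code table %s",
            locus$record_id, nchar(locus$cds), n_codons(locus),
            locus$genetic_code_table),
    sprintf("# architecture: %s | PAM %s | spacer %d nt | window %d-%d | %s->%s",
            arch$name, arch$pam, arch$spacer_length, arch$window_start,
            arch$window_end, arch$conversion_from, arch$conversion_to))
}

#' Export a guide report as GFF3, BED, or TSV
#'
#' GFF3 is 1-based inclusive with one `protospacer` feature per guide and a
#' child `stop_codon` feature at the predicted premature stop (always on
#' the CDS sense strand); attributes carry the protein-change label and
#' rank. BED6 is 0-based half-open, `name` = protein change, `score` =
#' rank. TSV carries one row per guide with the fixed column set
#' `REPORT_COLUMNS`, absent optional values as empty strings, preceded by
#' `#` header lines recording the architecture, window, PAM, genetic-code
#' table and tool version. All three formats round-trip through standard
#' parsers.
#'
#' @param reports Data.frame from [rank_guides()].
#' @param locus The [coding_sequence()] the guides were designed on.
#' @param format One of `"tsv"`, `"gff3"`, `"bed"`.
#' @param path Optional output file; when `NULL` the lines are only
#'   returned.
#' @param arch The [editor_architecture()] recorded in the header.
#' @return Invisibly, the file content as a character vector of lines.
#' @export
export_annotations <- function(reports, locus,
                               format = c("tsv", "gff3", "bed"),
                               path = NULL, arch = target_aid()) {
  format <- match.arg(format)
  n <- nrow(reports)
  b <- cds_bounds(locus)
  L <- if (n) nchar(reports$spacer[1]) else 20L

  lines <- switch(
    format,
    tsv = {
      body <- utils::capture.output(
        write.table(format_tsv_frame(reports), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      )
      c(report_header_lines(locus, arch), body)
    },
    bed = {
      if (!n) {
        lines <- character(0)
        if (!is.null(path)) writeLines(lines, path)
        return(invisible(lines))
      }
      gr <- GenomicRanges::GRanges(
        seqnames = rep(locus$record_id, n),
        ranges = IRanges::IRanges(start = reports$locus_start + 1L,
                                  end = reports$locus_end),
        strand = reports$strand
      )
      gr$name <- reports$protein_change
      gr$score <- reports$rank
      tmp <- tempfile(fileext = ".bed")
      on.exit(unlink(tmp), add = TRUE)
      rtracklayer::export(gr, tmp, format = "BED")
      readLines(tmp)
    },
    gff3 = {
      if (!n) {
        lines <- c("##gff-version 3", report_header_lines(locus, arch))
        if (!is.null(path)) writeLines(lines, path)
        return(invisible(lines))
      }
      ids <- sprintf("guide%03d", reports$rank)
      parent <- GenomicRanges::GRanges(
        seqnames = rep(locus$record_id, n),
        ranges = IRanges::IRanges(start = reports$locus_start + 1L,
                                  end = reports$locus_end),
        strand = reports$strand,
        type = rep("protospacer", n),
        ID = ids,
        Name = reports$protein_change,
        protein_change = reports$protein_change,
        rank = reports$rank,
        spacer = reports$spacer
      )
      stop_start <- b[["start"]] + (reports$nonsense_codon_number - 1L) * 3L
      child <- GenomicRanges::GRanges(
        seqnames = rep(locus$record_id, n),
        ranges = IRanges::IRanges(start = stop_start + 1L,
                                  end = stop_start + 3L),
        strand = rep("+", n),
        type = rep("stop_codon", n),
        ID = paste0(ids, ".stop"),
        Name = reports$alt_codon,
        protein_change = reports$protein_change,
        rank = reports$rank,
        spacer = reports$spacer
      )
      child$Parent <- as.character(ids)
      gr <- suppressWarnings(c(parent, child))
      gr$source <- "sgstop"
      tmp <- tempfile(fileext = ".gff3")
      on.exit(unlink(tmp), add = TRUE)
      rtracklayer::export(gr, tmp, format = "gff3", source = "sgstop")
      out <- readLines(tmp)
      append(out, report_header_lines(locus, arch), after = 1L)
    }
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

format_tsv_frame <- function(reports) {
  out <- reports[, REPORT_COLUMNS, drop = FALSE]
  for (k in names(out)) {
    v <- out[[k]]
    if (is.numeric(v)) {
      v <- ifelse(is.na(v), "",
                  format(v, trim = TRUE, scientific = FALSE, digits = 12))
    } else {
      v <- ifelse(is.na(v), "", as.character(v))
    }
    out[[k]] <- v
  }
  out
}

#' Read back a TSV guide report
#'
#' @param path TSV file written by [export_annotations()].
#' @return Data.frame with the fixed report columns.
#' @export
read_guide_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Assemble a cloning-ready oligo for a guide
#'
#' Single-stranded guide-insertion oligos for Golden-Gate style cloning are
#' the spacer flanked by homology arms complementary to the overhangs left
#' by BsaI digestion of the editor backbone:
#' `upstream_arm + spacer + downstream_arm`, written 5'->3'. The standard
#' arm length is 19 nt per side, giving a 58-nt oligo for a 20-nt spacer;
#' shorter arms (15-18 nt) draw a warning.
#'
#' @param report One report row from [rank_guides()], or a spacer string.
#' @param upstream_arm,downstream_arm Homology arms (A/C/G/T, >= 15 nt).
#'   The defaults from [default_cloning_arms()] are PLACEHOLDER sequences —
#'   substitute the true overhang-complementary arms for your backbone.
#' @return The oligo sequence, 5'->3'.
#' @export
#' @examples
#' make_cloning_oligo(strrep("A", 20), strrep("G", 19), strrep("C", 19))
make_cloning_oligo <- function(report,
                               upstream_arm = default_cloning_arms()$upstream_arm,
                               downstream_arm = default_cloning_arms()$downstream_arm) {
  spacer <- if (is.data.frame(report)) report$spacer[1] else report
  spacer <- toupper(spacer)
  check_dna(spacer, "spacer")
  for (arm in list(upstream = upstream_arm, downstream = downstream_arm)) {
    if (!nchar(arm)) {
      stop("cloning arms must be non-empty", call. = FALSE)
    }
  }
  upstream_arm <- toupper(upstream_arm)
  downstream_arm <- toupper(downstream_arm)
  check_dna(upstream_arm, "upstream arm")
  check_dna(downstream_arm, "downstream arm")
  for (arm in c(upstream_arm, downstream_arm)) {
    if (nchar(arm) < 15L) {
      stop("cloning arms must be at least 15 nt (got ", nchar(arm), ")",
           call. = FALSE)
    }
    if (nchar(arm) < 19L) {
      warning("cloning arm of ", nchar(arm),
              " nt is shorter than the standard 19 nt", call. = FALSE)
    }
  }
  paste0(upstream_arm, spacer, downstream_arm)
}

#' Placeholder cloning arms
#'
#' PLACEHOLDER 19-nt homology arms so that oligo assembly is runnable out
#' of the box. They are *not* the arms of any real editor backbone: replace
#' them with the sequences complementary to the overhangs your BsaI-digested
#' vector leaves behind.
#'
#' @return List with `upstream_arm` and `downstream_arm`.
#' @export
default_cloning_arms <- function() {
  list(upstream_arm = "ACGTACGTACGTACGTACG",
       downstream_arm = "TACGATCGATCGATCGATC")
}
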