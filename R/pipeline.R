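#' End-to-end guide design on a loaded locus
#'
#' Runs the full chain on an in-memory [coding_sequence()]: enumerate
#' candidates, filter to premature-stop guides, optionally count off-target
#' matches in a genome and join external on-target scores, and rank into a
#' report. Stage counts are logged with [message()].
#'
#' @param locus A [coding_sequence()].
#' @param arch An [editor_architecture()].
#' @param genome Optional off-target database (FASTA path, character
#'   vector, or `DNAStringSet`).
#' @param external_scores Optional data.frame (`spacer`, `score`) or TSV
#'   path.
#' @param max_mismatch Off-target Hamming bound.
#' @param require_clean Passed to [filter_guides()].
#' @param include_nag Also count NAG-PAM off-target sites.
#' @return List with `guides` (all candidates), `results` (viable guides),
#'   `offtargets` (list of hit tables, or `NULL`), `summaries` (per-guide
#'   mismatch tallies, or `NULL`), and `reports` (the ranked
#'   [rank_guides()] table).
#' @export
design_guides <- function(locus, arch = target_aid(), genome = NULL,
                          external_scores = NULL, max_mismatch = 3L,
                          require_clean = FALSE, include_nag = FALSE) {
  guides <- enumerate_guides(locus, arch)
  message(nrow(guides), " candidate guide(s) enumerated")
  results <- filter_guides(locus, guides, arch, require_clean)
  message(nrow(results), " viable (premature-stop) guide(s)")

  offtargets <- NULL
  summaries <- NULL
  if (!is.null(genome) && nrow(results)) {
    genome <- as_genome(genome)
    offtargets <- lapply(results$spacer, scan_offtargets, genome = genome,
                         arch = arch, max_mismatch = max_mismatch,
                         include_nag = include_nag)
    summaries <- do.call(rbind, lapply(offtargets, function(h)
      as.data.frame(as.list(summarize_offtargets(h, max_mismatch = 3L)))))
    message("off-target scan complete (", length(offtargets), " spacers)")
  }
  if (is.character(external_scores) && length(external_scores) == 1L) {
    external_scores <- read_external_scores(external_scores)
  }
  reports <- rank_guides(results, summaries, external_scores)
  message(nrow(reports), " guide(s) exported to report")
  list(guides = guides, results = results, offtargets = offtargets,
       summaries = summaries, reports = reports)
}

#' Run the design pipeline from files to files
#'
#' File-level wrapper matching the command-line workflow: load the locus
#' (GenBank, FASTA+GFF3, or bare FASTA), design guides under a
#' [run_config()], and export the report in the configured format.
#'
#' @param config A [run_config()].
#' @param locus_path Input locus file.
#' @param out_path Optional report output path.
#' @param gff,cds_id Passed to [load_locus()].
#' @return Invisibly, the [design_guides()] result list plus `locus`.
#' @export
run_pipeline <- function(config, locus_path, out_path = NULL, gff = NULL,
                         cds_id = NULL) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$genome_path, config$scores_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input does not exist: ", p, call. = FALSE)
    }
  }
  locus <- load_locus(locus_path, gff = gff, cds_id = cds_id,
                      flank = config$flank,
                      genetic_code_table = config$genetic_code_table,
                      strict = config$strict)
  design <- design_guides(locus, arch = config$architecture,
                          genome = config$genome_path,
                          external_scores = config$scores_path,
                          max_mismatch = config$max_mismatch,
                          require_clean = config$require_clean)
  if (!is.null(out_path)) {
    export_annotations(design$reports, locus, format = config$output_format,
                       path = out_path, arch = config$architecture)
    message("report written to ", out_path, " (", config$output_format, ")")
  }
  invisible(c(list(locus = locus), design))
}
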