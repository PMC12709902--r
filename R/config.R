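#' Run configuration for the design pipeline
#'
#' Gathers every knob of an end-to-end run into one object that serializes
#' losslessly to a flat `key: value` text file, so that runs are
#' reproducible and scriptable. Command-line flags in the bundled CLI
#' override file values.
#'
#' @param architecture An [editor_architecture()].
#' @param genetic_code_table NCBI translation-table id (default `"11"`).
#' @param strict Treat CDS annotation problems as errors.
#' @param require_clean Keep only guides whose maximal edit is
#'   bystander-missense free.
#' @param max_mismatch Off-target Hamming bound (default 3).
#' @param genome_path Optional off-target genome FASTA.
#' @param scores_path Optional external on-target score TSV.
#' @param output_format `"tsv"`, `"gff3"`, or `"bed"`.
#' @param flank Flank length retained when loading loci.
#' @param seed Optional integer seed recorded for reproducibility.
#' @return An object of class `run_config`.
#' @export
run_config <- function(architecture = target_aid(),
                       genetic_code_table = "11",
                       strict = FALSE, require_clean = FALSE,
                       max_mismatch = 3L, genome_path = NULL,
                       scores_path = NULL,
                       output_format = c("tsv", "gff3", "bed"),
                       flank = 30L, seed = NULL) {
  output_format <- match.arg(output_format)
  stopifnot(inherits(architecture, "editor_architecture"))
  structure(
    list(architecture = architecture,
         genetic_code_table = as.character(genetic_code_table),
         strict = isTRUE(strict), require_clean = isTRUE(require_clean),
         max_mismatch = as.integer(max_mismatch),
         genome_path = genome_path, scores_path = scores_path,
         output_format = output_format, flank = as.integer(flank),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path Config file path.
#' @export
write_run_config <- function(config, path) {
  a <- config$architecture
  kv <- c(
    arch.name = a$name, arch.pam = a$pam,
    arch.spacer_length = a$spacer_length,
    arch.window_start = a$window_start, arch.window_end = a$window_end,
    arch.conversion_from = a$conversion_from,
    arch.conversion_to = a$conversion_to,
    genetic_code_table = config$genetic_code_table,
    strict = config$strict, require_clean = config$require_clean,
    max_mismatch = config$max_mismatch,
    genome_path = if (is.null(config$genome_path)) "" else config$genome_path,
    scores_path = if (is.null(config$scores_path)) "" else config$scores_path,
    output_format = config$output_format, flank = config$flank,
    seed = if (is.null(config$seed)) "" else config$seed
  )
  writeLines(paste0(names(kv), ": ", vapply(kv, as.character, character(1))),
             path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z._]+)\\s*:\\s*(.*?)\\s*$",
                                 lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  kv <- stats::setNames(vapply(m, `[`, character(1), 3L),
                        vapply(m, `[`, character(1), 2L))
  get <- function(key, default = NULL) {
    if (key %in% names(kv) && nzchar(kv[[key]])) kv[[key]] else default
  }
  arch <- editor_architecture(
    name = get("arch.name", "Target-AID"),
    pam = get("arch.pam", "NGG"),
    spacer_length = as.integer(get("arch.spacer_length", "20")),
    window_start = as.integer(get("arch.window_start", "2")),
    window_end = as.integer(get("arch.window_end", "4")),
    conversion_from = get("arch.conversion_from", "C"),
    conversion_to = get("arch.conversion_to", "T")
  )
  run_config(
    architecture = arch,
    genetic_code_table = get("genetic_code_table", "11"),
    strict = as.logical(get("strict", "FALSE")),
    require_clean = as.logical(get("require_clean", "FALSE")),
    max_mismatch = as.integer(get("max_mismatch", "3")),
    genome_path = get("genome_path"),
    scores_path = get("scores_path"),
    output_format = get("output_format", "tsv"),
    flank = as.integer(get("flank", "30")),
    seed = {s <- get("seed"); if (is.null(s)) NULL else as.integer(s)}
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(x$architecture)
  cat(sprintf("  code table %s | strict=%s | require_clean=%s | max_mismatch=%d\n",
              x$genetic_code_table, x$strict, x$require_clean,
              x$max_mismatch))
  cat(sprintf("  genome=%s scores=%s format=%s flank=%d seed=%s\n",
              x$genome_path %||% "<none>", x$scores_path %||% "<none>",
              x$output_format, x$flank,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
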