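#' Load an annotated coding sequence from file
#'
#' Reads the locus a guide design runs on. Three input shapes are
#' supported and auto-detected by extension:
#'
#' * **GenBank flat file** (`.gb`, `.gbk`, `.gbff`, `.genbank`) with a CDS
#'   feature: the CDS is extracted strand-aware, with up to `flank` nt of
#'   genomic context on each side.
#' * **FASTA + GFF3**: pass the FASTA as `path` and the annotation as
#'   `gff`; a single-interval CDS feature is selected the same way.
#' * **Bare FASTA**: the whole (first) record is taken as an in-frame CDS
#'   with empty flanks.
#'
#' When a record carries several CDS features, `cds_id` (matched against
#' locus_tag, gene, protein_id, ID, or Name) disambiguates; otherwise the
#' candidates are listed in the error. Multi-exon (joined) CDS locations
#' are rejected: this is a bacterial tool.
#'
#' @param path Input sequence file.
#' @param format `"auto"` (default), `"genbank"`, `"fasta"`, or
#'   `"fasta_gff3"`.
#' @param gff GFF3 annotation path (implies `format = "fasta_gff3"`).
#' @param cds_id Identifier selecting one CDS among several.
#' @param flank Maximum flank length retained on each side (default 30).
#' @param genetic_code_table,strict Passed to [coding_sequence()].
#' @return A [coding_sequence()].
#' @export
load_locus <- function(path, format = c("auto", "genbank", "fasta",
                                        "fasta_gff3"),
                       gff = NULL, cds_id = NULL, flank = 30L,
                       genetic_code_table = "11", strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gb", "gbk", "gbff", "genbank")) "genbank"
              else if (!is.null(gff)) "fasta_gff3"
              else "fasta"
  }
  switch(format,
    genbank = load_locus_genbank(path, cds_id, flank, genetic_code_table,
                                 strict),
    fasta_gff3 = load_locus_fasta_gff3(path, gff, cds_id, flank,
                                       genetic_code_table, strict),
    fasta = {
      fa <- Biostrings::readDNAStringSet(path)
      if (!length(fa)) stop("FASTA file contains no sequence", call. = FALSE)
      if (length(fa) > 1L) {
        warning("FASTA contains ", length(fa),
                " records; using the first", call. = FALSE)
      }
      coding_sequence(as.character(fa[[1]]),
                      record_id = sub("\\s.*$", "", names(fa)[1]),
                      genetic_code_table = genetic_code_table,
                      strict = strict)
    }
  )
}

extract_cds_with_flanks <- function(seq, record_id, s, e, strand, flank,
                                    genetic_code_table, strict) {
  n <- nchar(seq)
  flank <- as.integer(flank)
  span <- substr(seq, s, e)
  right <- if (e < n) substr(seq, e + 1L, min(n, e + flank)) else ""
  left <- if (s > 1L) substr(seq, max(1L, s - flank), s - 1L) else ""
  if (strand == "+") {
    coding_sequence(span, upstream = left, downstream = right,
                    record_id = record_id, source_offset = s - 1L,
                    source_strand = "+",
                    genetic_code_table = genetic_code_table, strict = strict)
  } else {
    coding_sequence(revcomp(span), upstream = revcomp(right),
                    downstream = revcomp(left),
                    record_id = record_id, source_offset = s - 1L,
                    source_strand = "-",
                    genetic_code_table = genetic_code_table, strict = strict)
  }
}

pick_one_cds <- function(cands, cds_id) {
  if (!is.null(cds_id)) {
    hit <- vapply(cands, function(x) cds_id %in% x$ids, logical(1))
    cands <- cands[hit]
  }
  if (!length(cands)) {
    stop("no CDS feature", if (!is.null(cds_id))
      paste0(" matching '", cds_id, "'") else "", " found", call. = FALSE)
  }
  if (length(cands) > 1L) {
    desc <- vapply(cands, function(x) {
      sprintf("%s [%d..%d %s]",
              if (length(x$ids)) x$ids[1] else "<unnamed>",
              x$start, x$end, x$strand)
    }, character(1))
    stop("record contains ", length(cands),
         " CDS features; disambiguate with cds_id. Candidates: ",
         paste(desc, collapse = "; "), call. = FALSE)
  }
  cands[[1]]
}

## --- GenBank flat-file parsing -------------------------------------------
## Minimal single-record parser: FEATURES keys + locations + a few
## identifying qualifiers, and the ORIGIN sequence. join()/order()
## locations are rejected rather than silently spliced.

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fe <- grep("^FEATURES", lines)
  or <- grep("^ORIGIN", lines)
  if (!length(or)) stop("GenBank record has no ORIGIN section", call. = FALSE)
  end <- grep("^//", lines)
  end <- if (length(end)) end[1] else length(lines) + 1L
  seq <- toupper(gsub("[^A-Za-z]", "",
                      paste(lines[(or[1] + 1L):(end - 1L)], collapse = "")))

  feats <- list()
  if (length(fe)) {
    block <- lines[(fe[1] + 1L):(or[1] - 1L)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {               # new feature key
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        key <- sub("^ {5}(\\S+).*$", "\\1", ln)
        loc <- sub("^ {5}\\S+\\s+", "", ln)
        cur <- list(key = key, location = loc, qualifiers = character())
      } else if (!is.null(cur)) {
        body <- sub("^\\s+", "", ln)
        if (startsWith(body, "/")) {
          cur$qualifiers <- c(cur$qualifiers, body)
        } else if (!length(cur$qualifiers)) {     # location continuation
          cur$location <- paste0(cur$location, body)
        } else {                                  # qualifier continuation
          i <- length(cur$qualifiers)
          cur$qualifiers[i] <- paste0(cur$qualifiers[i], body)
        }
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  record_id <- if (length(locus_line)) {
    strsplit(sub("^LOCUS\\s+", "", locus_line[1]), "\\s+")[[1]][1]
  } else "genbank_record"
  list(record_id = record_id, sequence = seq, features = feats)
}

genbank_qualifier <- function(feat, name) {
  rx <- paste0("^/", name, "=")
  q <- grep(rx, feat$qualifiers, value = TRUE)
  if (!length(q)) return(character())
  gsub('^"|"$', "", sub(rx, "", q))
}

load_locus_genbank <- function(path, cds_id, flank, genetic_code_table,
                               strict) {
  gb <- parse_genbank(path)
  cds_feats <- Filter(function(f) f$key == "CDS", gb$features)
  cands <- lapply(cds_feats, function(f) {
    loc <- gsub("\\s", "", f$location)
    if (grepl("join|order", loc)) {
      stop("joined (multi-exon) CDS locations are not supported: ", loc,
           call. = FALSE)
    }
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    loc <- gsub("^complement\\(|\\)$", "", loc)
    loc <- gsub("[<>]", "", loc)
    m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
    if (length(m) != 3L) {
      stop("unsupported CDS location: ", f$location, call. = FALSE)
    }
    ids <- c(genbank_qualifier(f, "locus_tag"), genbank_qualifier(f, "gene"),
             genbank_qualifier(f, "protein_id"))
    list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand,
         ids = ids)
  })
  f <- pick_one_cds(cands, cds_id)
  extract_cds_with_flanks(gb$sequence, gb$record_id, f$start, f$end,
                          f$strand, flank, genetic_code_table, strict)
}

load_locus_fasta_gff3 <- function(path, gff, cds_id, flank,
                                  genetic_code_table, strict) {
  if (is.null(gff) || !file.exists(gff)) {
    stop("GFF3 annotation file not found: ", gff, call. = FALSE)
  }
  fa <- Biostrings::readDNAStringSet(path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "CDS"]
  if (!length(gr)) stop("no CDS feature in GFF3", call. = FALSE)
  md <- S4Vectors::mcols(gr)
  id_of <- function(i) {
    ids <- character()
    for (k in c("ID", "locus_tag", "gene", "Name", "protein_id")) {
      if (k %in% names(md)) {
        v <- md[[k]][i]
        v <- unlist(v)
        ids <- c(ids, v[!is.na(v)])
      }
    }
    unique(ids)
  }
  keys <- vapply(seq_along(gr), function(i) {
    ids <- id_of(i)
    if (length(ids)) ids[1] else paste0("cds", i)
  }, character(1))
  # multi-interval CDS (same ID over several rows) is multi-exon: reject
  if (anyDuplicated(keys)) {
    stop("joined (multi-exon) CDS features are not supported", call. = FALSE)
  }
  cands <- lapply(seq_along(gr), function(i) {
    list(start = BiocGenerics::start(gr)[i], end = BiocGenerics::end(gr)[i],
         strand = as.character(BiocGenerics::strand(gr))[i], ids = id_of(i),
         seqname = as.character(GenomicRanges::seqnames(gr))[i])
  })
  f <- pick_one_cds(cands, cds_id)
  if (!f$seqname %in% names(fa)) {
    stop("GFF3 seqid '", f$seqname, "' not found in FASTA", call. = FALSE)
  }
  if (!f$strand %in% c("+", "-")) f$strand <- "+"
  extract_cds_with_flanks(as.character(fa[[f$seqname]]), f$seqname,
                          f$start, f$end, f$strand, flank,
                          genetic_code_table, strict)
}

#' Read externally computed on-target scores
#'
#' Scores (e.g. Rule Set 2 efficiencies computed by other software) are
#' accepted as a two-column TSV keyed by exact spacer sequence; this
#' package never computes on-target scores itself.
#'
#' @param path TSV with columns `spacer` and `score`.
#' @return Data.frame with uppercase `spacer` and numeric `score`.
#' @export
read_external_scores <- function(path) {
  if (!file.exists(path)) stop("scores file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("spacer", "score") %in% names(df))) {
    stop("scores TSV must have columns 'spacer' and 'score'", call. = FALSE)
  }
  data.frame(spacer = toupper(df$spacer), score = as.numeric(df$score),
             stringsAsFactors = FALSE)
}
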