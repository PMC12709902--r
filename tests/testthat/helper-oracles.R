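# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain character arithmetic, regex PAM scanning, seqinr
# translation, and exhaustive mask enumeration.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

oracle_aa <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], numcode = 11)
}

# All guide (locus_start, strand) pairs found by regex-scanning every
# substring of both strands for spacer+PAM.
oracle_enumerate <- function(locus_string, L = 20L, pam_regex = "[ACGT]GG") {
  one_strand <- function(s, strand) {
    n <- nchar(s)
    tot <- L + 3L
    if (n < tot) {
      return(data.frame(locus_start = integer(), strand = character()))
    }
    idx <- seq_len(n - tot + 1L)                  # 1-based spacer starts
    pams <- substring(s, idx + L, idx + L + 2L)
    starts <- idx[grepl(paste0("^", pam_regex, "$"), pams)]
    ls <- if (strand == "+") starts - 1L else n - (starts - 1L) - L
    data.frame(locus_start = as.integer(ls), strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_strand(locus_string, "+"),
               one_strand(oracle_revcomp(locus_string), "-"))
  out[order(out$locus_start, out$strand), , drop = FALSE]
}

# Exhaustive-mask viability: try every nonempty subset of the window
# cytosines (protospacer strand) that fall inside the CDS; a guide is
# viable iff some subset creates a stop codon strictly before the final
# codon where the reference had none.
oracle_viable <- function(locus_string, cds_start, cds_len, locus_start,
                          strand, L = 20L, window = 2:4) {
  chars <- strsplit(locus_string, "")[[1]]
  wl <- if (strand == "+") locus_start + (window - 1L) else
    (locus_start + L - 1L) - (window - 1L)
  proto <- if (strand == "+") chars[wl + 1L] else
    chartr("ACGT", "TGCA", chars[wl + 1L])
  cpos <- wl[proto == "C"]
  cpos <- cpos[cpos >= cds_start & cpos < cds_start + cds_len]
  if (!length(cpos)) return(FALSE)
  n_cod <- cds_len %/% 3L
  sub_base <- if (strand == "+") "T" else "A"
  for (bits in seq_len(2L^length(cpos) - 1L)) {
    sel <- cpos[bitwAnd(bits, 2L^(seq_along(cpos) - 1L)) > 0L]
    ed <- chars
    ed[sel + 1L] <- sub_base
    affected <- unique((sel - cds_start) %/% 3L + 1L)
    for (cn in affected) {
      if (cn >= n_cod) next
      a <- cds_start + (cn - 1L) * 3L + 1L
      ref <- paste(chars[a:(a + 2L)], collapse = "")
      alt <- paste(ed[a:(a + 2L)], collapse = "")
      if (oracle_aa(alt) == "*" && oracle_aa(ref) != "*") return(TRUE)
    }
  }
  FALSE
}

# Position-by-position Hamming rescan of a contig (both strands) for
# PAM-adjacent protospacer matches.
oracle_offtarget <- function(spacer, contig_string, max_mismatch,
                             L = 20L, pam_regex = "[ACGT]GG") {
  sp <- strsplit(spacer, "")[[1]]
  one_strand <- function(s, strand) {
    n <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    tot <- L + 3L
    if (n < tot) return(NULL)
    idx <- seq_len(n - tot + 1L)
    pams <- substring(s, idx + L, idx + L + 2L)
    idx <- idx[grepl(paste0("^", pam_regex, "$"), pams)]
    if (!length(idx)) return(NULL)
    mm <- integer(length(idx))
    for (j in seq_len(L)) {
      mm <- mm + (chars[idx + j - 1L] != sp[j])
    }
    keep <- mm <= max_mismatch
    if (!any(keep)) return(NULL)
    idx <- idx[keep]
    pos <- if (strand == "+") idx - 1L else n - (idx - 1L) - L
    data.frame(position = as.integer(pos), strand = strand,
               mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(one_strand(contig_string, "+"),
               one_strand(oracle_revcomp(contig_string), "-"))
  if (is.null(out)) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer()))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

# Reference comparator sort for guide ranking (independent of order()):
# insertion of explicit pairwise comparisons.
oracle_rank_order <- function(df) {
  cmp <- function(i, j) {
    keys_i <- c(df$m0[i] - 1, df$m1[i], df$m2[i], df$m3[i],
                df$truncation_fraction[i])
    keys_j <- c(df$m0[j] - 1, df$m1[j], df$m2[j], df$m3[j],
                df$truncation_fraction[j])
    for (k in seq_along(keys_i)) {
      if (keys_i[k] < keys_j[k]) return(-1L)
      if (keys_i[k] > keys_j[k]) return(1L)
    }
    si <- if (is.na(df$external_score[i])) -Inf else df$external_score[i]
    sj <- if (is.na(df$external_score[j])) -Inf else df$external_score[j]
    if (si > sj) return(-1L)
    if (si < sj) return(1L)
    if (df$locus_start[i] < df$locus_start[j]) return(-1L)
    if (df$locus_start[i] > df$locus_start[j]) return(1L)
    0L
  }
  ord <- seq_len(nrow(df))
  # insertion sort with the explicit comparator
  for (a in seq_len(nrow(df))[-1]) {
    b <- a
    while (b > 1 && cmp(ord[b - 1], ord[b]) > 0) {
      tmp <- ord[b - 1]; ord[b - 1] <- ord[b]; ord[b] <- tmp
      b <- b - 1
    }
  }
  ord
}
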