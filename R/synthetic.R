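#' Specification of a synthetic test locus
#'
#' Describes a reproducible synthetic coding sequence with known,
#' *planted* stop-amenable codons (each guaranteed a supporting PAM so the
#' editing window reaches its cytosine) and, optionally, decoy PAM sites
#' whose windows contain no stop-amenable codon. Background codons are
#' drawn exclusively from codons that no C->T edit can turn into a stop, so
#' the planted sites are the only true positives — which makes the
#' generator's manifest a ground truth for testing the filter.
#'
#' @param n_codons Total codon count including start and stop (>= 10).
#' @param planted Planted sites: a data.frame with columns `codon_number`
#'   and `codon`, or a list of `c(codon_number, codon)` pairs. Codons must
#'   be stop-amenable (CAA/CAG/CGA/TGG under the default code); numbers
#'   unique, > 1 and < `n_codons`.
#' @param decoys Number of additional forced PAM sites over non-amenable
#'   background (default 0).
#' @param flank_length Flank length on each side (default 30).
#' @param seed Integer seed; generation is reproducible for a fixed seed.
#' @return An object of class `synthetic_locus_spec`.
#' @export
synthetic_locus_spec <- function(n_codons, planted = list(), decoys = 0L,
                                 flank_length = 30L, seed = 1L) {
  n_codons <- as.integer(n_codons)
  if (n_codons < 10L) stop("n_codons must be at least 10", call. = FALSE)
  if (is.data.frame(planted)) {
    pl <- planted
  } else if (length(planted)) {
    pl <- do.call(rbind, lapply(planted, function(p) {
      data.frame(codon_number = as.integer(p[[1]]),
                 codon = toupper(as.character(p[[2]])),
                 stringsAsFactors = FALSE)
    }))
  } else {
    pl <- data.frame(codon_number = integer(), codon = character(),
                     stringsAsFactors = FALSE)
  }
  pl$codon_number <- as.integer(pl$codon_number)
  amen <- amenable_codons()
  if (nrow(pl)) {
    if (!all(pl$codon %in% amen)) {
      stop("planted codons must be stop-amenable (",
           paste(amen, collapse = ", "), ")", call. = FALSE)
    }
    if (anyDuplicated(pl$codon_number) ||
        any(pl$codon_number <= 1L | pl$codon_number >= n_codons)) {
      stop("planted codon numbers must be unique, > 1 and < n_codons",
           call. = FALSE)
    }
  }
  structure(list(n_codons = n_codons, planted = pl,
                 decoys = as.integer(decoys),
                 flank_length = as.integer(flank_length),
                 seed = as.integer(seed)),
            class = "synthetic_locus_spec")
}

#' Generate a synthetic locus with a ground-truth manifest
#'
#' Builds the locus described by a [synthetic_locus_spec()]: a start codon,
#' non-amenable background codons, the planted amenable codons with a
#' supporting PAM forced into place (sense-codon sites get an NGG forced
#' downstream for a plus-strand guide; TGG sites get a CC forced upstream
#' so a minus-strand guide's window covers an opposite-strand cytosine),
#' decoy PAMs, random flanks, and a terminal stop. Construction is
#' validated and retried until no non-planted codon is amenable or a stop;
#' an error is raised after `max_tries` failed draws.
#'
#' @param spec A [synthetic_locus_spec()].
#' @param arch The [editor_architecture()] the planted PAMs must support.
#' @param max_tries Bounded number of generation attempts.
#' @return List with `locus` (a [coding_sequence()]), `manifest` (one row
#'   per planted site: `codon_number`, `codon`, `strand` of the supporting
#'   guide, `guide_locus_start`, `window_position`, `target_locus_pos`),
#'   and `spec`.
#' @export
#' @examples
#' fx <- generate_locus(synthetic_locus_spec(60, list(c(20, "CAG")), seed = 7))
#' fx$manifest
generate_locus <- function(spec, arch = target_aid(), max_tries = 200L) {
  stopifnot(inherits(spec, "synthetic_locus_spec"))
  withr::with_seed(spec$seed, {
    code <- genetic_code("11")
    amen <- amenable_codons(code)
    stops <- stop_codons(code)
    pool <- setdiff(all_codons(), c(stops, amen))
    nc <- spec$n_codons
    fl <- spec$flank_length
    L <- arch$spacer_length
    window <- arch$window_start:arch$window_end

    for (try in seq_len(max_tries)) {
      codons <- c("ATG", sample(pool, nc - 2L, replace = TRUE), "TAA")
      codons[spec$planted$codon_number] <- spec$planted$codon
      chars <- strsplit(paste0(
        paste(sample(DNA_BASES, fl, replace = TRUE), collapse = ""),
        paste(codons, collapse = ""),
        paste(sample(DNA_BASES, fl, replace = TRUE), collapse = "")
      ), "")[[1]]
      n <- length(chars)

      # locus positions (0-based) that must not be overwritten; the
      # terminal stop is deliberately left forcible — a PAM overlapping it
      # is legal as long as the codon stays a stop (TAG/TGA carry a G),
      # which the final validation checks
      protected <- fl + 0:2
      if (nrow(spec$planted)) {
        protected <- c(protected, unlist(lapply(
          spec$planted$codon_number, function(k) fl + (k - 1L) * 3L + 0:2)))
      }

      force_at <- function(pos0, bases) {
        # returns updated chars or NULL when a protected position would
        # need a different base than it already has
        for (j in seq_along(pos0)) {
          p <- pos0[j]
          if (p < 0L || p >= n) return(NULL)
          if (chars[p + 1L] != bases[j] && (p %in% protected)) return(NULL)
        }
        chars[pos0 + 1L] <- bases
        chars
      }

      manifest <- list()
      ok <- TRUE
      for (i in seq_len(nrow(spec$planted))) {
        kn <- spec$planted$codon_number[i]
        kc <- spec$planted$codon[i]
        q <- fl + (kn - 1L) * 3L          # 0-based codon start in locus
        placed <- FALSE
        if (kc == "TGG") {
          # knockable from the opposite strand: cytosines sit antisense of
          # the two Gs; a minus-strand guide needs a CCN PAM upstream
          combos <- expand.grid(p = q + 1:2, w = window)
          combos <- combos[sample(nrow(combos)), , drop = FALSE]
          for (r in seq_len(nrow(combos))) {
            p <- combos$p[r]; w <- combos$w[r]
            ls <- p - L + w               # guide locus_start (0-based)
            if (ls - 3L < 0L || ls + L > n) next
            upd <- force_at(c(ls - 3L, ls - 2L), c("C", "C"))
            if (is.null(upd)) next
            chars <- upd
            protected <- c(protected, ls - 3L, ls - 2L)
            manifest[[length(manifest) + 1L]] <- data.frame(
              codon_number = kn, codon = kc, strand = "-",
              guide_locus_start = ls, window_position = w,
              target_locus_pos = p, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        } else {
          # sense-editable: single C at codon offset 0; plus-strand guide
          # with NGG forced just past the spacer
          p <- q
          for (w in sample(window)) {
            ls <- p - (w - 1L)
            if (ls < 0L || ls + L + 3L > n) next
            upd <- force_at(c(ls + L + 1L, ls + L + 2L), c("G", "G"))
            if (is.null(upd)) next
            chars <- upd
            protected <- c(protected, ls + L + 1L, ls + L + 2L)
            manifest[[length(manifest) + 1L]] <- data.frame(
              codon_number = kn, codon = kc, strand = "+",
              guide_locus_start = ls, window_position = w,
              target_locus_pos = p, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next

      # decoy PAMs over non-amenable background
      d <- 0L
      attempts <- 0L
      while (d < spec$decoys && attempts < 50L * max(1L, spec$decoys)) {
        attempts <- attempts + 1L
        r <- sample(fl:(n - fl - 2L), 1L)
        upd <- force_at(c(r, r + 1L), c("G", "G"))
        if (is.null(upd)) next
        chars <- upd
        protected <- c(protected, r, r + 1L)
        d <- d + 1L
      }
      if (d < spec$decoys) next

      # validate: planted intact, frame anchors intact, and no non-planted
      # codon amenable or a stop
      cds_chars <- chars[(fl + 1L):(fl + 3L * nc)]
      got <- codon_split(paste(cds_chars, collapse = ""))
      background <- setdiff(seq_len(nc),
                            c(1L, nc, spec$planted$codon_number))
      if (got[1] != "ATG" || !(got[nc] %in% stops)) next
      if (nrow(spec$planted) &&
          !identical(got[spec$planted$codon_number], spec$planted$codon)) next
      if (any(got[background] %in% c(amen, stops))) next

      locus <- coding_sequence(
        paste(got, collapse = ""),
        upstream = paste(chars[seq_len(fl)], collapse = ""),
        downstream = paste(chars[(fl + 3L * nc + 1L):n], collapse = ""),
        record_id = sprintf("synthetic_locus_seed%d", spec$seed)
      )
      manifest <- if (length(manifest)) do.call(rbind, manifest) else
        data.frame(codon_number = integer(), codon = character(),
                   strand = character(), guide_locus_start = integer(),
                   window_position = integer(), target_locus_pos = integer(),
                   stringsAsFactors = FALSE)
      return(list(locus = locus, manifest = manifest, spec = spec))
    }
    stop("failed to generate a locus satisfying the constraints after ",
         max_tries, " attempts; relax the spec (longer CDS or fewer ",
         "planted/decoy sites)", call. = FALSE)
  })
}
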