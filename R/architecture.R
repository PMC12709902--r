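#' Describe a base-editor architecture
#'
#' Bundles the parameters that define where a cytosine base editor can act:
#' the PAM pattern, the spacer length, the editing window, and the conversion
#' chemistry. The defaults describe the Target-AID architecture
#' (SpCas9-derived NGG PAM, 20-nt spacers, C->T conversion with the window at
#' spacer positions 2-4 counted from the PAM-distal 5' end). Other
#' deaminase fusions can be expressed by changing the window or the
#' conversion bases.
#'
#' Window positions are 1-based from the PAM-distal (5') end of the spacer,
#' inclusive of both bounds — the dominant convention in the base-editing
#' literature.
#'
#' @param name Human-readable architecture name.
#' @param pam IUPAC PAM pattern immediately 3' of the protospacer
#'   (default `"NGG"`).
#' @param spacer_length Protospacer length in nt (default 20).
#' @param window_start,window_end Inclusive editing-window bounds, 1-based
#'   from the PAM-distal end (default 2 and 4).
#' @param conversion_from,conversion_to The edited base and its product on
#'   the protospacer strand (default C and T).
#' @return An object of class `editor_architecture`.
#' @export
#' @examples
#' editor_architecture()           # Target-AID defaults
#' editor_architecture(window_start = 1, window_end = 10)
editor_architecture <- function(name = "Target-AID",
                                pam = "NGG",
                                spacer_length = 20L,
                                window_start = 2L,
                                window_end = 4L,
                                conversion_from = "C",
                                conversion_to = "T") {
  spacer_length <- as.integer(spacer_length)
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  pam <- toupper(pam)
  iupac_regex(pam)  # errors on non-IUPAC characters
  if (!(window_start >= 1L && window_start <= window_end &&
        window_end <= spacer_length)) {
    stop("editing window must satisfy ",
         "1 <= window_start <= window_end <= spacer_length", call. = FALSE)
  }
  conversion_from <- toupper(conversion_from)
  conversion_to <- toupper(conversion_to)
  if (!conversion_from %in% DNA_BASES || !conversion_to %in% DNA_BASES) {
    stop("conversion bases must be single A/C/G/T letters", call. = FALSE)
  }
  if (conversion_from == conversion_to) {
    stop("conversion_from and conversion_to must differ", call. = FALSE)
  }
  structure(
    list(name = name, pam = pam, spacer_length = spacer_length,
         window_start = window_start, window_end = window_end,
         conversion_from = conversion_from, conversion_to = conversion_to),
    class = "editor_architecture"
  )
}

#' Target-AID architecture defaults
#'
#' @return The default `editor_architecture` (NGG PAM, 20-nt spacer,
#'   C->T in window 2-4).
#' @export
target_aid <- function() editor_architecture()

#' @export
print.editor_architecture <- function(x, ...) {
  cat(sprintf("<editor_architecture> %s\n", x$name))
  cat(sprintf("  PAM %s | spacer %d nt | window %d-%d (PAM-distal) | %s->%s\n",
              x$pam, x$spacer_length, x$window_start, x$window_end,
              x$conversion_from, x$conversion_to))
  invisible(x)
}
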