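# IUPAC nucleotide code arithmetic.
#
# Each code is a 4-bit mask over {A=1, C=2, G=4, T=8}; degeneracy is the
# union of bits. The scanner's matching rule ("subset rule") is then a
# single bitwAnd per position: a sequence letter s matches a pattern
# letter p iff bits(s) is a subset of bits(p).

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

.IUPAC_LETTERS <- names(.IUPAC_MASK)

# complement of a mask: swap A<->T and C<->G bits
.comp_mask <- function(m) {
  bitwOr(
    bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L), bitwShiftR(bitwAnd(m, 8L), 3L)),
    bitwOr(bitwShiftL(bitwAnd(m, 2L), 1L), bitwShiftR(bitwAnd(m, 4L), 1L))
  )
}

.seq_to_masks <- function(x) {
  m <- .IUPAC_MASK[strsplit(x, "", fixed = TRUE)[[1]]]
  unname(m)
}

.validate_iupac <- function(x, what = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% .IUPAC_LETTERS))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC nucleotide code '%s' in %s at position %d",
                 chars[bad[1L]], what, bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of an IUPAC DNA string
#'
#' Complements every IUPAC code (degenerate codes map to the code for the
#' complemented base set, e.g. `R` -> `Y`, `W` -> `W`) and reverses the
#' string.
#'
#' @param x A single DNA string over the IUPAC alphabet.
#' @return The reverse-complemented string.
#' @examples
#' revcomp("CAGCTG")  # palindromic E box
#' revcomp("CTGGTG")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  .validate_iupac(x)
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Match a DNA window against an IUPAC pattern under the subset rule
#'
#' A window letter matches a pattern letter iff the window letter's base
#' set is a subset of the pattern letter's base set. In particular an `N`
#' in the window matches only a pattern `N`: an undetermined sequence
#' position is never taken as evidence for a binding site.
#'
#' @param pattern IUPAC DNA pattern.
#' @param window DNA window of the same length.
#' @return `TRUE` iff every position matches.
#' @examples
#' iupac_match("CANNTG", "CAGCTG")  # TRUE
#' iupac_match("CANNTG", "CAGCTA")  # FALSE
#' @export
iupac_match <- function(pattern, window) {
  stopifnot(is.character(pattern), length(pattern) == 1L,
            is.character(window), length(window) == 1L)
  .validate_iupac(pattern, "pattern")
  .validate_iupac(window, "window")
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window must have equal length", call. = FALSE)
  }
  pm <- .seq_to_masks(pattern)
  wm <- .seq_to_masks(window)
  all(bitwAnd(wm, pm) == wm)
}
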