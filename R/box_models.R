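# SOPE binding-site classes and the double-stranded scanner.
#
# Two kinds of definition exist: a degenerate IUPAC consensus (E, alpha and
# N boxes) and an AT-rich window rule (beta boxes, for which no consensus
# is known). Hits are always reported in forward-strand coordinates.

#' Define a binding-site class
#'
#' @param name Box label (conventionally one of `"E"`, `"alpha"`, `"beta"`,
#'   `"N"`, but any label is accepted).
#' @param kind `"iupac_pattern"` or `"at_rich_window"`.
#' @param pattern IUPAC consensus (iupac_pattern kind only).
#' @param width Window width in bp (at_rich_window kind only, `>= 4`).
#' @param min_at_fraction Minimum fraction of A/T in a window
#'   (at_rich_window kind only, in `(0, 1]`).
#' @param both_strands Scan the reverse strand too? Ignored for the
#'   AT-rich kind, which is strand-symmetric.
#' @return An object of class `box_definition`.
#' @seealso [default_box_set()]
#' @export
box_definition <- function(name, kind = c("iupac_pattern", "at_rich_window"),
                           pattern = NULL, width = NULL,
                           min_at_fraction = NULL, both_strands = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "iupac_pattern") {
    if (is.null(pattern) || !nzchar(pattern)) {
      stop("iupac_pattern definition requires a non-empty pattern", call. = FALSE)
    }
    .validate_iupac(pattern, sprintf("pattern for box '%s'", name))
  } else {
    width <- as.integer(width)
    if (is.na(width) || width < 4L) stop("at_rich_window width must be >= 4", call. = FALSE)
    if (is.null(min_at_fraction) || min_at_fraction <= 0 || min_at_fraction > 1) {
      stop("min_at_fraction must be in (0, 1]", call. = FALSE)
    }
  }
  structure(list(name = name, kind = kind, pattern = pattern, width = width,
                 min_at_fraction = min_at_fraction,
                 both_strands = isTRUE(both_strands)),
            class = "box_definition")
}

#' The default SOPE box set
#'
#' E = `CANNTG` (canonical bHLH E box; the pooled arthropod logo `CAGCTG`
#' is one of its instances), N = `CACNAG` (canonical Hairy/Enhancer-of-split
#' repressor site), alpha = `GGGWWWNCC` (NF-kappaB/Dorsal-class site),
#' beta = AT-rich window of width 8 at >= 0.85 AT fraction. E, N and alpha
#' are scanned on both strands. All four are overridable via
#' [box_definition()] or the run config.
#'
#' @return A named list of four `box_definition` objects.
#' @export
default_box_set <- function() {
  list(
    E     = box_definition("E", "iupac_pattern", pattern = "CANNTG"),
    alpha = box_definition("alpha", "iupac_pattern", pattern = "GGGWWWNCC"),
    beta  = box_definition("beta", "at_rich_window", width = 8L,
                           min_at_fraction = 0.85),
    N     = box_definition("N", "iupac_pattern", pattern = "CACNAG")
  )
}

.empty_hits <- function() {
  structure(data.frame(box = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       matched = character(0), stringsAsFactors = FALSE),
            class = c("box_hits", "data.frame"))
}

# positions (0-based starts) at which `pat_masks` matches the mask vector
# `seq_masks`; subset rule when strict, intersection rule otherwise
.match_positions <- function(seq_masks, pat_masks, strict = TRUE) {
  w <- length(pat_masks)
  n <- length(seq_masks) - w + 1L
  if (n < 1L) return(integer(0))
  ok <- rep(TRUE, n)
  for (j in seq_len(w)) {
    sm <- seq_masks[j:(j + n - 1L)]
    ok <- ok & if (strict) bitwAnd(sm, pat_masks[j]) == sm
               else        bitwAnd(sm, pat_masks[j]) != 0L
  }
  which(ok) - 1L
}

#' Scan a sequence for IUPAC-pattern boxes on both strands
#'
#' Every window of each pattern's length is tested on the forward strand
#' and, for `both_strands` definitions, against the reverse complement.
#' All hits are reported in forward-strand coordinates, sorted by
#' `(start, box, strand)`. When a locus matches on both strands and the
#' matched site is its own reverse complement, a single hit with strand
#' `"+"` is emitted (palindrome deduplication).
#'
#' By default a sequence letter matches a pattern letter only if its base
#' set is a subset of the pattern letter's base set (an `N` run in a draft
#' sequence yields no hits); `ambiguity` = `"wildcard"` relaxes this to
#' base-set intersection.
#'
#' @param sequence DNA string.
#' @param defs A list of `box_definition` objects of kind iupac_pattern
#'   (a single definition is also accepted).
#' @param ambiguity `"strict"` (subset rule) or `"wildcard"`.
#' @return A `box_hits` data frame with columns `box`, `start`, `end`
#'   (0-based half-open), `strand`, `matched` (forward-strand slice).
#' @examples
#' scan_iupac_boxes("TTCAGCTGTT", default_box_set()["E"])
#' @export
scan_iupac_boxes <- function(sequence, defs, ambiguity = c("strict", "wildcard")) {
  ambiguity <- match.arg(ambiguity)
  strict <- ambiguity == "strict"
  if (inherits(defs, "box_definition")) defs <- list(defs)
  lapply(defs, function(d) {
    if (!inherits(d, "box_definition") || d$kind != "iupac_pattern") {
      stop("scan_iupac_boxes requires iupac_pattern box definitions", call. = FALSE)
    }
  })
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(.empty_hits())
  .validate_iupac(sequence)
  sm <- .seq_to_masks(sequence)

  rows <- list()
  for (d in defs) {
    pm <- .seq_to_masks(d$pattern)
    w <- length(pm)
    fwd <- .match_positions(sm, pm, strict)
    rev_ <- integer(0)
    if (d$both_strands) {
      # reverse-strand match at [i, i+w) <=> forward match of revcomp(pattern)
      rc_pm <- rev(.comp_mask(pm))
      rev_ <- .match_positions(sm, rc_pm, strict)
    }
    both <- intersect(fwd, rev_)
    for (i in sort(unique(c(fwd, rev_)))) {
      site <- substr(sequence, i + 1L, i + w)
      if (i %in% both) {
        if (identical(site, revcomp(site))) {
          rows[[length(rows) + 1L]] <- list(d$name, i, i + w, "+", site)
        } else {
          rows[[length(rows) + 1L]] <- list(d$name, i, i + w, "+", site)
          rows[[length(rows) + 1L]] <- list(d$name, i, i + w, "-", site)
        }
      } else if (i %in% fwd) {
        rows[[length(rows) + 1L]] <- list(d$name, i, i + w, "+", site)
      } else {
        rows[[length(rows) + 1L]] <- list(d$name, i, i + w, "-", site)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_hits())
  out <- data.frame(
    box = vapply(rows, `[[`, "", 1L),
    start = vapply(rows, function(r) as.integer(r[[2L]]), 0L),
    end = vapply(rows, function(r) as.integer(r[[3L]]), 0L),
    strand = vapply(rows, `[[`, "", 4L),
    matched = vapply(rows, `[[`, "", 5L),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$box, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("box_hits", "data.frame")
  out
}

#' Scan a sequence for AT-rich (beta box) regions
#'
#' Every window of the definition's width whose A/T fraction reaches
#' `min_at_fraction` qualifies; overlapping or adjacent qualifying windows
#' are merged into maximal regions, each reported as one strandless hit
#' (strand `"+"`). Only literal `A` and `T` count toward the fraction;
#' ambiguity codes (including `W`) do not.
#'
#' @param sequence DNA string.
#' @param def A `box_definition` of kind at_rich_window.
#' @return A `box_hits` data frame (see [scan_iupac_boxes()]).
#' @export
scan_at_rich <- function(sequence, def) {
  if (!inherits(def, "box_definition") || def$kind != "at_rich_window") {
    stop("scan_at_rich requires an at_rich_window box definition", call. = FALSE)
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  w <- def$width
  if (n < w) return(.empty_hits())
  .validate_iupac(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_at <- as.integer(chars %in% c("A", "T"))
  cs <- c(0L, cumsum(is_at))
  counts <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  qual <- which(counts / w >= def$min_at_fraction) - 1L  # 0-based starts
  if (length(qual) == 0L) return(.empty_hits())
  # merge overlapping or adjacent windows [i, i+w)
  starts <- ends <- integer(0)
  cur_s <- qual[1L]; cur_e <- qual[1L] + w
  for (i in qual[-1L]) {
    if (i <= cur_e) {
      cur_e <- i + w
    } else {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e)
      cur_s <- i; cur_e <- i + w
    }
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e)
  out <- data.frame(
    box = rep(def$name, length(starts)), start = starts, end = ends,
    strand = rep("+", length(starts)),
    matched = substring(sequence, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
  class(out) <- c("box_hits", "data.frame")
  out
}

#' Scan a sequence with a full box set
#'
#' Dispatches each definition to [scan_iupac_boxes()] or [scan_at_rich()]
#' and returns the combined, coordinate-sorted hit table.
#'
#' @inheritParams scan_iupac_boxes
#' @param defs A list of `box_definition` objects of either kind.
#' @return A `box_hits` data frame.
#' @export
scan_boxes <- function(sequence, defs = default_box_set(),
                       ambiguity = c("strict", "wildcard")) {
  ambiguity <- match.arg(ambiguity)
  if (inherits(defs, "box_definition")) defs <- list(defs)
  parts <- lapply(defs, function(d) {
    if (d$kind == "iupac_pattern") scan_iupac_boxes(sequence, list(d), ambiguity)
    else scan_at_rich(sequence, d)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0L) return(.empty_hits())
  out <- out[order(out$start, out$box, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("box_hits", "data.frame")
  out
}

#' @export
print.box_hits <- function(x, ...) {
  cat(sprintf("%d box hit(s)\n", nrow(x)))
  if (nrow(x) > 0L) print.data.frame(x, ...)
  invisible(x)
}
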