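# Independent brute-force oracle for the IUPAC box scanner.
#
# Deliberately shares no code with the package: base sets are spelled out
# as character vectors, the subset rule is a literal set comparison, and
# every (position, pattern, strand) triple is tested by looping.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(ORACLE_COMP[chars])), collapse = "")
}

# window letter set must be a subset of the pattern letter set
oracle_letter_match <- function(pat_letter, win_letter) {
  all(ORACLE_SETS[[win_letter]] %in% ORACLE_SETS[[pat_letter]])
}

oracle_window_match <- function(pattern_chars, window_chars) {
  for (j in seq_along(pattern_chars)) {
    if (!oracle_letter_match(pattern_chars[j], window_chars[j])) return(FALSE)
  }
  TRUE
}

# all-windows / all-strands scan of one iupac_pattern definition; output
# mirrors scan_iupac_boxes (0-based half-open coordinates, palindromic
# loci collapsed to a single "+" hit)
oracle_scan_one <- function(sequence, name, pattern, both_strands = TRUE) {
  n <- nchar(sequence)
  w <- nchar(pattern)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  rows <- list()
  if (n >= w) {
    for (i in 0:(n - w)) {
      win <- substr(sequence, i + 1, i + w)
      win_chars <- strsplit(win, "", fixed = TRUE)[[1]]
      fwd <- oracle_window_match(pat, win_chars)
      rev_ <- FALSE
      if (both_strands) {
        rc <- oracle_revcomp(win)
        rev_ <- oracle_window_match(pat, strsplit(rc, "", fixed = TRUE)[[1]])
      }
      if (fwd && rev_ && identical(win, oracle_revcomp(win))) {
        rows[[length(rows) + 1]] <- list(name, i, i + w, "+", win)
      } else {
        if (fwd) rows[[length(rows) + 1]] <- list(name, i, i + w, "+", win)
        if (rev_) rows[[length(rows) + 1]] <- list(name, i, i + w, "-", win)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(box = character(0), start = integer(0), end = integer(0),
                      strand = character(0), matched = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    box = vapply(rows, function(r) r[[1]], ""),
    start = vapply(rows, function(r) as.integer(r[[2]]), 0L),
    end = vapply(rows, function(r) as.integer(r[[3]]), 0L),
    strand = vapply(rows, function(r) r[[4]], ""),
    matched = vapply(rows, function(r) r[[5]], ""),
    stringsAsFactors = FALSE
  )
}

oracle_scan <- function(sequence, defs) {
  parts <- lapply(defs, function(d) {
    oracle_scan_one(sequence, d$name, d$pattern, d$both_strands)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out <- out[order(out$start, out$box, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# strip the box_hits class for data-frame comparison against the oracle
as_plain_df <- function(x) {
  out <- as.data.frame(x, stringsAsFactors = FALSE)
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}
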