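# Sequence I/O, ORF location and UTR derivation.
#
# Coordinates are 0-based half-open everywhere inside the package; only
# human-readable report fields are converted to 1-based inclusive.

.AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y","X","*")

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines), upper-cases
#' the sequences and validates them against the chosen alphabet. The record
#' id is the first whitespace-delimited token of the header; the remainder
#' is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` (IUPAC nucleotide codes) or `"protein"`
#'   (single-letter amino-acid codes plus `X` and `*`).
#' @return A data frame with columns `id`, `sequence`, `description`, one
#'   row per record in file order. Zero rows for an empty file.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      description = character(0), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  allowed <- if (alphabet == "dna") .IUPAC_LETTERS else .AA_LETTERS
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad) > 0L) {
      stop(sprintf("record '%s': illegal %s character '%s' at position %d",
                   ids[[i]], alphabet, chars[bad[1L]], bad[1L]), call. = FALSE)
    }
  }
  data.frame(id = ids, sequence = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description` (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locate the open reading frame of a transcript
#'
#' When `provided` is given the coordinates are validated and returned
#' verbatim (`source = "provided"`). Otherwise the longest forward-strand
#' open reading frame is inferred: it begins at an exact `ATG`, ends at the
#' first in-frame stop codon (`TAA`, `TAG`, `TGA`; the stop is included in
#' the reported region), and ties on length are broken toward the smallest
#' start. Codons containing any ambiguity code are never accepted as start
#' or stop.
#'
#' @param sequence Transcript DNA string (IUPAC alphabet).
#' @param provided Optional length-2 integer vector `c(start, end)`,
#'   0-based half-open, giving known ORF coordinates.
#' @return A list of class `orf_annotation` with elements `orf` (a
#'   length-2 integer vector `c(start, end)` or `NULL` when no ORF exists)
#'   and `source` (`"provided"`, `"inferred"` or `"none"`).
#' @examples
#' find_orf("AAATGAAATAA")  # ORF [2, 11)
#' find_orf("CCCCCC")       # no ORF
#' @export
find_orf <- function(sequence, provided = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  .validate_iupac(sequence)
  n <- nchar(sequence)
  if (!is.null(provided)) {
    provided <- as.integer(provided)
    if (length(provided) != 2L || anyNA(provided)) {
      stop("provided ORF must be c(start, end)", call. = FALSE)
    }
    s <- provided[1L]; e <- provided[2L]
    if (s < 0L || s > e || e > n) stop("provided ORF out of bounds", call. = FALSE)
    if ((e - s) %% 3L != 0L) stop("provided ORF length not divisible by 3", call. = FALSE)
    out <- list(orf = c(s, e), source = "provided")
    class(out) <- "orf_annotation"
    return(out)
  }
  starts <- integer(0)
  if (n >= 6L) {
    m <- gregexpr("(?=ATG)", sequence, perl = TRUE)[[1]]
    if (m[1L] != -1L) starts <- as.integer(m) - 1L  # to 0-based
  }
  best <- NULL
  for (s in starts) {
    cs <- seq.int(s, n - 3L, by = 3L)
    if (length(cs) < 2L) next
    codons <- substring(sequence, cs + 1L, cs + 3L)
    hit <- which(codons %in% .STOP_CODONS)
    if (length(hit) == 0L) next
    e <- cs[hit[1L]] + 3L
    if (is.null(best) || (e - s) > (best[2L] - best[1L])) best <- c(s, e)
  }
  out <- if (is.null(best)) {
    list(orf = NULL, source = "none")
  } else {
    list(orf = best, source = "inferred")
  }
  class(out) <- "orf_annotation"
  out
}

#' Derive UTR regions from an ORF annotation
#'
#' Partitions a transcript into 5' UTR, ORF and 3' UTR. A UTR is reported
#' only when non-empty.
#'
#' @param sequence Transcript DNA string (used for its length).
#' @param orf An `orf_annotation` (from [find_orf()]) or a length-2
#'   `c(start, end)` vector, 0-based half-open.
#' @return A list with elements `five_prime` and `three_prime`, each a
#'   length-2 `c(start, end)` vector or `NULL` when the UTR is empty.
#' @export
extract_utrs <- function(sequence, orf) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (inherits(orf, "orf_annotation")) orf <- orf$orf
  if (is.null(orf)) stop("no ORF: cannot derive UTRs", call. = FALSE)
  orf <- as.integer(orf)
  n <- nchar(sequence)
  if (length(orf) != 2L || orf[1L] < 0L || orf[1L] > orf[2L] || orf[2L] > n) {
    stop("ORF region out of bounds for sequence", call. = FALSE)
  }
  list(
    five_prime  = if (orf[1L] > 0L) c(0L, orf[1L]) else NULL,
    three_prime = if (orf[2L] < n) c(orf[2L], n) else NULL
  )
}

#' Write hits or clusters as BED6
#'
#' @param x Data frame with columns `start`, `end` (0-based half-open) and
#'   optionally `strand`; names taken from `name_col`.
#' @param path Output path.
#' @param chrom Record id used as the BED chrom field (recycled).
#' @param name_col Column of `x` holding the BED name field, or a single
#'   string used for every row.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path, chrom, name_col = "box") {
  nm <- if (name_col %in% names(x)) x[[name_col]] else rep(name_col, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep("+", nrow(x))
  bed <- data.frame(chrom = rep_len(chrom, nrow(x)), start = x$start,
                    end = x$end, name = nm, score = 0L, strand = strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.orf_annotation <- function(x, ...) {
  if (is.null(x$orf)) {
    cat("ORF: none found\n")
  } else {
    # 1-based inclusive for display
    cat(sprintf("ORF: positions %d-%d (%d bp, %s)\n",
                x$orf[1L] + 1L, x$orf[2L], x$orf[2L] - x$orf[1L], x$source))
  }
  invisible(x)
}
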