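# Position frequency matrices, information-content logo tracks, IUPAC
# consensus calling and a permutation test for flank conservation.

.BASES <- c("A", "C", "G", "T")

# IUPAC letter for each base-set bitmask 1..15 (A=1, C=2, G=4, T=8)
.MASK_TO_LETTER <- c("A", "C", "M", "G", "R", "S", "V",
                     "T", "W", "Y", "H", "K", "D", "B", "N")

#' Build a site alignment
#'
#' @param sites Character vector of equal-length DNA strings (aligned box
#'   instances, optionally with retained flanking context).
#' @param box_name Label of the box class the sites instantiate.
#' @param flank_len Bases of flanking context on each side of the core
#'   (0 when sites are core-only).
#' @return An object of class `site_alignment`.
#' @export
site_alignment <- function(sites, box_name = "site", flank_len = 0L) {
  stopifnot(is.character(sites), length(sites) >= 1L)
  sites <- toupper(sites)
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) {
    stop("all sites in an alignment must have equal length", call. = FALSE)
  }
  flank_len <- as.integer(flank_len)
  if (flank_len < 0L || 2L * flank_len >= lens[1L]) {
    stop("flank_len must satisfy 0 <= 2*flank_len < site length", call. = FALSE)
  }
  for (i in seq_along(sites)) .validate_iupac(sites[[i]], sprintf("site %d", i))
  structure(list(sites = sites, box_name = box_name, flank_len = flank_len,
                 width = lens[1L]),
            class = "site_alignment")
}

#' Build a position frequency matrix from aligned sites
#'
#' Column-wise base counts over the unambiguous sites; any site containing
#' a non-ACGT code is excluded entirely (and the number excluded is
#' recorded), so counts are exact integer tallies.
#'
#' @param alignment A [site_alignment()] (or a character vector of
#'   equal-length sites).
#' @return An object of class `site_pfm` with elements `counts` (4 x width
#'   integer matrix, rows A/C/G/T), `frequencies`, `n_sites` (sites
#'   counted) and `n_excluded`.
#' @export
build_pfm <- function(alignment) {
  if (is.character(alignment)) alignment <- site_alignment(alignment)
  stopifnot(inherits(alignment, "site_alignment"))
  sites <- alignment$sites
  clean <- grepl("^[ACGT]*$", sites)
  n_excluded <- sum(!clean)
  sites <- sites[clean]
  if (length(sites) == 0L) {
    stop("no unambiguous sites left to tally", call. = FALSE)
  }
  w <- alignment$width
  mat <- matrix(unlist(strsplit(sites, "", fixed = TRUE)),
                nrow = length(sites), ncol = w, byrow = TRUE)
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(mat[, j], levels = .BASES))
    as.integer(tab)
  }, integer(4L))
  rownames(counts) <- .BASES
  structure(list(counts = counts, frequencies = counts / length(sites),
                 n_sites = length(sites), n_excluded = n_excluded,
                 box_name = alignment$box_name,
                 flank_len = alignment$flank_len),
            class = "site_pfm")
}

.column_ic <- function(freqs, n_sites, small_sample_correction = FALSE) {
  h <- apply(freqs, 2L, function(f) {
    nz <- f[f > 0]
    -sum(nz * log2(nz))
  })
  ic <- 2 - h
  if (small_sample_correction) {
    ic <- pmax(0, ic - 3 / (2 * log(2) * n_sites))
  }
  ic
}

.consensus_letter <- function(f, ic) {
  top <- which.max(f)
  if (f[top] >= 0.75 && ic >= 1) return(.BASES[top])
  incl <- which(f >= 0.25)
  if (length(incl) == 0L) return("N")
  .MASK_TO_LETTER[sum(.IUPAC_MASK[.BASES[incl]])]
}

#' Per-column information content and consensus of a PFM
#'
#' Information content per column is `2 - H` bits, `H` the Shannon entropy
#' of the column's base frequencies. With the small-sample correction on,
#' `e(n) = 3 / (2 ln 2 n)` is subtracted and the result floored at 0
#' (off by default: published arthropod SOPE logos pool very few sites).
#' The consensus letter is the single base when its frequency is at least
#' 0.75 and the column carries at least 1 bit; otherwise the minimal IUPAC
#' code covering all bases at frequency of at least 0.25.
#'
#' @param pfm A `site_pfm` from [build_pfm()].
#' @param small_sample_correction Apply the correction?
#' @return An object of class `logo_track` with elements `ic` (bits per
#'   column, in `[0, 2]`), `consensus` (IUPAC string),
#'   `correction_applied` and `frequencies`.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  stopifnot(inherits(pfm, "site_pfm"))
  ic <- .column_ic(pfm$frequencies, pfm$n_sites, small_sample_correction)
  cons <- vapply(seq_len(ncol(pfm$frequencies)), function(j) {
    .consensus_letter(pfm$frequencies[, j], ic[j])
  }, "")
  structure(list(ic = unname(ic), consensus = paste(cons, collapse = ""),
                 correction_applied = isTRUE(small_sample_correction),
                 frequencies = pfm$frequencies, box_name = pfm$box_name),
            class = "logo_track")
}

#' IUPAC consensus string of a PFM
#'
#' @inheritParams information_content
#' @return The consensus as a single IUPAC string.
#' @examples
#' consensus_from_pfm(build_pfm(rep("CAGCTG", 5)))  # "CAGCTG"
#' @export
consensus_from_pfm <- function(pfm, small_sample_correction = FALSE) {
  information_content(pfm, small_sample_correction)$consensus
}

#' Permutation test for conservation of motif flanks
#'
#' Tests whether the nucleotides flanking aligned box instances are more
#' conserved than expected by chance. The statistic is the mean
#' information content over the flank columns. The null distribution is
#' built by pooling all flank letters (across both flanks and all sites)
#' and redistributing them uniformly at random over the flank positions
#' `n_perm` times; `p = (1 + #{null >= observed}) / (1 + n_perm)`. Under
#' an i.i.d. flank model all arrangements of the pooled letters are
#' exchangeable, so the test is exact.
#'
#' Sites containing ambiguity codes are excluded (as in [build_pfm()]).
#'
#' @param alignment A [site_alignment()] with `flank_len >= 1`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the result is bit-for-bit reproducible given
#'   `(alignment, n_perm, seed)`.
#' @return A list of class `flank_test` with elements `observed` (mean
#'   flank IC in bits), `p_value`, `n_perm`, `n_sites`, `flank_len`. When
#'   fewer than 3 unambiguous sites are available, a `flank_test` with
#'   `insufficient_sites = TRUE` and `p_value = NA` is returned instead of
#'   an error.
#' @export
flank_conservation_test <- function(alignment, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(alignment, "site_alignment"))
  if (alignment$flank_len < 1L) {
    stop("flank_conservation_test requires flank_len >= 1", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  sites <- alignment$sites[grepl("^[ACGT]*$", alignment$sites)]
  if (length(sites) < 3L) {
    return(structure(list(insufficient_sites = TRUE, p_value = NA_real_,
                          observed = NA_real_, n_sites = length(sites),
                          n_perm = n_perm, flank_len = alignment$flank_len),
                     class = "flank_test"))
  }
  w <- alignment$width
  f <- alignment$flank_len
  flank_cols <- c(seq_len(f), (w - f + 1L):w)
  mat <- matrix(unlist(strsplit(sites, "", fixed = TRUE)),
                nrow = length(sites), ncol = w, byrow = TRUE)
  flanks <- mat[, flank_cols, drop = FALSE]
  n_sites <- nrow(flanks); n_cols <- ncol(flanks)

  mean_flank_ic <- function(m) {
    idx <- match(m, .BASES)
    cnt <- matrix(tabulate((rep(seq_len(n_cols), each = n_sites) - 1L) * 4L + idx,
                           nbins = 4L * n_cols), nrow = 4L)
    fr <- cnt / n_sites
    mean(.column_ic(fr, n_sites, FALSE))
  }
  observed <- mean_flank_ic(flanks)

  pool <- as.vector(flanks)
  null <- numeric(n_perm)
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- matrix(pool[sample.int(length(pool))], nrow = n_sites)
      null[b] <- mean_flank_ic(perm)
    }
  })
  p <- (1 + sum(null >= observed - 1e-12)) / (1 + n_perm)
  structure(list(observed = observed, p_value = p, n_perm = n_perm,
                 n_sites = n_sites, flank_len = f,
                 insufficient_sites = FALSE),
            class = "flank_test")
}

#' Write a PFM and logo track as TSV
#'
#' One row per column: position (1-based), A/C/G/T frequencies, bits.
#'
#' @param logo A `logo_track` from [information_content()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  stopifnot(inherits(logo, "logo_track"))
  fr <- logo$frequencies
  df <- data.frame(position = seq_len(ncol(fr)), A = fr["A", ], C = fr["C", ],
                   G = fr["G", ], T = fr["T", ], ic = logo$ic)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an information-content logo track
#'
#' A simple base-graphics rendering: stacked letter heights proportional
#' to frequency times column information content.
#'
#' @param x A `logo_track`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.logo_track <- function(x, ...) {
  fr <- x$frequencies
  w <- ncol(fr)
  graphics::plot(NULL, xlim = c(0.5, w + 0.5), ylim = c(0, 2),
                 xlab = "position", ylab = "bits",
                 main = sprintf("%s box logo (%s)", x$box_name, x$consensus), ...)
  cols <- c(A = "forestgreen", C = "blue3", G = "orange2", T = "red3")
  for (j in seq_len(w)) {
    ord <- order(fr[, j])
    y0 <- 0
    for (b in ord) {
      h <- fr[b, j] * x$ic[j]
      if (h > 0) {
        graphics::rect(j - 0.4, y0, j + 0.4, y0 + h, col = cols[b], border = NA)
        if (h > 0.12) graphics::text(j, y0 + h / 2, .BASES[b], col = "white", cex = 0.8)
        y0 <- y0 + h
      }
    }
  }
  invisible(x)
}

#' @export
print.site_pfm <- function(x, ...) {
  cat(sprintf("PFM for %s box: %d site(s) over %d column(s)",
              x$box_name, x$n_sites, ncol(x$counts)))
  if (x$n_excluded > 0L) cat(sprintf(" (%d ambiguous site(s) excluded)", x$n_excluded))
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' @export
print.logo_track <- function(x, ...) {
  cat(sprintf("Logo track (%s box): consensus %s\n", x$box_name, x$consensus))
  cat("bits per column:", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  if (x$correction_applied) cat("small-sample correction applied\n")
  invisible(x)
}

#' @export
print.flank_test <- function(x, ...) {
  if (isTRUE(x$insufficient_sites)) {
    cat(sprintf("Flank conservation test: insufficient sites (%d < 3)\n", x$n_sites))
  } else {
    cat(sprintf("Flank conservation test: mean flank IC %.3f bits, p = %.4g (%d permutations, %d sites)\n",
                x$observed, x$p_value, x$n_perm, x$n_sites))
  }
  invisible(x)
}
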