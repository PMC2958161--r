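# Diagnostic protein motifs of the achaete-scute family and the
# ASH / ase-like classification.

#' Reference 16-residue C-terminal ASH domain
#'
#' The C-terminal domain characteristic of arthropod proneural ASH
#' proteins. Ase proteins conserve it poorly (50% identity or less).
#' @export
ASH_CTERM_REFERENCE <- "PDDEELLDYISWWQQQ"

#' Amino-acid class configuration for the Ase motif
#'
#' The five-residue Ase motif is hydrophobic-Lys-polar-Glu-hydrophobic.
#' Class membership follows standard biochemical groupings; Y and C sit in
#' both classes. Both sets are overridable.
#'
#' @param hydrophobic Character vector of single-letter codes.
#' @param polar Character vector of single-letter codes.
#' @return An object of class `aa_class_config`.
#' @export
aa_class_config <- function(hydrophobic = c("A","V","L","I","M","F","W","Y","C"),
                            polar = c("S","T","N","Q","Y","C","G","H")) {
  hydrophobic <- toupper(hydrophobic); polar <- toupper(polar)
  if (length(hydrophobic) == 0L || length(polar) == 0L) {
    stop("amino-acid class sets must be non-empty", call. = FALSE)
  }
  if (any(nchar(c(hydrophobic, polar)) != 1L)) {
    stop("amino-acid classes use single-letter codes", call. = FALSE)
  }
  structure(list(hydrophobic = hydrophobic, polar = polar),
            class = "aa_class_config")
}

#' Best ungapped match of the C-terminal ASH domain
#'
#' Compares every 16-residue window within the final `search_tail`
#' residues of the protein, ungapped, to the reference domain; returns the
#' window with maximal identity, ties broken toward the C-terminus.
#' The identity is an exact fraction over the 16 positions; the display
#' percent truncates toward zero (10/16 -> 62), matching the convention of
#' printed identity percentages for this domain.
#'
#' @param protein Protein sequence (single-letter codes).
#' @param reference 16-residue reference domain.
#' @param search_tail Number of C-terminal residues searched.
#' @return A list of class `domain_match` with elements `window`
#'   (`c(start, end)`, 0-based half-open, protein coordinates), `identity`
#'   (fraction in `[0, 1]`), `percent` (truncated display percent),
#'   `reference` and `matched` (the aligned 16-mers); or `NULL` when the
#'   protein is shorter than 16 residues.
#' @examples
#' cterm_identity(paste0(strrep("G", 50), "PDDEELLDYISWWQQQ"))
#' @export
cterm_identity <- function(protein, reference = ASH_CTERM_REFERENCE,
                           search_tail = 40L) {
  stopifnot(is.character(protein), length(protein) == 1L)
  w <- nchar(reference)
  n <- nchar(protein)
  if (n < w) return(NULL)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  lo <- max(0L, n - as.integer(search_tail))  # windows start at >= lo (0-based)
  starts <- lo:(n - w)
  best_s <- NA_integer_; best_id <- -1L
  for (s in starts) {
    win <- strsplit(substr(protein, s + 1L, s + w), "", fixed = TRUE)[[1]]
    id <- sum(win == ref_chars)
    if (id >= best_id) { best_id <- id; best_s <- s }  # >= ties toward C-terminus
  }
  structure(list(
    window = c(best_s, best_s + w),
    identity = best_id / w,
    percent = trunc(100 * best_id / w),
    reference = reference,
    matched = substr(protein, best_s + 1L, best_s + w)
  ), class = "domain_match")
}

#' Find Ase-motif instances in a protein
#'
#' Reports every 5-residue window matching
#' `[hydrophobic] K [polar] E [hydrophobic]`, overlapping windows
#' included.
#'
#' @param protein Protein sequence.
#' @param classes An [aa_class_config()].
#' @return Integer vector of 0-based start positions (possibly empty).
#' @examples
#' find_ase_motif("AAVKSEIAA")  # hit at position 2
#' @export
find_ase_motif <- function(protein, classes = aa_class_config()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) < 5L) return(integer(0))
  h <- paste(classes$hydrophobic, collapse = "")
  p <- paste(classes$polar, collapse = "")
  pat <- sprintf("(?=[%s]K[%s]E[%s])", h, p, h)
  m <- gregexpr(pat, protein, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Classify a protein as ASH, ase or indeterminate
#'
#' Any Ase-motif hit labels the protein `ase` (the motif is absent from
#' all proneural ASH proteins outside the Diptera). Otherwise a
#' C-terminal domain identity at or above `cterm_min` labels it `ASH`;
#' below that the protein is `indeterminate` — a poorly conserved domain
#' alone does not establish an ase orthologue.
#'
#' @param cterm A `domain_match` from [cterm_identity()], or `NULL`.
#' @param motif_hits Integer vector from [find_ase_motif()].
#' @param cterm_min Identity threshold for the ASH call (default 0.5,
#'   from the published 50% boundary).
#' @return One of `"ase"`, `"ASH"`, `"indeterminate"`.
#' @export
classify_protein <- function(cterm, motif_hits, cterm_min = 0.5) {
  if (length(motif_hits) > 0L) return("ase")
  if (!is.null(cterm) && cterm$identity >= cterm_min) return("ASH")
  "indeterminate"
}

#' Measure both diagnostic motifs and classify a protein
#'
#' Convenience wrapper running [cterm_identity()], [find_ase_motif()] and
#' [classify_protein()].
#'
#' @inheritParams cterm_identity
#' @inheritParams find_ase_motif
#' @inheritParams classify_protein
#' @return A list of class `protein_evidence` with elements `cterm`,
#'   `ase_motif_hits` and `label`.
#' @export
protein_evidence <- function(protein, reference = ASH_CTERM_REFERENCE,
                             search_tail = 40L, classes = aa_class_config(),
                             cterm_min = 0.5) {
  cterm <- cterm_identity(protein, reference, search_tail)
  hits <- find_ase_motif(protein, classes)
  structure(list(cterm = cterm, ase_motif_hits = hits,
                 label = classify_protein(cterm, hits, cterm_min)),
            class = "protein_evidence")
}

#' Integrate protein and regulatory evidence into a gene-level call
#'
#' The presence of a SOPE in the UTR is a second, independent feature
#' distinguishing ase-like from proneural genes: an ase or indeterminate
#' protein with a UTR SOPE is `ase_like`; an ASH protein with a UTR SOPE
#' is `ancestral_ASH_ase_like` (a single gene carrying both functions, as
#' in myriapods); an ASH protein without a SOPE is `proneural_ASH`; an
#' ase protein without a SOPE is still `ase_like` (protein evidence
#' suffices); an indeterminate protein without a SOPE stays
#' `indeterminate`.
#'
#' @param protein_label `"ASH"`, `"ase"` or `"indeterminate"`.
#' @param has_sope Was a SOPE called in the gene's UTRs?
#' @return One of `"proneural_ASH"`, `"ase_like"`,
#'   `"ancestral_ASH_ase_like"`, `"indeterminate"`.
#' @export
integrate_gene_call <- function(protein_label, has_sope) {
  stopifnot(protein_label %in% c("ASH", "ase", "indeterminate"))
  if (isTRUE(has_sope)) {
    if (protein_label == "ASH") "ancestral_ASH_ase_like" else "ase_like"
  } else {
    switch(protein_label, ase = "ase_like", ASH = "proneural_ASH",
           indeterminate = "indeterminate")
  }
}

#' @export
print.domain_match <- function(x, ...) {
  w <- nchar(x$reference)
  cat(sprintf("C-terminal domain match: %s vs %s, identity %d/%d (%d%%)\n",
              x$matched, x$reference, round(x$identity * w), w, x$percent))
  invisible(x)
}

#' @export
print.protein_evidence <- function(x, ...) {
  cat("Protein evidence\n")
  if (!is.null(x$cterm)) {
    cat(sprintf("  C-terminal domain: %s (%d%% identity)\n",
                x$cterm$matched, x$cterm$percent))
  } else {
    cat("  C-terminal domain: not measurable (protein < 16 residues)\n")
  }
  if (length(x$ase_motif_hits) > 0L) {
    cat(sprintf("  Ase motif at position(s): %s\n",
                paste(x$ase_motif_hits + 1L, collapse = ", ")))
  } else {
    cat("  Ase motif: absent\n")
  }
  cat(sprintf("  label: %s\n", x$label))
  invisible(x)
}
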