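# Cluster calling: group box hits into candidate SOPEs and localize them
# relative to the ORF.

#' Clustering parameters for SOPE calling
#'
#' The defaults (`gap_max = 450`, `min_boxes = 4`, `min_types = 3`) admit
#' the five published arthropod SOPEs — 5 to 13 boxes of 3 to 4 classes
#' over spans of 246 to 1,052 bp — while rejecting isolated hits.
#'
#' @param gap_max Maximum allowed gap (bp) between consecutive hits in a
#'   chain.
#' @param min_boxes Minimum number of member hits.
#' @param min_types Minimum number of distinct box classes.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(gap_max = 450L, min_boxes = 4L, min_types = 3L) {
  gap_max <- as.integer(gap_max); min_boxes <- as.integer(min_boxes)
  min_types <- as.integer(min_types)
  if (is.na(gap_max) || gap_max < 0L) stop("gap_max must be >= 0", call. = FALSE)
  if (is.na(min_boxes) || min_boxes < 1L) stop("min_boxes must be >= 1", call. = FALSE)
  if (is.na(min_types) || min_types < 1L) stop("min_types must be >= 1", call. = FALSE)
  structure(list(gap_max = gap_max, min_boxes = min_boxes,
                 min_types = min_types), class = "cluster_params")
}

#' Call SOPE candidate clusters from box hits
#'
#' Single-linkage chaining along the sequence: hits sorted by start belong
#' to one chain while the gap between the chain's rightmost end and the
#' next hit's start is at most `gap_max`. Chains with fewer than
#' `min_boxes` hits or fewer than `min_types` distinct box classes are
#' discarded. A merged AT-rich (beta) region is a single hit and counts as
#' one box.
#'
#' @param hits A `box_hits` data frame, all from one sequence.
#' @param params A [cluster_params()] object.
#' @return A `sope_calls` data frame with columns `start`, `end`, `span`,
#'   `n_boxes`, `n_types` plus list-columns `counts` (named per-class hit
#'   tallies) and `hits` (the member `box_hits`). Zero rows when nothing
#'   passes.
#' @export
call_clusters <- function(hits, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  empty <- structure(
    data.frame(start = integer(0), end = integer(0), span = integer(0),
               n_boxes = integer(0), n_types = integer(0)),
    class = c("sope_calls", "data.frame"))
  empty$counts <- list(); empty$hits <- list()
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits$start <- as.integer(hits$start); hits$end <- as.integer(hits$end)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  # chain membership via running max end (single linkage on intervals)
  n <- nrow(hits)
  chain <- integer(n); chain[1L] <- 1L
  max_end <- hits$end[1L]
  for (i in seq_len(n)[-1L]) {
    gap <- hits$start[i] - max_end
    chain[i] <- if (gap <= params$gap_max) chain[i - 1L] else chain[i - 1L] + 1L
    max_end <- max(max_end, hits$end[i])
    if (chain[i] != chain[i - 1L]) max_end <- hits$end[i]
  }
  rows <- list()
  for (k in unique(chain)) {
    members <- hits[chain == k, , drop = FALSE]
    counts <- table(members$box)
    n_types <- sum(counts > 0L)
    if (nrow(members) < params$min_boxes || n_types < params$min_types) next
    rows[[length(rows) + 1L]] <- list(
      start = min(members$start), end = max(members$end),
      n_boxes = nrow(members), n_types = n_types,
      counts = stats::setNames(as.integer(counts), names(counts)),
      hits = members
    )
  }
  if (length(rows) == 0L) return(empty)
  out <- data.frame(
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    n_boxes = vapply(rows, `[[`, 0L, "n_boxes"),
    n_types = vapply(rows, `[[`, 0L, "n_types")
  )
  out$span <- out$end - out$start
  out <- out[, c("start", "end", "span", "n_boxes", "n_types")]
  out$counts <- lapply(rows, `[[`, "counts")
  out$hits <- lapply(rows, `[[`, "hits")
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sope_calls", "data.frame")
  out
}

#' Localize a called cluster relative to the ORF
#'
#' Distances use the gap convention: the number of bases strictly between
#' the element and the codon. A cluster ending where the start codon
#' begins is 0 bp upstream; the published "144 bp upstream of the start
#' codon" corresponds to `orf_start - cluster_end = 144` under half-open
#' coordinates.
#'
#' @param region Length-2 `c(start, end)` of the cluster, 0-based
#'   half-open, in transcript coordinates.
#' @param orf ORF region `c(start, end)` or an `orf_annotation`.
#' @param seq_length Transcript length in bp.
#' @return A list of class `sope_location`: `utr_side` is one of
#'   `"five_prime"`, `"three_prime"`, `"overlapping_orf"`; for 5'
#'   clusters `upstream_distance` is given; for 3' clusters
#'   `downstream_near` and `downstream_far` (distances of the cluster's
#'   near and far edges from the stop codon).
#' @examples
#' localize_sope(c(10, 156), c(300, 600), 1000)  # 144 bp upstream
#' localize_sope(c(503, 749), c(100, 500), 1000) # 3 to 249 bp downstream
#' @export
localize_sope <- function(region, orf, seq_length) {
  if (inherits(orf, "orf_annotation")) orf <- orf$orf
  region <- as.integer(region); orf <- as.integer(orf)
  seq_length <- as.integer(seq_length)
  if (region[1L] < 0L || region[1L] > region[2L] || region[2L] > seq_length) {
    stop("cluster region out of sequence bounds", call. = FALSE)
  }
  out <- if (region[2L] <= orf[1L]) {
    list(utr_side = "five_prime",
         upstream_distance = orf[1L] - region[2L])
  } else if (region[1L] >= orf[2L]) {
    list(utr_side = "three_prime",
         downstream_near = region[1L] - orf[2L],
         downstream_far = region[2L] - orf[2L])
  } else {
    list(utr_side = "overlapping_orf")
  }
  class(out) <- "sope_location"
  out
}

#' @export
format.sope_location <- function(x, ...) {
  switch(x$utr_side,
    five_prime = sprintf("5' UTR, %d bp upstream of the start codon",
                         x$upstream_distance),
    three_prime = sprintf("3' UTR, between %d bp and %d bp downstream of the stop codon",
                          x$downstream_near, x$downstream_far),
    overlapping_orf = "overlapping the ORF")
}

#' @export
print.sope_location <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.sope_calls <- function(x, ...) {
  cat(sprintf("%d SOPE candidate cluster(s)\n", nrow(x)))
  if (nrow(x) > 0L) {
    show <- x[, c("start", "end", "span", "n_boxes", "n_types")]
    show$composition <- vapply(x$counts, function(cts) {
      paste(sprintf("%s:%d", names(cts), cts), collapse = " ")
    }, "")
    print.data.frame(show, ...)
  }
  invisible(x)
}
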