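# Synthetic transcripts and proteins with planted ground truth.
#
# The generator emulates what the scanner assumes about real data: random
# DNA backgrounds of configurable base composition carrying planted box
# instances at known UTR offsets, ORFs free of internal in-frame stops,
# and proteins whose C-terminal 16-mer matches the ASH reference at an
# exact, chosen number of positions with the Ase motif present or absent
# by construction.

#' Random DNA of given length and GC content
#'
#' Independent draws with `P(G) = P(C) = gc/2` and `P(A) = P(T) =
#' (1-gc)/2`. Identical `(length, gc, seed)` give identical output; the
#' caller's RNG state is untouched.
#'
#' @param length Number of bases (`>= 0`).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
random_dna <- function(length, gc = 0.5, seed = 1L) {
  length <- as.integer(length)
  stopifnot(length >= 0L, gc >= 0, gc <= 1)
  if (length == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  .with_seed(seed, paste(sample(names(p), length, replace = TRUE, prob = p),
                         collapse = ""))
}

# random protein body over the 20 standard residues
.random_protein <- function(length, seed) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  if (length <= 0L) return("")
  .with_seed(seed, paste(sample(aa, length, replace = TRUE), collapse = ""))
}

#' Plan the planted content of a synthetic UTR
#'
#' @param utr_side `"five_prime"` or `"three_prime"`: which UTR carries
#'   the planted boxes.
#' @param planted_boxes Data frame with columns `box` (class label),
#'   `offset` (0-based start within the designated UTR) and `instance`
#'   (concrete DNA text). May have zero rows.
#' @param utr_length Length (bp) of the designated UTR.
#' @param background_gc GC fraction of the background (default 0.45;
#'   arthropod UTRs lean AT-rich).
#' @param other_utr_length Length of the opposite UTR (default 0).
#' @param defs Box definitions the instances must satisfy.
#' @return An object of class `plant_plan`.
#' @export
plant_plan <- function(utr_side = c("five_prime", "three_prime"),
                       planted_boxes, utr_length, background_gc = 0.45,
                       other_utr_length = 0L, defs = default_box_set()) {
  utr_side <- match.arg(utr_side)
  utr_length <- as.integer(utr_length)
  stopifnot(is.data.frame(planted_boxes),
            all(c("box", "offset", "instance") %in% names(planted_boxes)),
            utr_length >= 0L, background_gc >= 0, background_gc <= 1)
  pb <- planted_boxes[order(planted_boxes$offset), , drop = FALSE]
  if (nrow(pb) > 0L) {
    ends <- pb$offset + nchar(pb$instance)
    if (any(pb$offset < 0L) || any(ends > utr_length)) {
      stop("planted box outside UTR bounds", call. = FALSE)
    }
    if (nrow(pb) > 1L && any(pb$offset[-1L] < ends[-nrow(pb)])) {
      stop("planted boxes overlap", call. = FALSE)
    }
    for (i in seq_len(nrow(pb))) {
      d <- defs[[pb$box[i]]]
      if (is.null(d)) stop("no definition for box '", pb$box[i], "'", call. = FALSE)
      ok <- if (d$kind == "iupac_pattern") {
        nchar(pb$instance[i]) == nchar(d$pattern) &&
          iupac_match(d$pattern, pb$instance[i])
      } else {
        chars <- strsplit(pb$instance[i], "", fixed = TRUE)[[1]]
        nchar(pb$instance[i]) >= d$width &&
          mean(chars %in% c("A", "T")) >= d$min_at_fraction
      }
      if (!ok) {
        stop(sprintf("instance '%s' does not satisfy the %s box definition",
                     pb$instance[i], pb$box[i]), call. = FALSE)
      }
    }
  }
  structure(list(utr_side = utr_side, planted_boxes = pb,
                 utr_length = utr_length, background_gc = background_gc,
                 other_utr_length = as.integer(other_utr_length),
                 defs = defs),
            class = "plant_plan")
}

#' Draw a concrete instance of an IUPAC pattern
#'
#' Fills each degenerate position uniformly at random over its base set
#' (seeded).
#'
#' @param pattern IUPAC pattern.
#' @param seed Integer seed.
#' @return A concrete DNA string matching the pattern.
#' @export
draw_instance <- function(pattern, seed = 1L) {
  .validate_iupac(pattern, "pattern")
  masks <- .seq_to_masks(pattern)
  .with_seed(seed, {
    paste(vapply(masks, function(m) {
      opts <- .BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, ""), collapse = "")
  })
}

# ORF body: ATG + random non-stop codons + TAA
.random_orf <- function(orf_length, seed) {
  stopifnot(orf_length %% 3L == 0L, orf_length >= 6L)
  n_mid <- orf_length / 3L - 2L
  all_codons <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                                .BASES, paste0))
  sense <- setdiff(all_codons, .STOP_CODONS)
  mid <- if (n_mid > 0L) {
    .with_seed(seed, paste(sample(sense, n_mid, replace = TRUE), collapse = ""))
  } else ""
  paste0("ATG", mid, "TAA")
}

#' Generate a synthetic transcript with planted boxes and known truth
#'
#' Emits `[5' UTR][ORF][3' UTR]` with the planned box instances written at
#' their offsets in the designated UTR and seeded random background
#' everywhere else. The ORF begins with `ATG`, contains no in-frame stops
#' and ends with `TAA`; backgrounds that would make the planted ORF not
#' the unique longest ORF of the transcript are rejected and redrawn (at
#' most 100 attempts, then an error).
#'
#' @param plan A [plant_plan()].
#' @param orf_length ORF length in bp (divisible by 3, `>= 6`).
#' @param seed Integer seed.
#' @param id Record identifier.
#' @return A list of class `synthetic_transcript` with elements `record`
#'   (list: `id`, `sequence`, `description`) and `truth` (list: `orf`
#'   region, `hits` data frame in transcript coordinates, `cluster_span`
#'   `c(start, end)` or `NULL`, `utr_side`).
#' @export
synth_transcript <- function(plan, orf_length = 300L, seed = 1L,
                             id = "synthetic_transcript") {
  stopifnot(inherits(plan, "plant_plan"))
  orf_length <- as.integer(orf_length)
  if (orf_length %% 3L != 0L || orf_length < 6L) {
    stop("orf_length must be divisible by 3 and >= 6", call. = FALSE)
  }
  utr5_len <- if (plan$utr_side == "five_prime") plan$utr_length else plan$other_utr_length
  utr3_len <- if (plan$utr_side == "three_prime") plan$utr_length else plan$other_utr_length

  for (attempt in seq_len(100L)) {
    s1 <- .sub_seed(seed, 3L * attempt)
    s2 <- .sub_seed(seed, 3L * attempt + 1L)
    s3 <- .sub_seed(seed, 3L * attempt + 2L)
    utr5 <- random_dna(utr5_len, plan$background_gc, s1)
    utr3 <- random_dna(utr3_len, plan$background_gc, s2)
    orf_seq <- .random_orf(orf_length, s3)

    target <- if (plan$utr_side == "five_prime") utr5 else utr3
    pb <- plan$planted_boxes
    if (nrow(pb) > 0L) {
      for (i in seq_len(nrow(pb))) {
        substr(target, pb$offset[i] + 1L,
               pb$offset[i] + nchar(pb$instance[i])) <- pb$instance[i]
      }
    }
    if (plan$utr_side == "five_prime") utr5 <- target else utr3 <- target

    transcript <- paste0(utr5, orf_seq, utr3)
    orf_region <- c(utr5_len, utr5_len + orf_length)
    inferred <- find_orf(transcript)
    if (!is.null(inferred$orf) && identical(inferred$orf, as.integer(orf_region))) {
      shift <- if (plan$utr_side == "five_prime") 0L else utr5_len + orf_length
      hits <- if (nrow(pb) > 0L) {
        data.frame(box = pb$box, start = pb$offset + shift,
                   end = pb$offset + nchar(pb$instance) + shift,
                   strand = "+", matched = pb$instance,
                   stringsAsFactors = FALSE)
      } else {
        .empty_hits()
      }
      span <- if (nrow(pb) > 0L) c(min(hits$start), max(hits$end)) else NULL
      return(structure(list(
        record = list(id = id, sequence = transcript, description = "synthetic"),
        truth = list(orf = as.integer(orf_region), hits = hits,
                     cluster_span = span, utr_side = plan$utr_side)
      ), class = "synthetic_transcript"))
    }
  }
  stop("could not generate a background in which the planted ORF is the unique longest ORF",
       call. = FALSE)
}

#' Generate a synthetic protein with planted classification evidence
#'
#' The C-terminal 40 residues are `[filler][16-mer]` where the 16-mer
#' equals the ASH reference at exactly `cterm_matches` positions
#' (mismatched positions and the filler use arginine, which matches the
#' reference at no position and belongs to neither Ase-motif amino-acid
#' class). This construction guarantees that the best-scoring tail window
#' is the terminal one with identity exactly `cterm_matches/16`. The body
#' is random; an Ase-motif instance (`VKSEI`) is inserted iff `motif`,
#' and motif-free backgrounds are verified by scanning (redrawn up to 100
#' times).
#'
#' @param label Planted label: `"ASH"`, `"ase"` or `"indeterminate"`.
#'   Must be consistent with `(cterm_matches, motif)` under the default
#'   classification thresholds.
#' @param cterm_matches Integer `k` in `[0, 16]`: positions of the
#'   C-terminal 16-mer that match the reference.
#' @param motif Plant an Ase-motif instance?
#' @param length Protein length in residues (`>= 30`).
#' @param seed Integer seed.
#' @param id Record identifier.
#' @return A list of class `synthetic_protein` with elements `record`
#'   and `truth` (list: `label`, `cterm_matches`, `motif`).
#' @export
synth_protein <- function(label = c("ASH", "ase", "indeterminate"),
                          cterm_matches = 16L, motif = FALSE, length = 200L,
                          seed = 1L, id = "synthetic_protein") {
  label <- match.arg(label)
  k <- as.integer(cterm_matches); length <- as.integer(length)
  stopifnot(k >= 0L, k <= 16L, length >= 30L)
  implied <- if (motif) "ase" else if (k >= 8L) "ASH" else "indeterminate"
  if (label != implied) {
    stop(sprintf("label '%s' inconsistent with cterm_matches = %d, motif = %s (implies '%s')",
                 label, k, motif, implied), call. = FALSE)
  }
  ref_chars <- strsplit(ASH_CTERM_REFERENCE, "", fixed = TRUE)[[1]]
  filler <- "R"  # matches the reference nowhere; in neither amino-acid class
  keep <- .with_seed(.sub_seed(seed, 0L), sort(sample.int(16L, k)))
  planted <- rep(filler, 16L)
  planted[keep] <- ref_chars[keep]
  planted <- paste(planted, collapse = "")
  filler_len <- min(24L, length - 16L)
  body_len <- length - 16L - filler_len

  for (attempt in seq_len(100L)) {
    body <- .random_protein(body_len, .sub_seed(seed, attempt))
    if (motif && body_len >= 5L) {
      at <- max(1L, body_len %/% 2L - 2L)
      substr(body, at, at + 4L) <- "VKSEI"
    }
    protein <- paste0(body, strrep(filler, filler_len), planted)
    hits <- find_ase_motif(protein)
    ok <- if (motif) length(hits) >= 1L else length(hits) == 0L
    if (ok) {
      return(structure(list(
        record = list(id = id, sequence = protein, description = "synthetic"),
        truth = list(label = label, cterm_matches = k, motif = motif)
      ), class = "synthetic_protein"))
    }
  }
  stop("could not generate a protein body with the required Ase-motif status",
       call. = FALSE)
}

# analytic per-window match probability of an IUPAC pattern under an
# i.i.d. background with the given base probabilities
.pattern_match_prob <- function(pattern, base_probs) {
  masks <- .seq_to_masks(pattern)
  prod(vapply(masks, function(m) {
    sum(base_probs[.BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L]])
  }, 0))
}

#' Benchmark planted-cluster recovery of the scan + call pipeline
#'
#' Generates `n_transcripts` synthetic transcripts, each carrying one
#' planted box cluster (concrete instances drawn from the consensus
#' definitions, seeded) in the 5' UTR, runs the scanner and the cluster
#' caller on the UTRs, and measures recovery. A planted cluster counts as
#' recovered when some called cluster covers at least `min_overlap` of its
#' span; a called cluster is a true positive when it recovers a planted
#' one.
#'
#' Background false positives are tallied per IUPAC pattern as
#' strand-match events (windows matching on a given strand) outside the
#' planted instances, together with their analytic expectation under the
#' background base composition and a binomial standard deviation.
#'
#' @param n_transcripts Number of transcripts.
#' @param seed Integer seed.
#' @param utr_length 5' UTR length per transcript (bp).
#' @param orf_length ORF length (bp).
#' @param gc Background GC fraction.
#' @param defs Box definitions.
#' @param params Cluster-calling parameters.
#' @param min_overlap Fraction of the planted span a call must cover.
#' @return A list of class `benchmark_result`: `recall`, `precision`,
#'   `n_planted`, `n_recovered`, `n_called`, `n_true_calls`, and
#'   `background` (data frame per IUPAC pattern: `box`, `observed`,
#'   `expected`, `sd`).
#' @export
benchmark_recovery <- function(n_transcripts = 100L, seed = 1L,
                               utr_length = 600L, orf_length = 300L,
                               gc = 0.45, defs = default_box_set(),
                               params = cluster_params(),
                               min_overlap = 0.9) {
  n_transcripts <- as.integer(n_transcripts)
  stopifnot(n_transcripts >= 1L)
  iupac_defs <- Filter(function(d) d$kind == "iupac_pattern", defs)
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  offsets <- c(10L, 60L, 120L, 170L, 220L)
  boxes <- c("E", "alpha", "beta", "E", "N")

  n_recovered <- 0L; n_called <- 0L; n_true <- 0L
  bg_obs <- stats::setNames(numeric(length(iupac_defs)), names(iupac_defs))
  bg_windows <- bg_obs
  for (i in seq_len(n_transcripts)) {
    si <- .sub_seed(seed, i)
    inst <- vapply(seq_along(boxes), function(j) {
      d <- defs[[boxes[j]]]
      if (d$kind == "iupac_pattern") draw_instance(d$pattern, .sub_seed(si, j))
      else strrep("AT", ceiling(d$width / 2))
    }, "")
    plan <- plant_plan("five_prime",
                       data.frame(box = boxes, offset = offsets,
                                  instance = inst, stringsAsFactors = FALSE),
                       utr_length = utr_length, background_gc = gc,
                       defs = defs)
    st <- synth_transcript(plan, orf_length = orf_length, seed = si,
                           id = sprintf("t%03d", i))
    seq_ <- st$record$sequence
    utrs <- extract_utrs(seq_, st$truth$orf)
    all_calls <- list()
    for (side in c("five_prime", "three_prime")) {
      reg <- utrs[[side]]
      if (is.null(reg)) next
      sub <- substr(seq_, reg[1L] + 1L, reg[2L])
      hits <- scan_boxes(sub, defs)
      if (nrow(hits) > 0L) { hits$start <- hits$start + reg[1L]; hits$end <- hits$end + reg[1L] }
      cl <- call_clusters(hits, params)
      if (nrow(cl) > 0L) all_calls[[side]] <- cl[, c("start", "end")]
    }
    called <- if (length(all_calls) > 0L) do.call(rbind, all_calls) else
      data.frame(start = integer(0), end = integer(0))

    span <- st$truth$cluster_span
    covered <- FALSE
    truth_flags <- logical(nrow(called))
    if (!is.null(span) && nrow(called) > 0L) {
      for (r in seq_len(nrow(called))) {
        ov <- max(0L, min(called$end[r], span[2L]) - max(called$start[r], span[1L]))
        if (ov / (span[2L] - span[1L]) >= min_overlap) truth_flags[r] <- TRUE
      }
      covered <- any(truth_flags)
    }
    n_recovered <- n_recovered + as.integer(covered)
    n_called <- n_called + nrow(called)
    n_true <- n_true + sum(truth_flags)

    # background strand-match accounting on the planted UTR
    utr5 <- substr(seq_, 1L, st$truth$orf[1L])
    planted <- st$truth$hits
    sm <- .seq_to_masks(utr5)
    for (nm in names(iupac_defs)) {
      d <- iupac_defs[[nm]]
      pm <- .seq_to_masks(d$pattern)
      w <- length(pm)
      pos <- 0:(nchar(utr5) - w)
      is_bg <- vapply(pos, function(p0) {
        !any(p0 < planted$end & (p0 + w) > planted$start)
      }, TRUE)
      fwd <- .match_positions(sm, pm, strict = TRUE)
      n_strands <- 1L + as.integer(d$both_strands)
      obs <- sum(fwd %in% pos[is_bg])
      if (d$both_strands) {
        rev_ <- .match_positions(sm, rev(.comp_mask(pm)), strict = TRUE)
        obs <- obs + sum(rev_ %in% pos[is_bg])
      }
      bg_obs[nm] <- bg_obs[nm] + obs
      bg_windows[nm] <- bg_windows[nm] + sum(is_bg) * n_strands
    }
  }
  p <- vapply(iupac_defs, function(d) .pattern_match_prob(d$pattern, base_probs), 0)
  background <- data.frame(
    box = names(iupac_defs),
    observed = as.numeric(bg_obs),
    expected = as.numeric(bg_windows * p),
    sd = as.numeric(sqrt(bg_windows * p * (1 - p))),
    stringsAsFactors = FALSE
  )
  rownames(background) <- NULL
  structure(list(
    recall = n_recovered / n_transcripts,
    precision = if (n_called > 0L) n_true / n_called else NA_real_,
    n_planted = n_transcripts, n_recovered = n_recovered,
    n_called = n_called, n_true_calls = n_true,
    background = background
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Planted-cluster recovery over %d transcripts\n", x$n_planted))
  cat(sprintf("  recall: %.3f (%d/%d)\n", x$recall, x$n_recovered, x$n_planted))
  cat(sprintf("  precision: %.3f (%d/%d called)\n", x$precision,
              x$n_true_calls, x$n_called))
  cat("  background strand-match events vs analytic expectation:\n")
  print(x$background, row.names = FALSE)
  invisible(x)
}
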