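test_that("iupac_match applies the subset rule", {
  expect_true(iupac_match("CANNTG", "CAGCTG"))
  expect_false(iupac_match("CANNTG", "CAGCTA"))
  expect_true(iupac_match("NNNNNN", "ACGTAC"))
  # N in the window matches only an N-compatible pattern letter
  expect_true(iupac_match("CANNTG", "CANNTG"))
  expect_false(iupac_match("CAGCTG", "CANCTG"))
  expect_true(iupac_match("GGGWWWNCC", "GGGATAACC"))
  expect_error(iupac_match("CANNTG", "CAGCT"), "equal length")
  expect_error(iupac_match("CAXNTG", "CAGCTG"), "invalid IUPAC")
})

test_that("scan_iupac_boxes finds stranded hits in forward coordinates", {
  hits <- scan_iupac_boxes("TTCAGCTGTT", default_box_set()["E"])
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 8L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$matched, "CAGCTG")

  # reverse complement of CTGGTG is CACCAG, an N-box instance
  hits <- scan_iupac_boxes("CTGGTG", default_box_set()["N"])
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(c(hits$start, hits$end), c(0L, 6L))

  expect_equal(nrow(scan_iupac_boxes("", default_box_set()["E"])), 0L)
})

test_that("palindromic sites yield a single forward-strand hit", {
  hits <- scan_iupac_boxes("ACACGTGA", default_box_set()["E"])
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_identical(hits$matched, revcomp(hits$matched))
})

test_that("strict ambiguity policy suppresses N-run hits; wildcard relaxes it", {
  seq_ <- "TTCAGCNGTT"  # E-box window with N at a constrained position
  e <- default_box_set()["E"]
  expect_equal(nrow(scan_iupac_boxes(seq_, e)), 0L)
  relaxed <- scan_iupac_boxes(seq_, e, ambiguity = "wildcard")
  expect_true(2L %in% relaxed$start)
  # an N at a pattern-N position is compatible even under the subset rule
  expect_equal(unique(scan_iupac_boxes("TTCANCTGTT", e)$start), 2L)
})

test_that("scan_at_rich finds and merges qualifying windows", {
  beta <- default_box_set()$beta
  hits <- scan_at_rich("ATATATAT", beta)
  expect_equal(c(hits$start, hits$end), c(0L, 8L))

  expect_equal(nrow(scan_at_rich("GCGCGCGC", beta)), 0L)

  # oracle (exhaustive window evaluation): windows [1,9) and [11,19) have
  # AT fraction 7/8 >= 0.85 and merge with their neighbours
  hits <- scan_at_rich("ATATATATGGGGATATATAT", beta)
  expect_equal(hits$start, c(0L, 11L))
  expect_equal(hits$end, c(9L, 20L))
  expect_true(all(hits$strand == "+"))

  # width exceeding sequence length is an empty result, not an error
  expect_equal(nrow(scan_at_rich("ATAT", beta)), 0L)
})

test_that("default box set has the four published classes", {
  defs <- default_box_set()
  expect_setequal(names(defs), c("E", "alpha", "beta", "N"))
  expect_true(iupac_match(defs$E$pattern, "CAGCTG"))
  expect_equal(defs$N$pattern, "CACNAG")
  expect_equal(defs$beta$kind, "at_rich_window")
  for (d in defs) expect_s3_class(d, "box_definition")
})

test_that("box_definition enforces its invariants", {
  expect_error(box_definition("E", "iupac_pattern", pattern = ""), "non-empty")
  expect_error(box_definition("E", "iupac_pattern", pattern = "CAXNTG"), "invalid")
  expect_error(box_definition("b", "at_rich_window", width = 3, min_at_fraction = 0.9), ">= 4")
  expect_error(box_definition("b", "at_rich_window", width = 8, min_at_fraction = 0), "min_at_fraction")
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  defs <- Filter(function(d) d$kind == "iupac_pattern", default_box_set())
  for (s in 1:20) {
    seq_ <- random_dna(150 + 17 * s, 0.45, s)
    expect_identical(as_plain_df(scan_iupac_boxes(seq_, defs)),
                     oracle_scan(seq_, defs))
  }
})

test_that("hits stay in bounds and are duplicate-free", {
  defs <- default_box_set()
  for (s in 1:10) {
    seq_ <- random_dna(400, 0.45, s + 500)
    hits <- scan_boxes(seq_, defs)
    expect_true(all(hits$start >= 0L & hits$end <= nchar(seq_)))
    key <- paste(hits$box, hits$start, hits$end, hits$strand)
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("scanning the reverse complement mirrors the hit set", {
  defs <- Filter(function(d) d$kind == "iupac_pattern", default_box_set())
  for (s in 1:10) {
    seq_ <- random_dna(300, 0.5, s + 900)
    L <- nchar(seq_)
    fwd <- scan_iupac_boxes(seq_, defs)
    rev_ <- scan_iupac_boxes(revcomp(seq_), defs)
    mirrored <- data.frame(
      box = rev_$box, start = L - rev_$end, end = L - rev_$start,
      stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$box), ]
    orig <- as_plain_df(fwd)[order(fwd$start, fwd$box), c("box", "start", "end")]
    rownames(mirrored) <- rownames(orig) <- NULL
    expect_equal(orig, mirrored)
  }
})

test_that("false-positive density on random DNA matches the per-window match probability", {
  # CANNTG: 1/256 per window per strand on uniform random DNA
  n_hits <- 0L; n_windows <- 0L
  e <- default_box_set()$E
  for (s in 1:40) {
    seq_ <- random_dna(1000, 0.5, s + 2000)
    hits <- scan_iupac_boxes(seq_, list(e))
    # count strand-match events: palindromic "+" hits match on both strands
    pal <- hits$matched == vapply(hits$matched, revcomp, "")
    n_hits <- n_hits + nrow(hits) + sum(pal)
    n_windows <- n_windows + 2L * (nchar(seq_) - 5L)
  }
  p <- 1 / 256
  expect_lt(abs(n_hits - n_windows * p), 4 * sqrt(n_windows * p * (1 - p)) + 1)
})
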