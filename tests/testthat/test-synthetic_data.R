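test_that("random_dna is seeded, composition-controlled and pure", {
  expect_equal(random_dna(0, 0.5, 1), "")
  expect_identical(random_dna(100, 0.5, 42), random_dna(100, 0.5, 42))
  expect_false(identical(random_dna(100, 0.5, 42), random_dna(100, 0.5, 43)))
  expect_true(grepl("^[GC]+$", random_dna(200, 1.0, 7)))
  expect_true(grepl("^[AT]+$", random_dna(200, 0.0, 7)))
  # generator does not disturb the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(random_dna(50, 0.5, 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("draw_instance yields concrete matches of the pattern", {
  for (s in 1:20) {
    inst <- draw_instance("GGGWWWNCC", s)
    expect_true(iupac_match("GGGWWWNCC", inst))
    expect_true(grepl("^[ACGT]+$", inst))
  }
  expect_identical(draw_instance("CANNTG", 5), draw_instance("CANNTG", 5))
})

test_that("plant_plan validates offsets, overlap and instance identity", {
  pb <- data.frame(box = "E", offset = 10L, instance = "CAGCTG",
                   stringsAsFactors = FALSE)
  expect_s3_class(plant_plan("five_prime", pb, 100), "plant_plan")
  expect_error(plant_plan("five_prime", transform(pb, offset = 98L), 100),
               "outside UTR bounds")
  two <- data.frame(box = c("E", "E"), offset = c(10L, 13L),
                    instance = "CAGCTG", stringsAsFactors = FALSE)
  expect_error(plant_plan("five_prime", two, 100), "overlap")
  expect_error(plant_plan("five_prime", transform(pb, instance = "CAGCTA"), 100),
               "does not satisfy")
})

test_that("synth_transcript plants boxes at known coordinates with a valid ORF", {
  plan <- plant_plan("five_prime", data.frame(
    box = c("E", "alpha", "beta", "E"),
    offset = c(10L, 60L, 120L, 170L),
    instance = c("CAGCTG", "GGGATAACC", "ATATATAT", "CACGTG"),
    stringsAsFactors = FALSE), utr_length = 250)
  st <- synth_transcript(plan, orf_length = 300, seed = 42)
  expect_equal(st$truth$cluster_span, c(10L, 176L))
  expect_equal(st$truth$orf, c(250L, 550L))
  # the planted ORF is the unique longest ORF of the emitted transcript
  expect_equal(find_orf(st$record$sequence)$orf, st$truth$orf)
  # planted instances sit at their recorded coordinates
  seq_ <- st$record$sequence
  for (i in seq_len(nrow(st$truth$hits))) {
    h <- st$truth$hits[i, ]
    expect_equal(substr(seq_, h$start + 1, h$end), h$matched)
  }
  # the scanner finds every planted hit (AT-rich regions may merge with
  # adjacent AT-rich background, so beta hits need only contain the plant)
  found <- scan_boxes(substr(seq_, 1, 250), default_box_set())
  for (i in seq_len(nrow(st$truth$hits))) {
    h <- st$truth$hits[i, ]
    same <- found[found$box == h$box & found$start <= h$start &
                    found$end >= h$end, , drop = FALSE]
    expect_gte(nrow(same), 1L)
  }
})

test_that("synth_transcript is deterministic and handles empty plans", {
  plan <- plant_plan("three_prime", data.frame(
    box = "E", offset = 5L, instance = "CAGCTG", stringsAsFactors = FALSE),
    utr_length = 100, other_utr_length = 30)
  a <- synth_transcript(plan, 120, seed = 5)
  b <- synth_transcript(plan, 120, seed = 5)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$truth, b$truth)

  empty <- plant_plan("five_prime", data.frame(
    box = character(0), offset = integer(0), instance = character(0),
    stringsAsFactors = FALSE), utr_length = 80)
  st <- synth_transcript(empty, 90, seed = 2)
  expect_equal(nrow(st$truth$hits), 0L)
  expect_null(st$truth$cluster_span)
})

test_that("synth_protein reproduces the planted evidence exactly", {
  cases <- list(list("ASH", 16L, FALSE), list("ASH", 8L, FALSE),
                list("ase", 5L, TRUE), list("ase", 12L, TRUE),
                list("indeterminate", 0L, FALSE), list("indeterminate", 7L, FALSE))
  for (cs in cases) {
    sp <- synth_protein(cs[[1]], cs[[2]], cs[[3]], length = 200, seed = 7)
    ev <- protein_evidence(sp$record$sequence)
    expect_equal(ev$label, cs[[1]])
    expect_equal(ev$cterm$identity, cs[[2]] / 16)
    expect_equal(length(ev$ase_motif_hits) > 0, cs[[3]])
  }
  expect_error(synth_protein("ASH", 5, FALSE), "inconsistent")
  expect_error(synth_protein("ase", 5, FALSE), "inconsistent")
  a <- synth_protein("ase", 9, TRUE, 200, 31)
  b <- synth_protein("ase", 9, TRUE, 200, 31)
  expect_identical(a$record$sequence, b$record$sequence)
})

test_that("short synthetic proteins still carry exact planted identity", {
  sp <- synth_protein("indeterminate", 3, FALSE, length = 30, seed = 2)
  expect_equal(nchar(sp$record$sequence), 30L)
  expect_equal(protein_evidence(sp$record$sequence)$cterm$identity, 3 / 16)
})

test_that("benchmark_recovery is seed-reproducible and recovers exact plants", {
  a <- benchmark_recovery(10, seed = 3)
  b <- benchmark_recovery(10, seed = 3)
  expect_identical(a$recall, b$recall)
  expect_identical(a$background, b$background)
  expect_equal(a$recall, 1.0)
})
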