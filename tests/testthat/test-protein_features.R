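REF <- ASH_CTERM_REFERENCE

test_that("cterm_identity measures the terminal domain exactly", {
  m <- cterm_identity(paste0(strrep("G", 60), REF))
  expect_equal(m$identity, 1.0)
  expect_equal(m$percent, 100)
  expect_equal(m$matched, REF)

  # final three positions differ: 13/16
  m <- cterm_identity(paste0(strrep("G", 60), "PDDEELLDYISWWAAA"))
  expect_equal(m$identity, 13 / 16)
  expect_equal(m$percent, 81)

  expect_null(cterm_identity("MKLQSTVWYP"))
})

test_that("display percent truncates toward zero", {
  # 10/16 = 62.5% prints as 62
  ten <- paste0(substr(REF, 1, 10), strrep("R", 6))
  m <- cterm_identity(paste0(strrep("G", 40), ten))
  expect_equal(m$identity, 10 / 16)
  expect_equal(m$percent, 62)
  # 9/16 = 56.25% prints as 56; 5/16 = 31.25% as 31
  expect_equal(trunc(100 * 9 / 16), 56)
  expect_equal(trunc(100 * 5 / 16), 31)
})

test_that("cterm_identity is symmetric and maximal only at identity", {
  a <- "PDDEELLDYISWWQQQ"; b <- "PDDEELLDYISWWAAA"
  expect_equal(cterm_identity(a, reference = b)$identity,
               cterm_identity(b, reference = a)$identity)
  expect_lt(cterm_identity(b, reference = a)$identity, 1)
  expect_equal(cterm_identity(a, reference = a)$identity, 1)
})

test_that("cterm_identity ignores residues outside the search tail", {
  tail40 <- paste0(strrep("R", 24), REF)
  for (s in 1:5) {
    body <- synth_protein("ASH", 16, FALSE, 120, s)$record$sequence
    p <- paste0(substr(body, 1, 80), tail40)
    expect_equal(cterm_identity(p)$identity, 1.0)
    expect_equal(cterm_identity(p)$window, c(nchar(p) - 16, nchar(p)))
  }
})

test_that("find_ase_motif matches hydrophobic-K-polar-E-hydrophobic windows", {
  expect_equal(find_ase_motif("AAVKSEIAA"), 2L)
  expect_equal(find_ase_motif("AAVRSEIAA"), integer(0))
  expect_equal(find_ase_motif(""), integer(0))
  # overlapping instances are all reported
  expect_equal(find_ase_motif("VKSEVKSEV"), c(0L, 4L))
  # custom classes are honoured
  cls <- aa_class_config(hydrophobic = "V", polar = "S")
  expect_equal(find_ase_motif("AKSEV", cls), integer(0))
  expect_equal(find_ase_motif("VKSEV", cls), 0L)
})

test_that("motif density on random residues matches the analytic rate", {
  # uniform residues: p = (9/20)(1/20)(8/20)(1/20)(9/20)
  p <- 9 * 1 * 8 * 1 * 9 / 20^5
  n_hits <- 0L; n_windows <- 0L
  for (s in 1:100) {
    prot <- sopescan:::.random_protein(505L, s)
    n_hits <- n_hits + length(find_ase_motif(prot))
    n_windows <- n_windows + 501L
  }
  expect_lt(abs(n_hits - n_windows * p), 4 * sqrt(n_windows * p) + 1)
})

test_that("classify_protein follows the ase > ASH > indeterminate rule", {
  perfect <- cterm_identity(paste0(strrep("G", 40), REF))
  weak <- cterm_identity(paste0(strrep("G", 40), substr(REF, 1, 5), strrep("R", 11)))
  expect_equal(classify_protein(perfect, integer(0)), "ASH")
  expect_equal(classify_protein(weak, c(3L)), "ase")
  expect_equal(classify_protein(weak, integer(0)), "indeterminate")
  expect_equal(classify_protein(NULL, integer(0)), "indeterminate")
  # boundary: exactly 50% identity is an ASH call
  half <- cterm_identity(paste0(strrep("G", 40), substr(REF, 1, 8), strrep("R", 8)))
  expect_equal(half$identity, 0.5)
  expect_equal(classify_protein(half, integer(0)), "ASH")
})

test_that("classification is monotone in the motif and the threshold", {
  m <- cterm_identity(paste0(strrep("G", 40), REF))
  # adding a motif hit never moves a label away from ase
  for (hits in list(integer(0), 1L)) {
    lbl <- classify_protein(m, hits)
    if (length(hits) > 0) expect_equal(lbl, "ase")
  }
  # raising cterm_min never converts indeterminate to ASH
  weak <- cterm_identity(paste0(strrep("G", 40), substr(REF, 1, 7), strrep("R", 9)))
  for (thr in c(0.3, 0.5, 0.8)) {
    lbl_low <- classify_protein(weak, integer(0), cterm_min = thr)
    lbl_high <- classify_protein(weak, integer(0), cterm_min = thr + 0.1)
    expect_false(lbl_low == "indeterminate" && lbl_high == "ASH")
  }
})

test_that("integrate_gene_call implements the evidence truth table", {
  expect_equal(integrate_gene_call("ASH", TRUE), "ancestral_ASH_ase_like")
  expect_equal(integrate_gene_call("indeterminate", TRUE), "ase_like")
  expect_equal(integrate_gene_call("ase", TRUE), "ase_like")
  expect_equal(integrate_gene_call("ASH", FALSE), "proneural_ASH")
  expect_equal(integrate_gene_call("ase", FALSE), "ase_like")
  expect_equal(integrate_gene_call("indeterminate", FALSE), "indeterminate")
  expect_error(integrate_gene_call("bogus", TRUE))
})

test_that("protein_evidence bundles the measurements consistently", {
  sp <- synth_protein("ase", 5, TRUE, 200, 3)
  ev <- protein_evidence(sp$record$sequence)
  expect_equal(ev$label, "ase")
  expect_equal(ev$cterm$identity, 5 / 16)
  expect_gte(length(ev$ase_motif_hits), 1L)
})
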