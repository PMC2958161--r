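test_that("read_fasta parses records in order, upper-cases and splits headers", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a first record", "acgt", ">b", "NNNN"), f)
  recs <- read_fasta(f, "dna")
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$sequence, c("ACGT", "NNNN"))
  expect_equal(recs$description, c("first record", ""))
})

test_that("read_fasta handles wrapped lines and empty files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGTAC", "GTACGT"), f)
  expect_equal(read_fasta(f, "dna")$sequence, "ACGTACGTACGT")
  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f, "dna")), 0L)
})

test_that("read_fasta rejects illegal characters, naming record and position", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGU"), f)
  expect_error(read_fasta(f, "dna"), "record 'a'.*'U'.*position 4")
  writeLines(c(">p", "MKLQ*"), f)
  expect_equal(read_fasta(f, "protein")$sequence, "MKLQ*")
})

test_that("FASTA write/read round-trip preserves ids and sequences", {
  recs <- data.frame(
    id = sprintf("s%d", 1:5),
    sequence = vapply(1:5, function(i) random_dna(40 + 13 * i, 0.5, i), ""),
    description = c("", "desc one", "", "x y z", ""),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f, width = 17L)
  back <- read_fasta(f, "dna")
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$description, recs$description)
})

test_that("find_orf infers the longest ATG..stop frame, ties to smallest start", {
  ann <- find_orf("AAATGAAATAA")
  expect_equal(ann$orf, c(2L, 11L))
  expect_equal(ann$source, "inferred")

  expect_null(find_orf("CCCCCC")$orf)
  expect_equal(find_orf("CCCCCC")$source, "none")

  # two ORFs of equal length: the earlier start wins
  two <- paste0("ATGAAATAA", "C", "ATGCCCTAA")
  expect_equal(find_orf(two)$orf, c(0L, 9L))

  # longest wins regardless of order
  seq_ <- paste0("ATGTAA", "C", "ATGAAAAAATAG")
  expect_equal(find_orf(seq_)$orf, c(7L, 19L))
})

test_that("ambiguity codes are never accepted as start or stop codons", {
  # TAN is not a stop; the only complete ORF is absent
  expect_null(find_orf("ATGAAATAN")$orf)
  # N-containing ATG-like codon is not a start
  expect_null(find_orf("ATNAAATAA")$orf)
  # ambiguity inside the ORF body is fine
  expect_equal(find_orf("ATGNNNTAA")$orf, c(0L, 9L))
})

test_that("find_orf validates and passes through provided coordinates", {
  ann <- find_orf("ATGTAACCC", provided = c(0L, 6L))
  expect_equal(ann$orf, c(0L, 6L))
  expect_equal(ann$source, "provided")
  expect_error(find_orf("ATGTAACCC", provided = c(0L, 7L)), "divisible")
  expect_error(find_orf("ATGTAA", provided = c(0L, 9L)), "bounds")
})

test_that("extract_utrs partitions the transcript", {
  u <- extract_utrs("AAATGAAATAA", c(2L, 11L))
  expect_equal(u$five_prime, c(0L, 2L))
  expect_null(u$three_prime)

  u <- extract_utrs(strrep("A", 80), c(5L, 14L))
  expect_equal(u$five_prime, c(0L, 5L))
  expect_equal(u$three_prime, c(14L, 80L))

  u <- extract_utrs("ATGTAA", c(0L, 6L))
  expect_null(u$five_prime)
  expect_null(u$three_prime)
})

test_that("UTRs and ORF are disjoint and cover the whole record", {
  for (s in 1:10) {
    seq_ <- paste0(random_dna(20, 0.5, s), "ATG",
                   strrep("GCA", 10), "TAA", random_dna(15, 0.5, s + 100))
    ann <- find_orf(seq_)
    u <- extract_utrs(seq_, ann)
    segs <- Filter(Negate(is.null), list(u$five_prime, ann$orf, u$three_prime))
    segs <- segs[order(vapply(segs, `[[`, 0L, 1L))]
    expect_equal(segs[[1]][1], 0L)
    expect_equal(segs[[length(segs)]][2], nchar(seq_))
    for (i in seq_len(length(segs) - 1)) {
      expect_equal(segs[[i]][2], segs[[i + 1]][1])
    }
  }
})

test_that("write_bed6 emits 0-based half-open six-column rows", {
  h <- scan_iupac_boxes("TTCAGCTGTT", default_box_set()["E"])
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed6(h, f, chrom = "tx1")
  bed <- utils::read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(unlist(bed[1, ], use.names = FALSE),
               c("tx1", "2", "8", "E", "0", "+"))
})
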