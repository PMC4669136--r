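# Sequence primitives and the pairwise alignment engine.

test_that("reverse complement handles IUPAC codes and rejects junk", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  # HinfI site is its own reverse complement
  expect_equal(reverse_complement("GANTC"), "GANTC")
  expect_equal(reverse_complement("RY"), "RY")
  expect_equal(reverse_complement("acgtn"), "NACGT")
  err <- tryCatch(reverse_complement("ACXGT"), error = conditionMessage)
  expect_match(err, "'X'")
  expect_match(err, "position 3")
  # involution on random sequences
  set.seed(1)
  for (i in 1:20) {
    s <- random_dna(sample(5:60, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("IUPAC pattern matching follows the code table", {
  expect_true(iupac_match("GANTC", "GATTC"))
  expect_false(iupac_match("GANTC", "GACTA"))
  expect_true(iupac_match("RY", "AC"))
  expect_false(iupac_match("RY", "CA"))
  expect_true(iupac_match("N", "G"))
  expect_error(iupac_match("GAN", "GA"), "equal length")
})

test_that("AT content excludes ambiguity codes and flags undefined input", {
  expect_equal(at_content("ATAT"), 1.0)
  expect_equal(at_content("ACGT"), 0.5)
  expect_equal(at_content("ANNT"), 1.0)      # N dropped from both sides
  expect_true(is.na(at_content("NNNN")))
  expect_error(at_content(""), "empty")
  # AT + GC fractions sum to one on unambiguous sequences
  set.seed(2)
  for (i in 1:10) {
    s <- random_dna(50)
    gc <- 1 - at_content(s)
    expect_equal(at_content(s) + gc, 1.0)
  }
})

test_that("global alignment matches the exhaustive enumeration oracle", {
  set.seed(3)
  expect_equal(align("ACGT", "ACGT")$score, 4)
  a <- align("ACGT", "AGGT")
  expect_equal(a$score, 2)
  expect_equal(a$matches, 3)
  expect_equal(a$mismatches, 1)
  for (i in 1:40) {
    x <- random_dna(sample(2:6, 1))
    y <- random_dna(sample(2:6, 1))
    expect_equal(align(x, y)$score, enum_align_score(x, y),
                 info = paste(x, y))
  }
  # a couple of longer cases at the 8-mer limit
  for (i in 1:3) {
    x <- random_dna(8); y <- random_dna(8)
    expect_equal(align(x, y)$score, enum_align_score(x, y),
                 info = paste(x, y))
  }
})

test_that("alignment invariants hold in all modes", {
  set.seed(4)
  for (i in 1:25) {
    x <- random_dna(sample(8:30, 1))
    y <- random_dna(sample(8:30, 1))
    mode <- sample(c("global", "semiglobal", "wraparound"), 1)
    a <- align(x, y, mode = mode)
    # equal-length gapped strings, no gap-gap column
    expect_equal(nchar(a$aligned_a), nchar(a$aligned_b))
    ca <- strsplit(a$aligned_a, "")[[1]]; cb <- strsplit(a$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
    # column counts add up
    expect_equal(a$matches + a$mismatches + a$gap_columns,
                 nchar(a$aligned_a))
    # degapping recovers the first input in every mode
    expect_equal(gsub("-", "", a$aligned_a), x)
    if (mode != "wraparound") expect_equal(gsub("-", "", a$aligned_b), y)
    # reported score equals the score recomputed from the aligned strings
    expect_equal(a$score, satkit:::.score_from_alignment(a))
  }
  expect_error(align("", "ACGT"), "empty")
})

test_that("wraparound alignment counts origin traversals on tandem arrays", {
  set.seed(5)
  m <- random_dna(43)
  a <- align(strrep(m, 3), m, mode = "wraparound")
  expect_equal(nrow(a$segments), 3)
  expect_equal(a$n_traversals, 3)
  expect_equal(a$mismatches, 0)
  expect_equal(a$gap_columns, 0)
  # phase-shifted array: partial flanking monomers, complete core
  arr <- substr(strrep(m, 4), 20, 150)
  b <- align(arr, m, mode = "wraparound")
  expect_equal(b$n_traversals, 2)
  expect_equal(sum(b$segments$read_end - b$segments$read_start), nchar(arr))
})

test_that("pairwise identity is symmetric, rc-invariant, and policy-aware", {
  expect_equal(pairwise_identity("ACGT", "ACGT")$value, 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA")$value, 0.75)
  set.seed(6)
  for (i in 1:15) {
    x <- random_dna(sample(10:40, 1)); y <- random_dna(sample(10:40, 1))
    i1 <- pairwise_identity(x, y); i2 <- pairwise_identity(y, x)
    expect_equal(i1$value, i2$value)
    # simultaneous reverse complement leaves identity unchanged
    i3 <- pairwise_identity(reverse_complement(x), reverse_complement(y))
    expect_equal(i1$value, i3$value)
  }
  # gap policy changes the denominator
  p1 <- pairwise_identity("AAAATTTT", "AAAATT")
  p2 <- pairwise_identity("AAAATTTT", "AAAATT",
                          gap_policy = "count_gaps_as_mismatch")
  expect_equal(p1$n_compared_columns, 6)
  expect_equal(p2$n_compared_columns, 8)
  expect_true(p2$value < p1$value)
})

test_that("global alignment score agrees with Biostrings on random pairs", {
  set.seed(7)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    x <- random_dna(sample(10:50, 1)); y <- random_dna(sample(10:50, 1))
    ref <- Biostrings::pairwiseAlignment(
      x, y, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(align(x, y)$score, ref)
  }
})

test_that("FASTA/FASTQ round trips and EMBL parsing work", {
  seqs <- c(r1 = "ACGTACGTAA", r2 = "TTTTGGGGCC")
  fa <- tempfile(fileext = ".fasta"); fq <- tempfile(fileext = ".fastq")
  write_fasta(seqs, fa)
  expect_equal(read_seqs(fa), seqs)
  write_fastq(seqs, fq)
  expect_equal(read_seqs(fq), seqs)
  embl <- tempfile(fileext = ".embl")
  writeLines(c(
    "ID   LN000001; SV 1; linear; genomic DNA; STD; PLN; 10 BP.",
    "AC   LN000001;",
    "SQ   Sequence 10 BP;",
    "     acgtacgtaa                                                      10",
    "//",
    "ID   LN000002; SV 1; linear; genomic DNA; STD; PLN; 8 BP.",
    "SQ   Sequence 8 BP;",
    "     ttttgggg                                                         8",
    "//"), embl)
  got <- read_embl(embl)
  expect_equal(got, c(LN000001 = "ACGTACGTAA", LN000002 = "TTTTGGGG"))
})
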