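# Read nomination, period detection, monomer extraction, digests.

test_that("repetitiveness scores follow direct k-mer counting", {
  rd <- strrep("ACGT", 50)
  nom <- nominate_reads(c(tandem = rd), k = 8)
  # 193 k-mers, 4 distinct
  expect_equal(nom$repetitiveness, 1 - 4 / 193)
  set.seed(1)
  rnd <- random_dna(300)
  nom2 <- nominate_reads(c(r = rnd), k = 11)
  expect_equal(nom2$repetitiveness, 0)
  # array read outranks background reads
  w <- small_world(seed = 51, n_reads = 300)
  nom3 <- nominate_reads(w$lib$reads, k = 11, top_fraction = 0.05)
  fam <- setNames(w$lib$read_truth$family, w$lib$read_truth$read_id)
  expect_true(fam[nom3$read_id[1]] != "background")
  # short reads score zero and are flagged
  nom4 <- nominate_reads(c(s = "ACGT"), k = 8)
  expect_true(nom4$too_short)
  expect_equal(nom4$repetitiveness, 0)
})

test_that("detect_period recovers exact and divergent periods", {
  p <- detect_period(strrep("ACGTA", 20), p_min = 3, p_max = 40)
  expect_equal(p$period, 5L)
  expect_equal(p$score, 1.0)
  # harmonics of an exact repeat are flagged, not reported
  expect_true(10 %in% p$harmonics)

  set.seed(2)
  # no-period on random sequence
  r <- detect_period(random_dna(400))
  expect_true(r$no_period)
  expect_true(is.na(r$period))
})

test_that("period detection handles divergence, HOR harmonics and rc", {
  w <- small_world(seed = 61, n_reads = 2000)
  tr <- w$lib$read_truth
  r43 <- w$lib$reads[tr$read_id[tr$family == "sat43" & tr$length >= 300]]
  r177 <- w$lib$reads[tr$read_id[tr$family == "sat177" & tr$length >= 400]]
  ok43 <- 0; ok177 <- 0
  for (rd in r43[1:10]) {
    p <- detect_period(rd)
    if (!p$no_period && abs(p$period - 43) <= 1) ok43 <- ok43 + 1
    # the dimer gives a harmonic at twice the monomer
    if (!p$no_period && p$period == 43) expect_true(86 %in% p$harmonics)
    # invariant under reverse complement
    prc <- detect_period(reverse_complement(rd))
    expect_equal(p$period, prc$period)
  }
  for (rd in r177[1:10]) {
    p <- detect_period(rd)
    if (!p$no_period && abs(p$period - 177) <= 1) ok177 <- ok177 + 1
  }
  expect_gte(ok43, 9)
  expect_gte(ok177, 9)
})

test_that("extract_monomers splits exact arrays and respects strand", {
  set.seed(3)
  m <- random_dna(43)
  mon <- extract_monomers(strrep(m, 4), m, read_id = "r")
  expect_equal(nrow(mon), 4)
  expect_equal(mon$ordinal, 0:3)
  expect_true(all(mon$completeness == 1))
  expect_true(all(mon$seq == m))
  expect_true(all(mon$strand == "+"))

  # reverse-complemented array: strand -, sequences in consensus orientation
  mon2 <- extract_monomers(reverse_complement(strrep(m, 3)), m,
                           read_id = "r2")
  expect_equal(nrow(mon2), 3)
  expect_true(all(mon2$strand == "-"))
  expect_true(all(mon2$seq == m))

  # a non-family read is rejected with a reason
  rej <- extract_monomers(random_dna(200), m, read_id = "bg")
  expect_equal(nrow(rej), 0)
  expect_match(attr(rej, "reason"), "identity")

  # re-concatenating complete monomers reconstructs the read interior
  arr <- substr(strrep(m, 5), 11, 43 * 5 - 7)
  mon3 <- extract_monomers(arr, m, read_id = "r3")
  expect_equal(paste(mon3$seq, collapse = ""), arr)
})

test_that("monomer recovery against the simulation truth table", {
  w <- small_world(seed = 71, n_reads = 2500)
  tr <- w$lib$read_truth
  ids <- tr$read_id[tr$family == "sat43" & tr$length >= 150][1:40]
  mon <- extract_monomers_all(w$lib$reads[ids], w$f43$consensus)
  mt <- w$lib$monomer_truth[w$lib$monomer_truth$read_id %in% ids, ]
  found <- 0; total <- 0
  for (rid in ids) {
    a <- mt[mt$read_id == rid & mt$complete, ]
    b <- mon[mon$read_id == rid & mon$complete, ]
    total <- total + nrow(a)
    for (i in seq_len(nrow(a))) {
      d <- abs(b$start - a$start[i]) + abs(b$end - a$end[i])
      if (length(d) > 0 && min(d) <= 6) found <- found + 1  # <= 3 bp per end
    }
  }
  expect_gte(found / total, 0.95)
})

test_that("digest finds IUPAC sites and conserves sequence length", {
  d0 <- digest("AAAATTTTCCCC", "GANTC")
  expect_equal(d0$fragments, 12L)
  expect_length(d0$cut_positions, 0)

  d1 <- digest("AAAGACTCAAAGACTCAAAA", "GANTC")
  expect_equal(d1$cut_positions, c(3L, 11L))
  expect_equal(d1$fragments, c(3L, 8L, 9L))

  # conservation on random sequences (and with a nonzero cut offset)
  set.seed(4)
  for (i in 1:50) {
    s <- random_dna(sample(20:400, 1))
    enz <- enzyme_table()[sample(1:5, 1), ]
    d <- digest(s, enz$site, sample(0:3, 1))
    expect_equal(sum(d$fragments), nchar(s))
  }
})

test_that("ladder inference reports the repeat unit, not a divisor", {
  lu <- ladder_unit(c(177, 354, 531, 177))
  expect_equal(lu$unit, 177L)
  expect_equal(lu$support, 1.0)

  # simulated partial digest of a dimeric 43 bp array
  fam <- make_family(example_family("sat43"), seed = 5)
  arr <- simulate_array(fam, 150, seed = 6)
  d <- digest(arr$seq, "GANTC", enzyme = "HinfI")
  lu2 <- ladder_unit(d$fragments)
  expect_equal(lu2$unit, 43L)
  expect_gte(lu2$support, 0.8)

  # and of a 177 bp array: ladder unit at the monomer length
  fam2 <- make_family(example_family("sat177"), seed = 7)
  arr2 <- simulate_array(fam2, 40, seed = 8)
  lu3 <- ladder_unit(digest(arr2$seq, "GANTC")$fragments)
  expect_equal(lu3$unit, 177L)

  # random fragments carry no ladder
  set.seed(9)
  lur <- ladder_unit(sample(30:500, 60))
  expect_true(is.na(lur$unit))
})
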