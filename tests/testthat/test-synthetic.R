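# Synthetic tandem-array generator: consensus construction, mutation model
# calibration, array/library simulation and ground truth.

test_that("make_consensus plants motifs and sites at the stated identities", {
  spec <- family_spec("f", 43, at_target = 0.6,
                      motif_plan = list(list(kind = "inverted", length = 9,
                                             copies = 2, identity = 1.0)))
  cons <- make_consensus(spec, seed = 3)
  expect_equal(nchar(cons$seq), 43)
  m <- cons$motifs
  expect_equal(nrow(m), 2)
  c1 <- substr(cons$seq, m$start[1] + 1, m$end[1])
  c2 <- substr(cons$seq, m$start[2] + 1, m$end[2])
  expect_equal(c1, reverse_complement(c2))

  # two 23 bp direct copies at ~70% identity in a 177 bp monomer
  spec2 <- family_spec("g", 177, at_target = 0.59,
                       motif_plan = list(list(kind = "direct", length = 23,
                                              copies = 2, identity = 0.70)))
  cons2 <- make_consensus(spec2, seed = 4)
  m2 <- cons2$motifs
  d1 <- substr(cons2$seq, m2$start[1] + 1, m2$end[1])
  d2 <- substr(cons2$seq, m2$start[2] + 1, m2$end[2])
  got <- pairwise_identity(d1, d2)$value
  expect_true(abs(got - 0.70) <= 0.10)

  # pure-AT consensus without motifs
  at <- make_consensus(family_spec("h", 20, at_target = 1), seed = 1)
  expect_true(grepl("^[AT]+$", at$seq))

  # impossible packing is rejected with a diagnostic
  expect_error(
    make_consensus(family_spec("i", 24,
                               motif_plan = list(list(kind = "direct",
                                                      length = 10,
                                                      copies = 3,
                                                      identity = 1))),
                   seed = 1),
    "without overlap")
})

test_that("consensus AT content tracks the target", {
  for (sd in 1:3) {
    c43 <- make_consensus(example_family("sat43"), seed = sd)
    c177 <- make_consensus(example_family("sat177"), seed = sd)
    expect_true(abs(at_content(c43$seq) - 0.605) < 0.05, info = sd)
    expect_true(abs(at_content(c177$seq) - 0.59) < 0.03, info = sd)
  }
})

test_that("substitution-rate calibration matches its closed form", {
  # identity(q) = (1-q)^2 + q^2/3 inverts correctly
  for (w in c(0.95, 0.89, 0.75, 0.6)) {
    q <- divergence_for_identity(w)
    expect_equal((1 - q)^2 + q^2 / 3, w, tolerance = 1e-10)
  }
})

test_that("simulate_array hits the calibrated pairwise identity", {
  # q = 0.05: expected identity (1-q)^2 + q^2/3 ~ 0.9033
  spec <- family_spec("f", 100, within_divergence = 0.05)
  fam <- make_family(spec, seed = 5)
  arr <- simulate_array(fam, 220, seed = 6)
  expect_equal(nchar(arr$seq), 220 * 100)
  # truth tiles the array exactly
  expect_equal(arr$truth$start, seq(0, by = 100, length.out = 220))
  expect_equal(arr$truth$end - arr$truth$start, rep(100L, 220))
  mono <- substring(arr$seq, arr$truth$start + 1, arr$truth$end)
  set.seed(7)
  pick <- replicate(150, sample.int(220, 2))
  ids <- vapply(seq_len(150), function(k) {
    sum(strsplit(mono[pick[1, k]], "")[[1]] ==
          strsplit(mono[pick[2, k]], "")[[1]]) / 100
  }, numeric(1))
  expect_true(abs(mean(ids) - ((1 - 0.05)^2 + 0.05^2 / 3)) <= 0.02)

  # zero divergence: exact copies
  arr0 <- simulate_array(make_family(family_spec("z", 50,
                                                 within_divergence = 0),
                                     seed = 1), 5, seed = 2)
  expect_equal(arr0$seq, strrep(substr(arr0$seq, 1, 50), 5))
})

test_that("dimeric HOR arrays alternate classes at calibrated identities", {
  fam <- make_family(example_family("sat43"), seed = 8)
  expect_length(fam$class_consensus, 2)
  arr <- simulate_array(fam, 200, seed = 9)
  expect_equal(arr$truth$class, rep(c(1L, 2L), 100))
  mono <- substring(arr$seq, arr$truth$start + 1, arr$truth$end)
  idm <- identity_matrix(setNames(mono, seq_along(mono)))
  cls <- arr$truth$class
  within <- mean(idm[cls == 1, cls == 1][upper.tri(idm[cls == 1, cls == 1])])
  between <- mean(idm[cls == 1, cls == 2])
  expect_true(abs(within - 0.89) <= 0.02)
  expect_true(abs(between - 0.685) <= 0.02)
})

test_that("same seed gives byte-identical libraries, truth tables tile reads", {
  w1 <- small_world(seed = 31, n_reads = 400)
  w2 <- small_world(seed = 31, n_reads = 400)
  expect_identical(w1$lib$reads, w2$lib$reads)
  expect_identical(w1$lib$read_truth, w2$lib$read_truth)
  expect_identical(w1$lib$monomer_truth, w2$lib$monomer_truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(w1$lib$reads, f1); write_fastq(w2$lib$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  mt <- w1$lib$monomer_truth
  expect_true(all(mt$end > mt$start))
  # within each read, monomers are ordered and contiguous (indel rate 0)
  for (rid in unique(mt$read_id)[1:10]) {
    sub <- mt[mt$read_id == rid, ]
    expect_true(all(diff(sub$start) > 0))
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
  }
  # classes alternate along dimeric reads
  sub43 <- mt[mt$family == "sat43", ]
  for (rid in unique(sub43$read_id)[1:10]) {
    cls <- sub43$class[sub43$read_id == rid]
    if (length(cls) > 1) expect_true(all(abs(diff(cls)) == 1))
  }
})

test_that("error-free reads are exact substrings of their source", {
  f <- make_family(family_spec("f", 60, within_divergence = 0.03), seed = 1)
  g <- simulate_genome(list(f), 2, 30, background_length = 5000, seed = 2)
  lib <- simulate_library(g, library_spec("x", 150, error_rate = 0),
                          seed = 3)
  for (i in seq_len(50)) {
    tr <- lib$read_truth[i, ]
    src <- g$sequences[[tr$source]]
    rd <- lib$reads[[i]]
    if (tr$strand == "-") rd <- reverse_complement(rd)
    expect_equal(substr(src, tr$start + 1, tr$start + tr$length), rd)
  }
  # reads longer than their source are truncated and flagged
  libT <- simulate_library(g, library_spec("y", 50, read_len_mean = 10000,
                                           read_len_sd = 1, error_rate = 0),
                           seed = 4)
  expect_true(all(libT$read_truth$truncated |
                    libT$read_truth$family == "background"))
})

test_that("library abundance lands inside the binomial 99% interval", {
  w <- small_world(seed = 41, n_reads = 10000)
  n_sat43 <- sum(w$lib$read_truth$family == "sat43")
  ci <- qbinom(c(0.005, 0.995), 10000, 0.0393)
  expect_true(n_sat43 >= ci[1] && n_sat43 <= ci[2])
})
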