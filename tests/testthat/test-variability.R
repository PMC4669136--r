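# Identity reports, diagnostic positions, HOR inference.

test_that("identity report matches hand-enumerated pair means", {
  msa <- as_msa(c(a = "AAAA", b = "AAAT", c = "TTTT"),
                labels = c("x", "x", "y"))
  r <- identity_report(msa)
  expect_equal(r$overall, (0.75 + 0 + 0.25) / 3)
  expect_equal(unname(r$within["x"]), 0.75)
  expect_true(is.na(r$within["y"]))          # single-member group
  expect_equal(unname(r$between["x|y"]), 0.125)

  r3 <- identity_report(as_msa(c(a = "ACG", b = "ACG", c = "ACG")))
  expect_equal(r3$overall, 1.0)
})

test_that("overall identity equals the upper-triangle mean of the matrix", {
  set.seed(1)
  for (i in 1:5) {
    rows <- vapply(1:8, function(k) random_dna(30), character(1))
    names(rows) <- paste0("s", 1:8)
    msa <- as_msa(rows)
    r <- identity_report(msa)
    idm <- outer(seq_along(rows), seq_along(rows), Vectorize(function(a, b) {
      mean(strsplit(rows[a], "")[[1]] == strsplit(rows[b], "")[[1]])
    }))
    expect_equal(r$overall, mean(idm[upper.tri(idm)]))
  }
})

test_that("relabeling groups leaves symmetric statistics unchanged", {
  set.seed(2)
  rows <- setNames(vapply(1:10, function(k) random_dna(40), character(1)),
                   paste0("s", 1:10))
  lab <- rep(c("A", "B"), 5)
  r1 <- identity_report(as_msa(rows, labels = lab))
  lab2 <- ifelse(lab == "A", "B", "A")
  r2 <- identity_report(as_msa(rows, labels = lab2))
  expect_equal(r1$overall, r2$overall)
  expect_equal(unname(r1$within["A"]), unname(r2$within["B"]))
  expect_equal(unname(r1$between), unname(r2$between))
})

test_that("diagnostic positions: hand case, planted difference, clean null", {
  msa <- as_msa(c(a = "AAAA", b = "AAAA", c = "AAAT", d = "AAAT"),
                labels = c("x", "x", "y", "y"))
  d <- diagnostic_positions(msa)
  expect_equal(d$fraction_identical, 0.75)
  expect_equal(nrow(d$diagnostics), 1)
  expect_equal(d$diagnostics$column, 3L)
  expect_equal(d$diagnostics$state_a, "A")
  expect_equal(d$diagnostics$state_b, "T")

  msa2 <- as_msa(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
                 labels = c("x", "x", "y", "y"))
  d2 <- diagnostic_positions(msa2)
  expect_equal(d2$fraction_identical, 1.0)
  expect_equal(nrow(d2$diagnostics), 0)

  # planted fixed difference in otherwise diverged groups: exactly one
  # diagnostic, none under the null
  fam <- make_family(example_family("sat177"), seed = 3)
  cons <- fam$consensus
  base10 <- substr(cons, 10, 10)
  alt10 <- setdiff(c("A", "C", "G", "T"), base10)[1]
  gA <- mutate_copies(cons, 30, 0.05, seed = 4,
                      force = setNames(base10, 10), prefix = "MAL")
  gB <- mutate_copies(cons, 30, 0.05, seed = 5,
                      force = setNames(alt10, 10), prefix = "FEM")
  msa3 <- build_msa(c(gA, gB), cons, labels = rep(c("m", "f"), each = 30))
  d3 <- diagnostic_positions(msa3)
  expect_equal(nrow(d3$diagnostics), 1)
  expect_equal(d3$diagnostics$column, 9L)

  gB0 <- mutate_copies(cons, 30, 0.05, seed = 6, prefix = "FEM")
  msa4 <- build_msa(c(gA, gB0), cons, labels = rep(c("m", "f"), each = 30))
  expect_equal(nrow(diagnostic_positions(msa4)$diagnostics), 0)
})

test_that("hor_scan calls a planted perfect dimer and respects tie rules", {
  set.seed(7)
  A <- random_dna(40)
  B <- random_dna(40)
  mk <- function(read, n) data.frame(
    monomer_id = paste0(read, "|", 0:(n - 1)), read_id = read,
    ordinal = 0:(n - 1),
    seq = rep(c(A, B), length.out = n), stringsAsFactors = FALSE)
  mon <- rbind(mk("r1", 6), mk("r2", 4), mk("r3", 4))
  h <- hor_scan(mon)
  expect_equal(h$hor_order, 2L)
  expect_equal(h$non_contiguous_fraction, 1.0)
  expect_equal(h$alternation_consistency, 1.0)
  expect_true(h$between_identity < min(h$within_identity))

  # all-identical monomers: adjacency tie-break forces contiguity, order 1
  mon2 <- mon
  mon2$seq <- A
  h2 <- hor_scan(mon2)
  expect_equal(h2$hor_order, 1L)
  expect_equal(h2$non_contiguous_fraction, 0.0)

  expect_error(hor_scan(mk("r1", 12)), "3 reads")
})

test_that("hor_scan recovers planted classes from simulated reads", {
  w <- small_world(seed = 81, n_reads = 2500)
  tr <- w$lib$read_truth
  ids <- tr$read_id[tr$family == "sat43" & tr$length >= 150][1:60]
  mon <- extract_monomers_all(w$lib$reads[ids], w$f43$consensus)
  comp <- mon[mon$complete, ]
  h <- hor_scan(comp)
  expect_equal(h$hor_order, 2L)
  expect_gte(h$non_contiguous_fraction, 0.9)
  expect_true(abs(h$between_identity - 0.685) <= 0.02)
  expect_true(all(abs(h$within_identity - 0.89) <= 0.02))

  # class agreement vs planted truth (up to label permutation)
  mt <- w$lib$monomer_truth
  truth_cls <- integer(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    sub <- mt[mt$read_id == comp$read_id[i], ]
    d <- abs(sub$start - comp$start[i]) + abs(sub$end - comp$end[i])
    truth_cls[i] <- sub$class[which.min(d)]
  }
  agree <- max(mean(h$classes == truth_cls),
               mean(h$classes == 3L - truth_cls))
  expect_gte(agree, 0.95)

  # monomeric family: no dimeric call
  ids2 <- tr$read_id[tr$family == "sat177" & tr$length >= 380][1:25]
  mon2 <- extract_monomers_all(w$lib$reads[ids2], w$f177$consensus)
  h2 <- hor_scan(mon2[mon2$complete, ])
  expect_equal(h2$hor_order, 1L)
})
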