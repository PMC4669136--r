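# Distance matrices, neighbor joining, bootstrap, group support.

test_that("p-distance matrix follows hand counts and is a pseudometric", {
  msa <- as_msa(c(a = "AAAA", b = "AAAT", c = "AATT"))
  d <- p_distance_matrix(msa)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0.5)
  expect_equal(d["b", "c"], 0.25)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  set.seed(1)
  rows <- setNames(vapply(1:6, function(i) random_dna(25), character(1)),
                   letters[1:6])
  d2 <- p_distance_matrix(as_msa(rows))
  expect_true(all(d2 >= 0 & d2 <= 1))
  expect_equal(d2, t(d2))
})

test_that("NJ reproduces the known 4-taxon additive case exactly", {
  dm <- matrix(c(0, 3, 5, 3,
                 3, 0, 6, 4,
                 5, 6, 0, 4,
                 3, 4, 4, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(dm)
  # topology AB|CD with branch lengths 1,2,3,1 and internal 1
  expect_equal(sort(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)] -
                      dm), rep(0, 16), tolerance = 1e-9, ignore_attr = TRUE)
  ab <- ape::getMRCA(ape::root(tr, "C"), c("A", "B"))
  expect_true(!is.null(ab))
  lens <- setNames(tr$edge.length[match(1:4, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens[c("A", "B", "C", "D")]), c(1, 2, 3, 1))
})

test_that("NJ recovers random additive 4- and 5-taxon trees exactly", {
  set.seed(2)
  for (i in 1:30) {
    ra <- random_additive(sample(4:5, 1))
    tr <- neighbor_joining(ra$dm)
    ids <- rownames(ra$dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ra$tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(max(abs(ape::cophenetic.phylo(tr)[ids, ids] -
                           ra$dm[ids, ids])), 0, tolerance = 1e-8)
  }
})

test_that("NJ matches ape::nj topologies on random non-additive matrices", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    X <- matrix(runif(n * n, 0.1, 1), n, n)
    X <- (X + t(X)) / 2; diag(X) <- 0
    dimnames(X) <- list(letters[1:n], letters[1:n])
    t1 <- neighbor_joining(X)
    t2 <- ape::nj(as.dist(X))
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ handles degenerate and invalid input", {
  # equidistant taxa: all internal branches collapse to length ~0
  E <- matrix(0.5, 5, 5); diag(E) <- 0
  dimnames(E) <- list(letters[1:5], letters[1:5])
  tr <- neighbor_joining(E)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-9))
  # binary unrooted: n - 3 internal edges
  expect_equal(sum(internal), 5 - 3)
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  B <- matrix(c(0, 1, 2, 5, 0, 1, 2, 1, 0), 3, 3)
  expect_error(neighbor_joining(B), "symmetric")
})

test_that("bootstrap supports are deterministic and behave at the limits", {
  fam <- make_family(example_family("sat43"), seed = 4)
  a <- mutate_copies(fam$class_consensus[1], 6, 0.03, seed = 5, prefix = "Aa")
  b <- mutate_copies(fam$class_consensus[2], 6, 0.03, seed = 6, prefix = "Bb")
  msa <- build_msa(c(a, b), fam$consensus,
                   labels = rep(c("A", "B"), each = 6))
  t1 <- bootstrap_support(msa, n_replicates = 100, seed = 7)
  t2 <- bootstrap_support(msa, n_replicates = 100, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # clearly separated clades: the separating edge has support >= 99
  gs <- group_support(t1, setNames(attr(msa, "labels"), rownames(msa)),
                      threshold = 99)
  expect_true(all(gs$verdict == "supported"))
  # single replicate: supports are 0 or 100
  t3 <- bootstrap_support(msa, n_replicates = 1, seed = 8)
  expect_true(all(as.numeric(t3$node.label) %in% c(0, 100)))
})

test_that("bootstrap supports are invariant under taxon reordering", {
  fam <- make_family(example_family("sat43"), seed = 9)
  a <- mutate_copies(fam$class_consensus[1], 5, 0.05, seed = 1, prefix = "Aa")
  b <- mutate_copies(fam$class_consensus[2], 5, 0.05, seed = 2, prefix = "Bb")
  msa1 <- build_msa(c(a, b), fam$consensus)
  perm <- c(7, 3, 1, 9, 5, 2, 10, 4, 8, 6)
  msa2 <- as_msa(msa_rows(msa1)[perm])
  t1 <- bootstrap_support(msa1, n_replicates = 50, seed = 3)
  t2 <- bootstrap_support(msa2, n_replicates = 50, seed = 3)
  key <- function(tr) {
    parts <- ape::prop.part(tr)
    sup <- suppressWarnings(as.numeric(tr$node.label))
    cl <- vapply(seq_along(parts), function(k)
      paste(sort(tr$tip.label[parts[[k]]]), collapse = ","), character(1))
    sort(paste(cl, sup))[-1]   # drop the trivial full split
  }
  expect_equal(key(t1), key(t2))
})

test_that("group support verdicts handle random labels and edge cases", {
  fam <- make_family(example_family("sat43"), seed = 10)
  a <- mutate_copies(fam$class_consensus[1], 6, 0.03, seed = 2, prefix = "Aa")
  b <- mutate_copies(fam$class_consensus[2], 6, 0.03, seed = 3, prefix = "Bb")
  msa <- build_msa(c(a, b), fam$consensus)
  tr <- bootstrap_support(msa, n_replicates = 50, seed = 4)
  # random labels: no supported group expected
  set.seed(5)
  rl <- setNames(sample(rep(c("u", "v"), 6)), rownames(msa))
  gs <- group_support(tr, rl)
  expect_true(all(gs$verdict != "supported"))
  # whole-set and singleton labels are not assessable
  gs2 <- group_support(tr, setNames(rep("all", 12), rownames(msa)))
  expect_true(all(gs2$verdict == "not_assessable"))
  gs3 <- group_support(tr, setNames(c("solo", rep("rest", 11)),
                                    rownames(msa)))
  expect_equal(gs3$verdict[gs3$label == "solo"], "not_assessable")
})

test_that("newick round trip preserves topology, lengths and supports", {
  fam <- make_family(example_family("sat43"), seed = 11)
  a <- mutate_copies(fam$consensus, 8, 0.08, seed = 12)
  msa <- build_msa(a, fam$consensus)
  tr <- bootstrap_support(msa, n_replicates = 20, seed = 13)
  p <- tempfile(fileext = ".nwk")
  write_newick(tr, p)
  tr2 <- read_newick(p)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  ids <- tr$tip.label
  expect_equal(ape::cophenetic.phylo(tr2)[ids, ids],
               ape::cophenetic.phylo(tr)[ids, ids], tolerance = 1e-9)
  expect_identical(tr2$node.label, tr$node.label)
})
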