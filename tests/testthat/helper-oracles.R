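# Independent oracles used across the suite.

# Exhaustive enumeration of all global alignments (no dynamic programming):
# recursively tries every column type and returns the maximal score.
enum_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= n) best <- max(best, gap + rec(i + 1, j))
    if (j <= m) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random unrooted binary tree with positive branch lengths and its additive
# (cophenetic) distance matrix.
random_additive <- function(n_taxa, min_len = 0.5, max_len = 2) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, min_len, max_len))
  tr$tip.label <- sort(tr$tip.label)   # fixed ids, random shape
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# Small two-family monomer world used by several files.
small_world <- function(seed = 11, n_reads = 3000) {
  f43 <- make_family(example_family("sat43"), seed)
  f177 <- make_family(example_family("sat177"), seed + 1)
  genome <- satkit:::.merge_genomes(list(
    simulate_genome(list(f43), 4, 120, background_length = 60000,
                    seed = seed + 10),
    simulate_genome(list(f177), 4, 40, background_length = 0,
                    seed = seed + 20)))
  lib <- simulate_library(
    genome,
    library_spec("male", n_reads,
                 abundance = c(sat43 = 0.0393, sat177 = 0.0379)),
    seed = seed + 30)
  list(f43 = f43, f177 = f177, genome = genome, lib = lib)
}
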