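# p-distance matrices, neighbor-joining, bootstrap support, and
# labeled-group support assessment. Trees are ape "phylo" objects; newick
# IO goes through ape.

#' p-distance matrix from a multiple alignment
#'
#' d(i,j) = 1 - identity(i,j) with gap-excluded (pairwise deletion)
#' identity.
#'
#' @param msa a `sat_msa` with >= 3 rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  stopifnot(nrow(msa) >= 3)
  rows <- msa_rows(msa)
  cc <- cpp_msa_identity(unname(rows))
  bad <- which(cc$compared == 0 & upper.tri(cc$compared), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 names(rows)[bad[1, 1]], names(rows)[bad[1, 2]]),
         call. = FALSE)
  }
  d <- 1 - cc$matches / cc$compared
  diag(d) <- 0
  dimnames(d) <- list(names(rows), names(rows))
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix:
#' Q(i,j) = (r-2) d(i,j) - R_i - R_j is minimized at each step, with ties
#' broken by the lexicographically smallest pair of cluster representatives
#' (a cluster is represented by its smallest leaf id), making the tree
#' bit-reproducible. Negative branch lengths are clamped to zero; the total
#' clamped deficit is recorded in the `clamped` attribute.
#'
#' @param dm symmetric distance matrix with >= 3 taxa (dimnames = ids).
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- sprintf("t%03d", seq_len(n))
  }
  if (max(abs(dm - t(dm))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(dm < -1e-12)) {
    stop("distance matrix must be non-negative", call. = FALSE)
  }

  clamped <- 0
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + abs(x); 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)

  labels <- rownames(dm)          # newick fragment per active cluster
  reps <- rownames(dm)            # smallest leaf id per cluster
  D <- dm
  while (nrow(D) > 3) {
    r <- nrow(D)
    Rs <- rowSums(D)
    Q <- (r - 2) * D - outer(Rs, Rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(reps[ij[1]], reps[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    dij <- D[i, j]
    li <- clamp(dij / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2)))
    lj <- clamp(dij - (dij / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2))))
    new_label <- sprintf("(%s:%s,%s:%s)", labels[i], fmt(li),
                         labels[j], fmt(lj))
    new_rep <- min(reps[i], reps[j])
    dk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    labels <- c(labels[keep], new_label)
    reps <- c(reps[keep], new_rep)
    D <- D2
  }

  # final three clusters: closed-form branch lengths
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 labels[1], fmt(la), labels[2], fmt(lb), labels[3], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Felsenstein bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and maps the percentage of replicates containing each internal
#' bipartition of the original tree onto its node labels.
#'
#' @param msa a `sat_msa` with >= 4 rows.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return the original NJ tree with `node.label` set to support
#'   percentages (the root trifurcation label is the trivial full split).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed = 1) {
  stopifnot(n_replicates >= 1)
  mat <- unclass(msa)
  tree <- neighbor_joining(.safe_pdist(mat))
  set.seed(seed)
  boots <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    boots[[b]] <- neighbor_joining(.safe_pdist(mat[, cols, drop = FALSE]))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- as.character(round(100 * counts / n_replicates))
  tree
}

# p-distance matrix straight from a character matrix, tolerating pairs with
# no comparable columns (distance 1) as can happen in bootstrap replicates.
.safe_pdist <- function(mat) {
  rows <- apply(mat, 1, paste, collapse = "")
  cc <- cpp_msa_identity(unname(rows))
  d <- 1 - cc$matches / pmax(cc$compared, 1)
  d[cc$compared == 0] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Does any supported bipartition separate each label group?
#'
#' A label is "highly supported" iff some internal edge's bipartition
#' exactly separates that label's leaves from the rest and its bootstrap
#' support reaches the threshold.
#'
#' @param tree a `phylo` with bootstrap percentages in `node.label` (as from
#'   [bootstrap_support()]).
#' @param labels named character vector (names = leaf ids).
#' @param threshold support percentage required (default 70).
#' @return data frame per label: verdict ("supported", "unsupported",
#'   "not_assessable"), best matching support.
#' @export
group_support <- function(tree, labels, threshold = 70) {
  labels <- labels[tree$tip.label]
  supports <- suppressWarnings(as.numeric(tree$node.label))
  parts <- ape::prop.part(tree)       # clade tip sets per internal node
  ntip <- length(tree$tip.label)
  out <- list()
  for (g in sort(unique(labels))) {
    members <- sort(tree$tip.label[labels == g])
    if (length(members) < 2 || length(members) >= ntip) {
      out[[g]] <- data.frame(label = g, verdict = "not_assessable",
                             support = NA_real_, stringsAsFactors = FALSE)
      next
    }
    best <- NA_real_
    for (k in seq_along(parts)) {
      clade <- sort(tree$tip.label[parts[[k]]])
      comp <- sort(setdiff(tree$tip.label, clade))
      if (identical(clade, members) || identical(comp, members)) {
        s <- supports[k]
        if (is.na(best) || (!is.na(s) && s > best)) best <- s
      }
    }
    verdict <- if (!is.na(best) && best >= threshold) "supported"
               else "unsupported"
    out[[g]] <- data.frame(label = g, verdict = verdict, support = best,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a tree to newick (supports as internal node labels)
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path newick file.
#' @return a `phylo`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
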