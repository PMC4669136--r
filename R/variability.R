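# Variability statistics (identity reports, diagnostic positions) and
# higher-order-repeat inference from contiguous vs non-contiguous monomer
# similarity.

# Pairwise identity matrix over MSA rows (pairwise deletion).
.msa_identity_matrix <- function(msa, gap_policy = "exclude_gap_columns") {
  rows <- msa_rows(msa)
  cc <- cpp_msa_identity(unname(rows))
  denom <- if (gap_policy == "exclude_gap_columns") cc$compared
           else matrix(nchar(rows[1]), length(rows), length(rows))
  idm <- cc$matches / denom
  diag(idm) <- 1
  dimnames(idm) <- list(names(rows), names(rows))
  idm
}

.upper_mean <- function(m) {
  if (nrow(m) < 2) return(NA_real_)
  mean(m[upper.tri(m)])
}

#' Identity report over a (possibly grouped) monomer alignment
#'
#' Mean pairwise identity over all unordered pairs (not the mean of group
#' means), within each group, and between groups, computed column-wise on
#' the alignment rows under pairwise deletion.
#'
#' @param msa a `sat_msa` (>= 2 rows).
#' @param labels optional group labels (defaults to the MSA's labels
#'   attribute); groups with < 2 members get `NA` within-group values.
#' @param gap_policy "exclude_gap_columns" (pairwise deletion, default) or
#'   "count_gaps_as_mismatch".
#' @return object of class `group_identity_report`: list with `overall`,
#'   `within` (named vector), `between` (named vector for each group pair),
#'   `n` (group sizes), `gap_policy`.
#' @export
identity_report <- function(msa, labels = attr(msa, "labels"),
                            gap_policy = c("exclude_gap_columns",
                                           "count_gaps_as_mismatch")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(nrow(msa) >= 2)
  idm <- .msa_identity_matrix(msa, gap_policy)
  out <- list(overall = .upper_mean(idm), within = NULL, between = NULL,
              n = nrow(idm), gap_policy = gap_policy)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    stopifnot(length(labels) == nrow(idm))
    groups <- sort(unique(labels))
    within <- setNames(vapply(groups, function(g) {
      sub <- idm[labels == g, labels == g, drop = FALSE]
      .upper_mean(sub)
    }, numeric(1)), groups)
    btw <- c()
    if (length(groups) >= 2) {
      for (a in seq_len(length(groups) - 1)) {
        for (b in (a + 1):length(groups)) {
          sub <- idm[labels == groups[a], labels == groups[b], drop = FALSE]
          btw[[paste(groups[a], groups[b], sep = "|")]] <- mean(sub)
        }
      }
    }
    out$within <- within
    out$between <- unlist(btw)
    out$n <- table(labels)
  }
  structure(out, class = "group_identity_report")
}

#' @export
print.group_identity_report <- function(x, ...) {
  cat(sprintf("identity report (%s): overall %.4f\n",
              x$gap_policy, x$overall))
  if (!is.null(x$within)) {
    for (g in names(x$within))
      cat(sprintf("  within %-10s %.4f (n = %d)\n", g, x$within[g],
                  x$n[[g]]))
    for (p in names(x$between))
      cat(sprintf("  between %-9s %.4f\n", p, x$between[p]))
  }
  invisible(x)
}

#' Shared identical positions and fixed diagnostic positions
#'
#' A column is "identical across both groups" when it carries one single
#' state (gap counted as a state) over all rows of both groups; a "fixed
#' diagnostic" column is monomorphic within each group with different states
#' between them.
#'
#' @param msa a `sat_msa`.
#' @param labels two-group labels (defaults to the MSA's labels attribute);
#'   both groups need >= 2 members.
#' @return list with `fraction_identical`, `diagnostics` (data frame:
#'   0-based column index, state in each group), `n_columns`.
#' @export
diagnostic_positions <- function(msa, labels = attr(msa, "labels")) {
  stopifnot(!is.null(labels))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("both groups need at least 2 members", call. = FALSE)
  }
  mat <- unclass(msa)
  if (ncol(mat) == 0) stop("alignment has no columns", call. = FALSE)
  ga <- mat[labels == groups[1], , drop = FALSE]
  gb <- mat[labels == groups[2], , drop = FALSE]
  mono_a <- apply(ga, 2, function(c) length(unique(c)) == 1)
  mono_b <- apply(gb, 2, function(c) length(unique(c)) == 1)
  state_a <- ga[1, ]
  state_b <- gb[1, ]
  identical_both <- mono_a & mono_b & state_a == state_b
  diag_cols <- which(mono_a & mono_b & state_a != state_b)
  list(
    fraction_identical = mean(identical_both),
    diagnostics = data.frame(column = diag_cols - 1L,
                             state_a = unname(state_a[diag_cols]),
                             state_b = unname(state_b[diag_cols]),
                             stringsAsFactors = FALSE),
    n_columns = ncol(mat),
    groups = groups)
}

#' Higher-order-repeat scan from monomer contiguity
#'
#' Infers HOR structure directly from the monomer identity matrix: for every
#' eligible monomer (one having an adjacent monomer, ordinal +/- 1 on the
#' same read, in the set) the nearest neighbour is the monomer with the
#' highest pairwise identity, ties broken in favour of the adjacent monomer
#' (conservative: divergence-free data can never signal a HOR). The
#' non-contiguous fraction is the share of eligible monomers whose nearest
#' neighbour is not adjacent. Monomers are then partitioned into two classes
#' by average-linkage clustering on (1 - identity), and a dimeric HOR is
#' called when the non-contiguous fraction exceeds `nc_threshold`, the
#' between-class identity falls below both within-class identities, and
#' adjacent monomers alternate classes more often than `alt_threshold`.
#'
#' @param monomers monomer data frame ([extract_monomers_all()] output or
#'   any frame with monomer_id, read_id, ordinal, seq); >= 10 monomers and
#'   >= 3 reads contributing adjacent pairs required.
#' @param gap_policy identity gap policy.
#' @param nc_threshold,alt_threshold HOR call thresholds.
#' @param scoring see [alignment_scoring()].
#' @return object of class `hor_report`: list with `non_contiguous_fraction`,
#'   `classes` (named integer vector, 1/2), `within_identity` (length 2),
#'   `between_identity`, `alternation_consistency`, `hor_order` (1 or 2),
#'   `low_confidence`, `n_eligible`.
#' @export
hor_scan <- function(monomers, gap_policy = "exclude_gap_columns",
                     nc_threshold = 0.5, alt_threshold = 0.7,
                     scoring = alignment_scoring()) {
  stopifnot(is.data.frame(monomers), nrow(monomers) >= 10)
  n <- nrow(monomers)
  ids <- monomers$monomer_id
  key <- paste(monomers$read_id, monomers$ordinal, sep = "\r")
  pos <- setNames(seq_len(n), key)
  adj <- lapply(seq_len(n), function(i) {
    k <- c(paste(monomers$read_id[i], monomers$ordinal[i] - 1, sep = "\r"),
           paste(monomers$read_id[i], monomers$ordinal[i] + 1, sep = "\r"))
    unname(pos[k[k %in% names(pos)]])
  })
  has_adj <- lengths(adj) > 0
  reads_with_pairs <- unique(monomers$read_id[has_adj])
  if (length(reads_with_pairs) < 3) {
    stop("need adjacent monomer pairs from at least 3 reads", call. = FALSE)
  }

  cc <- cpp_identity_matrix(monomers$seq, scoring$match, scoring$mismatch,
                            scoring$gap)
  denom <- if (gap_policy == "exclude_gap_columns") cc$compared else cc$alen
  idm <- cc$matches / denom
  diag(idm) <- -Inf   # exclude self from nearest-neighbour search

  eligible <- which(has_adj)
  non_contig <- vapply(eligible, function(i) {
    best <- max(idm[i, ])
    # tie toward adjacency: contiguous if any adjacent monomer attains the max
    !any(idm[i, adj[[i]]] >= best - 1e-12)
  }, logical(1))
  nc_frac <- mean(non_contig)

  diag(idm) <- 1
  cl <- cutree(hclust(as.dist(1 - idm), method = "average"), k = 2)
  names(cl) <- ids
  w1 <- idm[cl == 1, cl == 1, drop = FALSE]
  w2 <- idm[cl == 2, cl == 2, drop = FALSE]
  within <- c(.upper_mean(w1), .upper_mean(w2))
  between <- mean(idm[cl == 1, cl == 2, drop = FALSE])

  adj_pairs <- 0L; alt_pairs <- 0L
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j > i) {
        adj_pairs <- adj_pairs + 1L
        if (cl[i] != cl[j]) alt_pairs <- alt_pairs + 1L
      }
    }
  }
  alternation <- if (adj_pairs > 0) alt_pairs / adj_pairs else NA_real_

  separable <- !any(is.na(within)) && between < min(within)
  low_confidence <- !separable ||
    (min(within) - between) < 0.02
  order2 <- separable && nc_frac > nc_threshold &&
    !is.na(alternation) && alternation > alt_threshold

  structure(list(
    non_contiguous_fraction = nc_frac,
    classes = cl,
    within_identity = within,
    between_identity = between,
    alternation_consistency = alternation,
    hor_order = if (order2) 2L else 1L,
    low_confidence = low_confidence && !order2,
    n_eligible = length(eligible),
    n_adjacent_pairs = adj_pairs), class = "hor_report")
}

#' @export
print.hor_report <- function(x, ...) {
  cat(sprintf("HOR scan: order %d%s\n", x$hor_order,
              if (x$low_confidence) " (low confidence)" else ""))
  cat(sprintf("  non-contiguous nearest-neighbour fraction: %.3f (%d eligible)\n",
              x$non_contiguous_fraction, x$n_eligible))
  cat(sprintf("  within-class identities: %.3f / %.3f; between: %.3f\n",
              x$within_identity[1], x$within_identity[2],
              x$between_identity))
  cat(sprintf("  alternation consistency: %.3f over %d adjacent pairs\n",
              x$alternation_consistency, x$n_adjacent_pairs))
  invisible(x)
}
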