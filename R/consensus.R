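# Reference-anchored star alignment, majority consensus, and internal
# direct/inverted repeat detection within a monomer.

#' Build a star multiple alignment of monomers against an anchor
#'
#' Each monomer is globally aligned to the anchor consensus; gaps are merged
#' into a common coordinate system (insertions relative to the anchor are
#' left-aligned and padded). Monomers are expected to be phase-aligned to the
#' anchor already (as produced by [extract_monomers()]).
#'
#' @param monomers named character vector of monomer sequences, or a monomer
#'   data frame from [extract_monomers_all()] (ids taken from monomer_id).
#' @param anchor anchor consensus string.
#' @param labels optional group labels, recycled/named per monomer.
#' @param min_identity monomers with identity to the anchor below this are
#'   excluded (and reported in the `excluded` attribute).
#' @param scoring see [alignment_scoring()].
#' @return object of class `sat_msa`: a character matrix (one row per
#'   monomer, one column per alignment column, entries A/C/G/T/N/-) with
#'   attributes `labels` and `excluded`.
#' @export
build_msa <- function(monomers, anchor, labels = NULL, min_identity = 0.5,
                      scoring = alignment_scoring()) {
  if (is.data.frame(monomers)) {
    seqs <- setNames(monomers$seq, monomers$monomer_id)
  } else {
    seqs <- monomers
    if (is.null(names(seqs))) names(seqs) <- sprintf("m%04d", seq_along(seqs))
  }
  seqs <- .normalize_seq(seqs)
  anchor <- .normalize_seq(anchor)
  La <- nchar(anchor)
  stopifnot(La > 0, length(seqs) > 0)

  parsed <- vector("list", length(seqs))
  excluded <- character(0)
  for (i in seq_along(seqs)) {
    aln <- align(seqs[[i]], anchor, mode = "global", scoring = scoring)
    denom <- aln$matches + aln$mismatches
    ident <- if (denom > 0) aln$matches / denom else 0
    if (ident < min_identity) {
      excluded <- c(excluded, names(seqs)[i])
      next
    }
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    # at_col[k]: monomer char aligned to anchor column k (or "-");
    # ins[[k+1]]: monomer chars inserted after anchor column k
    at_col <- character(La)
    ins <- vector("list", La + 1)
    k <- 0L
    for (c in seq_along(ca)) {
      if (cb[c] != "-") {
        k <- k + 1L
        at_col[k] <- ca[c]
      } else {
        ins[[k + 1L]] <- c(ins[[k + 1L]], ca[c])
      }
    }
    parsed[[i]] <- list(at_col = at_col, ins = ins)
  }
  keep <- !vapply(parsed, is.null, logical(1))
  if (!any(keep)) stop("no monomer reached the anchor identity floor",
                       call. = FALSE)
  parsed <- parsed[keep]
  ids <- names(seqs)[keep]

  max_ins <- integer(La + 1)
  for (p in parsed) {
    li <- lengths(p$ins)
    max_ins <- pmax(max_ins, li)
  }
  width <- La + sum(max_ins)
  mat <- matrix("-", nrow = length(parsed), ncol = width)
  for (r in seq_along(parsed)) {
    p <- parsed[[r]]
    col <- 1L
    for (k in 0:La) {
      if (max_ins[k + 1] > 0) {
        v <- p$ins[[k + 1]]
        if (length(v) > 0) mat[r, col:(col + length(v) - 1)] <- v
        col <- col + max_ins[k + 1]
      }
      if (k < La) {
        mat[r, col] <- p$at_col[k + 1]
        col <- col + 1L
      }
    }
  }
  anchor_col <- logical(width)
  col <- 1L
  for (k in 0:La) {
    col <- col + max_ins[k + 1]
    if (k < La) { anchor_col[col] <- TRUE; col <- col + 1L }
  }
  rownames(mat) <- ids
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[ids]
    else labels <- rep_len(labels, length(ids))
  }
  structure(mat, class = c("sat_msa", "matrix"),
            labels = labels, excluded = excluded, anchor = anchor,
            anchor_col = anchor_col)
}

#' Alignment rows as gapped strings
#' @param msa a `sat_msa`.
#' @return named character vector.
#' @export
msa_rows <- function(msa) {
  setNames(apply(unclass(msa), 1, paste, collapse = ""), rownames(msa))
}

#' Remove gaps from alignment rows
#' @param msa a `sat_msa` (or character vector of gapped strings).
#' @return named character vector of ungapped sequences.
#' @export
degap <- function(msa) {
  rows <- if (inherits(msa, "sat_msa")) msa_rows(msa) else msa
  gsub("-", "", rows, fixed = TRUE)
}

#' @export
print.sat_msa <- function(x, ...) {
  cat(sprintf("multiple alignment: %d sequences x %d columns\n",
              nrow(x), ncol(x)))
  if (length(attr(x, "excluded")) > 0) {
    cat(sprintf("  %d sequence(s) excluded (below anchor identity floor)\n",
                length(attr(x, "excluded"))))
  }
  invisible(x)
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column, the most frequent non-gap state; a column is emitted only if
#' non-gap states outnumber gaps. Ties default to the alphabetically first
#' base; tied columns are recorded in the `ties` attribute.
#'
#' @param msa a `sat_msa` (>= 2 rows).
#' @param tie_rule only "alphabetical" is implemented.
#' @param insertions "keep" (default) considers every alignment column;
#'   "drop" restricts the consensus to anchor-mapped columns, so that rare
#'   systematic insertions cannot grow the consensus beyond the anchor
#'   (used during iterative consensus inference).
#' @return consensus string with attribute `ties`.
#' @export
majority_consensus <- function(msa, tie_rule = "alphabetical",
                               insertions = c("keep", "drop")) {
  stopifnot(tie_rule == "alphabetical")
  insertions <- match.arg(insertions)
  mat <- unclass(msa)
  if (insertions == "drop" && !is.null(attr(msa, "anchor_col"))) {
    mat <- mat[, attr(msa, "anchor_col"), drop = FALSE]
  }
  if (is.null(dim(mat)) || nrow(mat) < 2) {
    stop("consensus requires an alignment of at least 2 rows", call. = FALSE)
  }
  out <- character(0)
  ties <- integer(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    nongap <- col[col != "-"]
    if (length(nongap) <= length(col) - length(nongap)) next
    tab <- sort(table(nongap), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    if (length(top) > 1) ties <- c(ties, j)
    out <- c(out, sort(top)[1])
  }
  res <- paste(out, collapse = "")
  attr(res, "ties") <- ties
  res
}

# Best qualifying windows along one match diagonal: for each start keep the
# window length (min_len..len cap) maximizing matches - mismatches at
# identity >= min_identity (so an exact core is not diluted by noisy
# flanks). Returns a data frame of (i, l, matches).
.diag_windows <- function(mvec, min_len, min_identity, lcap) {
  n <- length(mvec)
  if (n < min_len) return(NULL)
  lcap <- rep_len(lcap, n)           # per-start window length cap
  cum <- c(0, cumsum(mvec))
  best_s <- rep(-Inf, n); best_m <- integer(n); best_l <- integer(n)
  for (l in min_len:min(max(lcap), n)) {
    ws <- cum[(l + 1):(n + 1)] - cum[1:(n - l + 1)]
    need <- ceiling(min_identity * l) - 1e-9
    sc <- 2 * ws - l                 # matches - mismatches
    ok <- which(ws >= need & lcap[seq_len(n - l + 1)] >= l)
    if (length(ok) > 0) {
      better <- sc[ok] > best_s[ok] |
        (sc[ok] == best_s[ok] & l > best_l[ok])
      upd <- ok[better]
      best_s[upd] <- sc[upd]
      best_m[upd] <- ws[upd]
      best_l[upd] <- l
    }
  }
  hit <- which(best_l > 0)
  if (length(hit) == 0) return(NULL)
  data.frame(i = hit, l = best_l[hit], matches = best_m[hit])
}

#' Find internal direct and inverted repeats within a monomer
#'
#' Exhaustive scan over equal-length, non-overlapping substring pairs of
#' length >= `min_len`. Direct pairs are compared as-is; inverted pairs
#' against the reverse complement of the second copy. Identity is the
#' ungapped column match fraction. Overlapping hits are reduced greedily by
#' decreasing match count (identity x length), never keeping two hits whose
#' copy intervals overlap by more than `max_overlap` of the shorter one.
#'
#' @param monomer monomer sequence (length >= 2 * min_len).
#' @param min_len minimum repeat length (>= 5).
#' @param min_identity minimum identity between copies.
#' @param kinds subset of c("direct", "inverted").
#' @param max_overlap maximal tolerated interval overlap fraction.
#' @return data frame of motif hits: kind, start1/end1/start2/end2 (0-based
#'   half-open, within the monomer), length, identity, and `short` (TRUE for
#'   hits below 12 bp — the "short repeat" annotation class). Empty when no
#'   hit qualifies.
#' @export
find_internal_repeats <- function(monomer, min_len = 8, min_identity = 0.65,
                                  kinds = c("direct", "inverted"),
                                  max_overlap = 0.5) {
  stopifnot(min_len >= 5)
  monomer <- .normalize_seq(monomer)
  L <- nchar(monomer)
  stopifnot(L >= 2 * min_len)
  x <- strsplit(monomer, "", fixed = TRUE)[[1]]
  cand <- list()

  if ("direct" %in% kinds) {
    for (d in min_len:(L - min_len)) {
      mvec <- x[1:(L - d)] == x[(d + 1):L]
      w <- .diag_windows(mvec, min_len, min_identity, lcap = d)
      if (is.null(w)) next
      cand[[length(cand) + 1]] <- data.frame(
        kind = "direct", start1 = w$i - 1L, end1 = w$i - 1L + w$l,
        start2 = w$i - 1L + d, end2 = w$i - 1L + d + w$l,
        length = w$l, matches = w$matches, stringsAsFactors = FALSE)
    }
  }

  if ("inverted" %in% kinds) {
    t <- strsplit(reverse_complement(monomer), "", fixed = TRUE)[[1]]
    # comparing x[i..i+l) to t[i+d..i+d+l) tests x[i..] against the reverse
    # complement of x[j..j+l) with j = L - i - l - d (0-based)
    for (d in (-(L - 1)):(L - 1)) {
      if (d >= 0) {
        i_idx <- 1:(L - d)
        mvec <- x[i_idx] == t[i_idx + d]
        off <- 0L
      } else {
        i_idx <- (1 - d):L
        mvec <- x[i_idx] == t[i_idx + d]
        off <- -d
      }
      # non-overlap + canonical order require l <= (L - d - 2*i0) / 2
      i0_all <- seq_along(mvec) - 1L + off
      w <- .diag_windows(mvec, min_len, min_identity,
                         lcap = pmax(0, (L - d - 2L * i0_all) %/% 2L))
      if (is.null(w)) next
      i0 <- w$i - 1L + off           # 0-based start in x
      j0 <- L - i0 - w$l - d         # 0-based start of the partner copy
      keep <- j0 >= i0 + w$l         # canonical order, non-overlapping
      if (!any(keep)) next
      w <- w[keep, , drop = FALSE]; i0 <- i0[keep]; j0 <- j0[keep]
      cand[[length(cand) + 1]] <- data.frame(
        kind = "inverted", start1 = i0, end1 = i0 + w$l,
        start2 = j0, end2 = j0 + w$l,
        length = w$l, matches = w$matches, stringsAsFactors = FALSE)
    }
  }

  empty <- data.frame(kind = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), length = integer(0),
                      identity = numeric(0), short = logical(0))
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand$identity <- cand$matches / cand$length
  # rank like an ungapped alignment score so exact cores outrank longer,
  # noisier windows that merely contain them
  score <- 2 * cand$matches - cand$length
  cand <- cand[order(-score, -cand$matches, -cand$identity, cand$kind,
                     cand$start1, cand$start2), ]

  ov_frac <- function(a0, a1, b0, b1) {
    ov <- max(0, min(a1, b1) - max(a0, b0))
    ov / min(a1 - a0, b1 - b0)
  }
  acc <- list()
  for (r in seq_len(nrow(cand))) {
    h <- cand[r, ]
    clash <- FALSE
    for (g in acc) {
      f <- max(ov_frac(h$start1, h$end1, g$start1, g$end1),
               ov_frac(h$start1, h$end1, g$start2, g$end2),
               ov_frac(h$start2, h$end2, g$start1, g$end1),
               ov_frac(h$start2, h$end2, g$start2, g$end2))
      if (f > max_overlap) { clash <- TRUE; break }
    }
    if (!clash) acc[[length(acc) + 1]] <- h
  }
  out <- do.call(rbind, acc)
  out$matches <- NULL
  out$short <- out$length < 12
  rownames(out) <- NULL
  out
}
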