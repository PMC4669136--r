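# Pairwise alignment wrappers around the C++ dynamic-programming core.

#' Default alignment scoring
#'
#' Match +1, mismatch -1, gap -2, linear (no affine extension). Sufficient at
#' the 40-180 bp monomer scale; every identity-bearing report carries the
#' scoring used so deviations from other aligners stay traceable.
#'
#' @param match,mismatch,gap numeric scores (gap must be negative).
#' @return list with elements match, mismatch, gap.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap),
            gap < 0)
  list(match = match, mismatch = mismatch, gap = gap)
}

#' Pairwise alignment (global, semiglobal or wraparound)
#'
#' `mode = "wraparound"` treats `b` as circular / tandemly repeated: the
#' alignment path may enter `b` at any phase and traverse its origin any
#' number of times; each traversal marks a monomer boundary. `a` is always
#' consumed end to end. `mode = "semiglobal"` leaves end gaps of `b` free
#' (overhangs of `a` are not penalized).
#'
#' Ties between equal-scoring paths are broken deterministically: diagonal
#' moves are preferred over gaps, then gap-in-b over gap-in-a.
#'
#' @param a,b nucleotide strings (non-empty; case-insensitive).
#' @param mode one of "global", "semiglobal", "wraparound".
#' @param scoring see [alignment_scoring()].
#' @return object of class `pairwise_alignment`: a list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `matches`,
#'   `mismatches`, `gap_columns`, `mode`, `scoring`, and for wraparound
#'   alignments `segments` (one row per consensus traversal, 0-based
#'   half-open read/consensus coordinates) and `n_traversals` (number of
#'   complete consensus units covered).
#' @export
align <- function(a, b, mode = c("global", "semiglobal", "wraparound"),
                  scoring = alignment_scoring()) {
  mode <- match.arg(mode)
  a <- .normalize_seq(a); b <- .normalize_seq(b)
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("cannot align empty sequences", call. = FALSE)
  }
  res <- cpp_align(a, b, mode, scoring$match, scoring$mismatch, scoring$gap)
  out <- list(
    aligned_a = res$aligned_a, aligned_b = res$aligned_b,
    score = res$score, matches = res$matches,
    mismatches = res$mismatches, gap_columns = res$gap_columns,
    mode = mode, scoring = scoring,
    start_j = res$start_j, end_j = res$end_j
  )
  if (mode == "wraparound") {
    segs <- .wrap_segments(res$aligned_a, res$aligned_b, res$start_j, nchar(b))
    out$segments <- segs
    out$n_traversals <- sum(segs$completeness >= 1 - 1e-9)
  }
  class(out) <- "pairwise_alignment"
  out
}

# Decompose a wraparound alignment into monomer segments by walking the
# aligned columns and tracking the consensus phase (which wraps at m).
# Returns 0-based half-open coordinates; read_seq is the ungapped read
# portion of each segment.
.wrap_segments <- function(aligned_a, aligned_b, start_j, m) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  rpos <- 0L
  cpos <- as.integer(start_j)
  seg_r0 <- 0L; seg_c0 <- cpos
  rows <- list()
  push <- function(r1, c1) {
    rows[[length(rows) + 1L]] <<- data.frame(
      read_start = seg_r0, read_end = r1,
      cons_start = seg_c0, cons_end = c1,
      completeness = (c1 - seg_c0) / m,
      stringsAsFactors = FALSE)
  }
  for (k in seq_along(ca)) {
    if (ca[k] != "-") rpos <- rpos + 1L
    if (cb[k] != "-") {
      cpos <- cpos + 1L
      if (cpos == m) {           # origin traversal after consuming column m
        push(rpos, m)
        seg_r0 <- rpos; seg_c0 <- 0L
        cpos <- 0L
      }
    }
  }
  if (rpos > seg_r0 || cpos > seg_c0) push(rpos, cpos)
  do.call(rbind, rows)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment (%s), score %g: %d match, %d mismatch, %d gap columns\n",
              x$mode, x$score, x$matches, x$mismatches, x$gap_columns))
  if (!is.null(x$segments)) {
    cat(sprintf("  %d segment(s), %d complete consensus traversal(s)\n",
                nrow(x$segments), x$n_traversals))
  }
  invisible(x)
}

#' Identity between two sequences
#'
#' Aligns `a` and `b` (global by default) and reports the fraction of
#' identical columns. The default gap policy excludes gap columns from the
#' denominator (pairwise-deletion p-distance convention); the alternative
#' counts them as mismatches.
#'
#' @param a,b nucleotide strings.
#' @param gap_policy "exclude_gap_columns" (default) or
#'   "count_gaps_as_mismatch".
#' @param mode,scoring passed to [align()].
#' @return list with `value` (fraction in \[0,1\], or `NA` when no column is
#'   comparable) and `n_compared_columns`.
#' @export
pairwise_identity <- function(a, b,
                              gap_policy = c("exclude_gap_columns",
                                             "count_gaps_as_mismatch"),
                              mode = "global",
                              scoring = alignment_scoring()) {
  gap_policy <- match.arg(gap_policy)
  aln <- align(a, b, mode = mode, scoring = scoring)
  denom <- if (gap_policy == "exclude_gap_columns") {
    aln$matches + aln$mismatches
  } else {
    aln$matches + aln$mismatches + aln$gap_columns
  }
  list(value = if (denom > 0) aln$matches / denom else NA_real_,
       n_compared_columns = denom)
}

# Identity between two already-aligned (gapped, equal-length) rows.
.aligned_identity <- function(ra, rb,
                              gap_policy = "exclude_gap_columns") {
  ca <- strsplit(ra, "", fixed = TRUE)[[1]]
  cb <- strsplit(rb, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  matches <- sum(ca[both] == cb[both])
  denom <- if (gap_policy == "exclude_gap_columns") sum(both)
           else sum(ca != "-" | cb != "-")
  if (denom == 0) return(list(value = NA_real_, n_compared_columns = 0L))
  list(value = matches / denom, n_compared_columns = denom)
}

#' Pairwise identity matrix over a set of sequences
#'
#' Every pair is globally aligned; identity is computed under the requested
#' gap policy.
#'
#' @param seqs named character vector of (ungapped) sequences.
#' @param gap_policy see [pairwise_identity()].
#' @param scoring see [alignment_scoring()].
#' @return symmetric numeric matrix with unit diagonal.
#' @export
identity_matrix <- function(seqs,
                            gap_policy = c("exclude_gap_columns",
                                           "count_gaps_as_mismatch"),
                            scoring = alignment_scoring()) {
  gap_policy <- match.arg(gap_policy)
  seqs <- .normalize_seq(seqs)
  cc <- cpp_identity_matrix(seqs, scoring$match, scoring$mismatch, scoring$gap)
  denom <- if (gap_policy == "exclude_gap_columns") cc$compared else cc$alen
  idm <- cc$matches / denom
  diag(idm) <- 1
  dimnames(idm) <- list(names(seqs), names(seqs))
  idm
}

# Recompute an alignment score from its aligned strings (self-consistency).
.score_from_alignment <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  s <- aln$scoring
  gaps <- ca == "-" | cb == "-"
  if (aln$mode == "semiglobal") {
    # leading/trailing a-overhangs are free
    core <- which(cb != "-")
    if (length(core) > 0) {
      inner <- seq(min(core), max(core))
      gaps_pen <- sum(gaps[inner])
    } else gaps_pen <- 0
  } else gaps_pen <- sum(gaps)
  matches <- sum(!gaps & ca == cb)
  mismatches <- sum(!gaps & ca != cb)
  matches * s$match + mismatches * s$mismatch + gaps_pen * s$gap
}
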