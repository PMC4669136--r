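# Repeat-read nomination, period detection, monomer extraction and
# in-silico restriction digests.

#' Rank reads by k-mer repetitiveness
#'
#' Repetitiveness of a read = 1 - (#distinct k-mers / #k-mers): 0 for a
#' read with no repeated k-mer, approaching 1 for a pure tandem array.
#' A lightweight stand-in for graph-based read clustering when nominating
#' candidate satellite reads.
#'
#' @param reads named character vector of reads.
#' @param k k-mer size (>= 5).
#' @param top_fraction fraction of reads flagged as nominated.
#' @return data frame sorted by decreasing repetitiveness with columns
#'   read_id, length, repetitiveness, nominated. Reads shorter than `k`
#'   score 0 and are flagged in the `too_short` column.
#' @export
nominate_reads <- function(reads, k = 11, top_fraction = 0.1) {
  stopifnot(k >= 5, length(reads) > 0)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  cnt <- cpp_kmer_distinct(unname(reads), k)
  score <- ifelse(cnt$total > 0, 1 - cnt$distinct / cnt$total, 0)
  df <- data.frame(read_id = ids, length = nchar(unname(reads)),
                   repetitiveness = score,
                   too_short = cnt$total == 0,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$repetitiveness, df$read_id), ]
  df$nominated <- seq_len(nrow(df)) <= ceiling(top_fraction * nrow(df))
  rownames(df) <- NULL
  df
}

#' Detect the repeat period of a tandem-array read
#'
#' The self-match score of period p is the fraction of positions where the
#' sequence equals itself shifted by p. The reported period is the smallest
#' p whose score is within `epsilon` of the maximum and above `threshold`;
#' if a divisor p/k (k = 2..4) of that period also scores above `threshold`
#' the divisor is reported instead (the base monomer) and the longer period
#' is flagged as a harmonic — the signature of a higher-order repeat, whose
#' resolution is left to [hor_scan()].
#'
#' @param seq read sequence (length >= 2 * p_max recommended).
#' @param p_min,p_max candidate period range.
#' @param threshold minimum self-match score for a period call.
#' @param epsilon score slack under the maximum for the smallest-period rule.
#' @return list with `period` (NA when no period reaches the threshold),
#'   `score`, `profile` (score per candidate period), `harmonics` (periods
#'   whose multiples also clear the threshold, flagged for HOR follow-up)
#'   and `no_period`.
#' @export
detect_period <- function(seq, p_min = 10, p_max = 250, threshold = 0.5,
                          epsilon = 0.02) {
  stopifnot(p_min >= 2, p_min < p_max)
  seq <- .normalize_seq(seq)
  p_max_eff <- min(p_max, nchar(seq) - 1)
  if (p_max_eff < p_min) {
    return(list(period = NA_integer_, score = NA_real_,
                profile = numeric(0), harmonics = integer(0),
                no_period = TRUE))
  }
  prof <- cpp_self_match_profile(seq, p_min, p_max_eff)
  names(prof) <- as.character(p_min:p_max_eff)
  ok <- !is.na(prof)
  if (!any(ok) || max(prof[ok]) < threshold) {
    return(list(period = NA_integer_, score = NA_real_, profile = prof,
                harmonics = integer(0), no_period = TRUE))
  }
  smax <- max(prof[ok])
  cand <- which(ok & prof >= smax - epsilon & prof >= threshold)
  p_star <- p_min + cand[1] - 1L

  # divisor refinement: a dimeric (or higher) HOR peaks at the HOR unit,
  # but the base monomer still scores above threshold at p*/k
  period <- p_star
  harmonics <- integer(0)
  for (k in 4:2) {
    if (p_star %% k != 0) next
    p0 <- p_star %/% k
    if (p0 < p_min) next
    s0 <- prof[as.character(p0)]
    if (!is.na(s0) && s0 >= threshold && s0 < smax - epsilon) {
      period <- p0
      harmonics <- p_star
      break
    }
  }
  # flag multiples of the reported period that also clear the threshold
  kmax <- floor(p_max_eff / period)
  mult <- if (kmax >= 2) period * (2:kmax) else integer(0)
  mult <- mult[mult >= p_min]
  if (length(mult) > 0) {
    sm <- prof[as.character(mult)]
    harmonics <- sort(unique(c(harmonics, mult[!is.na(sm) & sm >= threshold])))
  }
  list(period = as.integer(period),
       score = unname(prof[as.character(period)]),
       profile = prof, harmonics = harmonics, no_period = FALSE)
}

# Zero-row monomer frame carrying the rejection reason.
.rejected_monomers <- function(reason) {
  out <- data.frame(monomer_id = character(0), read_id = character(0),
                    ordinal = integer(0), seq = character(0),
                    strand = character(0), completeness = numeric(0),
                    complete = logical(0), start = integer(0),
                    end = integer(0), cons_start = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "reason") <- reason
  out
}

#' Extract phase-aligned monomers from a read
#'
#' Wraparound alignment of the read against the tandemly repeated consensus,
#' on both strands (the better-scoring strand is kept). Monomer boundaries
#' fall at origin traversals of the alignment path; every monomer is thereby
#' reported in consensus phase (complete monomers start at consensus
#' position 0). Minus-strand monomers are stored reverse-complemented (i.e.
#' in consensus orientation); their read coordinates refer to the original
#' read.
#'
#' @param read read sequence.
#' @param consensus family consensus.
#' @param read_id id recorded in the output.
#' @param min_completeness fraction of consensus columns a monomer must
#'   cover to be flagged complete.
#' @param min_identity minimum whole-read alignment identity; below this
#'   floor the read is rejected as not belonging to the family.
#' @param scoring see [alignment_scoring()].
#' @return data frame of monomer records (monomer_id, read_id, ordinal,
#'   seq, strand, completeness, complete, start, end, cons_start; start/end
#'   are 0-based half-open in original read coordinates; ordinals are
#'   consecutive along the consensus orientation), or a zero-row frame with attribute
#'   `reason` when the read is rejected (zero rows).
#' @export
extract_monomers <- function(read, consensus, read_id = "read",
                             min_completeness = 0.95, min_identity = 0.55,
                             scoring = alignment_scoring()) {
  read <- .normalize_seq(read)
  consensus <- .normalize_seq(consensus)
  m <- nchar(consensus)
  if (nchar(read) < m / 2) {
    return(.rejected_monomers("read shorter than half a monomer"))
  }
  aln_p <- align(read, consensus, mode = "wraparound", scoring = scoring)
  rc <- reverse_complement(read)
  aln_m <- align(rc, consensus, mode = "wraparound", scoring = scoring)
  if (aln_p$score >= aln_m$score) {
    aln <- aln_p; strand <- "+"; aseq <- read
  } else {
    aln <- aln_m; strand <- "-"; aseq <- rc
  }
  # rejection identity counts gap columns in the denominator: random reads
  # reach ~0.56 gap-excluded identity against a circularized short
  # consensus (optimal-path bias), but stay well below 0.55 once their
  # many gap columns are counted
  denom <- aln$matches + aln$mismatches + aln$gap_columns
  ident <- if (denom > 0) aln$matches / denom else 0
  if (ident < min_identity) {
    return(.rejected_monomers(
      sprintf("alignment identity %.3f below floor %.3f",
              ident, min_identity)))
  }
  segs <- aln$segments
  n <- nchar(read)
  # segment coordinates are along the aligned orientation; map to original
  # read coordinates for minus-strand reads
  if (strand == "+") {
    start <- segs$read_start; end <- segs$read_end
  } else {
    start <- n - segs$read_end; end <- n - segs$read_start
  }
  seqs <- substring(aseq, segs$read_start + 1, segs$read_end)
  keep <- nchar(seqs) > 0
  df <- data.frame(
    monomer_id = sprintf("%s|%d", read_id, seq_len(nrow(segs)) - 1L),
    read_id = read_id, ordinal = seq_len(nrow(segs)) - 1L,
    seq = seqs, strand = strand,
    completeness = segs$completeness,
    complete = segs$completeness >= min_completeness,
    start = start, end = end, cons_start = segs$cons_start,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df$ordinal <- seq_len(nrow(df)) - 1L
  df$monomer_id <- sprintf("%s|%d", read_id, df$ordinal)
  attr(df, "alignment_identity") <- ident
  df
}

#' Extract monomers from many reads
#'
#' @param reads named character vector.
#' @param consensus family consensus.
#' @param ... passed to [extract_monomers()].
#' @return combined monomer data frame; rejected reads are listed in the
#'   `rejected` attribute.
#' @export
extract_monomers_all <- function(reads, consensus, ...) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  rejected <- character(0)
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    df <- extract_monomers(reads[[i]], consensus, read_id = ids[i], ...)
    if (nrow(df) == 0) rejected <- c(rejected, ids[i]) else out[[i]] <- df
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  attr(res, "rejected") <- rejected
  res
}

#' Built-in restriction enzyme battery
#'
#' The classic satellite-hunting set; every site is its own reverse
#' complement, so forward-strand scanning suffices.
#'
#' @return data frame with columns name, site (IUPAC), cut_offset.
#' @export
enzyme_table <- function() {
  data.frame(
    name = c("HinfI", "TaqI", "AluI", "RsaI", "EcoRI"),
    site = c("GANTC", "TCGA", "AGCT", "GTAC", "GAATTC"),
    cut_offset = c(0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

#' In-silico restriction digest of a linear sequence
#'
#' Finds all IUPAC site matches on the forward strand and cuts at
#' match start + offset.
#'
#' @param seq sequence to digest.
#' @param site IUPAC recognition site (length >= 4).
#' @param cut_offset cut position within the site (0..site length).
#' @param enzyme enzyme name recorded in the result.
#' @return list of class `digest_result`: `fragments` (bp, in order),
#'   `cut_positions` (0-based), `enzyme`, `site`.
#' @export
digest <- function(seq, site, cut_offset = 0, enzyme = NA_character_) {
  seq <- .normalize_seq(seq)
  site <- .normalize_seq(site)
  stopifnot(nchar(site) >= 4, cut_offset >= 0, cut_offset <= nchar(site))
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(seq),
                                   fixed = FALSE)
  cuts <- sort(unique(Biostrings::start(hits) - 1L + cut_offset))
  n <- nchar(seq)
  cuts <- cuts[cuts > 0 & cuts < n]
  frags <- diff(c(0L, cuts, n))
  structure(list(fragments = frags, cut_positions = cuts,
                 enzyme = enzyme, site = site, total_length = n),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("digest (%s, site %s): %d fragment(s), %d cut(s), %d bp total\n",
              ifelse(is.na(x$enzyme), "?", x$enzyme), x$site,
              length(x$fragments), length(x$cut_positions), x$total_length))
  invisible(x)
}

#' Infer the ladder unit from restriction fragment lengths
#'
#' Grid search over candidate units u: support(u) is the fraction of
#' fragment mass (bp) within tolerance of a positive integer multiple of u.
#' Every divisor of the true unit supports at least as much mass as the
#' unit itself, so the reported unit is chosen from all units whose support
#' is within `epsilon` of the maximum: the one with the smallest mean
#' relative deviation from exact multiples, largest u on ties.
#'
#' @param fragments numeric vector of fragment lengths (>= 3).
#' @param u_min,u_max candidate unit range (bp).
#' @param tolerance relative tolerance: a fragment f supports u when
#'   |f - round(f/u) * u| <= tolerance * u.
#' @param min_support supports below this give a "no ladder" result.
#' @param epsilon support slack under the maximum for the candidate set.
#' @return list with `unit` (NA when no ladder), `support` (of the reported
#'   unit), `profile` (support per candidate unit).
#' @export
ladder_unit <- function(fragments, u_min = 20, u_max = 500,
                        tolerance = 0.05, min_support = 0.5,
                        epsilon = 0.05) {
  stopifnot(length(fragments) >= 3)
  units <- seq.int(u_min, u_max)
  total <- sum(fragments)
  stats <- vapply(units, function(u) {
    k <- pmax(1, round(fragments / u))
    dev <- abs(fragments - k * u)
    ok <- dev <= tolerance * u
    c(support = sum(fragments[ok]) / total,
      meandev = if (any(ok)) mean(dev[ok]) / u else Inf)
  }, numeric(2))
  support <- stats["support", ]
  best <- max(support)
  if (best < min_support) {
    return(list(unit = NA_integer_, support = best,
                profile = setNames(support, units)))
  }
  cand <- which(support >= best - epsilon)
  cand <- cand[stats["meandev", cand] <=
                 min(stats["meandev", cand]) + 1e-9]
  unit <- max(units[cand])
  list(unit = as.integer(unit),
       support = unname(support[match(unit, units)]),
       profile = setNames(support, units))
}
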