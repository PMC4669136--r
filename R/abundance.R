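# Satellite-positive read classification and between-library abundance
# testing.

#' Classify reads as satellite-positive for one family
#'
#' A read is positive when its best wraparound alignment against the family
#' consensus (either strand) reaches `min_identity` over a span of at least
#' `min_span` (reads shorter than `min_span` are negative). A k-mer
#' prefilter skips the alignment for reads sharing no k-mer with the
#' (circularized, both-strand) consensus — at the default k this loses
#' essentially no true positives while making 10^5-read libraries
#' tractable; set `prefilter_k = 0` to disable.
#'
#' @param reads named character vector.
#' @param consensus family consensus.
#' @param min_identity minimum gap-excluded alignment identity.
#' @param min_span minimum read length (default: one monomer length).
#' @param prefilter_k k-mer size of the prefilter (0 disables).
#' @param min_kmer_hits prefilter pass threshold.
#' @param scoring see [alignment_scoring()].
#' @return logical vector (named as `reads`) with attributes `n_aligned`
#'   (reads that reached the alignment stage) and `identity` (per-aligned
#'   read identity, NA for prefiltered-out reads).
#' @export
classify_reads <- function(reads, consensus, min_identity = 0.70,
                           min_span = nchar(consensus), prefilter_k = 11,
                           min_kmer_hits = 1,
                           scoring = alignment_scoring()) {
  stopifnot(nchar(consensus) > 0)
  consensus <- .normalize_seq(consensus)
  n <- length(reads)
  positive <- logical(n)
  ident <- rep(NA_real_, n)
  long_enough <- nchar(reads) >= min_span

  candidates <- which(long_enough)
  if (prefilter_k > 0 && length(candidates) > 0) {
    refs <- c(strrep(consensus, 2),
              reverse_complement(strrep(consensus, 2)))
    hits <- cpp_kmer_hits(unname(reads[candidates]), refs, prefilter_k)
    candidates <- candidates[hits >= min_kmer_hits]
  }
  for (i in candidates) {
    a1 <- cpp_align(reads[[i]], consensus, "wraparound",
                    scoring$match, scoring$mismatch, scoring$gap)
    a2 <- cpp_align(reverse_complement(reads[[i]]), consensus, "wraparound",
                    scoring$match, scoring$mismatch, scoring$gap)
    a <- if (a1$score >= a2$score) a1 else a2
    denom <- a$matches + a$mismatches
    ident[i] <- if (denom > 0) a$matches / denom else 0
    positive[i] <- ident[i] >= min_identity
  }
  names(positive) <- names(reads)
  attr(positive, "n_aligned") <- length(candidates)
  attr(positive, "identity") <- ident
  positive
}

#' Two-proportion test (pooled z, Fisher fallback)
#'
#' Default two-proportion z-test with pooled variance and no continuity
#' correction; z^2 equals the Pearson chi-square statistic of the 2x2
#' table. When any expected cell is below 5 (and `method = "auto"`), the
#' test falls back to Fisher's exact test.
#'
#' @param x1,n1 positives and totals in library 1.
#' @param x2,n2 positives and totals in library 2.
#' @param method "auto", "z" or "fisher".
#' @return list with `statistic` (z; NA for Fisher), `p_value` (two-sided),
#'   `method`, `estimate1`, `estimate2`.
#' @export
proportion_test <- function(x1, n1, x2, n2,
                            method = c("auto", "z", "fisher")) {
  method <- match.arg(method)
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  expected <- c(n1 * pp, n1 * (1 - pp), n2 * pp, n2 * (1 - pp))
  use_fisher <- method == "fisher" ||
    (method == "auto" && any(expected < 5))
  if (use_fisher) {
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
    p <- fisher.test(tab)$p.value
    return(list(statistic = NA_real_, p_value = p, method = "fisher",
                estimate1 = p1, estimate2 = p2))
  }
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- 2 * pnorm(-abs(z))
  list(statistic = z, p_value = p, method = "z",
       estimate1 = p1, estimate2 = p2)
}

#' Per-library, per-family abundance with between-library tests
#'
#' Classifies every read of every library against every family consensus
#' and, for each family, tests the difference between the first two
#' libraries with [proportion_test()].
#'
#' @param libraries named list of read vectors (e.g. male/female).
#' @param consensuses named list/vector of family consensus strings.
#' @param ... passed to [classify_reads()].
#' @return object of class `abundance_result`: list with `counts` (data
#'   frame: library, family, positives, total, fraction) and `tests` (data
#'   frame per family: z, p_value, method).
#' @export
abundance_stats <- function(libraries, consensuses, ...) {
  stopifnot(length(libraries) >= 1, length(consensuses) >= 1)
  rows <- list()
  flags <- list()
  for (lib in names(libraries)) {
    for (fam in names(consensuses)) {
      pos <- classify_reads(libraries[[lib]], consensuses[[fam]], ...)
      flags[[paste(lib, fam)]] <- pos
      rows[[length(rows) + 1]] <- data.frame(
        library = lib, family = fam,
        positives = sum(pos), total = length(pos),
        fraction = mean(pos), stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  tests <- NULL
  if (length(libraries) >= 2) {
    l1 <- names(libraries)[1]; l2 <- names(libraries)[2]
    trows <- list()
    for (fam in names(consensuses)) {
      c1 <- counts[counts$library == l1 & counts$family == fam, ]
      c2 <- counts[counts$library == l2 & counts$family == fam, ]
      tst <- proportion_test(c1$positives, c1$total,
                             c2$positives, c2$total)
      trows[[fam]] <- data.frame(
        family = fam, statistic = tst$statistic, p_value = tst$p_value,
        method = tst$method, stringsAsFactors = FALSE)
    }
    tests <- do.call(rbind, trows)
    rownames(tests) <- NULL
  }
  structure(list(counts = counts, tests = tests),
            class = "abundance_result")
}

#' @export
print.abundance_result <- function(x, ...) {
  cat("satellite abundance per library:\n")
  print(x$counts, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("between-library two-proportion tests:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}
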