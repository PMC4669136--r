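# Nucleotide primitives and sequence IO.
#
# Sequences are plain uppercase character strings over {A,C,G,T,N} plus IUPAC
# ambiguity codes; collections are named character vectors (names = ids).
# Heavier containers (DNAStringSet) are used only at the IO boundary.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

.check_nucleotides <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_COMPLEMENT))
  if (length(bad) > 0) {
    stop(sprintf("non-nucleotide character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(chars)
}

.normalize_seq <- function(seq) toupper(seq)

#' Reverse complement of nucleotide sequences
#'
#' IUPAC ambiguity codes map to their complements (N to N, R to Y, ...).
#'
#' @param seq character vector of nucleotide strings (case-insensitive).
#' @return character vector of reverse complements (uppercase).
#' @examples
#' reverse_complement("AAAC")   # "GTTT"
#' reverse_complement("GANTC")  # its own reverse complement
#' @export
reverse_complement <- function(seq) {
  seq <- .normalize_seq(seq)
  vapply(seq, function(s) {
    if (nchar(s) == 0) return("")
    chars <- .check_nucleotides(s)
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Match an IUPAC pattern against a nucleotide window
#'
#' @param pattern IUPAC string (same length as `window`); N matches anything.
#' @param window nucleotide string over A/C/G/T.
#' @return logical scalar: TRUE iff every pattern code's nucleotide set
#'   contains the corresponding window base.
#' @examples
#' iupac_match("GANTC", "GATTC")  # TRUE
#' iupac_match("RY", "AC")        # TRUE
#' @export
iupac_match <- function(pattern, window) {
  pattern <- .normalize_seq(pattern)
  window <- .normalize_seq(window)
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window must have equal lengths", call. = FALSE)
  }
  pc <- .check_nucleotides(pattern, "pattern")
  wc <- .check_nucleotides(window, "window")
  all(mapply(function(p, w) w %in% IUPAC_SETS[[p]], pc, wc))
}

#' AT content of a sequence
#'
#' Ambiguity codes are excluded from both numerator and denominator.
#'
#' @param seq nucleotide string.
#' @return fraction (#A + #T) / (#A + #C + #G + #T), or `NA` when the sequence
#'   contains no unambiguous base.
#' @examples
#' at_content("ACGT")  # 0.5
#' @export
at_content <- function(seq) {
  seq <- .normalize_seq(seq)
  if (nchar(seq) == 0) stop("empty sequence", call. = FALSE)
  chars <- .check_nucleotides(seq)
  n_at <- sum(chars %in% c("A", "T"))
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (n_acgt == 0) return(NA_real_)
  n_at / n_acgt
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTQ qualities are parsed but discarded (analysis is sequence-only).
#'
#' @param path input file.
#' @param format "fasta", "fastq" or "auto" (by extension).
#' @return named character vector of uppercase sequences.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(gsub("-", "", seqs, fixed = TRUE))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write sequences to FASTQ with constant quality
#' @param seqs named character vector.
#' @param path output file.
#' @param quality_char single quality character for every base (default "I",
#'   Phred 40 on the Sanger scale).
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n",
                strrep(quality_char, nchar(seqs)))
  writeLines(rec, path)
  invisible(path)
}

#' Write a gapped alignment to FASTA (gaps kept)
#' @param rows named character vector of equal-length gapped strings.
#' @param path output file.
#' @export
write_gapped_fasta <- function(rows, path) {
  ids <- names(rows)
  if (is.null(ids)) ids <- sprintf("row%04d", seq_along(rows))
  writeLines(paste0(">", ids, "\n", rows), path)
  invisible(path)
}

#' Read an EMBL flat file (ID + sequence only)
#'
#' Minimal reader for deposited monomer records: extracts the primary
#' accession from each ID line and the concatenated sequence block.
#'
#' @param path EMBL flat file, possibly with multiple entries.
#' @return named character vector of uppercase sequences.
#' @export
read_embl <- function(path) {
  lines <- readLines(path)
  out <- character(0)
  id <- NULL
  seq_open <- FALSE
  buf <- character(0)
  flush <- function() {
    if (!is.null(id)) {
      s <- toupper(gsub("[^A-Za-z]", "", paste(buf, collapse = "")))
      out[[id]] <<- s
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "ID ")) {
      flush()
      id <- sub(";.*$", "", sub("^ID\\s+", "", ln))
      id <- trimws(id)
      seq_open <- FALSE
      buf <- character(0)
    } else if (startsWith(ln, "SQ ")) {
      seq_open <- TRUE
    } else if (startsWith(ln, "//")) {
      flush()
      id <- NULL
      seq_open <- FALSE
      buf <- character(0)
    } else if (seq_open) {
      buf <- c(buf, ln)
    }
  }
  flush()
  out
}
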