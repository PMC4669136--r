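# Helpers around the study's deposited monomer sets (EMBL accessions).
# Fetching needs network access; all analyses run offline once the FASTA
# files exist locally.

DEPOSITED_SETS <- list(
  family180_clones = "LN831332-LN831351",   # PCR-cloned 176-178 bp monomers
  family180_reads  = "LN868813-LN868923",   # 176-178 bp monomers from reads
  family40_reads   = "LN868680-LN868812"    # 43 bp monomers from reads
)

#' Fetch the deposited monomer sets from ENA (network required)
#'
#' Downloads the three deposited accession ranges as FASTA into `dest`.
#' Analyses themselves never touch the network: run this once, then point
#' [deposited_stats()] at the directory.
#'
#' @param dest destination directory.
#' @return invisibly, the paths written.
#' @export
fetch_deposited <- function(dest) {
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(DEPOSITED_SETS)) {
    url <- paste0("https://www.ebi.ac.uk/ena/browser/api/fasta/",
                  DEPOSITED_SETS[[nm]])
    path <- file.path(dest, paste0(nm, ".fasta"))
    utils::download.file(url, path, quiet = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# Guess male/female labels from record descriptions/ids (deposited records
# are labelled MAL.../FEM...); NA when no tag is recognizable.
.sex_labels <- function(ids) {
  up <- toupper(ids)
  ifelse(grepl("MAL", up), "male",
         ifelse(grepl("FEM", up), "female", NA_character_))
}

#' Variability, diagnostic and HOR statistics on deposited monomer FASTAs
#'
#' Recomputes the printed characterization statistics from monomer FASTA
#' files: consensus length and AT content, overall/within-sex/between-sex
#' identity, shared identical positions and fixed diagnostic positions
#' (when sex labels are recognizable), and the HOR scan (when read of
#' origin and ordinal are encoded in the record ids as `...read<id>_<ord>`
#' or `<read>|<ord>`).
#'
#' @param fasta_paths character vector of monomer FASTA files for ONE
#'   family (combined before analysis).
#' @param anchor optional anchor consensus; defaults to a majority
#'   consensus bootstrapped from the sequences themselves.
#' @return list of statistics (elements NA when the needed metadata is not
#'   encoded in the deposited records).
#' @export
deposited_stats <- function(fasta_paths, anchor = NULL) {
  seqs <- unlist(lapply(fasta_paths, read_seqs))
  stopifnot(length(seqs) >= 3)
  if (is.null(anchor)) {
    # bootstrap an anchor: align everything to the first sequence, take the
    # majority consensus, then re-align
    msa0 <- build_msa(seqs, seqs[[1]], min_identity = 0)
    anchor <- as.character(majority_consensus(msa0))
  }
  labels <- .sex_labels(names(seqs))
  msa <- build_msa(seqs, anchor,
                   labels = if (all(is.na(labels))) NULL else labels,
                   min_identity = 0)
  cons <- as.character(majority_consensus(msa))
  rep <- identity_report(msa)
  dg <- NULL
  if (!any(is.na(labels)) && length(unique(labels)) == 2 &&
      all(table(labels) >= 2)) {
    dg <- diagnostic_positions(msa)
  }
  hor <- NULL
  m <- regmatches(names(seqs),
                  regexec("([A-Za-z0-9.-]+)[|_](\\d+)$", names(seqs)))
  ok <- lengths(m) == 3
  if (sum(ok) >= 10) {
    mon <- data.frame(
      monomer_id = names(seqs)[ok],
      read_id = vapply(m[ok], `[`, character(1), 2),
      ordinal = as.integer(vapply(m[ok], `[`, character(1), 3)),
      seq = unname(seqs[ok]), stringsAsFactors = FALSE)
    hor <- tryCatch(hor_scan(mon), error = function(e) NULL)
  }
  list(
    n_sequences = length(seqs),
    consensus = cons,
    consensus_length = nchar(cons),
    at_content = at_content(cons),
    overall_identity = rep$overall,
    within_identity = rep$within,
    between_identity = rep$between,
    fraction_identical = if (is.null(dg)) NA_real_ else dg$fraction_identical,
    n_diagnostic_positions = if (is.null(dg)) NA_integer_
                             else nrow(dg$diagnostics),
    hor = hor)
}
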