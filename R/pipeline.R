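# Pipeline configuration and orchestration. Subcommand wrappers are thin:
# the exported analysis functions do the work; `satkit.R` under
# inst/scripts/ exposes them from the shell.

#' Default pipeline configuration
#'
#' All stage parameters in one (JSON-serializable) list. Unknown keys in a
#' user config are rejected. Library sizes and abundances default to the
#' published world the synthetic generator emulates; `n_reads` scales both
#' libraries down for quick runs.
#'
#' @param n_reads optional per-library read count override.
#' @param seed integer seed for every stochastic stage.
#' @return nested named list.
#' @export
default_config <- function(n_reads = 4000, seed = 1) {
  list(
    seed = seed,
    simulate = list(
      n_reads = n_reads,
      arrays_per_family = 6,
      copies_per_array = list(sat43 = 120, sat177 = 40),
      background_length = 100000,
      background_at = 0.6
    ),
    nominate = list(k = 11, top_fraction = 0.08),
    period = list(p_min = 10, p_max = 250, threshold = 0.5,
                  n_reads = 100),
    monomerize = list(min_completeness = 0.95, min_identity = 0.55,
                      n_reads_per_family = 150, refine_rounds = 2),
    motifs = list(min_len = 8, min_identity = 0.65),
    hor = list(nc_threshold = 0.5, alt_threshold = 0.7,
               max_monomers = 250),
    tree = list(n_replicates = 100, max_leaves = 40,
                support_threshold = 70),
    digest = list(enzyme = "HinfI", u_min = 20, u_max = 500,
                  tolerance = 0.05, max_reads = 200),
    abundance = list(min_identity = 0.70, prefilter_k = 11)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON config and merges it over [default_config()]; unknown keys
#' (top level or within a stage) are rejected.
#'
#' @param path JSON file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  merge1 <- function(base, user, where) {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown) > 0) {
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (k in names(user)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
        merge1(base[[k]], user[[k]], paste0(where, "$", k))
      } else user[[k]]
    }
    base
  }
  merge1(base, user, "config")
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a `sat_msa` from gapped rows
#' @param rows named character vector of equal-length gapped strings.
#' @param labels optional per-row group labels.
#' @return a `sat_msa`.
#' @export
as_msa <- function(rows, labels = NULL) {
  stopifnot(length(unique(nchar(rows))) == 1)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- names(rows)
  structure(mat, class = c("sat_msa", "matrix"), labels = labels)
}

#' Infer a family consensus from reads of known period
#'
#' Seeds the consensus with one monomer-length window of the most
#' repetitive read, then iterates: extract monomers with the current
#' anchor, star-align them, take the majority consensus. The recovered
#' consensus is a rotation — possibly on the opposite strand — of the
#' underlying repeat unit (neither phase nor strand of a tandem repeat is
#' identifiable from the reads).
#'
#' @param reads named character vector of candidate tandem-array reads.
#' @param period monomer length (from [detect_period()]).
#' @param rounds refinement iterations.
#' @param min_identity extraction identity floor.
#' @return list with `consensus`, `monomers` (last-round monomer frame) and
#'   `msa`.
#' @export
infer_consensus <- function(reads, period, rounds = 2, min_identity = 0.5) {
  stopifnot(length(reads) >= 1, period >= 2)
  rep_score <- nominate_reads(reads, k = min(11, period), top_fraction = 1)
  seed_read <- reads[[rep_score$read_id[1]]]
  stopifnot(nchar(seed_read) >= period)
  anchor <- substr(seed_read, 1, period)
  monomers <- NULL
  msa <- NULL
  for (r in seq_len(rounds)) {
    monomers <- extract_monomers_all(reads, anchor,
                                     min_identity = min_identity)
    if (is.null(monomers) || sum(monomers$complete) < 2) {
      stop("too few complete monomers to build a consensus", call. = FALSE)
    }
    comp <- monomers[monomers$complete, ]
    msa <- build_msa(comp, anchor)
    anchor <- as.character(majority_consensus(msa, insertions = "drop"))
    # a seed anchor one base off the true unit length leaves one spread-out
    # gap per row that column-wise majority cannot remove: snap the anchor
    # to the median complete-monomer length by re-anchoring on the closest
    # actual monomer of that length
    med <- as.integer(round(median(nchar(comp$seq))))
    if (r < rounds && nchar(anchor) != med) {
      cand <- unique(comp$seq[nchar(comp$seq) == med])
      if (length(cand) > 0) {
        ids <- vapply(utils::head(cand, 25), function(s)
          pairwise_identity(s, anchor)$value, numeric(1))
        anchor <- cand[which.max(ids)]
      }
    }
  }
  list(consensus = anchor, monomers = monomers, msa = msa)
}

#' Run the full analysis pipeline on synthetic libraries
#'
#' Simulates the two-library synthetic world, then runs every stage:
#' nomination, period detection, consensus inference, monomer extraction,
#' motif detection, variability and diagnostic statistics, HOR scan,
#' NJ + bootstrap tree with sex-group support, in-silico digest ladder,
#' and between-library abundance tests. Artifacts are written under
#' `outdir`; a JSON summary is both written and returned.
#'
#' @param config see [default_config()].
#' @param outdir output directory (created).
#' @param quiet suppress progress messages.
#' @return invisibly, a nested list of stage summaries.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("satkit_"),
                         quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  summary <- list(seed = seed)

  # --- simulate -----------------------------------------------------------
  say("simulating genome and libraries (seed %d)", seed)
  fams <- list(make_family(example_family("sat43"), seed),
               make_family(example_family("sat177"), seed + 1))
  cpa <- config$simulate$copies_per_array
  genomes <- lapply(seq_along(fams), function(i) {
    simulate_genome(fams[i],
                    arrays_per_family = config$simulate$arrays_per_family,
                    copies_per_array = cpa[[fams[[i]]$spec$name]],
                    background_length = 0 + config$simulate$background_length,
                    background_at = config$simulate$background_at,
                    seed = seed + 10 * i)
  })
  genome <- .merge_genomes(genomes)
  lspecs <- example_library_specs(config$simulate$n_reads)
  libs <- list(
    male = simulate_library(genome, lspecs$male, seed + 101),
    female = simulate_library(genome, lspecs$female, seed + 202))
  for (lib in names(libs)) {
    write_fastq(libs[[lib]]$reads, file.path(outdir, paste0(lib, ".fastq")))
    .write_tsv(libs[[lib]]$read_truth,
               file.path(outdir, paste0(lib, "_read_truth.tsv")))
  }
  reads_all <- c(libs$male$reads, libs$female$reads)
  summary$simulate <- list(n_reads = length(reads_all))

  # --- nominate + period --------------------------------------------------
  say("nominating repeat-rich reads")
  nom <- nominate_reads(reads_all, k = config$nominate$k,
                        top_fraction = config$nominate$top_fraction)
  .write_tsv(nom[nom$nominated, ], file.path(outdir, "nominated.tsv"))
  # sample the nominated reads evenly across the repetitiveness ranking:
  # families differ widely in repetitiveness, so the very top of the list
  # can be monopolized by the most repetitive family
  n_nom <- sum(nom$nominated)
  ranks <- unique(round(seq(1, n_nom,
                            length.out = min(config$period$n_reads, n_nom))))
  top_ids <- nom$read_id[ranks]
  say("detecting repeat periods")
  calls <- lapply(reads_all[top_ids], detect_period,
                  p_min = config$period$p_min, p_max = config$period$p_max,
                  threshold = config$period$threshold)
  periods <- vapply(calls, function(x)
    if (x$no_period) NA_integer_ else x$period, integer(1))
  pt <- table(periods[!is.na(periods)])
  # group near-identical periods (+/- 1 bp) and keep groups seen >= 3 times
  fam_periods <- .period_groups(as.integer(names(pt)), as.integer(pt))
  summary$period <- list(calls = unname(periods), families = fam_periods)
  say("period groups: %s", paste(fam_periods, collapse = ", "))

  # --- per-family consensus, motifs, variability, HOR, tree, digest -------
  fam_out <- list()
  for (p in fam_periods) {
    fam_name <- sprintf("fam_p%d", p)
    say("characterizing %s", fam_name)
    fam_reads <- reads_all[top_ids[which(!is.na(periods) &
                                           abs(periods - p) <= 1)]]
    n_use <- min(config$monomerize$n_reads_per_family, length(fam_reads))
    inf <- infer_consensus(fam_reads[seq_len(n_use)], p,
                           rounds = config$monomerize$refine_rounds)
    write_fasta(setNames(inf$consensus, fam_name),
                file.path(outdir, paste0(fam_name, "_consensus.fasta")))
    monomers <- inf$monomers
    if (nrow(monomers) > config$hor$max_monomers) {
      keep_reads <- unique(monomers$read_id)
      monomers_hor <- monomers[monomers$read_id %in% keep_reads[
        seq_len(min(length(keep_reads), 60))], ]
    } else monomers_hor <- monomers
    .write_tsv(monomers, file.path(outdir, paste0(fam_name, "_monomers.tsv")))

    motifs <- find_internal_repeats(inf$consensus,
                                    min_len = config$motifs$min_len,
                                    min_identity = config$motifs$min_identity)
    .write_tsv(motifs, file.path(outdir, paste0(fam_name, "_motifs.tsv")))

    sex <- sub("_.*$", "", monomers$read_id[monomers$complete])
    comp <- monomers[monomers$complete, ]
    msa <- build_msa(comp, inf$consensus, labels = sex)
    write_gapped_fasta(msa_rows(msa),
                       file.path(outdir, paste0(fam_name, "_msa.fasta")))
    rep <- identity_report(msa)
    dg <- diagnostic_positions(msa)

    hor <- hor_scan(monomers_hor[monomers_hor$complete, ],
                    nc_threshold = config$hor$nc_threshold,
                    alt_threshold = config$hor$alt_threshold)

    sub <- seq_len(min(config$tree$max_leaves, nrow(msa)))
    msub <- as_msa(msa_rows(msa)[sub], labels = attr(msa, "labels")[sub])
    tree <- bootstrap_support(msub, n_replicates = config$tree$n_replicates,
                              seed = seed + 7)
    write_newick(tree, file.path(outdir, paste0(fam_name, "_nj.nwk")))
    gs <- group_support(tree, setNames(attr(msub, "labels"), rownames(msub)),
                        threshold = config$tree$support_threshold)

    enz <- enzyme_table()
    enz <- enz[enz$name == config$digest$enzyme, ]
    pos_reads <- names(reads_all)[nchar(reads_all) >= 2 * p][
      seq_len(min(config$digest$max_reads, sum(nchar(reads_all) >= 2 * p)))]
    frags <- unlist(lapply(fam_reads[seq_len(min(length(fam_reads),
                                                 config$digest$max_reads))],
                           function(rd) {
      d <- digest(rd, enz$site, enz$cut_offset, enz$name)
      f <- d$fragments
      if (length(f) >= 3) f[-c(1, length(f))] else numeric(0)  # internal only
    }))
    ladder <- if (length(frags) >= 3) {
      ladder_unit(frags, config$digest$u_min, config$digest$u_max,
                  config$digest$tolerance)
    } else list(unit = NA_integer_, support = NA_real_)

    fam_out[[fam_name]] <- list(
      period = p, consensus_length = nchar(inf$consensus),
      at_content = at_content(inf$consensus),
      n_monomers = nrow(monomers), n_complete = sum(monomers$complete),
      overall_identity = rep$overall,
      within_identity = as.list(rep$within),
      between_sex_identity = unname(rep$between),
      fraction_identical_positions = dg$fraction_identical,
      n_diagnostic_positions = nrow(dg$diagnostics),
      hor_order = hor$hor_order,
      non_contiguous_fraction = hor$non_contiguous_fraction,
      hor_within_identity = hor$within_identity,
      hor_between_identity = hor$between_identity,
      alternation_consistency = hor$alternation_consistency,
      sex_group_support = gs$verdict,
      n_motifs = nrow(motifs),
      ladder_unit = ladder$unit, ladder_support = ladder$support)
  }
  summary$families <- fam_out

  # --- abundance ----------------------------------------------------------
  say("classifying reads for abundance")
  consensuses <- lapply(fam_out, function(f) NULL)
  consensuses <- setNames(
    lapply(names(fam_out), function(fn)
      read_seqs(file.path(outdir, paste0(fn, "_consensus.fasta")))[[1]]),
    names(fam_out))
  ab <- abundance_stats(list(male = libs$male$reads,
                             female = libs$female$reads),
                        consensuses,
                        min_identity = config$abundance$min_identity,
                        prefilter_k = config$abundance$prefilter_k)
  .write_tsv(ab$counts, file.path(outdir, "abundance_counts.tsv"))
  if (!is.null(ab$tests)) {
    .write_tsv(ab$tests, file.path(outdir, "abundance_tests.tsv"))
  }
  summary$abundance <- list(counts = ab$counts, tests = ab$tests)

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("pipeline complete: %s", outdir)
  invisible(summary)
}

# Merge single-family genomes into one multi-family genome.
.merge_genomes <- function(genomes) {
  g <- genomes[[1]]
  if (length(genomes) > 1) {
    for (h in genomes[-1]) {
      extra <- h$sources$seq_id != "background"
      g$sequences <- c(g$sequences, h$sequences[h$sources$seq_id[extra]])
      g$sources <- rbind(g$sources, h$sources[extra, ])
      g$array_truth <- c(g$array_truth, h$array_truth)
      g$families <- c(g$families, h$families)
    }
  }
  g
}

# Cluster integer periods within +/- 1 bp and return one representative
# (the most frequent member) per group supported by >= 3 calls.
.period_groups <- function(values, counts) {
  if (length(values) == 0) return(integer(0))
  o <- order(values)
  values <- values[o]; counts <- counts[o]
  groups <- list(); cur <- 1
  for (i in seq_along(values)[-1]) {
    if (values[i] - values[i - 1] <= 1) cur <- c(cur, i)
    else { groups[[length(groups) + 1]] <- cur; cur <- i }
  }
  groups[[length(groups) + 1]] <- cur
  out <- integer(0)
  for (g in groups) {
    if (sum(counts[g]) >= 3) {
      out <- c(out, values[g][which.max(counts[g])])
    }
  }
  sort(out)
}

#' Run one pipeline subcommand
#'
#' Thin dispatcher used by the command-line script. `"simulate"` and
#' `"all"` run on the synthetic world from the config; the remaining
#' subcommands operate on files named in `args`.
#'
#' @param name subcommand: simulate, nominate, period, monomerize,
#'   consensus, motifs, variability, hor, tree, abundance, digest, all.
#' @param config a config list (see [default_config()] / [read_config()]).
#' @param args named list of subcommand inputs (paths) and outputs.
#' @return invisibly, the stage result; artifacts are written to
#'   `args$out` (a directory or file, per subcommand).
#' @export
run_subcommand <- function(name, config = default_config(), args = list()) {
  out <- args$out
  res <- switch(
    name,
    all = ,
    simulate = {
      if (name == "simulate") {
        cfg <- config
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        fams <- list(make_family(example_family("sat43"), cfg$seed),
                     make_family(example_family("sat177"), cfg$seed + 1))
        genome <- .merge_genomes(lapply(seq_along(fams), function(i)
          simulate_genome(fams[i],
                          arrays_per_family = cfg$simulate$arrays_per_family,
                          copies_per_array =
                            cfg$simulate$copies_per_array[[fams[[i]]$spec$name]],
                          background_length = cfg$simulate$background_length,
                          background_at = cfg$simulate$background_at,
                          seed = cfg$seed + 10 * i)))
        lspecs <- example_library_specs(cfg$simulate$n_reads)
        for (lib in names(lspecs)) {
          sim <- simulate_library(genome, lspecs[[lib]],
                                  cfg$seed + if (lib == "male") 101 else 202)
          write_fastq(sim$reads, file.path(out, paste0(lib, ".fastq")))
          .write_tsv(sim$read_truth,
                     file.path(out, paste0(lib, "_read_truth.tsv")))
          .write_tsv(sim$monomer_truth,
                     file.path(out, paste0(lib, "_monomer_truth.tsv")))
        }
        invisible(out)
      } else {
        run_pipeline(config, outdir = out)
      }
    },
    nominate = {
      reads <- read_seqs(args$reads)
      nom <- nominate_reads(reads, k = config$nominate$k,
                            top_fraction = config$nominate$top_fraction)
      .write_tsv(nom, out)
      nom
    },
    period = {
      reads <- read_seqs(args$reads)
      calls <- lapply(reads, detect_period, p_min = config$period$p_min,
                      p_max = config$period$p_max,
                      threshold = config$period$threshold)
      df <- data.frame(
        read_id = names(reads),
        period = vapply(calls, function(x)
          if (x$no_period) NA_integer_ else x$period, integer(1)),
        score = vapply(calls, function(x) {
          if (is.null(x$score) || length(x$score) == 0) NA_real_ else x$score
        }, numeric(1)),
        stringsAsFactors = FALSE)
      .write_tsv(df, out)
      df
    },
    monomerize = {
      reads <- read_seqs(args$reads)
      consensus <- read_seqs(args$consensus)[[1]]
      mon <- extract_monomers_all(
        reads, consensus,
        min_completeness = config$monomerize$min_completeness,
        min_identity = config$monomerize$min_identity)
      .write_tsv(mon, out)
      mon
    },
    consensus = {
      monomers <- read_seqs(args$monomers)
      anchor <- read_seqs(args$anchor)[[1]]
      msa <- build_msa(monomers, anchor)
      cons <- majority_consensus(msa)
      write_fasta(setNames(as.character(cons), "consensus"), out)
      if (!is.null(args$msa_out)) {
        write_gapped_fasta(msa_rows(msa), args$msa_out)
      }
      cons
    },
    motifs = {
      cons <- read_seqs(args$consensus)[[1]]
      hits <- find_internal_repeats(cons, min_len = config$motifs$min_len,
                                    min_identity = config$motifs$min_identity)
      .write_tsv(hits, out)
      hits
    },
    variability = {
      rows <- read_seqs(args$msa)
      labels <- sub("_.*$", "", names(rows))
      msa <- as_msa(rows, labels = labels)
      rep <- identity_report(msa)
      dg <- if (length(unique(labels)) == 2) diagnostic_positions(msa) else NULL
      res <- list(overall = rep$overall, within = as.list(rep$within),
                  between = as.list(rep$between),
                  fraction_identical = dg$fraction_identical,
                  n_diagnostics = if (is.null(dg)) NA else nrow(dg$diagnostics))
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      res
    },
    hor = {
      mon <- read.table(args$monomers, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, comment.char = "#")
      hor <- hor_scan(mon[mon$complete, ],
                      nc_threshold = config$hor$nc_threshold,
                      alt_threshold = config$hor$alt_threshold)
      jsonlite::write_json(hor[c("non_contiguous_fraction",
                                 "within_identity", "between_identity",
                                 "alternation_consistency", "hor_order")],
                           out, auto_unbox = TRUE, digits = NA)
      hor
    },
    tree = {
      rows <- read_seqs(args$msa)
      msa <- as_msa(rows)
      tree <- bootstrap_support(msa, n_replicates = config$tree$n_replicates,
                                seed = config$seed)
      write_newick(tree, out)
      tree
    },
    digest = {
      seqs <- read_seqs(args$seqs)
      enz <- enzyme_table()
      enz <- enz[enz$name == config$digest$enzyme, ]
      rows <- lapply(names(seqs), function(id) {
        d <- digest(seqs[[id]], enz$site, enz$cut_offset, enz$name)
        data.frame(seq_id = id, fragment = d$fragments,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      .write_tsv(df, out)
      df
    },
    abundance = {
      libs <- list()
      for (p in strsplit(args$reads, ",", fixed = TRUE)[[1]]) {
        nm <- sub("\\..*$", "", basename(p))
        libs[[nm]] <- read_seqs(p)
      }
      cons <- read_seqs(args$consensus)
      ab <- abundance_stats(libs, as.list(cons),
                            min_identity = config$abundance$min_identity,
                            prefilter_k = config$abundance$prefilter_k)
      .write_tsv(ab$counts, out)
      ab
    },
    stop(sprintf("unknown subcommand: %s", name), call. = FALSE)
  )
  invisible(res)
}
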