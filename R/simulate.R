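# Seeded generator of tandem-array genomes and pyrosequencing-like read
# libraries with planted ground truth.
#
# Mutation model: per-copy substitutions at a fixed per-base rate on
# "variable" columns (an optional fraction of columns is conserved and never
# substituted), the replacement base drawn uniformly from the 3 alternatives.
# Under this model two copies mutated at rate q agree at a variable site with
# probability (1-q)^2 + q^2/3, which gives closed-form calibration from
# target identities (see divergence_for_identity()).

#' Repeat-family specification
#'
#' @param name family name.
#' @param monomer_length monomer length in bp (>= 10).
#' @param at_target target AT fraction of the consensus.
#' @param motif_plan list of motif descriptors, each a list with `kind`
#'   ("direct" or "inverted"), `length` (bp), `copies` (>= 2) and `identity`
#'   (target identity between planted copies).
#' @param hor_order 1 (plain tandem) or 2 (dimeric higher-order repeat with
#'   two alternating monomer classes).
#' @param within_divergence per-copy substitution rate q applied to each
#'   emitted monomer (variable columns only).
#' @param between_divergence fraction of monomer columns at which the two
#'   HOR class consensuses differ (hor_order = 2 only); the differing
#'   columns are drawn from the variable (non-conserved, non-site) columns.
#' @param conserved_fraction fraction of monomer columns refractory to
#'   substitution (models the conserved boxes of real satellite families).
#' @param site_plan list of restriction-site descriptors, each a list with
#'   `enzyme`, `site` (IUPAC) and `intact_fraction` (fraction of monomer
#'   copies carrying an intact site).
#' @param indel_rate optional per-copy single-base indel rate (default 0;
#'   monomer-length variation in real families is secondary).
#' @return object of class `family_spec`.
#' @export
family_spec <- function(name, monomer_length, at_target = 0.6,
                        motif_plan = list(), hor_order = 1,
                        within_divergence = 0.05, between_divergence = 0,
                        conserved_fraction = 0, site_plan = list(),
                        indel_rate = 0) {
  stopifnot(monomer_length >= 10, hor_order %in% c(1, 2),
            within_divergence >= 0, within_divergence < 1,
            between_divergence >= 0, between_divergence < 1,
            conserved_fraction >= 0, conserved_fraction < 1,
            at_target >= 0, at_target <= 1, indel_rate >= 0)
  for (mp in motif_plan) {
    stopifnot(mp$length < monomer_length, mp$copies >= 2)
  }
  structure(list(name = name, monomer_length = monomer_length,
                 at_target = at_target, motif_plan = motif_plan,
                 hor_order = hor_order,
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 conserved_fraction = conserved_fraction,
                 site_plan = site_plan, indel_rate = indel_rate),
            class = "family_spec")
}

#' Per-copy substitution rate for a target pairwise identity
#'
#' Inverts identity(q) = (1-q)^2 + q^2/3, the probability that two copies
#' independently mutated at rate q agree at a site (uniform replacement).
#'
#' @param identity target mean pairwise identity in (1/4, 1].
#' @return substitution rate q.
#' @export
divergence_for_identity <- function(identity) {
  stopifnot(identity > 0.25, identity <= 1)
  # (4/3) q^2 - 2 q + (1 - identity) = 0, smaller root
  (2 - sqrt(4 - (16 / 3) * (1 - identity))) / (8 / 3)
}

#' Consensus divergence between HOR classes for a target between-class identity
#'
#' At a site where the two class consensuses differ, copies of different
#' classes mutated at rate q agree with probability (2q/3)(1-q) + 2q^2/9.
#' Solves for the fraction D of differing (variable) sites so that the
#' expected between-class identity equals `between`, given within-class
#' identity `within` at rate q.
#'
#' @param within expected within-class identity (at rate q).
#' @param between target between-class identity (< within).
#' @param q per-copy substitution rate.
#' @return fraction of variable columns at which class consensuses differ.
#' @export
between_divergence_for_identity <- function(within, between, q) {
  stopifnot(between < within)
  agree_diff <- (2 * q / 3) * (1 - q) + 2 * q^2 / 9
  D <- (within - between) / (within - agree_diff)
  stopifnot(D > 0, D < 1)
  D
}

# Random sequence with (near-)exact target AT composition: base counts are
# fixed by rounding, positions shuffled. Keeps the realized AT content of
# short consensuses at the target instead of binomially scattered.
.random_seq <- function(n, at_target) {
  n_at <- round(n * at_target)
  nA <- n_at %/% 2; nT <- n_at - nA
  nC <- (n - n_at) %/% 2; nG <- n - n_at - nC
  paste(sample(rep(c("A", "T", "C", "G"), c(nA, nT, nC, nG))),
        collapse = "")
}

# Mutate a copy of `motif` to approximately the target identity
# (deterministic number of substitutions, random positions).
.degrade_motif <- function(motif, identity) {
  n <- nchar(motif)
  k <- round((1 - identity) * n)
  if (k == 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  pos <- sample.int(n, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Destroy chance matches of the planted recognition sites anywhere but at
# their planted position (tandem junction included), preferring to edit
# columns outside planted elements. `protect` is a logical mask of columns
# not to edit unless unavoidable.
.scrub_extra_sites <- function(chars, sites_df, protect) {
  L <- length(chars)
  for (r in seq_len(nrow(sites_df))) {
    site <- sites_df$site[r]
    slen <- nchar(site)
    pat <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
    for (pass in 1:10) {
      doubled <- paste0(paste(chars, collapse = ""),
                        paste(chars[seq_len(slen - 1)], collapse = ""))
      hits <- Biostrings::start(Biostrings::matchPattern(
        site, Biostrings::DNAString(doubled), fixed = FALSE))
      hits <- unique(((hits - 1L) %% L) + 1L)        # 1-based, mod L
      hits <- hits[hits != sites_df$start[r] + 1L]
      if (length(hits) == 0) break
      for (h in hits) {
        offs <- which(pat != "N")                    # N cannot be broken
        cols <- ((h - 1L + offs - 1L) %% L) + 1L
        free <- which(!protect[cols])
        o <- if (length(free) > 0) offs[free[1]] else offs[1]
        col <- ((h - 1L + o - 1L) %% L) + 1L
        alt <- setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[pat[o]]])
        chars[col] <- alt[1]
      }
    }
  }
  chars
}

# Render an IUPAC site as a concrete sequence (first base of each code set).
.concrete_site <- function(site) {
  chars <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) IUPAC_SETS[[c]][1], character(1)),
        collapse = "")
}

#' Generate a family consensus with planted motifs and restriction sites
#'
#' Draws a random sequence at the requested length and AT content, then
#' plants motif copies (direct or reverse-complemented) and one concrete
#' instance of each restriction site at non-overlapping positions.
#'
#' @param spec a [family_spec()].
#' @param seed integer seed.
#' @return list with `seq` (the consensus), `motifs` (data frame of planted
#'   copies: motif id, kind, 0-based half-open coordinates, target identity),
#'   `sites` (data frame of planted restriction sites) and `conserved_cols`
#'   (1-based indices of columns refractory to substitution).
#' @export
make_consensus <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(seed)
  L <- spec$monomer_length
  base <- .random_seq(L, spec$at_target)
  chars <- strsplit(base, "", fixed = TRUE)[[1]]

  taken <- rep(FALSE, L)
  place <- function(len) {
    free_starts <- which(vapply(seq_len(L - len + 1),
                                function(s) !any(taken[s:(s + len - 1)]),
                                logical(1)))
    if (length(free_starts) == 0) {
      stop(sprintf("cannot place a %d bp element without overlap (monomer %d bp, %d bp already occupied)",
                   len, L, sum(taken)), call. = FALSE)
    }
    s <- if (length(free_starts) == 1) free_starts else sample(free_starts, 1)
    taken[s:(s + len - 1)] <<- TRUE
    s
  }

  motif_rows <- list()
  mi <- 0
  for (mp in spec$motif_plan) {
    mi <- mi + 1
    m0 <- .random_seq(mp$length, spec$at_target)
    for (cp in seq_len(mp$copies)) {
      copy_seq <- if (cp == 1) m0 else .degrade_motif(m0, mp$identity)
      if (mp$kind == "inverted" && cp > 1) {
        copy_seq <- reverse_complement(copy_seq)
      }
      s <- place(mp$length)
      chars[s:(s + mp$length - 1)] <- strsplit(copy_seq, "", fixed = TRUE)[[1]]
      motif_rows[[length(motif_rows) + 1]] <- data.frame(
        motif = sprintf("motif%d", mi), kind = mp$kind, copy = cp,
        start = s - 1L, end = s + mp$length - 1L,
        target_identity = mp$identity, stringsAsFactors = FALSE)
    }
  }

  site_rows <- list()
  for (sp in spec$site_plan) {
    site_seq <- .concrete_site(sp$site)
    len <- nchar(site_seq)
    s <- place(len)
    chars[s:(s + len - 1)] <- strsplit(site_seq, "", fixed = TRUE)[[1]]
    site_rows[[length(site_rows) + 1]] <- data.frame(
      enzyme = sp$enzyme, site = sp$site, start = s - 1L, end = s + len - 1L,
      intact_fraction = sp$intact_fraction, stringsAsFactors = FALSE)
  }

  # scrub chance occurrences of any planted recognition site elsewhere in
  # the monomer (including across the tandem junction), so that the site
  # count per monomer is exactly the planted one
  if (length(site_rows) > 0) {
    chars <- .scrub_extra_sites(chars, do.call(rbind, site_rows), taken)
  }

  planted <- which(taken)
  candidates <- setdiff(seq_len(L), planted)
  n_cons <- round(spec$conserved_fraction * L)
  conserved <- if (n_cons > 0) {
    if (n_cons > length(candidates)) {
      stop("conserved_fraction leaves no room next to planted elements",
           call. = FALSE)
    }
    sort(sample(candidates, n_cons))
  } else integer(0)

  list(seq = paste(chars, collapse = ""),
       motifs = if (length(motif_rows)) do.call(rbind, motif_rows) else
         data.frame(),
       sites = if (length(site_rows)) do.call(rbind, site_rows) else
         data.frame(),
       conserved_cols = conserved)
}

#' Instantiate a family: consensus plus (for HORs) class consensuses
#'
#' For `hor_order = 2` a second class consensus is derived from the first by
#' substituting a `between_divergence` fraction of the variable columns, so
#' that identities between monomers of different classes land at the
#' calibrated level while conserved columns and planted sites are shared.
#'
#' @param spec a [family_spec()].
#' @param seed integer seed.
#' @return object of class `sat_family` with elements `spec`, `consensus`,
#'   `motifs`, `sites`, `conserved_cols`, `class_consensus` (character vector
#'   of length `hor_order`).
#' @export
make_family <- function(spec, seed = 1) {
  cons <- make_consensus(spec, seed = seed)
  set.seed(seed + 1000003L)
  L <- spec$monomer_length
  protected <- cons$conserved_cols
  if (nrow(cons$sites) > 0) {
    for (r in seq_len(nrow(cons$sites))) {
      protected <- union(protected,
                         (cons$sites$start[r] + 1):(cons$sites$end[r]))
    }
  }
  variable_cols <- setdiff(seq_len(L), protected)
  classes <- cons$seq
  if (spec$hor_order == 2) {
    k <- round(spec$between_divergence * L)
    if (k > length(variable_cols)) {
      stop("between_divergence exceeds the available variable columns",
           call. = FALSE)
    }
    chars <- strsplit(cons$seq, "", fixed = TRUE)[[1]]
    flip <- sort(sample(variable_cols, k))
    for (p in flip) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    if (nrow(cons$sites) > 0) {
      prot <- rep(FALSE, L)
      prot[setdiff(seq_len(L), variable_cols)] <- TRUE
      chars <- .scrub_extra_sites(chars, cons$sites, prot)
    }
    classes <- c(cons$seq, paste(chars, collapse = ""))
  }
  structure(list(spec = spec, consensus = cons$seq, motifs = cons$motifs,
                 sites = cons$sites, conserved_cols = cons$conserved_cols,
                 variable_cols = variable_cols,
                 class_consensus = classes),
            class = "sat_family")
}

# Substitute bases of one monomer copy at rate q on the allowed columns.
.mutate_copy <- function(chars, q, allowed) {
  if (q <= 0 || length(allowed) == 0) return(chars)
  hit <- allowed[runif(length(allowed)) < q]
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  chars
}

#' Simulate a tandem array of a repeat family
#'
#' Tiles monomer copies (alternating the two class consensuses when
#' `hor_order = 2`), mutating each copy independently at the within-class
#' rate on variable columns, and destroying each planted restriction site in
#' a (1 - intact_fraction) share of copies by a targeted substitution at the
#' site's first base.
#'
#' @param family a [make_family()] object (or a [family_spec()], in which
#'   case the family is instantiated with the same seed).
#' @param n_copies number of monomer copies (>= 1).
#' @param seed integer seed.
#' @param class_start index (1-based) of the class used for the first copy.
#' @return list with `seq` (array sequence) and `truth` (data frame: copy
#'   ordinal, 0-based half-open start/end within the array, class index, and
#'   one logical column per planted enzyme site indicating an intact site).
#' @export
simulate_array <- function(family, n_copies, seed = 1, class_start = 1) {
  if (inherits(family, "family_spec")) family <- make_family(family, seed)
  stopifnot(inherits(family, "sat_family"), n_copies >= 1)
  set.seed(seed)
  spec <- family$spec
  L <- spec$monomer_length
  q <- spec$within_divergence
  mutable <- family$variable_cols
  n_classes <- length(family$class_consensus)
  class_chars <- lapply(family$class_consensus,
                        function(s) strsplit(s, "", fixed = TRUE)[[1]])
  site_df <- family$sites
  site_protect <- rep(FALSE, L)
  if (nrow(site_df) > 0) {
    for (r in seq_len(nrow(site_df))) {
      site_protect[(site_df$start[r] + 1):site_df$end[r]] <- TRUE
    }
  }
  copies <- character(n_copies)
  truth_rows <- vector("list", n_copies)
  pos <- 0L
  for (i in seq_len(n_copies)) {
    cls <- ((i - 1 + class_start - 1) %% n_classes) + 1
    chars <- .mutate_copy(class_chars[[cls]], q, mutable)
    site_intact <- logical(nrow(site_df))
    if (nrow(site_df) > 0) {
      for (r in seq_len(nrow(site_df))) {
        intact <- runif(1) < site_df$intact_fraction[r]
        site_intact[r] <- intact
        if (!intact) {
          p <- site_df$start[r] + 1L
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        }
      }
    }
    if (spec$indel_rate > 0 && runif(1) < spec$indel_rate) {
      p <- sample.int(length(chars), 1)
      if (runif(1) < 0.5) chars <- chars[-p]
      else chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = p)
    }
    copies[i] <- paste(chars, collapse = "")
    len <- length(chars)
    row <- data.frame(ordinal = i - 1L, start = pos, end = pos + len,
                      class = cls, stringsAsFactors = FALSE)
    if (nrow(site_df) > 0) {
      for (r in seq_len(nrow(site_df))) {
        row[[paste0("intact_", site_df$enzyme[r])]] <- site_intact[r]
      }
    }
    truth_rows[[i]] <- row
    pos <- pos + len
  }
  truth <- do.call(rbind, truth_rows)
  seq <- paste(copies, collapse = "")
  if (nrow(site_df) > 0) {
    # the site plan controls site occurrence per monomer: remove sites
    # created by chance through the random substitutions, including at
    # copy junctions
    seq <- .scrub_array_sites(seq, site_df, truth)
  }
  list(seq = seq, truth = truth)
}

# Destroy chance site matches anywhere in an assembled array except at the
# planted per-copy positions. Edits avoid planted site footprints.
.scrub_array_sites <- function(seq, site_df, truth) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (r in seq_len(nrow(site_df))) {
    site <- site_df$site[r]
    pat <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
    planted0 <- truth$start + site_df$start[r]          # 0-based starts
    footprint <- rep(FALSE, length(chars))
    for (p in planted0) {
      cols <- (p + 1):(p + length(pat))
      footprint[cols[cols <= length(chars)]] <- TRUE
    }
    for (pass in 1:5) {
      hits <- Biostrings::start(Biostrings::matchPattern(
        site, Biostrings::DNAString(paste(chars, collapse = "")),
        fixed = FALSE))
      hits <- hits[!(hits - 1L) %in% planted0]
      if (length(hits) == 0) break
      for (h in hits) {
        offs <- which(pat != "N")
        cols <- h - 1L + offs
        free <- which(!footprint[cols])
        o <- if (length(free) > 0) offs[free[1]] else offs[1]
        alt <- setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[pat[o]]])
        chars[h - 1L + o] <- alt[1]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Library specification for read simulation
#'
#' Defaults mimic long pyrosequencing reads: truncated-normal read lengths
#' (mean 350, sd 100, min 50) and a low post-trimming substitution error
#' rate (0.001, i.e. Q30-quality-trimmed reads).
#'
#' @param label library label (e.g. "male"/"female").
#' @param n_reads number of reads (>= 1).
#' @param read_len_mean,read_len_sd,read_len_min read-length model (bp).
#' @param error_rate per-base substitution error rate.
#' @param abundance named numeric vector: per-family fraction of reads drawn
#'   from that family's arrays (must sum to <= 1; remainder is background).
#' @return object of class `library_spec`.
#' @export
library_spec <- function(label, n_reads, read_len_mean = 350,
                         read_len_sd = 100, read_len_min = 50,
                         error_rate = 0.001, abundance = numeric(0)) {
  stopifnot(n_reads >= 1, sum(abundance) <= 1, all(abundance >= 0),
            error_rate >= 0, error_rate < 1)
  structure(list(label = label, n_reads = as.integer(n_reads),
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 read_len_min = read_len_min, error_rate = error_rate,
                 abundance = abundance),
            class = "library_spec")
}

#' Assemble a synthetic genome of tandem arrays plus background
#'
#' @param families list of `sat_family` objects (or `family_spec`s).
#' @param arrays_per_family,copies_per_array array layout per family.
#' @param background_length length of the single random background sequence.
#' @param background_at AT fraction of the background.
#' @param seed integer seed.
#' @return object of class `sat_genome`: list with `sequences` (named
#'   character vector: one background plus one sequence per array),
#'   `sources` (data frame naming the family of every sequence) and
#'   `array_truth` (per-array monomer truth tables).
#' @export
simulate_genome <- function(families, arrays_per_family = 8,
                            copies_per_array = 60,
                            background_length = 100000,
                            background_at = 0.6, seed = 1) {
  set.seed(seed)
  families <- lapply(families, function(f) {
    if (inherits(f, "family_spec")) make_family(f, seed) else f
  })
  seqs <- c(background = .random_seq(background_length, background_at))
  sources <- data.frame(seq_id = "background", family = "background",
                        stringsAsFactors = FALSE)
  truth <- list()
  for (f in families) {
    nm <- f$spec$name
    for (a in seq_len(arrays_per_family)) {
      arr <- simulate_array(f, copies_per_array,
                            seed = seed + 7919L * a + sum(utf8ToInt(nm)))
      sid <- sprintf("%s_array%02d", nm, a)
      seqs[[sid]] <- arr$seq
      sources <- rbind(sources, data.frame(seq_id = sid, family = nm,
                                           stringsAsFactors = FALSE))
      truth[[sid]] <- arr$truth
    }
  }
  structure(list(sequences = seqs, sources = sources, array_truth = truth,
                 families = families),
            class = "sat_genome")
}

#' Simulate a read library from a synthetic genome
#'
#' Each read is drawn either from one family's arrays or from the background
#' at the library's target proportions, at a uniform position and strand;
#' per-base substitution errors are applied at the library's error rate.
#' Reads longer than their source sequence are truncated and flagged.
#'
#' @param genome a [simulate_genome()] object.
#' @param lspec a [library_spec()].
#' @param seed integer seed.
#' @return list with `reads` (named character vector), `read_truth` (data
#'   frame: read id, source family, source sequence, 0-based start, strand,
#'   length, truncated flag) and `monomer_truth` (data frame of monomer
#'   intervals within each satellite read, 0-based half-open in original
#'   read coordinates, with class and completeness flag).
#' @export
simulate_library <- function(genome, lspec, seed = 1) {
  stopifnot(inherits(genome, "sat_genome"), inherits(lspec, "library_spec"))
  set.seed(seed)
  n <- lspec$n_reads
  fams <- names(lspec$abundance)
  stopifnot(all(fams %in% genome$sources$family))
  probs <- c(lspec$abundance, background = 1 - sum(lspec$abundance))
  category <- sample(names(probs), n, replace = TRUE, prob = probs)

  rl <- pmax(lspec$read_len_min,
             round(rnorm(n, lspec$read_len_mean, lspec$read_len_sd)))

  # pick a source sequence per read (arrays weighted by length)
  src <- character(n)
  for (cat in unique(category)) {
    idx <- which(category == cat)
    sids <- genome$sources$seq_id[genome$sources$family == cat]
    lens <- nchar(genome$sequences[sids])
    src[idx] <- if (length(sids) == 1) sids else
      sample(sids, length(idx), replace = TRUE, prob = lens)
  }
  src_len <- nchar(genome$sequences[src])
  truncated <- rl > src_len
  rl[truncated] <- src_len[truncated]
  start <- floor(runif(n) * (src_len - rl + 1))   # 0-based
  strand <- ifelse(runif(n) < 0.5, "+", "-")

  reads <- substring(genome$sequences[src], start + 1, start + rl)
  minus <- which(strand == "-")
  if (length(minus) > 0) {
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  }

  # substitution errors
  if (lspec$error_rate > 0) {
    n_err <- rbinom(n, rl, lspec$error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(rl[i], n_err[i])
      for (p in pos) {
        old <- substr(reads[i], p, p)
        if (!old %in% c("A", "C", "G", "T")) next
        substr(reads[i], p, p) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
  } else n_err <- integer(n)

  ids <- sprintf("%s_read%06d", lspec$label, seq_len(n))
  names(reads) <- ids
  read_truth <- data.frame(
    read_id = ids, family = category, source = src, start = start,
    strand = strand, length = rl, truncated = truncated,
    n_errors = n_err, stringsAsFactors = FALSE)

  # monomer-level truth for satellite reads
  mt <- list()
  sat <- which(category != "background")
  for (i in sat) {
    at <- genome$array_truth[[src[i]]]
    w0 <- start[i]; w1 <- start[i] + rl[i]
    keep <- at$end > w0 & at$start < w1
    if (!any(keep)) next
    sub <- at[keep, , drop = FALSE]
    s <- pmax(sub$start, w0) - w0
    e <- pmin(sub$end, w1) - w0
    complete <- sub$start >= w0 & sub$end <= w1
    if (strand[i] == "-") {
      ns <- rl[i] - e
      ne <- rl[i] - s
      o <- order(ns)
      s <- ns[o]; e <- ne[o]
      sub <- sub[o, , drop = FALSE]
      complete <- complete[o]
    }
    ord <- seq_len(nrow(sub)) - 1L
    mt[[length(mt) + 1]] <- data.frame(
      read_id = ids[i], family = category[i],
      monomer_index = ord, array_ordinal = sub$ordinal,
      start = s, end = e, class = sub$class, complete = complete,
      strand = strand[i], stringsAsFactors = FALSE)
  }
  monomer_truth <- if (length(mt)) do.call(rbind, mt) else
    data.frame(read_id = character(0), family = character(0),
               monomer_index = integer(0), array_ordinal = integer(0),
               start = integer(0), end = integer(0), class = integer(0),
               complete = logical(0), strand = character(0))

  list(reads = reads, read_truth = read_truth,
       monomer_truth = monomer_truth, spec = lspec)
}

#' Mutated copies of a consensus, with optional forced positions
#'
#' Convenience generator for variability studies: emits `n` monomer copies
#' mutated at rate `q`, optionally forcing specific columns to fixed bases
#' (e.g. to plant a diagnostic position in one group).
#'
#' @param consensus consensus string.
#' @param n number of copies.
#' @param q per-copy substitution rate.
#' @param seed integer seed.
#' @param force named character vector: names are 1-based column indices,
#'   values the base forced at that column in every copy.
#' @param prefix id prefix.
#' @return named character vector of monomer sequences.
#' @export
mutate_copies <- function(consensus, n, q, seed = 1,
                          force = character(0), prefix = "mono") {
  set.seed(seed)
  base <- strsplit(consensus, "", fixed = TRUE)[[1]]
  allowed <- setdiff(seq_along(base), as.integer(names(force)))
  out <- vapply(seq_len(n), function(i) {
    chars <- .mutate_copy(base, q, allowed)
    if (length(force) > 0) chars[as.integer(names(force))] <- force
    paste(chars, collapse = "")
  }, character(1))
  names(out) <- sprintf("%s%03d", prefix, seq_len(n))
  out
}

#' Built-in example family specifications
#'
#' Two families calibrated to the published world this package emulates:
#' `"sat43"`, a 43 bp monomer arranged as a dimeric higher-order repeat
#' (within-class identity 0.89, between-class identity 0.685, AT 60.5%),
#' with a 9 bp motif planted directly and inversely repeated and a HinfI
#' site intact in 70% of monomers; and `"sat177"`, a 177 bp monomer family
#' (mean pairwise identity 0.839 with 53% of columns conserved, AT 59%)
#' carrying two 23 bp direct copies at 70% identity and a HinfI site.
#'
#' Calibration is closed-form from the substitution model, accounting for
#' the default 0.001 sequencing error rate (see the methods vignette).
#'
#' @param name "sat43" or "sat177".
#' @return a [family_spec()].
#' @export
example_family <- function(name = c("sat43", "sat177")) {
  name <- match.arg(name)
  e <- 0.001   # library error rate assumed in calibration
  if (name == "sat43") {
    q_eff <- divergence_for_identity(0.89)
    q <- max(q_eff - e, 0)
    D <- between_divergence_for_identity(0.89, 0.685, q_eff)
    family_spec(
      name = "sat43", monomer_length = 43, at_target = 0.605,
      motif_plan = list(list(kind = "inverted", length = 9, copies = 2,
                             identity = 1.0)),
      hor_order = 2, within_divergence = q, between_divergence = D,
      conserved_fraction = 0,
      site_plan = list(list(enzyme = "HinfI", site = "GANTC",
                            intact_fraction = 0.7)))
  } else {
    # conserved fraction set so that ~53% of columns stay monomorphic over
    # ~131 sampled monomers at error rate e; variable-column rate set so the
    # overall mean pairwise identity lands at 0.839
    n_ref <- 131
    f <- 0.5311 / (1 - e)^n_ref
    w_var <- (0.839 - f * ((1 - e)^2 + e^2 / 3)) / (1 - f)
    q <- max(divergence_for_identity(w_var) - e, 0)
    family_spec(
      name = "sat177", monomer_length = 177, at_target = 0.59,
      motif_plan = list(list(kind = "direct", length = 23, copies = 2,
                             identity = 0.70)),
      hor_order = 1, within_divergence = q, conserved_fraction = f,
      site_plan = list(list(enzyme = "HinfI", site = "GANTC",
                            intact_fraction = 0.7)))
  }
}

#' Built-in example library specifications
#'
#' Male/female libraries at the published sizes (105,277 and 82,143 reads)
#' and satellite abundances (sat43: 3.93% vs 3.38%; sat177: 3.79% vs 3.05%).
#'
#' @param n_reads optional override of both library sizes (scaling down for
#'   quick runs); `NULL` keeps the published sizes.
#' @return list of two [library_spec()]s named "male" and "female".
#' @export
example_library_specs <- function(n_reads = NULL) {
  nm <- if (is.null(n_reads)) 105277L else n_reads
  nf <- if (is.null(n_reads)) 82143L else n_reads
  list(
    male = library_spec("male", nm,
                        abundance = c(sat43 = 0.0393, sat177 = 0.0379)),
    female = library_spec("female", nf,
                          abundance = c(sat43 = 0.0338, sat177 = 0.0305)))
}
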