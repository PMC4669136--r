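---
title: "Characterizing tandemly repeated satellite DNA from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing tandemly repeated satellite DNA from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Satellite DNAs are tandemly arrayed repeats — a short *monomeric unit*
repeated head-to-tail thousands of times, typically in heterochromatin.
Characterizing a newly discovered family from a long-read survey means
answering a fixed set of questions: What is the monomer length? What is the
consensus sequence and its AT content? Which internal sub-repeats (direct,
inverted, short) does the monomer carry? How variable are the copies, and do
they differ between groups of samples (here: male and female libraries of a
dioecious tree)? Are consecutive monomers organized into a *higher-order
repeat* (HOR) — an effective repeating unit of two or more divergent monomer
classes? And is the family differentially abundant between libraries?

`satkit` implements this workflow end to end, together with a fully seeded
simulator of tandem-array genomes and long-pyrosequencing-like read
libraries, so that every stage can be validated against planted ground truth
without any external download.

## The core machinery

### Wraparound alignment and monomerization

The central primitive is a linear-gap dynamic-programming aligner
(match +1, mismatch −1, gap −2; Rcpp) with three modes. The *wraparound*
mode treats the consensus as circular: the alignment path may enter at any
phase and traverse the consensus origin any number of times at no cost. Each
origin traversal is a monomer boundary, so a single alignment of a read
against its family consensus yields all monomers, their phases, strand, and
completeness (`extract_monomers()`). Ties between equal-scoring paths are
broken deterministically (diagonal over gaps, then gap-in-consensus over
gap-in-read), so every result is bit-reproducible.

Two identity conventions coexist and are kept explicit:

* *comparison identity* (default everywhere a published identity statistic
  is reproduced): matching columns / non-gap columns — the pairwise-deletion
  p-distance convention;
* *rejection identity* (used only for the question "is this read from this
  family at all?"): matching columns / all alignment columns. Random reads
  reach ≈ 0.52–0.56 gap-*excluded* identity against a short circular
  consensus, because the optimizer is free to choose the best of many paths;
  counting gap columns restores the separation (random ≈ 0.47–0.53, true
  family reads ≥ 0.8), which is why the extraction floor (0.55) and the
  abundance-classification threshold (0.70) are gap-inclusive.

### Repeat discovery

Reads are *nominated* by k-mer repetitiveness
(1 − distinct/total k-mers, default k = 11) — a deliberately lightweight
stand-in for graph-based read clustering; it ranks tandem-array reads far
above background but does not attempt to separate interspersed repeat
classes. The repeat *period* is the smallest shift whose self-match score
(fraction of positions where the read equals itself shifted by p) is within
0.02 of the maximum and above 0.5. One refinement matters for HORs: in a
dimeric family the score profile peaks at the HOR unit (2× the monomer),
with a secondary plateau at the monomer itself. The literal
smallest-within-epsilon rule would therefore report the *dimer*. We report
the smallest divisor p\*/k (k ≤ 4) of the peak that still clears the
threshold, and flag the peak as a harmonic; this matches the field's
convention that the "monomer" is the base unit and leaves HOR calling to the
dedicated statistic.

### Consensus and motifs

Monomers are star-aligned to an anchor (each monomer globally aligned to the
anchor, gaps merged; deterministic and adequate at ≤ 200 bp) and summarized
by a majority-rule consensus (alphabetical tie-break, ties recorded).
During *de novo* consensus inference the anchor is only an estimate: a seed
one base off the true unit length leaves one spread-out gap per row that no
column-wise majority can remove. Two measures keep the inferred length
honest: the consensus is computed over anchor-mapped columns only
(`insertions = "drop"`), and between refinement rounds the anchor snaps to
an actual monomer of the median complete-monomer length. The recovered
consensus is a rotation — possibly on the opposite strand — of the true
unit; neither phase nor strand of a tandem repeat is identifiable from
reads.

Internal repeats are found by an exhaustive scan over equal-length,
non-overlapping substring pairs (direct, and inverted via the reverse
complement), with ungapped (Hamming) identity. Reported hits are
maximal-score cores (score = matches − mismatches), which keeps a planted
exact 9-mer from being diluted by noisy flanks; the trade-off is that a
degraded motif may be reported slightly shorter than its planted extent.
Overlapping hits are reduced greedily by score, never keeping two hits whose
copy intervals overlap by more than half of the shorter. Hits under 12 bp
are additionally tagged "short" — the annotation class used for
sub-repeats — rather than given a kind of their own. The full hit *set* is
only guaranteed symmetric under reverse complement for the top
(planted-scale) hits: window representatives are chosen per diagonal start,
which can differ between a sequence and its mirror for marginal,
noise-level windows.

### Variability, diagnostic positions, HOR

`identity_report()` gives the mean pairwise identity over all unordered
pairs (not the mean of group means), per group and between groups.
`diagnostic_positions()` counts columns with a single state across both
groups ("identical in the two sexes"; the gap counts as a state) and
columns monomorphic within each group but different between them (fixed
diagnostic positions). The "identical" fraction is interpreted as
monomorphy across *all* sequences of both groups — the only reading
compatible with a shared-position fraction (≈ 53%) far below the mean
pairwise identity (≈ 84%); a consensus-versus-consensus reading would give
a number near the latter.

`hor_scan()` infers HOR structure directly from the monomer identity
matrix rather than from a tree: a monomer is *eligible* if an adjacent
monomer (same read, ordinal ± 1) is in the set; its nearest neighbour is
the highest-identity other monomer, with ties broken *toward* the adjacent
one, so that divergence-free data can never spuriously signal a HOR. The
non-contiguous fraction is the share of eligible monomers whose nearest
neighbour is not adjacent. A two-class partition (average-linkage
clustering on 1 − identity, cut at k = 2 — the dimeric case is the model;
higher orders are out of scope) yields within/between-class identities and
the alternation consistency of adjacent pairs; order 2 is called when the
non-contiguous fraction exceeds 0.5, the between-class identity is below
both within-class identities, and alternation exceeds 0.7 (all
configurable).

### Trees and abundance

Distances are p-distances (1 − identity, pairwise deletion); a
Kimura-style correction is deliberately not applied, keeping the tree scale
commensurate with the identity statistics. Neighbor joining is implemented
with explicit deterministic tie-breaking (lexicographically smallest pair
of cluster representatives at every Q-minimum; negative branch lengths
clamped to zero with the deficit recorded), and is cross-checked against an
independent implementation in the tests. Bootstrap support resamples
alignment columns, rebuilds the tree, and maps bipartition frequencies onto
the original topology. `group_support()` asks whether any internal edge
*exactly* separates a label group with support above 70% — the qualitative
question "do sequences cluster by sex / by HOR class".

Read classification for abundance uses the wraparound aligner on both
strands (positive: gap-inclusive identity ≥ 0.70 over at least one monomer
length), preceded by an exact k-mer prefilter (k = 11 against the doubled,
both-strand consensus) that skips alignment for reads sharing no k-mer with
the family. At k = 11 a true family read (≥ 85% identity over ≥ 150 bp)
retains a shared 11-mer with probability ≈ 1 − 10⁻⁶, while random reads
pass at ≈ 3 × 10⁻⁵ (and are then rejected by the alignment), so the filter
changes essentially no verdict — the tests assert filtered and unfiltered
runs agree. The male/female comparison is a pooled two-proportion z-test
without continuity correction (z² equals the 2 × 2 Pearson chi-square,
asserted exactly in the tests), with an automatic Fisher fallback when an
expected cell drops below 5. With only two families there is no multiple
testing correction, mirroring the original two-family report.

### Restriction ladders

`digest()` performs an in-silico digest (IUPAC-aware, forward strand; the
shipped enzyme battery uses palindromic sites, so forward scanning is
complete) and `ladder_unit()` infers the tandem unit from fragment
lengths: support of a candidate unit u is the fraction of fragment *mass*
within 5% of an integer multiple of u. Every divisor of the true unit
supports at least as much mass as the unit itself, so the reported unit is
chosen among all units within 0.05 support of the maximum as the one with
the smallest mean relative deviation from exact multiples, largest on ties.
A maximal support below 0.5 is reported as "no ladder".

## The synthetic world

The generator states one world and keeps it fixed:

* **sat43** — 43 bp monomer, AT 60.5%, dimeric HOR (two alternating monomer
  classes), a 9 bp motif planted directly and inversely repeated, a HinfI
  site intact in 70% of monomers.
* **sat177** — 177 bp monomer, AT 59%, no HOR, two 23 bp direct copies at
  70% identity, a HinfI site intact in 70% of monomers.
* **libraries** — male 105,277 and female 82,143 reads; truncated-normal
  read lengths (mean 350, sd 100, min 50 — long-pyrosequencing-like;
  unstated in the source, chosen once); substitution errors at 0.001/base
  (quality-trimmed reads); satellite abundances 3.93%/3.38% (sat43) and
  3.79%/3.05% (sat177) in male/female.

Mutation is substitution-only by default (real monomer lengths vary by only
a couple of bases, so indels are secondary; a per-copy indel rate is
available), with the replacement base uniform over the three alternatives.
That model has a closed form — two copies mutated at rate q agree at a site
with probability (1−q)² + q²/3 — which is inverted to calibrate the
generator to the published identity levels: within-class 0.89 and
between-class 0.685 for sat43; overall 0.839 for sat177. For sat177 a
fraction of columns is *conserved* (refractory to substitution): without
column heterogeneity, an 84% mean pairwise identity over ~131 copies would
leave essentially no column monomorphic, contradicting the published ~53%
shared-identical positions; the conserved fraction and the variable-column
rate are solved jointly from both constraints (accounting for the 0.001
error rate). Restriction-site occurrence is part of the stated world, so
chance site matches created by the random substitutions (including across
copy junctions) are scrubbed from the assembled arrays; without this, a
second in-phase site fragments the ladder into a constant sub-pattern.

Two published quantities are *not* reproducible in this clean two-class
world and are checked only against the deposited data: the overall 74.2%
identity of the 43 bp family (any two-class mixture at within 0.89 /
between 0.685 gives ≥ 0.787, because the within-pair fraction
π² + (1−π)² ≥ ½ for any class proportion π — the published value reflects
additional within-class structure), and the ≈ 60% non-contiguous
nearest-neighbour fraction (the clean dimer gives > 0.9; 60% reflects the
noise of real monomers). A green synthetic test therefore establishes
parameter *recovery*, not that real data would show these exact values.

## What a green test does and does not establish

The simulator emulates tandem arrays with planted structure and uniform
substitution noise. It does not emulate homopolymer-specific sequencing
errors, unequal crossover, library-preparation biases, or diploid genome
structure. Recovery results (period ± 1 bp, HOR order and class agreement
≥ 95%, identities within 2 percentage points, abundance significance at
the planted effect size) validate the *algorithms* under the stated world;
statistics on the deposited monomer sets are computed by the same code
paths via `deposited_stats()` once the FASTA files have been fetched
(`fetch_deposited()`, network required — all tests otherwise run offline).

## Numerical choices and degenerate inputs

* Alignment ties: diagonal > gap-in-b > gap-in-a; wraparound end column:
  largest on ties (so an exact trailing unit ends at the origin).
* Identity with no comparable columns is `NA` ("undefined"), never 0.
* `at_content()` excludes ambiguity codes from numerator and denominator;
  an all-ambiguous sequence is `NA`.
* NJ on an equidistant matrix returns a star-like tree with zero-length
  internal branches; non-symmetric or negative matrices are rejected.
* `detect_period()` on a sequence with no qualifying shift returns an
  explicit no-period result; harmonics of the reported period are flagged.
* Reads shorter than half a monomer, or below the alignment-identity
  floor, are rejected from monomerization with a recorded reason; reads
  shorter than the classification span count as negatives in the totals.
* Config files are JSON (no TOML parser is available in the supported
  stack); unknown keys are rejected rather than ignored.

## Known limitations

Star alignment accumulates no profile information, so columns near indels
can be locally misaligned relative to a full progressive MSA; the identity
statistics tolerate this at the ± 2 pp level but base-resolution column
claims near gaps should not be over-read. The motif scanner reports
trimmed maximal-score cores, not maximal threshold-qualifying windows. The
HOR machinery targets the dimeric case only. The nomination stage is not a
substitute for full read clustering when a genome carries many families of
similar repetitiveness.
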