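---
title: "Methods: cross-contamination purging and transporter classification"
author: "crosspurge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-contamination purging and transporter classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspurge)
```

## Why a pairwise, histogram-based procedure

Multiplexed Illumina sequencing misassigns a small fraction of reads
between samples sharing a lane. In de novo assemblies this does not show
up as a few stray reads but as complete, well-supported contigs of
*another project's* transcripts — typically the donor's most highly
expressed genes. Because the copies are assembled from the donor's own
reads, they are nearly identical to the donor contig (differing only by
sequencing and assembly error), while genuine between-species homologs
diverge much further. That separation in percent identity is the entire
basis of the procedure: within each pair of projects, contaminant hits
pile up at 100% identity (or just below) and true hits mass at the
species-to-species identity, leaving a local minimum in between.

The procedure is deliberately *pairwise*: contamination is a property of
a lane-sharing pair, thresholds differ by pair (closely related species
have high "true" identity, distant ones low), and pairs of projects that
are in fact the same species sequenced under two names are excluded
outright rather than decontaminated against each other
(`decontam_config(excluded_pairs = ...)`).

## Stage 1: soft-masking (symmetric DUST)

Low-complexity sequence produces spurious high-identity hits between
unrelated projects, exactly the signal the histogram trigger looks for.
Contigs are therefore soft-masked before comparison. The masker scores
every window of `window` nt (default 64) by its triplet composition,

$$S = \frac{10 \sum_t c_t (c_t - 1)/2}{m - 1},$$

where $c_t$ counts occurrences of triplet $t$ among the window's $m$
counted triplets (triplets touching an ambiguous base are skipped). Every
position covered by a window with $S > \mathrm{level}$ (default 20) is
lowercased; masked intervals separated by at most `linker` (default 1)
positions merge. A homopolymer saturates the score ($c = 62$ in a
64-window gives $S = 310$); a window whose 62 triplets are all distinct
scores 0. The defaults mirror the published defaults of the standard
DUST masker; the exact interval semantics of that tool's versions vary,
so the definition above — checked against an exhaustive per-window
oracle in the test suite — is normative for this package.

Masked positions are excluded from alignment *seeding* but remain
alignable inside extensions, so masking suppresses spurious hits without
truncating genuine ones. Masking is idempotent and only ever changes
case, never letters.

## Stage 2: all-vs-all comparison, gapless by design

Every cross-project contig pair is compared with a seed-and-extend local
aligner written for this package (C++ core): exact `seed_k`-mer seeds
(default 12) that are fully uppercase in both sequences, bidirectional
gapless x-drop extension (default 10), match +1 / mismatch −1, both
subject strands, and a raw-score cutoff `min_score = 64` — the score
cutoff used with the original procedure's aligner. Within a pair and
diagonal only the best-scoring alignment is kept, and `best_hits()`
reduces everything to the single top-scoring hit per unordered contig
pair (ties broken by identity, then length, then lexicographic ids, so
output is deterministic under input permutation).

Gapless alignment is a deliberate restriction, not a shortcut: the hits
that matter are near-identical copies, where indels are essentially
absent, and a gapless scorer with ±1 scoring makes score, alignment
length and identity mutually consistent (score = matches − mismatches)
and exactly reproducible by a brute-force all-diagonal scan — which is
how the aligner is tested. Externally computed (gapped) hit tables in
the standard 12-column tabular format can be ingested instead via
`read_hits_table()`.

With match = +1, a score-64 alignment is at least 64 nt long, so the
score cutoff and the 150-nt qualification below are two different
filters: the aligner cutoff limits what is *reported*, qualification
limits what enters the *histogram*.

## Stage 3: qualification, binning, threshold

A hit qualifies when the alignment spans ≥ `min_hit_len` (150 nt) **or**
≥ `min_frac_of_shorter` (50%) of the shorter contig — an inclusive OR:
requiring both would drop short-contig verbatim copies, which are
precisely the contaminants the procedure exists to catch.

Qualified identities are binned 1% wide. The bin rule is round-half-up
(`floor(pident + 0.5)`, configurable as `bin_rounding`): a copy with one
error in 300 nt has identity 99.67% and must land in the 100-adjacent
mass for the trigger to see it; floor-binning would demote every
imperfect copy out of bin 100 and break the trigger entirely.

Threshold detection follows the histogram shape. The pair is
contaminated only if `h(100) > h(99)`. Bins then descend from 99 in 1%
steps until three consecutive bins are found whose lower two each hold
at least as many hits as their predecessor — the first plateau of the
true-hit distribution. That first bin *t* is the threshold; hits
strictly above *t* are contaminant (the boundary bin is retained as
"true", the conservative reading; `threshold_inclusive` flips it). If
the scan exhausts without a plateau, the 100% peak has already fired and
no true-hit mass exists, so every populated bin below 100 is flagged
(`fallback_used`), with a warning.

## Stage 4: RPKM arbitration

By default both members of a flagged pair are discarded — with only
pairwise evidence, either could be the contaminant. Expression breaks
the tie: the contaminant copy is assembled from misassigned reads, a
small fraction of the donor's, so when one contig's RPKM is at least
`rpkm_ratio` (10×) the other's, the high-expression contig is retained
and the partner discarded; a partner with RPKM exactly 0 counts as
satisfying the ratio. Independently, a contig with RPKM ≥ `rpkm_retain`
(10,000) is always retained: extremely conserved, highly expressed genes
can legitimately match across species at high identity without a 10×
expression gap. Both exceptions are applied symmetrically to the two
members (the package's reading of a direction-ambiguous rule), so a pair
can end with both retained — e.g. both above 10,000 RPKM. The reason for
every decision (`default_both`, `rpkm_ratio_winner`, `rpkm_ratio_loser`,
`rpkm_high_expression`, `not_flagged`) is recorded for audit.

A contig flagged against several projects is discarded if *any* pair
decision discards it (discard dominates); purging removes discarded
contigs and their predicted proteins into separate "purged" files, as an
exact, order-preserving partition of the input.

## Sensitivity of the trigger at the bin boundary

The `h(100) > h(99)` trigger assumes the contaminant peak actually
concentrates in bin 100. The simulator's default conditions place
contaminant copies at a 0.5% per-site error — mean identity 99.5%,
*exactly at the 99/100 bin boundary* — so each contaminant hit falls in
bin 100 only with probability ≈ 0.55–0.65 (the probability that a
Binomial(L, 0.005) error count does not exceed its mean). With the
default four projects of 200 contigs and a 5% contamination rate, a
project pair carries only ~7 contaminant hits, and the trigger fires in
only roughly 60% of pairs. The consequence is visible in the measured
quantities the acceptance script computes: precision stays at 1 (a
triggered pair flags only true contaminants, and donors are rescued by
the RPKM rule), while recall is limited by the untriggered pairs. For
real index-misassignment contamination, which sits much closer to 100%
identity, the trigger is correspondingly more reliable; users simulating
or expecting heavily errored contaminants should treat recall — not
precision — as the vulnerable quantity, and can lower `bin` granularity
pressure only by pooling more hits per pair (more contigs, or fewer
multiplexed projects per comparison).

## The simulator

`simulate_projects()` generates the package's standard study conditions:
4 projects × 200 contigs, log-normal lengths (median ≈ 1000 nt, clamped
to 300–5000), 20% of contigs in two-project ortholog families, each
member mutated from the family ancestor at `divergence/2 = 0.075` per
site (substitutions always change the base), giving ≈ 85.7% pairwise
identity — comfortably below any plausible threshold; 5% of each
project's contigs copied into one other project at 0.5% per-site error
(≈ 99.5% identity) with read counts at 2% of the donor's, so the donor:
recipient RPKM ratio is ≈ 50×; native RPKM log-normal (median 100);
per-project totals are the realised count sums. All randomness flows
from one seed through an RNG-state-preserving wrapper, so runs are
byte-identical under a fixed seed.

What the simulator deliberately does *not* model: indels (so the gapless
aligner is exact and realized identity is analytically predictable),
fragmented or chimeric contaminant copies, position-dependent error
profiles, and within-project redundancy. Passing tests on simulated data
therefore demonstrate the correctness of the decision logic under the
stated identity structure, not robustness to assembly artefacts.

## Transporter classification

TMDs are predicted by the classic hydropathy criterion: the mean
Kyte–Doolittle value over a centred 19-residue window, threshold 1.6,
maximal runs merged across gaps < 5 residues, runs < 7 residues dropped.
This transparent predictor replaces the unversioned web tool used
historically for SIT work; its parameters are exposed (`tmd_params()`)
and the *tolerant* classification mode (SIT: 2 motif pairs and 8–12
TMDs; SIT-L: 1 pair and 4–6 TMDs) absorbs predictor disagreement about
marginal helices, while *strict* mode applies the literal definitions
(10 TMDs + 2 pairs; 5 TMDs + 1 pair). An equality-at-threshold guard of
1e-9 makes the run boundaries independent of floating-point summation
order.

Motif classes cover the documented variants — `E[GA]X[QKMH]` for the
EGXQ class (A-for-G, K/M/H-for-Q), `GRQ`/`GRH`/`GQS` for the GRQ class,
and the `xQxxxQx` glutamine pair of TMD4. A *pair* is an EGXQ hit within
15 residues before (or inside) TMD *n* plus a GRQ hit around TMD *n*+1,
assigned greedily left-to-right with each hit used at most once. The
15-residue margin is this package's quantification of the qualitative
"before the intracellular face" geometry; any adjacent TMD pair may
anchor a motif pair, not only 2/3 and 7/8, since truncated or atypical
sequences would otherwise be unclassifiable. Conserved single residues
(R/K between TMD2–3, E in TMD5, T in TMD8) are reported as annotation
notes only — they are conserved but not definitional.

Full SITs are split for half-vs-SIT-L phylogenetics at the midpoint of
the TMD5–TMD6 loop. The reference definition of this split point is an
alignment position against a reference diatom SIT; the midpoint rule
approximates it without requiring that alignment, and is a documented
divergence: on the package's canonical fixture each half re-classifies
as a 5-TMD, one-pair SIT-L, which is the property the split exists to
preserve.

## The tree screen

Given an existing support-annotated housekeeping-gene tree, the query is
walked from the tip outward through the bipartitions containing it
(their query-sides are nested, so the walk is well defined and
re-rooting invariant). At the first split with support strictly above
`support_threshold` (70): if the query's side contains any leaf of the
expected group, the query is clean; if all its non-query leaves belong
to one foreign group, the query is flagged — or excepted when that group
is in `exception_groups` (default: prokaryotes, whose presence reflects
common bacterial co-culture rather than misassignment); a well-supported
side mixing several foreign groups decides nothing and the walk
continues. No discriminating well-supported split means clean. In a
rooted binary newick the two root edges encode the same split, possibly
with two labels; the label on the clade containing the query governs,
the complement's label is the fallback — the reading that matches how
support values are attached to the clade "where the query branches".

## Numerical and degenerate-input choices

* Sequences shorter than 3 nt pass through the masker unchanged (warning);
  proteins shorter than the hydropathy window predict no TMDs (warning).
* `detect_threshold` on an all-zero histogram: `h(100) = h(99) = 0` is
  not contaminated — the trigger is strict.
* The fallback threshold is `max(0, lowest populated bin − 1)`; the clamp
  only matters in the unreachable bin-0 case.
* `best_hits` tie-breaking is total, so pipeline output is a pure
  function of the input set.
* Zero-length or zero-total expression records are errors, not zeros;
  a *missing* record for a flagged contig is an error when arbitration
  is enabled (silent rescue or silent discard would both be wrong).
* Proteins whose source contig is unknown fail open (retained, warned,
  counted): an id mismatch should surface in the report, not silently
  shrink the proteome.

## Problem sizes used by the tests

The test-suite and acceptance scenarios run the full pipeline on
4 × 200-contig projects over 20 simulation seeds (plus 20 ortholog-only
and 20 verbatim-copy seeds), the threshold detector against an
exhaustive oracle on 1000 random histograms, the aligner and masker
against brute-force oracles on 200 random instances each, and the tree
screen against an all-bipartition evaluation over every unrooted 6-leaf
topology. These sizes were chosen so the whole suite exercises every
rule path in a few minutes on one CPU while keeping the oracle
comparisons exhaustive where the space is enumerable.

## Known limitations

* Contamination evidence is pairwise only; no attempt is made to infer
  the *source* project beyond the per-hit evidence list.
* The histogram trigger needs a handful of contaminant hits per pair to
  be reliable, and degrades when contaminant identity sits at the
  99/100 bin boundary (see above).
* RPKM arbitration requires externally computed counts; the package does
  not map reads.
* The TMD predictor is a single-scale hydropathy window; it will
  disagree with modern topology predictors on marginal helices, which is
  why classification defaults to the tolerant ranges.
* The tree screen consumes a tree; it does not build one, select
  framework sequences, or judge alignment quality.
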