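---
title: "Methods and design of dgrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of dgrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrscan)
```

`dgrscan` implements a workflow for finding prophages in bacterial genome
assemblies, testing whether they replicate, and characterizing the
diversity-generating retroelements (DGRs) many of them carry. This vignette
explains the statistical procedures, the defaults and where they come from,
the design choices made where the procedure was genuinely open, and what the
package's synthetic data can and cannot establish.

## Window conventions

All positional signals are summarized over sliding windows laid 5'→3' from
position 1. Two conventions are used: bacterial contigs use a 3001 nt window
with a 500 nt step, phage genomes and alignments a 101 nt window with a
20 nt step. The last fully fitting window is extended 3'-wards to absorb an
uncovered tail of at most 1500 nt (bacterial) or 50 nt (phage). Because the
step never exceeds the extension + 1 in either convention, the windows
always cover the sequence exactly; a sequence shorter than one window is a
single window. The anchor at position 1 is a package decision (the
convention leaves the first window's anchor unspecified); it makes
enumeration deterministic and testable against brute-force recomputation.

Coordinates are 1-based inclusive in every function and file, except BED
output, which is 0-based half-open; the conversion lives in one function
(`regions_to_bed`) and is tested at the boundary.

## Prophage evidence and the region caller

Five per-window signals carry evidence of an integrated prophage: the four
nucleotide fractions (prophage composition differs from host), median ORF
length, median intergenic gap and strand-switch count (prophage genes are
shorter, tighter, and co-oriented), coding density, and the depth and
breadth of coverage by virus-like-particle (VLP) metagenome reads. Samples
whose reads cover more than 25% (strictly) of the cumulative strain assembly
are dropped as likely contaminated with bacterial DNA before any
read-recruitment evidence is used. "Covered" always means depth strictly
greater than zero.

The original evidence combination was visual. The caller here is an explicit
algorithmic stand-in, not a reconstruction: each signal becomes a robust
z-score against the whole contig (median/MAD), is multiplied by its expected
direction (+1 for depth and breadth, −1 for ORF length, gaps and strand
switches, either for composition), summed over the signals available in the
window, and thresholded at a summed z of 3.0. Windows over threshold merge
across gaps of at most one window; merged regions shorter than 15 kb are
dropped — conservative relative to typical prophage lengths of roughly
30–60 kb. Shuffling the tracks produces a region in fewer than 5% of trials
at these defaults (tested). Degenerate windows (all-N, fewer than two ORFs,
zero conserved columns, zero depth) always yield explicit missing values,
never silent zeros.

Induction is quantified by the coverage ratio: mean depth over the prophage
region divided by mean depth over the rest of its contig. A zero
denominator is reported as infinite with a flag rather than as an error.
For transposable (Mu-like) prophages, split-read junction positions are
clustered (positions within 100 nt collapse; the cluster's reported
position is its modal junction with that junction's own support, ties to
the smaller coordinate) and the two best-supported clusters are the
termini.

## DGR detection

DGR repeats are found by aligning the genome against itself and its reverse
complement with an in-package seed-and-extend local aligner: exact shared
words of length 12 seed the search, and each seed cluster is extended by
banded affine-gap Smith–Waterman with match +2, mismatch −3, gap open −5,
gap extend −2 (the classic BLASTN-style nucleotide scoring). The trivial
self-identity diagonal is excluded; mirror duplicates are canonicalized
away; alignments shorter than 90 columns or under 50% identity are
discarded; and overlapping alignments of the same locus pair reduce to the
highest-scoring representative. Replacing the external aligner's E-value
gate with these explicit gates makes the stage deterministic and testable:
an independent exhaustive enumerator (`exhaustive_repeat_alignments`, full
dynamic-programming matrix with iterative rectangle masking) validates the
seeded search in the test suite. Rectangle masking — rather than masking
whole rows and columns — matters because one template repeat may serve
several variable repeats and must be reported once per partner.

A repeat pair is a DGR pair when additionally it has at least 5 mismatches
and at least 75% of its mismatch columns (gap columns are neither mismatches
nor part of the denominator) hold adenine on one side. That side is the
template repeat (TR); the other is the variable repeat (VR). The bias is
evaluated on both strand readings of each side — a TR transcribed from the
minus strand shows its adenine bias as thymine in a plus-strand alignment —
which makes classification invariant under reverse complement of the whole
genome (tested). All boundaries are inclusive as stated: 90, 50%, 5, 75%.

Loci assemble by grouping pairs whose TRs overlap reciprocally by at least
50% (a package decision: one TR hitting two VRs yields two near-identical TR
intervals). The nearest reverse-transcriptase ORF is attached with its
distance (circular distance when requested); no distance cutoff is imposed,
but loci with the RT farther than 10 kb are flagged for review. VRs inside
an ORF are mapped to the codons they overlap, respecting strand; VRs
spanning an ORF edge are flagged partial, VRs outside every ORF intergenic.
RT genes themselves come from per-domain profile-search tables: envelopes of
the same protein–profile pair are unioned, pairs under 100 aa merged
coverage are dropped, the maximal-coverage profile wins (ties: smaller
e-value, then profile id), and the `RVT_1` profile marks an RT.

### Known limitations of the seeded detector (measured)

Two properties of optimal local alignment bound what any detector built on
these criteria can achieve, and were measured with this package's own
generator before the test suite was frozen:

* **Seeding completeness.** A shared exact 12-mer is guaranteed only when a
  repeat of length L carries fewer than `floor(L/12)` substitutions
  (pigeonhole): 9 for a 120 nt repeat. At 25 substitutions, roughly one
  planted pair in ten shares no 12-mer at all, and the seeded search —
  like any word-seeded aligner at that word size — cannot find it, while
  the exhaustive enumerator still does.
* **Edge trimming and flank extension.** Optimal local alignment trims a
  terminal mismatch (the trim gains +3 and loses 2 per dropped match), so
  substitutions planted at repeat edges can reduce the observed mismatch
  count below the ≥ 5 gate; conversely the alignment occasionally extends
  into randomly matching flank and picks up extra mismatch columns, which
  can push a 4-substitution pair over the gate or dilute the adenine
  fraction below 75%.

Consequently the planted-repeat detection probability is very close to,
but not exactly, 1 over the 5–25 substitution range (0.98 measured over
100 seeds) and not exactly 0 at 4 substitutions (0.17 measured). The
acceptance suite states the idealized claims and documents these edges; the
unit suite covers the regime where recovery is guaranteed.

## DGR activity

Activity leaves two signatures. Across cognate genomes (database genomes
covered ≥ 95% by high-identity hits to the query), per-column variation of
their alignment — one minus the frequency of the most frequent symbol, with
reference-gap columns dropped and non-reference gaps counted as a fifth
symbol — spikes at the VR, while the percentage of conserved adenine
columns among conserved columns (conserved: most frequent symbol ≥ 90%,
inclusive) dips, because hypermutation consumes precisely the adenines.
Ties for the most frequent symbol break in the fixed order A < C < G < T <
gap; the tie-break never affects the variation value itself. Windows with
no conserved column yield missing adenine percentages (the ratio is
undefined, not 0 or 100).

Within one sequenced sample, the same variation statistic per pileup
position (only A/C/G/T base calls are counted; depth-0 positions are
missing) captures a population mid-diversification. Samples qualify only
with depth ≥ 10 along ≥ 95% of the genome, both inclusive.

The activity call itself formalizes a visual judgment and is a package
decision: a VR is active when the mean windowed variation over windows
intersecting it exceeds the track median by more than 5 MADs (effect size
reported as (mean − median)/MAD). At the generator's defaults this yields
≥ 95% sensitivity at ≤ 5% false positives (tested); a flat track calls
nothing.

## Host linking and clustering

Detection rules are inclusive thresholds on merged-hit coverage fractions
(union of hit intervals over genome length): 0.75 for read breadth in bulk
metagenomes, 0.95 for isolate-genome hits, 0.30 for database matches to a
candidate-prophage region, 0.95 for cognates. Spacer–protospacer matching
is an exhaustive gap-free scan of both strands allowing
`floor(0.05 × length)` mismatches, so every reported match has ≥ 95%
identity over the full spacer; with typical 25–45 nt spacers this permits
at most 2 mismatches, making a Hamming scan both faithful and exhaustive
(validated against a position-by-position oracle). Species-level clustering
is the standard greedy pass over genomes sorted by decreasing length: join
the earliest-founded cluster whose representative has ANI ≥ 95% and ≥ 85%
coverage of the shorter genome, else found a new cluster. ANI tables are
consumed as input; asymmetric tables are symmetrized by the maximum.

## The synthetic generator

Every simulator takes an explicit seed, restores the caller's RNG state,
and returns full ground truth. The host-with-prophage generator emulates
the contrasts the evidence tracks test: i.i.d. sequence at two GC levels
(defaults 0.56 host — typical for *Faecalibacterium* — and 0.46 prophage),
host genes ~ Normal(900, 300) nt truncated at 150 vs prophage
Normal(450, 150), intergenic gaps Exponential with means 120 vs 40 nt,
strand-switch probabilities 0.35 vs 0.08. These defaults are package
choices: they only need to reproduce the qualitative contrasts at realistic
magnitudes, and they are not revisited per experiment. Depth profiles are
Poisson with the planted ratio; pileups put the reference base at each
position minus a 0.2% uniform error and a planted minor allele at VR
adenine targets; cognate sets apply background substitutions genome-wide
and adenine-targeted substitutions at the VR, so the identity alignment is
the true MSA and no aligner enters the tests; spacers are excised with an
exact mismatch count; junctions mix border draws with uniform noise.

What the generator does **not** emulate: real gene structure (no codon
bias, promoters, or operons), alignment uncertainty (cognates are
substitution-only, no indels), read-level artifacts (mapping bias, indels,
strand bias in pileups), mosaic prophage boundaries, or repeat families
beyond the planted DGR. A green test therefore establishes that each stage
recovers what it is defined to recover under its stated statistical model —
not performance on real assemblies, where composition signals are weaker
and alignments noisier.

## Numerical choices and degenerate inputs

Robust scale uses `stats::mad` with its default consistency constant.
Thresholds live in one structure (`dgr_thresholds()`) with validation and
named overrides; every CLI run logs the resolved values. Determinism rules:
window enumeration, region merging, terminus ties (smaller coordinate),
annotation ties (e-value, then profile id), alignment dedup (score, then
smallest end cell), and cluster founding order are all fixed, so identical
inputs give byte-identical outputs. Degenerate inputs — empty genomes,
ragged alignments, out-of-bounds intervals, negative counts, unknown ids —
raise immediate errors naming the offender; file readers name the file and,
for coordinate errors in annotations, the line.
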