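---
title: "Comparative microsatellite landscapes with ssrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative microsatellite landscapes with ssrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
library(ape)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are tandem repeats of
1–6 bp DNA motifs that accumulate very differently across genomes and
lineages. Comparing repeat landscapes between species requires four
ingredients that this package provides as one tested toolchain:

1. **Detection** of perfect (uninterrupted), imperfect (interrupted by a
   few edits) and compound (closely spaced) repeats in assembled genomes.
2. **Canonicalization**: a repeat read on either strand and at any phase
   is the same biological object, so motifs are grouped into classes
   under cyclic rotation and reverse complement. For motif sizes 1–6
   there are exactly 2, 4, 10, 33, 102 and 350 such classes — 501 in
   total — and every statistic in the package is keyed to this space.
3. **Normalization**: assemblies differ in size and in their content of
   unknown bases, so counts are expressed per Mbp of *valid* (non-N)
   sequence — relative abundance in loci/Mbp, relative density in
   bp/Mbp — while the percent-of-genome figure keeps the full assembly
   length as its denominator.
4. **Comparative models**: ranked-density score matrices for
   cross-species enrichment trends, Pearson correlations of repeat
   attributes with genome size, and Brownian-motion models of repeat
   abundance on a time-calibrated phylogeny, including a multirate
   penalized-likelihood fit that lets the rate itself evolve along the
   tree.

## Detection model and its parameters

A perfect SSR is a maximal run of a primitive repeat unit (a unit that
is not itself a repetition of a shorter one). Reported runs must reach a
minimum number of complete units, by motif size:

| motif size (bp) | 1 | 2 | 3 | 4 | 5 | 6 |
|---|---|---|---|---|---|---|
| min repeats | 12 | 7 | 5 | 5 | 5 | 5 |

These thresholds (`ssr_thresholds()`) are the conventional settings for
genome-scale repeat surveys; partial trailing units count toward neither
the repeat number nor the locus length, so `length == repeats * k`
always holds, and runs never span an unknown base. Scanning proceeds
smallest motif size first, masking emitted loci, so a `(AC)n` run is
never re-reported as a non-primitive `(ACAC)n`; where two runs of
different classes share bases at a junction, the leftmost run wins the
shared bases and the second is reported only if its remainder still
meets its threshold.

Imperfect repeats are found by seed-and-extend: every perfect run of at
least 3 units seeds a bidirectional extension scored against the ideal
repeat (+1 match, −1 mismatch, −2 indel). Extension stops when the score
drops more than 4 (twice the indel cost) below its running maximum or
when more than 2 consecutive positions are edits; the reported locus is
the score-maximal extent, kept only if it contains at least one edit
(otherwise it is a perfect repeat) and scores at least 10. Overlapping
imperfect loci of one class resolve to the higher-scoring call. These
parameters (`issr_params()`) are exposed because the literature's
repeat-mining tools do not agree on a single convention.

Compound repeats chain perfect loci separated by at most `d_max = 10` bp
into maximal chains of two or more components. Perfect loci that are
members of a chain are flagged; by default they still count in
perfect-repeat statistics (the behavior of the common mining tools), and
the flag lets a user exclude them instead.

## Genic localization

Exon/CDS intervals come from GFF3; introns are derived per transcript as
the gaps between consecutive exons whenever intron features are absent.
Classification uses union semantics across transcripts — a base is CDS
if it is coding in *any* transcript — and the priority CDS > exon >
intron, requiring the locus to be fully contained in the class union.
Annotation formats do not dictate what to do with a locus that straddles
a boundary (e.g. half in an exon, half in the following intron); the
package assigns such loci the class containing their start position,
which is deterministic, single-valued, and order-independent. Loci on
sequences missing from the annotation, or contained in no gene, are
intergenic.

## The ranked-density score matrix

To compare class-specific enrichment across species on a common scale,
each species' 501 class densities are ranked (descending; ties broken
lexicographically by canonical motif so that the row caps below are
exact). Ranks 1–5 score 3, ranks 6–20 score 2, ranks 21–35 score 1;
remaining classes with density above 1 score 0, those with density in
(0, 1] score −1, and classes absent from the genome score −2. Two
reading choices were genuinely open and are fixed as follows: the
boundary density of exactly 1 falls in the −1 bin ("between 0 and 1" is
read as a half-open interval from above), and zero-density classes never
receive a rank-based score even when fewer than 35 classes are present —
so every row carries at most five 3s, fifteen 2s and fifteen 1s. The
matrix is computed from relative density (bp/Mbp) by default; a
configuration switch (`ssr_config(density_metric = "rel_abundance")`)
ranks loci/Mbp instead, since either reading of "density" is defensible.

## Brownian-motion rate models

Repeat abundance (loci/Mbp) is treated as a continuous trait evolving on
a rooted time tree. Under single-rate Brownian motion the tip vector is
multivariate normal with covariance σ² × shared path length;
`fit_single_rate()` uses the closed-form GLS estimates (ML by default,
REML by flag — for two tips REML gives the familiar
(x₁−x₂)²/(t₁+t₂)).

The multirate model (`fit_multirate()`) places a log-rate at every tip
and internal node. A branch's rate is exp of the mean of its two
incident node log-rates, and the fit maximizes

> log L(trait | branch rates) + λ · log P(node log-rates | BM on the tree)

with the root state profiled analytically at each evaluation. The
penalty is the log-density of the log-rates under Brownian motion with
**unit rate**: profiling the rate of this second-level process instead
would let the penalty diverge as the rates homogenize (its variance
estimate collapses to zero), so fixing it at 1 keeps the objective
bounded and makes λ an interpretable smoothing weight. λ = 1 is the
default; λ → ∞ collapses all node rates to a common value and recovers
the single-rate maximum likelihood. Optimization is quasi-Newton
(`nlminb`) on the node log-rates, started from the single-rate fit, with
a relative objective tolerance of 1e-8 and a 500-iteration cap — the fit
is deterministic given its inputs. Per-clade rate summaries average the
fitted branch rates over branches whose descendant tips lie entirely
within the clade (pendant branches included, the stem branch included);
averaging over nodes instead would be an equally defensible convention,
but branches are what carry the fitted variance.

`bm_loglik()` is checked in the test suite against the explicit
multivariate-normal density built from the tip covariance matrix (to
1e-8 on trees of up to 10 tips), and the multirate fit is exercised
against simulations with planted clade rate shifts.

## Term enrichment

For coding sequences that contain perfect repeats, over-representation
of annotation terms (GO or pathway identifiers, e.g. from an
eggNOG-mapper table) is tested per term with the upper-tail
hypergeometric distribution — P(X ≥ k) for k query hits out of n query
IDs against K carriers among N background IDs — with Benjamini–Hochberg
adjustment and a raw-p cutoff of 0.05 by default. No GO-graph
propagation is attempted: the test operates on the annotation map as
given.

## What the synthetic data emulate — and what they do not

`generate_genome()` builds genomes in which every repeat is planted at a
known position: spacer sequence is rejection-sampled to contain no run
meeting the detection thresholds, guard bases at each flank prevent a
planted run from extending or phase-shifting into its surroundings, and
the assembled sequence is verified against the detector itself (and
rebuilt if verification fails), so recovery of planted perfect loci is
exact by construction rather than statistical. Gene structures are laid
out so each locus lands in its requested region (CDS, untranslated exon,
intron or intergenic spacer), and N-runs can be inserted at a chosen
per-bp rate, never overlapping planted loci. The background GC fraction
defaults to 0.40, mildly AT-rich as vertebrate genomes are.

These genomes validate the machinery; they do not mimic real genomes.
There are no transposable elements, no repeat families, no chance
near-threshold runs, and no assembly artifacts — so passing recovery
tests demonstrates correctness of coordinates, classes and statistics,
not detector performance on the messier repeat structure of real
assemblies. Likewise `generate_rate_shift_tree()` plants a single clean
rate shift on a random coalescent tree rescaled to unit depth; real
rate variation is rarely a single discrete jump.

## Problem sizes and numerical choices

The shipped tests run on synthetic genomes of a few kilobases (50 seeds
for exact-recovery checks), brute-force detector comparisons on
sequences of at most 200 bp, likelihood checks on trees of up to 10
tips, rate-recovery simulations with 200 tips and 100 replicates, and a
48-tip tree for the planted 10× rate-shift direction check — sizes at
which every oracle can be computed exactly while the whole suite stays
comfortably interactive. Degenerate inputs are defined rather than
accidental: zero trait variance yields a σ² = 0 boundary fit with a
warning, an empty locus set summarizes to zero abundance (GC content of
an empty group is missing, not zero), a zero-valid-length genome is an
error, and unsorted input to compound chaining is an error rather than
silently resorted.

## Known limitations

* The imperfect-repeat extension is greedy with single-base lookahead,
  not full dynamic-programming alignment; pathological edit patterns
  near block boundaries can shift a reported endpoint by a few bases.
* Region labels are single-valued by design; a locus spanning an
  exon–intron junction is attributed to its start's class rather than
  split.
* The multirate penalty fixes the rate of the log-rate process at 1;
  very short branches therefore shrink rate changes harder than long
  ones, which is intended smoothing behavior but means λ is not
  comparable across trees with very different depth scales (trees are
  best rescaled to unit depth, as the simulators here do).
* Minisatellites (units > 6 bp) and approximate compound repeats built
  from imperfect components are out of scope.
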