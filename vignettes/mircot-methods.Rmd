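---
title: "Methods: rule-based plant miRNA annotation and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based plant miRNA annotation and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant microRNAs are ~21-nt RNAs excised by Dicer-like enzymes from fold-back
precursors. Calling a miRNA from small RNA sequencing therefore requires
more than a read pile-up: the locus must fold into a hairpin, the dominant
read must sit on a stem arm, a passenger strand (miRNA*) should exist at the
position the duplex geometry predicts (with 2–3-nt 3' overhangs, the
signature of staggered Dicer cuts), and the excision should be *precise* —
most reads on the hairpin should be the mature or star sequence, not
scattered fragments. `mircot` implements this full decision path as small,
separately testable functions, plus the evolutionary analyses that typically
follow a discovery round in a paleopolyploid genome: retention of miRNA loci
on duplicated genome segments, conservation-age classification across plant
orders, Kimura 2-parameter dating, and Fisher-exact enrichment of target
genes in hierarchical functional bins.

## The discovery model, step by step

1. **Trimming and QC.** The 3' adaptor is located as the longest adaptor
   substring in the read; matches of 6 nt or less do not count as an
   adaptor. Ties between equally long matches trim at the leftmost
   occurrence (the adaptor follows the insert, so leftmost is the
   conservative choice). Qualified reads are 17–30 nt after trimming,
   contain no ambiguous base, and — when qualities exist — have no base
   below Q20. "Low quality" has no standard definition in count-based small
   RNA work; Q20 is the conventional floor and has no effect on FASTA input.
2. **Collapsing.** Identical reads collapse to one species with per-library
   counts; every downstream count is a cumulative exact-sequence count.
   Iso-reads (offset variants) are deliberately *never* added to a mature
   count.
3. **Mapping.** 0-mismatch matching on both strands; multi-mapping reads
   keep all hits and each locus receives the full count, because any
   fractional apportioning rule would be a guess; `n_hits` is kept so users
   can exclude multi-mapped contributions.
4. **Loci and windows.** Reads sharing 1-bp overlaps merge transitively
   into loci. Each locus is scanned with 250-nt windows (plant pre-miRNAs
   average ~200 nt), starting 220 nt upstream, advancing 10 nt, ending with
   the first window that reaches 220 nt downstream. For a locus of width
   *w* this yields `ceil((w + 190)/10) + 1` windows.
5. **Folding and filters.** Windows are folded (RNAfold by default). A
   window survives if the best-supported stem-loop has ≥ 18 *paired*
   positions on an arm (bulges allowed but not counted — a literal
   contiguous-18 reading would reject most real precursors), free energy ≤
   −18 kcal/mol (sign-sensitive: −18.0 passes, −17.9 fails), at least one
   read on an arm, and at most 5 unpaired positions within the read-covered
   region of *one* arm. A duplex mismatch leaves an unpaired base on both
   arms; counting per arm avoids double-counting it.
6. **Representatives.** Shifted windows that call the same structure
   (≥ 90% Jaccard agreement of read-covered paired positions, a
   quantification chosen here since "similar structure" has no standard
   metric) collapse to one representative: most arm reads, then lowest
   energy, then leftmost — fully deterministic.
7. **Annotation rules.** The mature is the arm read with the highest
   cumulative count (ties prefer a 5'-U read, the AGO1-loading expectation,
   then the leftmost). The star is the opposite-arm read at the
   structure-predicted duplex position, allowing ±2 nt of register shift
   for imprecise processing. Processing precision is
   `100 × (mature + star) / (all reads on the hairpin)`. A candidate is
   accepted iff the mature count is ≥ 10 over ≥ 2 libraries and either a
   valid duplex exists (2–3-nt 3' overhangs, ≤ 5 duplex mismatches, neither
   strand in the loop) with precision ≥ 10%, or no star was sequenced and
   precision ≥ 45%.
8. **Overlap resolution and families.** Overlapping accepted hairpins
   reduce to the best one (count, then precision, then leftmost). Overlap
   is compared on coordinates regardless of strand: a perfect inverted
   repeat folds into the same hairpin on both strands, and its reads map to
   both, so the two mirror calls are one biological locus. Mature sequences
   within edit distance 2 group into families by single linkage (a 1-nt
   difference is the precedent for same-family membership; the threshold is
   this package's choice and is exposed as a parameter).

Three readings were genuinely open and are resolved as follows. The
precision formula is parenthesized as `((mature + star)/total) × 100`, the
only reading that keeps a percentage in [0, 100]. The ≥ 10-read rule applies
to the mature read alone (it is the "read of the highest frequency"), not
mature + star combined. The ≤ 5-mismatch rule is applied to the read-covered
arm region during structure filtering *and* re-checked on the duplex during
annotation, covering both possible scopes.

## The synthetic study

No sequencing data are distributed with this package, so every claim is
validated against a generator whose output is fully known. The generator
plants hairpins built from a sampled mature sequence: arms of length
L + 2 as near-perfect inverted repeats, a 12-nt pyrimidine loop (pyrimidines
cannot pair with each other, keeping the terminal loop open), the mature
2 nt in from the stem base, and the star positioned so the duplex carries
2-nt 3' overhangs. G/C anchors at the duplex ends and a ≥ 3-nt mutation-free
margin there model well-formed Dicer substrates and keep the thermodynamic
fold in the planted register. Up to 3 mutations are planted on the arm
opposite the mature, exercising the mismatch filters near their boundary.

Default study conditions (one choice, stated here, used everywhere): 2
chromosomes × 3000 nt; 4 primary hairpins; 3 libraries; mature lengths
20–24 nt peaking at 21; 92% 5'-U probability; a mean of 80 mature reads per
hairpin (Poisson, split over libraries); miRNA/miRNA* ratios lognormal with
median 18 (published per-locus ratios span ~1.5 to ~2800); 5% iso-reads
offset ±1–2 nt; 24-nt background at 40% of all reads, of which 15% are
random (unmappable) sequence — so ~85% of reads map — and 20% come from
planted rRNA/tRNA intervals; the rest arise from 15 discrete cluster
origins placed away from miRNA slots, emulating heterochromatic siRNA
clusters. Duplicated segment pairs cover half the primary hairpins; the
retained-locus fraction is 45%, implemented as a per-pair copy probability
of p/(2−p) because a surviving duplicate contributes two retained loci to
the observed fraction. An IR-cluster mode instead plants tandem copies of
one hairpin with ≤ 2 mature mutations — the birth of a young family by
local amplification of an inverted duplication — for family-grouping and
K2P/NJ dating tests.

What the generator does *not* emulate: sequencing errors, ligation bias,
expression heterogeneity across libraries, multi-branched precursors, and
genome-scale repeat structure. Passing tests therefore demonstrate that the
decision path implements its rules correctly and recovers planted truth
under clean conditions; they do not measure sensitivity on real tissue
libraries.

Problem sizes are deliberately desk-scale: a full pipeline run folds
roughly a thousand 250-nt windows, and the recovery audit repeats it on
five independent seeds; the generator's genome and read depths were sized
so that this entire audit completes in minutes on one core while still
placing every rule's boundary under test.

## Folding backends

`fold_sequences()` is pluggable. The default backend shells out to RNAfold
and uses its MFE structure; when a backend yields only the MFE, that single
structure is used (RNAsubopt's energy-window output is unbounded on 250-mers
and is not consumed). The second backend, `irscan`, aligns a sequence
against its own reverse complement (local alignment), reads the stem off
the alignment, and scores it with Watson–Crick nearest-neighbour stacking
energies plus flat loop penalties. It is an estimator — on hairpin-bearing
segments its energies track the thermodynamic backend to roughly 10% — and
exists as a fast pre-screen and as an independent cross-check in tests.

## Numerical and tie-breaking conventions

Internal coordinates are 0-based half-open, converted to 1-based inclusive
only at GFF3/BED boundaries. T and U are one symbol (stored as T, displayed
as U). Published-table ratios round half-up to 2 decimals, retention
percentages half-up to integers (R's own `round()` is banker's rounding and
would print 18.155 differently than a table does). All order-dependent
choices (mature ties, representative ties, overlap ties, NJ input order,
family ids) are resolved by explicit deterministic rules, and the generator
derives one named random stream per stage from a single seed, so identical
configurations reproduce byte-identical bundles.

## Evolutionary analyses

Homoeolog retention takes segment pairs as *input* (synteny detection is
out of scope) and calls a locus retained when the partner segment holds a
locus whose mature is within edit distance 2 — the outcome-level published
quantity is a percentage of loci, and the homology rule is this package's
explicit, configurable choice. K2P distance is computed from transition and
transversion proportions, `K = -1/2 ln((1-2P-Q)√(1-2Q))`, with pairwise gap
deletion and a hard error outside the formula's domain rather than a
clamped value; divergence time is `T = K/(2R)` with a default legume rate
of R = 6.1×10⁻⁹ substitutions/site/year. Tree building delegates to ape's
neighbor joining; tests verify exact recovery of random additive trees
(Robinson–Foulds 0, branch lengths to 1e-8) rather than re-deriving the
agglomeration. Conservation age is the class of the deepest-diverging plant
order in which a family is present, with "absent outside fabales" mapping
to soybean-specific.

## Enrichment

Bin enrichment uses the two-sided Fisher exact test with the *sample* odds
ratio `(a·d)/(b·c)` (published bin tables report sample odds ratios, not
the conditional MLE). Gene membership propagates up the dotted bin
hierarchy. The universe defaults to the genes in the bin table — the
binned-gene universe, not all genome genes — and both the universe and the
sidedness are overridable. No multiple-testing correction is applied by
default, matching how such tables are conventionally reported; a
Benjamini–Hochberg option exists.

## Known limitations

- Exact mapping is contract-first, not speed-first; genomes beyond tens of
  megabases would need an FM-index-backed replacement behind the same
  interface.
- Only single-hairpin precursors are modeled; multi-loop precursors are
  rejected by design.
- The star search assumes the duplex sits within one stem-loop; duplexes
  spanning branch points are not found.
- The irscan backend underestimates stability for structures dominated by
  coaxial stacking or G:U-rich stems.
- The retention homology rule (edit ≤ 2) will overcount retention for large
  families with near-identical members on both segments.
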