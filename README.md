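# mircot

Rule-based discovery and evolutionary analysis of plant microRNAs from
small RNA sequencing, built as a tested R package with a synthetic-data
generator so that every stage — from raw adaptor-ligated reads to accepted
miRNA annotations, homoeolog retention, divergence dating, and target-bin
enrichment — can be validated without any external dataset.

## The problem and the model

Plant miRNAs are ~21-nt RNAs diced from fold-back precursors. Calling one
from sequencing data requires structural evidence, not just abundance. The
decision path implemented here:

1. **Qualified reads**: 3′ adaptor located as the longest adaptor substring
   (> 6 nt) in the read; inserts of 17–30 nt without ambiguous bases are
   collapsed to unique species with per-library counts.
2. **Mapping**: exact (0-mismatch) matching on both genome strands; reads
   identical to known mature miRNAs or overlapping rRNA/tRNA tracks are
   excluded from novel discovery.
3. **Hairpin prediction**: read loci merged by overlap are scanned with
   250-nt windows (step 10 nt, reaching 220 nt up/downstream) and folded;
   a candidate needs ≥ 18 paired positions on a stem arm, ΔG ≤ −18
   kcal/mol, reads on the stem, and ≤ 5 unpaired positions under the reads
   on one arm.
4. **Annotation rules**: the mature is the highest-count arm read (counts
   are exact-sequence only — iso-miRs never count); acceptance requires
   ≥ 10 mature reads in ≥ 2 libraries and either a miRNA/miRNA\* duplex
   with 2–3-nt 3′ overhangs, ≤ 5 duplex mismatches, neither strand in the
   loop, and processing precision ≥ 10 %, or — with no star sequenced —
   precision ≥ 45 %, where

   precision = 100 · (mature + star reads) / (all reads on the hairpin).

5. **Post-processing**: overlapping hairpins reduce to the best-supported
   one; mature sequences within edit distance 2 group into families.

Downstream modules compute homoeolog retention of miRNA loci on duplicated
genome segments, conservation-age classes across plant orders, Kimura
2-parameter distances K = −½ ln((1−2P−Q)·√(1−2Q)) with divergence times
T = K/(2R) (R = 6.1×10⁻⁹ site⁻¹ yr⁻¹), neighbor-joining trees, and
Fisher-exact enrichment of miRNA targets in hierarchical functional bins.

## Worked example

The `analysis/` scripts run the whole study end to end on a synthetic
bundle (`01_simulate.R` … `05_enrichment.R`), writing tables under
`results/`. The core discovery run:

```r
library(mircot)
bundle <- simulate_bundle(synthetic_config(seed = 1))
res <- run_pipeline_on_bundle(bundle)
evaluate_against_truth(res$accepted, bundle$truth)[c("recall", "n_false_discoveries")]
res$table[, c("strand", "arm", "mature_count", "star_count", "ratio", "precision")]
```

prints (seed 1):

```
recall               : 1.00
false discoveries    : 0

   strand arm mature_count star_count ratio precision
1       +  5p           86         12  7.17     97.03
11      +  5p           81          8 10.13     92.71
12      +  3p           74          3 24.67     97.47
13      -  5p           99          6 16.50     98.13
14      -  3p           92         10  9.20     98.08
15      -  3p           89          4 22.25     93.00
```

Every planted hairpin is recovered with its exact mature sequence and
ledger-exact counts (e.g. 86 mature / 12 star reads were planted for the
first hairpin), the reported miRNA/miRNA\* ratios match the planted
lognormal ratios, and precision is high because the generator emulates
precise Dicer processing. Ratio accounting follows the printed-table
dialect, e.g. `mirna_star_ratio(30656, 1688)` is `18.16` and a zero star
count is a blank (NA).

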