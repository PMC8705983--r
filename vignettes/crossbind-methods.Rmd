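---
title: "Methods: comparative TF occupancy analysis in crossbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative TF occupancy analysis in crossbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crossbind` compares the chromatin binding of one transcription factor
between two tissues from called ChIP-seq peaks. This vignette documents the
models and procedures, the parameters that matter, the design choices made
where the methodology was genuinely open, what the synthetic-data generator
does and does not emulate, and the package's known limitations.

## Coordinates and the peak-to-gene model

All intervals are handled internally as 0-based half-open `[start, end)`,
the BED convention; GTF input (1-based inclusive) is converted on read.
Half-open arithmetic removes off-by-one ambiguity from interval
intersection, gap and coverage computations.

Each peak is reduced to a **representative point**: the called summit when
present (narrowPeak column 10), otherwise the floor of the interval
midpoint. Classification and gene association are functions of this point
only, which makes them invariant to how the peak's extent is represented and
deterministic across equivalent inputs.

The **location scheme** assigns exactly one label per peak, by strand-aware
offset from the TSS:

| label            | definition                                              |
|------------------|---------------------------------------------------------|
| promoter         | offsets −1000..+10 bp from the TSS, plus the 5′ UTR     |
| distal_enhancer  | offsets −2000..−1001 bp, plus the 3′ UTR, plus 1 kb downstream of the gene 3′ end |
| intron           | inside the gene body but in no exon                     |
| other            | inside an exon, in none of the classes above            |
| intergenic       | none of the above                                       |

Both printed bounds are closed (+10 belongs to the promoter; −1000 belongs
to the promoter, not the distal class). When windows of several genes
overlap, the priority is promoter > distal_enhancer > intron > other >
intergenic. The size of the "downstream" window (1 kb) is a package choice:
the class is conventionally described without a size, and 1 kb matches the
association flank below so that every point inside an extended gene body
receives a non-intergenic label.

**Gene association**: a peak is assigned to every gene whose flank-extended
body (`flank_up` = 2000 bp upstream of the TSS, `flank_down` = 1000 bp
downstream of the 3′ end) contains its representative point; a peak
contained in no extended body falls back to the nearest TSS within
`max_tss_distance` = 10 kb, and is otherwise unassigned. Multi-gene
assignment is deliberate — a peak between two genes may regulate both — and
per-gene analyses consume the full assignment table. Ties at equal TSS
distance break by lexicographic gene id, so results are reproducible. These
defaults are an explicit stand-in: published peak-to-gene associations of
this kind rarely state whether nearest-TSS, overlap, or annotation-package
defaults were used, so the package fixes one well-defined rule and exposes
every constant.

The package handles one model per gene (no transcript isoforms); whether 5′
UTR membership should be evaluated per transcript is therefore moot here —
UTR intervals, when the GTF provides them, are attached to the gene.

## Cross-tissue comparison

Genes bound (≥ 1 assigned peak) in both tissues are **common**; genes bound
in exactly one are **tissue-specific**. Percentages are reported rounded
half-up to integer percent, the display convention of category bar plots
(`round_half_up` exists because R's `round` is round-half-even, which would
turn 35.5 into 35 rather than 36).

**Binding frequency** counts distinct peaks per gene and tissue: one peak =
singlePeak, more = multiPeak.

**The 2 kb subdivision** operates on enhancer-class peaks (distal_enhancer,
intron, intergenic) assigned to common genes. Cross-tissue peak pairs with
edge-to-edge distance ≤ 2000 bp (overlap counts as 0) are matched greedily
by increasing distance, ties broken by peak ids, each peak in at most one
pair. Matched peaks are `shared_2kb` — treated as one regulatory element
bound in both tissues — and the rest are `A_only`/`B_only`. Design choices
here: edge-to-edge distance rather than midpoint distance (midpoint is
available as an option) because "within 2 kb" naturally reads as gap, and
one-to-one greedy pairing rather than cluster merging because it is
deterministic, order-invariant, and attains the exhaustive
maximum-cardinality matching on every randomized small instance in the test
suite (dense pathological configurations could in principle differ; the
tests would surface that).

**Occupancy matrix**: consensus regions are the union of all peaks merged at
overlap; entries are binary occupancy (or peak score). Pearson correlations
between sample columns and PCA of the samples summarize cross-tissue
similarity. This is a declared surrogate for read-count-based differential
binding analysis — adequate for the qualitative correlation/PCA surface, not
a replicate-aware differential test. Zero-variance samples yield `NA`
correlations (undefined, not 0). PCA fixes the sign of each component by
making the largest-magnitude loading positive.

## Motif analysis

PWMs are per-position probability matrices over A/C/G/T with a pseudocount
(default 0.5 per cell) and an explicit background. Scanning reports
log2-odds scores against that background on both strands, in forward
coordinates; windows containing N are skipped.

**Scan threshold.** The default threshold of `scan_pwm` is 60% of the PWM's
maximal achievable score. For *enrichment counting*, however, the pipeline
default is 90% (`scan_threshold_frac` in the run config). The reason is
measured, not cosmetic: with a 7-bp degenerate AT-rich motif scanned over
200–600 bp AT-rich sequences, some weak window exceeds the 60% cutoff in
roughly 19 of 20 sequences — in the foreground *and* in the
dinucleotide-shuffled background — so sequence-level counts saturate and the
Fisher test has no power regardless of planting. At 90%, planted foregrounds
separate cleanly from shuffled backgrounds. Users scanning long or
GC-balanced motifs can lower the threshold.

**Enrichment** follows the sequence-level counting convention: a sequence
"has" a motif if it contains ≥ 1 hit; a one-sided Fisher exact test compares
foreground and background sets; p-values are Bonferroni-corrected across the
motif set (Bonferroni, not FDR, because motif sets here are small and the
correction is the conventional one for this analysis); motifs at adjusted
p ≥ 0.05 are flagged not enriched. Backgrounds are dinucleotide-preserving
Euler-path shuffles of the foreground (order 1, a plain permutation, is
available); shuffles are deterministic under a mandatory seed.

**De novo discovery** is a seeded k-mer algorithm defined by this package:

1. count, for every canonical k-mer (k = 6..10, collapsed with its reverse
   complement), the number of foreground and background sequences containing
   it; k-mers in fewer than 3 foreground sequences are not evaluated;
2. score each evaluated seed by the one-sided Fisher (hypergeometric tail)
   p-value of sequence-level occurrence, and Bonferroni-adjust the best seed
   over the evaluated seed set;
3. collect all foreground occurrences of the best seed within one mismatch
   on either strand, align them (with up to 3 bp of flanking context per
   side), and build a PWM with pseudocount 0.5, widening by one column per
   side while the added column's information content is ≥ 0.3 bits and at
   least half the sites provide context;
4. mask the matched sites (replace with N) in the foreground and repeat,
   until `n_motifs` motifs are found or the best adjusted p is ≥ 0.05.

Consensus strings use the IUPAC code covering all bases with probability
≥ 0.5 × the column maximum. Foregrounds below 10 sequences are refused —
sequence-level Fisher counting has essentially no power there.

The shipped `hox_pwm()` is a documented stand-in built around the degenerate
Hox core `T(A/T)AT(T/G)(A/G)` preceded by T (strict consensus `TTAATGA`);
measured motif models should be supplied as MEME minimal files for real
analyses.

## Affinity model

Relative binding affinity uses a position-specific affinity matrix (PSAM):
every column is scaled to maximum 1, a window's affinity is the product of
its per-position entries, so the consensus window scores exactly 1 and every
substitution multiplies the score by that position's entry. This is a
declared product model — a deliberate simplification of trained
biophysical affinity models, whose parameter sets are consumed as input
(MEME file via `psam_from_pwm`, or a 4-column TSV) rather than fitted.
Mode `max` (default) reports the best single window over both strands, the
natural per-region statistic; mode `sum` aggregates all windows,
occupancy-style.

Rank-sum comparisons between category score distributions use exact
enumeration below a combined n of 20 without ties, and the tie-corrected
normal approximation (no continuity correction) otherwise; two samples that
are identical multisets report p = 1 rather than an error. Stars follow the
annotation convention `*` p < 0.05, `***` p < 0.001 on the two-sided
p-value.

## Chromatin marks

Coverage of a peak by a mark track is (covered bases)/(peak length) after
merging the track. A peak is "marked" at coverage ≥ 0.25 (configurable); a
coverage criterion, rather than any-overlap, because mark domains are broad
and a 1-bp touch should not flip a class. The cross-tissue class of a
focal-tissue-specific peak is a pure function of four booleans (H3K27ac /
H3K27me3 × focal / other tissue): acetylated-focal peaks are
`active_shared` or `active_focal_only` depending on the other tissue;
trimethylated-focal peaks are `repressed_shared` or `repressed_focal_only`;
peaks with neither or both marks in the focal tissue go to an explicit
`unclassified` bucket (logged and counted) instead of being double-counted.
Mark tracks are interval BEDs; signal-level (bigWig) analysis is out of
scope.

## The synthetic-data generator

`simulation_config()` defaults define the study conditions the package is
validated under: 2000 genes split 35/29/36 percent into common / A-specific
/ B-specific; common genes singlePeak with probability 0.10 (the single/
multi flag is drawn once per gene, since the emulated design describes
common genes as multiply bound *in both tissues* in 90% of cases); specific
genes singlePeak with probability 0.375; multiPeak counts uniform on 2..5;
a target fraction 0.25 of common-gene enhancer peaks planted as cross-tissue
shared pairs with edge gaps below 2 kb (hence ~75% tissue-specific); peak
widths 200–600 bp; an AT-rich order-0 background (A/C/G/T =
0.3/0.2/0.2/0.3) chosen to stress AT-rich motif discovery; the classical
Hox-like motif embedded at rate 0.7 in B-only and shared peaks and a
divergent two-mismatch AT-rich variant (`TAAATAA`) at rate 0.7 in A-only
peaks; and mark classes drawn per tissue such that A-specific active peaks
are predominantly shared-active while A-specific repressed peaks are
focal-only, with the inverse pattern for tissue B.

Geometry guarantees make downstream recovery exact up to sampling noise:
intergenic gaps exceed 4 kb so flank-extended gene bodies never overlap and
every peak is assigned to exactly the gene it was planted in; non-paired
cross-tissue enhancer peaks are kept more than 2 kb apart (slot cursors with
2.1 kb separation, carried across introns) while planted pairs sit closer
than 2 kb, so the subdivision recovers the manifest exactly; mark intervals
cover their peaks completely (coverage 1.0) and never place both marks of
one tissue on one peak. Peak units that do not fit a gene's introns are
dropped (counted in the manifest) — this truncates the upper tail of the
peak-count distribution slightly, which is why recovered multiPeak shares
sit a few points below the planted rate — and a bound tissue that loses all
its units receives a promoter peak so gene categories stay exact.

What the generator does **not** emulate: read-level signal (no FASTQ, no
peak-shape or score structure), replicates, overlapping or nested genes,
transcript isoforms, chromatin-accessibility confounding between motif
content and mark state, and real intergenic enhancer landscapes (enhancer
peaks are placed in introns, with occasional distal-window peaks for
specific genes). Passing recovery tests therefore demonstrates the
pipeline's correctness on data satisfying its assumptions, not performance
on the full messiness of measured ChIP-seq.

## Numerical and degenerate-input conventions

* Exact arithmetic everywhere intervals are concerned; floating comparisons
  in tests use explicit tolerances (1e-12 for product/ formula oracles,
  1e-9 for scan scores).
* Empty inputs are states, not errors: empty gene sets classify everything
  intergenic; an empty tissue warns and yields all-specific genes;
  zero-variance occupancy columns give `NA` correlations; all-tied rank-sum
  inputs give p = 1. Malformed files, negative gaps, missing mark tracks
  and undersized foregrounds are errors with named causes.
* All stochastic steps (generator stages, shuffles, discovery) take explicit
  seeds and are deterministic under them; fixture directories are
  byte-identical across runs of one seed.
* Problem sizes in the shipped validation: oracle-equivalence suites run 100
  randomized small instances per operation; parameter recovery uses the
  2000-gene default study; the discovery-stability suite runs 20 seeded
  200-gene studies; enrichment contrast uses an 800-gene study. These sizes
  keep the whole suite in the minutes range while leaving binomial bands
  tight enough to be informative.

## Known limitations

* The occupancy correlation/PCA surface is a binary surrogate; it does not
  reproduce read-count normalization or affinity-based differential tests.
* Discovery is a k-mer seed-and-extend heuristic: motifs longer than 10 bp
  with no strong 6–10 bp core, or motifs present in fewer than 3 foreground
  sequences, will be missed; Bonferroni over the evaluated seed set is
  conservative.
* The PSAM product model assumes positional independence and one binding
  mode; cooperative, multi-footprint or flanking-sequence effects are out of
  scope.
* Gene association assumes non-overlapping extended gene territories; in
  gene-dense regions multi-assignment is reported rather than resolved.
* GO-term interpretation of gene lists requires external databases; the
  package emits the per-class gene lists for such tools instead.
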