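# crossbind

Comparative analysis of one transcription factor's ChIP-seq binding across
two tissues.

Hox transcription factors such as Drosophila Ultrabithorax bind short,
degenerate AT-rich motifs (core `T(A/T)AT(T/G)(A/G)`) yet act with striking
tissue specificity. A standard way to study this is to call the TF's peaks
separately in two tissues (e.g. mesoderm and nervous system) and ask: which
genes are bound in both tissues and which in only one; are genes bound once
or repeatedly, and where relative to gene structure; which binding events
within commonly bound genes are truly shared regulatory elements and which
are tissue-specific; do the tissue-specific peak classes differ in motif
content and predicted binding affinity; and how do active (H3K27ac) and
repressive (H3K27me3) chromatin marks at those peaks compare across tissues.

`crossbind` implements that entire comparison as a reusable, tested R
pipeline for anyone with two peak sets (BED/narrowPeak), a GTF annotation, a
genome FASTA, histone-mark interval tracks and motif models (MEME minimal
format):

* **Peak annotation** — each peak's representative point (summit, else
  midpoint) is classified as promoter (−1000..+10 bp of the TSS, plus 5′
  UTR), distal enhancer (−2000..−1000 bp, 3′ UTR, 1 kb downstream), intron,
  other (exonic) or intergenic, and associated with genes by flank-extended
  overlap with a nearest-TSS fallback.
* **Cross-tissue comparison** — genes are categorized common /
  tissue-specific; binding frequency separates singlePeak from multiPeak
  genes; enhancer-class peaks within common genes are subdivided into
  tissue-specific and shared elements by greedy cross-tissue pairing within
  2 kb; a binary occupancy matrix over consensus regions supports sample
  correlation and PCA.
* **Motif analysis** — PWM log-odds scanning, sequence-level Fisher-exact
  enrichment against dinucleotide-shuffled backgrounds with Bonferroni
  correction, and k-mer-seeded de novo discovery (Fisher-scored seeds,
  1-mismatch site collection, information-content widening, masking).
* **Affinity model** — relative binding affinities under a
  position-specific affinity matrix (PSAM; column maxima 1, window affinity
  = product of entries), with exact/normal Wilcoxon rank-sum comparisons
  between peak categories.
* **Chromatin marks** — per-peak coverage fractions and the four-way
  cross-tissue classification of tissue-specific peaks: active_shared,
  active_focal_only, repressed_shared, repressed_focal_only.
* **Synthetic data** — a deterministic generator that emits a toy genome,
  two tissue peak sets, embedded motifs and mark tracks with a truth
  manifest, so every stage can be validated end to end against known ground
  truth.

## Worked example

Generate a synthetic study (300 genes, two tissues labelled `meso` and
`neuro`) and run the full pipeline:

```r
library(crossbind)

cfg <- simulation_config(seed = 42, n_genes = 300, n_chromosomes = 2)
rc  <- make_fixture(cfg, "demo")      # writes FASTA/GTF/narrowPeak/BED/MEME
rep <- run_full_analysis(rc)          # writes TSVs + summary.json under demo/results

unlist(rep$gene_category_percentages)
#>     common A_specific B_specific
#>         35         30         35
rep$pct_tissue_specific_peaks
#> [1] 76
rep$enrichment
#>           motif   category   p_adjusted enriched
#> 1 hox_classical     A_only 1.000000e+00    FALSE
#> 2     divergent     A_only 1.684275e-14     TRUE
#> 3 hox_classical     B_only 1.097399e-02     TRUE
#> 4     divergent     B_only 4.742345e-01    FALSE
#> 5 hox_classical shared_2kb 1.708388e-02     TRUE
#> 6     divergent shared_2kb 1.000000e+00    FALSE
rep$discovered_motifs
#> [1] "TAAATAA"
```

Reading the output: 35% of bound genes are bound in both tissues and 76% of
enhancer-class peaks within those common genes are nevertheless
tissue-specific. The classical Hox-like motif is enriched (Bonferroni
p < 0.05) in neuro-only and shared peaks but not in meso-only peaks, where
de novo discovery instead recovers the planted divergent AT-rich variant
`TAAATAA` — the low-affinity binding signature the pipeline is designed to
expose. Affinity rank-sum tests and the cross-tissue mark classes are in
`rep$affinity_tests` and `rep$mark_class_counts`, and every table is also
written under `demo/results/`.

Real analyses use the same `run_full_analysis()` with a run config pointing
at measured peak/annotation/mark/motif files (see `validate_run_config()`).

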