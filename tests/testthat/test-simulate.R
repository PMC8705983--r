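# The synthetic-data generator and its truth manifest.

small_cfg <- function(seed = 1, n_genes = 60, ...) {
  simulation_config(seed = seed, n_genes = n_genes, n_chromosomes = 2, ...)
}

test_that("the generator is fully deterministic under the seed", {
  cfg <- small_cfg(seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.character(d1$sequences), as.character(d2$sequences))
  expect_identical(d1$manifest$peaks, d2$manifest$peaks)
  expect_identical(d1$peaks_a, d2$peaks_a)
  # and different under another seed
  d3 <- simulate_dataset(small_cfg(seed = 6))
  expect_false(identical(as.character(d1$sequences)[1],
                         as.character(d3$sequences)[1]))
})

test_that("fixture directories are byte-identical across runs of one seed", {
  cfg <- small_cfg(seed = 9, n_genes = 25)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixture(cfg, d1, overwrite = TRUE)
  make_fixture(cfg, d2, overwrite = TRUE)
  for (f in c("genome.fa", "genes.gtf", "peaks_meso.narrowPeak",
              "peaks_neuro.narrowPeak", "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  expect_error(make_fixture(cfg, d1), "not empty")
})

test_that("background base composition matches the configuration", {
  cfg <- small_cfg(seed = 2, n_genes = 50)
  g <- simulate_genome(cfg)
  freq <- Biostrings::alphabetFrequency(g$sequences, collapse = TRUE)
  tot <- sum(freq[c("A", "C", "G", "T")])
  expect_gt(tot, 1e6) # composition measured over at least a megabase
  got <- freq[c("A", "C", "G", "T")] / tot
  expect_true(all(abs(got - cfg$background_freqs) < 0.01))
})

test_that("simulated gene models satisfy the annotation invariants", {
  g <- simulate_genome(small_cfg(seed = 3, n_genes = 50))
  ann <- g$annotation
  expect_silent(crossbind:::validate_annotation(ann))
  # >= 2 exons per gene, both strands used, genes within chromosomes
  n_ex <- table(ann$exons$gene_id)
  expect_true(all(n_ex >= 2))
  expect_setequal(unique(ann$genes$strand), c("+", "-"))
  expect_true(all(ann$genes$end <= g$chrom_lengths[ann$genes$chrom]))
  # fixed chromosome_length too small must refuse
  expect_error(simulate_genome(small_cfg(seed = 3, n_genes = 50,
                                         chromosome_length = 1e5)),
               "chromosome_length")
})

test_that("peak sets realize the planted category and pairing structure", {
  cfg <- small_cfg(seed = 4, n_genes = 120)
  ds <- simulate_dataset(cfg)
  mp <- ds$manifest$peaks
  all_peaks <- rbind(ds$peaks_a, ds$peaks_b)
  # manifest consistency: every manifest peak exists in a peak set
  expect_setequal(mp$peak_id, all_peaks$peak_id)
  # shared pairs: one-to-one, symmetric, edge gap < 2000
  sh <- mp[!is.na(mp$subdivision) & mp$subdivision == "shared_2kb", ]
  expect_equal(sort(sh$peak_id), sort(sh$partner_peak_id))
  m1 <- match(sh$peak_id, all_peaks$peak_id)
  m2 <- match(sh$partner_peak_id, all_peaks$peak_id)
  gap <- pmax(0, pmax(all_peaks$start[m1], all_peaks$start[m2]) -
                pmin(all_peaks$end[m1], all_peaks$end[m2]))
  expect_true(all(gap < 2000))
  expect_true(all(all_peaks$tissue[m1] != all_peaks$tissue[m2]))
  # A-only enhancer peaks stay > 2 kb from every B enhancer peak of the gene
  a_only <- mp[!is.na(mp$subdivision) & mp$subdivision == "A_only", ]
  b_enh <- mp[!is.na(mp$subdivision) & mp$tissue_key == "B", ]
  for (i in seq_len(nrow(a_only))) {
    b_ids <- b_enh$peak_id[b_enh$gene_id == a_only$gene_id[i]]
    if (length(b_ids) == 0) next
    a <- all_peaks[all_peaks$peak_id == a_only$peak_id[i], ]
    b <- all_peaks[all_peaks$peak_id %in% b_ids, ]
    d <- pmax(0, pmax(a$start, b$start) - pmin(a$end, b$end))
    expect_true(all(d > 2000))
  }
})

test_that("a zero A-specific proportion leaves no A-only-bound genes", {
  cfg <- small_cfg(seed = 8, n_genes = 60,
                   gene_category_props = c(common = 0.5, A_specific = 0,
                                           B_specific = 0.5))
  ds <- simulate_dataset(cfg)
  g <- ds$manifest$genes
  expect_true(all(g$n_peaks_B > 0 | g$n_peaks_A == 0))
  expect_false(any(g$category == "A_specific"))
})

test_that("realized category proportions stay inside binomial 99 percent bands", {
  cfg <- small_cfg(seed = 10, n_genes = 400)
  ds <- simulate_dataset(cfg)
  tab <- table(ds$manifest$genes$category)
  for (cat in names(cfg$gene_category_props)) {
    p <- cfg$gene_category_props[[cat]]
    ci <- qbinom(c(0.005, 0.995), 400, p)
    expect_gte(tab[[cat]], ci[1])
    expect_lte(tab[[cat]], ci[2])
  }
})

test_that("planted motifs are recoverable by scanning with the true PWM", {
  cfg <- small_cfg(seed = 11, n_genes = 100,
                   embed_plan = data.frame(motif = "classical",
                                           category = c("A_only", "B_only",
                                                        "shared_2kb"),
                                           rate = 1.0))
  ds <- simulate_dataset(cfg)
  mp <- ds$manifest$peaks
  planted <- mp[!is.na(mp$motif), ]
  expect_equal(sort(planted$peak_id),
               sort(mp$peak_id[!is.na(mp$subdivision)])) # rate 1.0 plants all
  all_peaks <- rbind(ds$peaks_a, ds$peaks_b)
  m <- match(planted$peak_id, all_peaks$peak_id)
  seqs <- setNames(as.character(Biostrings::subseq(
    ds$sequences[all_peaks$chrom[m]], all_peaks$start[m] + 1L, all_peaks$end[m])),
    planted$peak_id)
  hits <- scan_pwm(seqs, cfg$motifs$classical, threshold_frac = 0.5)
  expect_gte(length(unique(hits$sequence_id)) / nrow(planted), 0.95)
  # the exact plant offset is among the hits for most peaks (words sampled
  # from the PWM occasionally carry low-probability bases and score below
  # the threshold, so this is bounded away from 1)
  key_hit <- paste(hits$sequence_id, hits$offset)
  key_plant <- paste(planted$peak_id, planted$motif_offset)
  expect_gte(mean(key_plant %in% key_hit), 0.8)
})

test_that("a zero embedding rate leaves the genome untouched", {
  cfg0 <- small_cfg(seed = 12, n_genes = 30,
                    embed_plan = data.frame(motif = character(0),
                                            category = character(0),
                                            rate = numeric(0)))
  g <- simulate_genome(cfg0)
  pk <- simulate_peaks(cfg0, g)
  emb <- embed_motifs(g$sequences, rbind(pk$peaks_a, pk$peaks_b),
                      pk$manifest, cfg0)
  expect_identical(as.character(emb$sequences), as.character(g$sequences))
  expect_true(all(is.na(emb$manifest$peaks$motif)))
})

test_that("mark tracks realize the planted classes exactly at saturated coverage", {
  cfg <- small_cfg(seed = 13, n_genes = 150)
  ds <- simulate_dataset(cfg)
  mp <- ds$manifest$peaks
  all_peaks <- rbind(ds$peaks_a, ds$peaks_b)
  for (tk in c("A", "B")) {
    sel <- mp[!is.na(mp$mark_class) & mp$tissue_key == tk, ]
    pk <- all_peaks[match(sel$peak_id, all_peaks$peak_id), ]
    focal <- cfg$tissue_labels[[tk]]
    other <- cfg$tissue_labels[[setdiff(c("A", "B"), tk)]]
    res <- classify_cross_tissue(pk, ds$tracks, focal, other)
    expect_equal(res$class, sel$mark_class)
  }
  # no bivalent plants: ac and me3 of one tissue never cover the same peak
  for (tissue in unname(cfg$tissue_labels)) {
    spec <- all_peaks[all_peaks$peak_id %in%
                        mp$peak_id[!is.na(mp$mark_class)], ]
    ac <- coverage_fraction(spec, ds$tracks[[tissue]]$H3K27ac)
    me <- coverage_fraction(spec, ds$tracks[[tissue]]$H3K27me3)
    expect_false(any(ac >= 0.25 & me >= 0.25))
  }
})
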