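# Gene categorization, binding frequency, 2 kb subdivision, occupancy
# matrix, correlation and PCA.

asg <- function(peaks, genes) {
  data.frame(peak_id = peaks, gene_id = genes,
             distance_to_tss = rep_len(0L, length(peaks)),
             location = rep_len("intron", length(peaks)),
             stringsAsFactors = FALSE)
}

test_that("gene categories split into common and tissue-specific sets", {
  a <- asg(c("p1", "p2"), c("g1", "g2"))
  b <- asg(c("q1", "q2"), c("g2", "g3"))
  cats <- categorize_genes(a, b)
  expect_equal(cats$category[match(c("g1", "g2", "g3"), cats$gene_id)],
               c("A_specific", "common", "B_specific"))
  # swapping tissues swaps the specific sets and fixes common
  sw <- categorize_genes(b, a)
  expect_equal(sw$category[sw$gene_id == "g1"], "B_specific")
  expect_equal(sw$category[sw$gene_id == "g2"], "common")
  expect_equal(sum(attr(cats, "counts")), 3)
})

test_that("an empty tissue warns and yields all-specific genes", {
  a <- asg(character(0), character(0))
  b <- asg("q1", "g1")
  expect_warning(cats <- categorize_genes(a, b), "specific")
  expect_equal(cats$category, "B_specific")
})

test_that("binding frequency counts distinct peaks per gene", {
  a <- asg(c("p1", "p2", "p3", "p4", "p4"), c("g1", "g2", "g2", "g2", "g3"))
  bf <- binding_frequency(a)
  expect_equal(bf$n_peaks[match(c("g1", "g2", "g3"), bf$gene_id)], c(1L, 3L, 1L))
  expect_equal(bf$class[bf$gene_id == "g1"], "singlePeak")
  expect_equal(bf$class[bf$gene_id == "g2"], "multiPeak")
  # histogram equals a brute-force group-by tally on random tables
  set.seed(41)
  for (rep in 1:5) {
    tab <- asg(sprintf("p%03d", 1:200),
               sample(sprintf("g%02d", 1:40), 200, replace = TRUE))
    bf <- binding_frequency(tab)
    brute <- table(table(tab$gene_id))
    expect_equal(as.integer(attr(bf, "histogram")), as.integer(brute))
  }
})

test_that("2 kb subdivision pairs overlapping and nearby cross-tissue peaks", {
  pa <- make_peaks("chr1", c(1000, 50000), c(1200, 50400), tissue = "ta",
                   ids = c("a1", "a2"))
  pb <- make_peaks("chr1", c(1100, 55000), c(1300, 55400), tissue = "tb",
                   ids = c("b1", "b2"))
  sub <- subdivide_common_peaks(pa, pb)
  expect_equal(sub$category[sub$peak_id == "a1"], "shared_2kb") # overlap
  expect_equal(sub$partner_peak_id[sub$peak_id == "a1"], "b1")
  expect_equal(sub$partner_peak_id[sub$peak_id == "b1"], "a1")
  expect_equal(sub$category[sub$peak_id == "a2"], "A_only") # nearest b is 4.6 kb
  expect_equal(sub$category[sub$peak_id == "b2"], "B_only")
  expect_equal(attr(sub, "fraction_specific"), 0.5)
  expect_error(subdivide_common_peaks(pa, pb, gap = -1), "non-negative")
})

test_that("every peak appears once, pairing is symmetric and order-invariant", {
  set.seed(42)
  for (rep in 1:10) {
    na <- sample(5:15, 1); nb <- sample(5:15, 1)
    sa <- sample.int(30000, na); sb <- sample.int(30000, nb)
    pa <- make_peaks("chr1", sa, sa + 300, tissue = "ta",
                     ids = sprintf("a%02d", seq_len(na)))
    pb <- make_peaks("chr1", sb, sb + 300, tissue = "tb",
                     ids = sprintf("b%02d", seq_len(nb)))
    sub <- subdivide_common_peaks(pa, pb)
    expect_setequal(sub$peak_id, c(pa$peak_id, pb$peak_id))
    shared <- sub[sub$category == "shared_2kb", ]
    expect_equal(sum(shared$peak_id %in% pa$peak_id),
                 sum(shared$peak_id %in% pb$peak_id))
    expect_equal(sort(shared$peak_id), sort(shared$partner_peak_id))
    # input order must not matter
    perm <- subdivide_common_peaks(pa[sample.int(na), ], pb[sample.int(nb), ])
    perm <- perm[match(sub$peak_id, perm$peak_id), ]
    expect_equal(perm$category, sub$category)
  }
})

test_that("greedy pairing attains the exhaustive maximum matching on small instances", {
  set.seed(43)
  for (rep in 1:20) {
    na <- sample(3:7, 1); nb <- sample(3:7, 1)
    sa <- sample.int(12000, na); sb <- sample.int(12000, nb)
    pa <- make_peaks("chr1", sa, sa + 200, tissue = "ta",
                     ids = sprintf("a%02d", seq_len(na)))
    pb <- make_peaks("chr1", sb, sb + 200, tissue = "tb",
                     ids = sprintf("b%02d", seq_len(nb)))
    d <- outer(seq_len(na), seq_len(nb), function(i, j)
      pmax(0, pmax(sa[i], sb[j]) - pmin(sa[i] + 200, sb[j] + 200)))
    sub <- subdivide_common_peaks(pa, pb)
    got_pairs <- sum(sub$category == "shared_2kb") / 2
    expect_equal(got_pairs, oracle_max_pairs(d, 2000))
  }
})

test_that("enhancer/common-gene restriction filters the subdivision input", {
  pa <- make_peaks("chr1", c(100, 5000), c(300, 5200), tissue = "ta",
                   ids = c("a1", "a2"))
  pb <- make_peaks("chr1", c(150, 5050), c(350, 5250), tissue = "tb",
                   ids = c("b1", "b2"))
  aa <- data.frame(peak_id = c("a1", "a2"), gene_id = c("g1", "g2"),
                   distance_to_tss = 0L, location = c("intron", "promoter"))
  ab <- data.frame(peak_id = c("b1", "b2"), gene_id = c("g1", "g2"),
                   distance_to_tss = 0L, location = c("intron", "intron"))
  sub <- subdivide_common_peaks(pa, pb, assignments_a = aa, assignments_b = ab,
                                common_genes = c("g1", "g2"))
  # a2 is promoter-class, so excluded; its partner b2 becomes B_only
  expect_setequal(sub$peak_id, c("a1", "b1", "b2"))
  expect_equal(sub$category[sub$peak_id == "b2"], "B_only")
})

test_that("occupancy matrix marks consensus regions per sample", {
  pa <- make_peaks("chr1", c(100, 900), c(300, 1100), tissue = "ta")
  m <- occupancy_matrix(list(s1 = pa, s2 = pa))
  expect_true(all(m == 1))
  expect_equal(nrow(m), 2)

  pb <- make_peaks("chr1", c(5000, 9000), c(5300, 9100), tissue = "tb")
  m <- occupancy_matrix(list(s1 = pa, s2 = pb))
  expect_equal(unname(rowSums(m)), rep(1, 4)) # disjoint: block identity
  expect_error(occupancy_matrix(list(s1 = pa[0, ], s2 = pb[0, ])), "empty")
})

test_that("consensus-region counts match the sweep-line oracle", {
  set.seed(44)
  for (rep in 1:10) {
    mk <- function(n) {
      s <- sample.int(20000, n)
      make_peaks(sample(c("chr1", "chr2"), n, replace = TRUE), s,
                 s + sample(100:800, n, replace = TRUE))
    }
    sets <- list(s1 = mk(15), s2 = mk(15), s3 = mk(10))
    m <- occupancy_matrix(sets)
    iv <- do.call(rbind, lapply(sets, function(p) p[, c("chrom", "start", "end")]))
    expect_equal(nrow(m), oracle_consensus_count(iv))
  }
})

test_that("sample correlations match the covariance formula and flag zero variance", {
  set.seed(45)
  m <- matrix(rnorm(60), ncol = 3)
  C <- sample_correlation(m)
  for (i in 1:3) for (j in 1:3) {
    x <- m[, i]; y <- m[, j]
    manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(C[i, j], manual, tolerance = 1e-12)
  }
  dup <- cbind(a = m[, 1], b = m[, 1], c = 1 - m[, 1])
  C <- sample_correlation(dup)
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "c"], -1)
  zv <- cbind(a = m[, 1], z = rep(2, 20))
  C <- sample_correlation(zv)
  expect_true(is.na(C["a", "z"]))
  expect_false(C["a", "z"] %in% 0)
})

test_that("PCA scores match an independent eigen-decomposition", {
  set.seed(46)
  m <- matrix(rnorm(200), nrow = 40, ncol = 5) # 5 samples
  pc <- pca_scores(m, n_components = 4)
  X <- scale(t(m), center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(X))
  ev <- eg$values / sum(eg$values)
  expect_equal(pc$explained_variance, ev[1:4], tolerance = 1e-9)
  for (j in 1:4) {
    expect_equal(abs(pc$scores[, j]), abs(as.numeric(X %*% eg$vectors[, j])),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # sign convention: the largest-magnitude loading is positive
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  # identical samples land on the same point in PC space
  m2 <- cbind(m[, 1], m[, 1], m[, 3])
  pc2 <- pca_scores(m2, 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-9)
  # all components at full rank account for the total variance
  expect_equal(sum(pca_scores(m, 5)$explained_variance), 1, tolerance = 1e-9)
  expect_error(pca_scores(m, 6), "n_components")
})
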