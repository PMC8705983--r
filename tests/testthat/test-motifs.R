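# PWM construction, scanning, shuffling, enrichment, discovery.

test_that("PWM construction normalizes counts with pseudocounts", {
  p <- pwm_from_counts(matrix(c(10, 0, 0, 0), nrow = 4), pseudocount = 0)
  expect_equal(unname(p$matrix[, 1]), c(1, 0, 0, 0))
  u <- pwm_from_counts(matrix(5, nrow = 4, ncol = 6), pseudocount = 0.5)
  expect_true(all(abs(u$matrix - 0.25) < 1e-12))
  expect_error(pwm_from_counts(matrix(0, nrow = 4, ncol = 2)), "all-zero")
  set.seed(51)
  for (rep in 1:100) {
    counts <- matrix(rpois(4 * sample(4:12, 1), 5) + 1, nrow = 4)
    p <- pwm_from_counts(counts, pseudocount = runif(1, 0, 2))
    expect_true(all(abs(colSums(p$matrix) - 1) < 1e-9))
    expect_true(all(p$matrix > 0))
  }
})

test_that("scanning finds the consensus with the maximal score on both strands", {
  pwm <- word_pwm("TTAACG")
  cons <- "TTAACG"
  hits <- scan_pwm(setNames(cons, "s1"), pwm, threshold_frac = 0.5)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$score, pwm_max_score(pwm), tolerance = 1e-9)
  expect_equal(hits$score, sum(log2(apply(pwm$matrix, 2, max) / 0.25)),
               tolerance = 1e-9)
  # reverse complement: same hit set with strands flipped
  seq <- paste0("ACGTACGT", cons, "GGGCCCAT")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  h1 <- scan_pwm(setNames(seq, "x"), pwm, threshold_frac = 0.8)
  h2 <- scan_pwm(setNames(rc, "x"), pwm, threshold_frac = 0.8)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
  expect_setequal(paste(nchar(seq) - h1$offset - 6, ifelse(h1$strand == "+", "-", "+")),
                  paste(h2$offset, h2$strand))
})

test_that("hit sets equal the all-window enumeration oracle", {
  set.seed(52)
  for (rep in 1:15) {
    w <- sample(4:8, 1)
    counts <- matrix(rpois(4 * w, 3) + 1, nrow = 4)
    pwm <- pwm_from_counts(counts, pseudocount = 0.5)
    seq <- rand_dna(sample(50:200, 1), c(0.3, 0.2, 0.2, 0.3))
    thr <- runif(1, 0.3, 0.8) * pwm_max_score(pwm)
    got <- scan_pwm(setNames(seq, "s"), pwm, threshold_bits = thr)
    want <- oracle_scan(seq, pwm, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("windows containing N are skipped and short sequences yield no hits", {
  pwm <- word_pwm("ACGTAC")
  expect_equal(nrow(scan_pwm(setNames("ACG", "s"), pwm, threshold_frac = 0.1)), 0)
  h <- scan_pwm(setNames("ACGNACGTACGTA", "s"), pwm, threshold_frac = 0.95)
  expect_true(all(h$offset >= 4))
})

test_that("shuffles conserve base composition exactly", {
  expect_equal(unname(shuffle_background("AAAA", order = 1, seed = 1)), "AAAA")
  expect_equal(unname(shuffle_background("AAAA", order = 2, seed = 1)), "AAAA")
  set.seed(53)
  seqs <- replicate(20, rand_dna(sample(20:200, 1), c(0.3, 0.2, 0.2, 0.3)))
  tab1 <- function(s) table(factor(strsplit(s, "")[[1]], levels = BASES))
  sh1 <- shuffle_background(seqs, order = 1, seed = 7)
  for (i in seq_along(seqs)) {
    expect_equal(nchar(sh1[i]), nchar(seqs[i]))
    expect_equal(tab1(sh1[i]), tab1(seqs[i]))
  }
  # order 2 preserves all 16 dinucleotide counts (Euler-path shuffle)
  din <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(factor(paste0(ch[-length(ch)], ch[-1]),
                 levels = as.vector(outer(BASES, BASES, paste0))))
  }
  sh2 <- shuffle_background(seqs, order = 2, seed = 7)
  for (i in seq_along(seqs)) expect_equal(din(sh2[i]), din(seqs[i]))
  # deterministic under the seed
  expect_identical(sh2, shuffle_background(seqs, order = 2, seed = 7))
  expect_warning(shuffle_background("AC", order = 2, seed = 1), "order-1")
})

test_that("enrichment p-values equal the hypergeometric tail and behave at the null", {
  pwm <- word_pwm("TTAACGG", p = 0.999)
  with_word <- function(n) {
    vapply(seq_len(n), function(i)
      paste0(rand_dna(20, c(0, 0.5, 0.5, 0)), "TTAACGG",
             rand_dna(20, c(0, 0.5, 0.5, 0))), character(1))
  }
  without_word <- function(n) {
    vapply(seq_len(n), function(i) rand_dna(47, c(0, 0.5, 0.5, 0)), character(1))
  }
  set.seed(54)
  fg <- c(with_word(80), without_word(20))
  bg <- c(with_word(10), without_word(190))
  res <- motif_enrichment(fg, bg, list(pwm), threshold_frac = 0.8)
  expect_equal(res$fg_hits, 80)
  expect_equal(res$bg_hits, 10)
  # oracle: log-gamma hypergeometric tail sum for the 2x2 table
  lchoose_tail <- function(a, nf, b, nb) {
    K <- a + b; N <- nf + nb
    sum(exp(lchoose(K, a:min(K, nf)) + lchoose(N - K, nf - (a:min(K, nf))) -
              lchoose(N, nf)))
  }
  expect_equal(res$p_value, lchoose_tail(80, 100, 10, 200), tolerance = 1e-9)
  # identical fg and bg: odds ratio 1, p well above 0.5
  same <- c(with_word(30), without_word(30))
  res <- motif_enrichment(same, same, list(pwm), threshold_frac = 0.8)
  expect_equal(res$odds_ratio, 1)
  expect_gte(res$p_value, 0.5)
  expect_error(motif_enrichment(fg, bg, list()), "empty")
})

test_that("the Fisher tail is monotone in the foreground count", {
  p <- crossbind:::fisher_tail(0:50, 100, 10, 200)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("a strongly planted motif reaches tiny adjusted p-values", {
  set.seed(55)
  mk <- function(n, rate) {
    vapply(seq_len(n), function(i) {
      s <- rand_dna(100, c(0.3, 0.2, 0.2, 0.3))
      if (runif(1) < rate) {
        at <- sample(1:93, 1)
        s <- paste0(substr(s, 1, at - 1), "TTAACGG", substr(s, at + 7, 100))
      }
      s
    }, character(1))
  }
  fg <- mk(200, 0.8); bg <- mk(200, 0.05)
  res <- motif_enrichment(fg, bg, list(word_pwm("TTAACGG", p = 0.999),
                                       word_pwm("CCGGCCG", p = 0.999)),
                          threshold_frac = 0.9)
  expect_lt(res$p_adjusted[1], 1e-6)
  expect_false(res$enriched[2])
})

test_that("discovery recovers a planted word and respects masking", {
  set.seed(56)
  plant <- "TTAATGA"
  fg <- vapply(1:300, function(i) {
    s <- rand_dna(80, c(0.3, 0.2, 0.2, 0.3))
    if (i <= 210) { # 70 percent planting rate
      at <- sample(1:73, 1)
      s <- paste0(substr(s, 1, at - 1), plant, substr(s, at + 7, 80))
    }
    s
  }, character(1))
  bg <- vapply(1:300, function(i) rand_dna(80, c(0.3, 0.2, 0.2, 0.3)), character(1))
  disc <- discover_motifs(fg, bg, n_motifs = 2, seed = 1)
  expect_gte(nrow(disc), 1)
  top <- attr(disc, "pwms")[[1]]
  core <- crossbind:::pwm_top_word(top)
  # rank-1 consensus within one mismatch of the plant (either strand);
  # allow for adopted flanking columns
  dists <- vapply(0:(nchar(core) - 7), function(o)
    hamming_min_strand(substr(core, o + 1, o + 7), plant), numeric(1))
  expect_lte(min(dists), 1)
  # masking: a second motif never re-reports the rank-1 consensus
  if (nrow(disc) > 1) expect_false(disc$consensus[2] == disc$consensus[1])
})

test_that("discovery refuses tiny foregrounds and stays quiet at the null", {
  expect_error(discover_motifs(rep("ACGT", 5), rep("ACGT", 5)), "10")
  set.seed(57)
  fg <- vapply(1:200, function(i) rand_dna(60, c(0.3, 0.2, 0.2, 0.3)), character(1))
  bg <- vapply(1:200, function(i) rand_dna(60, c(0.3, 0.2, 0.2, 0.3)), character(1))
  disc <- discover_motifs(fg, bg, n_motifs = 3, seed = 2)
  expect_equal(nrow(disc), 0)
})

test_that("motif location distributions are normalized per motif", {
  hits <- data.frame(sequence_id = c("p1", "p1", "p2", "p3"),
                     offset = 0L, strand = "+", score = 1,
                     motif = c("m1", "m1", "m1", "m2"))
  locs <- data.frame(peak_id = c("p1", "p2", "p3"),
                     location = c("intron", "intron", "promoter"))
  d <- motif_location_distribution(hits, locs)
  m1 <- d[d$motif == "m1", ]
  expect_equal(m1$fraction[m1$location == "intron"], 1)
  expect_equal(sum(m1$fraction), 1)
  expect_equal(sum(d$fraction[d$motif == "m2"]), 1)
  # equals a direct per-hit tally
  expect_equal(d$n_hits[d$motif == "m1" & d$location == "intron"], 3L)
})

test_that("IUPAC consensus covers bases above half the column maximum", {
  expect_equal(pwm_consensus(hox_pwm()), "TTWATKR")
  expect_equal(pwm_consensus(word_pwm("ACGT")), "ACGT")
})
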