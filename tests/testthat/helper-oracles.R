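# Shared fixtures and independent brute-force oracles.  Every oracle here is
# a deliberately naive reimplementation (per-base loops, all-pairs scans,
# exhaustive enumeration) kept separate from the package's vectorized code
# paths.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = freqs), collapse = "")
}

make_peaks <- function(chrom, start, end, summit = NA_integer_,
                       tissue = "t", score = 1, strand = "*",
                       ids = NULL) {
  n <- length(start)
  data.frame(peak_id = if (is.null(ids)) sprintf("pk%03d", seq_len(n)) else ids,
             chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n), tissue = tissue, stage = "s",
             score = rep_len(score, n), summit = rep_len(summit, n),
             stringsAsFactors = FALSE)
}

# random annotation: genes (possibly with overlapping windows across genes)
# on one chromosome, each with 2-3 exons
random_annotation <- function(n_genes, chrom_len = 50000, min_gap = 0) {
  starts <- sort(sample.int(chrom_len - 6000, n_genes))
  genes <- list(); exons <- list()
  for (i in seq_len(n_genes)) {
    gstart <- starts[i]
    m <- sample(2:3, 1)
    ex <- sort(sample(200:700, m))
    intr <- sample(500:1500, m - 1, replace = TRUE)
    glen <- sum(ex) + sum(intr)
    gid <- sprintf("g%03d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = "chr1", start = gstart,
                             end = gstart + glen,
                             strand = sample(c("+", "-"), 1),
                             stringsAsFactors = FALSE)
    pos <- gstart
    for (k in seq_len(m)) {
      exons[[length(exons) + 1]] <- data.frame(gene_id = gid, chrom = "chr1",
                                               start = pos, end = pos + ex[k],
                                               stringsAsFactors = FALSE)
      pos <- pos + ex[k] + if (k < m) intr[k] else 0
    }
  }
  gene_annotation(do.call(rbind, genes), do.call(rbind, exons))
}

# --- location classification oracle: paint every base of the chromosome ----
# in ascending priority (other < intron < distal < promoter), then look up
# each peak's representative point
oracle_location_labels <- function(peaks, ann, chrom_len) {
  lab <- rep("intergenic", chrom_len) # index = position + 1
  g <- ann$genes
  paint <- function(from, to, value) { # 0-based half-open, clipped
    from <- max(from, 0); to <- min(to, chrom_len)
    if (to > from) lab[(from + 1):to] <<- value
  }
  for (i in seq_len(nrow(g))) {
    ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], ]
    for (k in seq_len(nrow(ex))) paint(ex$start[k], ex$end[k], "other")
  }
  for (i in seq_len(nrow(g))) {
    ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], ]
    pos <- g$start[i]:(g$end[i] - 1)
    in_exon <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(ex))) {
      in_exon <- in_exon | (pos >= ex$start[k] & pos < ex$end[k])
    }
    hit <- pos[!in_exon]
    hit <- hit[hit >= 0 & hit < chrom_len]
    lab[hit + 1] <- "intron"
  }
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") {
      paint(g$tss[i] - 2000, g$tss[i] - 1000, "distal_enhancer")
      paint(g$end[i], g$end[i] + 1000, "distal_enhancer")
    } else {
      paint(g$tss[i] + 1001, g$tss[i] + 2001, "distal_enhancer")
      paint(g$start[i] - 1000, g$start[i], "distal_enhancer")
    }
  }
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") {
      paint(g$tss[i] - 1000, g$tss[i] + 11, "promoter")
    } else {
      paint(g$tss[i] - 10, g$tss[i] + 1001, "promoter")
    }
  }
  pts <- representative_point(peaks)
  lab[pts + 1]
}

# --- assignment oracle: all-pairs distance scan ----------------------------
oracle_assignments <- function(peaks, ann, flank_up = 2000, flank_down = 1000,
                               max_tss = 10000) {
  g <- ann$genes
  pts <- representative_point(peaks)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    hit <- character(0)
    for (j in seq_len(nrow(g))) {
      if (peaks$chrom[i] != g$chrom[j]) next
      lo <- if (g$strand[j] == "+") g$start[j] - flank_up else g$start[j] - flank_down
      hi <- if (g$strand[j] == "+") g$end[j] + flank_down else g$end[j] + flank_up
      if (pts[i] >= lo && pts[i] < hi) hit <- c(hit, g$gene_id[j])
    }
    if (length(hit) == 0) {
      cand <- g[g$chrom == g$chrom, ]
      d <- abs(pts[i] - g$tss)
      d[g$chrom != peaks$chrom[i]] <- Inf
      ord <- order(d, g$gene_id)
      if (d[ord[1]] <= max_tss) hit <- g$gene_id[ord[1]] else hit <- NA_character_
    }
    rows[[i]] <- data.frame(peak_id = peaks$peak_id[i],
                            gene_id = if (all(is.na(hit))) NA_character_ else sort(hit),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# --- per-base coverage oracle ----------------------------------------------
oracle_coverage <- function(peak, track) {
  pos <- peak$start:(peak$end - 1)
  covered <- rep(FALSE, length(pos))
  tr <- track[track$chrom == peak$chrom, , drop = FALSE]
  for (k in seq_len(nrow(tr))) {
    covered <- covered | (pos >= tr$start[k] & pos < tr$end[k])
  }
  mean(covered)
}

# --- consensus-region count oracle: sweep line -----------------------------
oracle_consensus_count <- function(intervals) {
  n <- 0
  for (chrom in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chrom, ]
    ev <- rbind(data.frame(pos = iv$start, d = 1), data.frame(pos = iv$end, d = -1))
    ev <- ev[order(ev$pos, -ev$d), ]
    depth <- 0
    for (r in seq_len(nrow(ev))) {
      if (depth == 0 && ev$d[r] == 1) n <- n + 1
      depth <- depth + ev$d[r]
    }
  }
  n
}

# --- PWM scan oracle: enumerate every window on both strands ---------------
oracle_scan <- function(seq, pwm, threshold) {
  w <- ncol(pwm$matrix)
  L <- nchar(seq)
  rc_base <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  score_word <- function(word) {
    ch <- strsplit(word, "")[[1]]
    if (any(!ch %in% BASES)) return(NA_real_)
    s <- 0
    for (j in seq_along(ch)) {
      s <- s + log2(pwm$matrix[ch[j], j] / pwm$background[ch[j]])
    }
    s
  }
  for (off in 0:(L - w)) {
    word <- substr(seq, off + 1, off + w)
    s <- score_word(word)
    if (!is.na(s) && s >= threshold) {
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "+", score = s)
    }
    rcw <- paste(rev(rc_base[strsplit(word, "")[[1]]]), collapse = "")
    s <- score_word(rcw)
    if (!is.na(s) && s >= threshold) {
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "-", score = s)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  h <- do.call(rbind, hits)
  h[order(h$offset, h$strand), ]
}

# --- exhaustive maximum-cardinality matching oracle (<= 15 peaks) ----------
# returns the maximal number of cross-tissue pairs with distance <= gap
oracle_max_pairs <- function(dist_matrix, gap) {
  na <- nrow(dist_matrix); nb <- ncol(dist_matrix)
  best <- 0
  recurse <- function(i, used_b, count) {
    if (count + (na - i + 1) <= best) return()
    if (i > na) { best <<- max(best, count); return() }
    for (j in seq_len(nb)) {
      if (!used_b[j] && dist_matrix[i, j] <= gap) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, count + 1)
        used_b[j] <- FALSE
      }
    }
    recurse(i + 1, used_b, count)
  }
  recurse(1, rep(FALSE, nb), 0)
  best
}

# hamming distance between equal-length words, minimized over strands
hamming_min_strand <- function(a, b) {
  hd <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  rc <- function(x) paste(rev(c(A = "T", C = "G", G = "C", T = "A")[
    strsplit(x, "")[[1]]]), collapse = "")
  if (nchar(a) != nchar(b)) return(Inf)
  min(hd(a, b), hd(rc(a), b))
}

# small deterministic gene annotation: one + strand and one - strand gene
two_gene_annotation <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(5000L, 20000L), end = c(9000L, 24000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gA", "gB", "gB"), chrom = "chr1",
                      start = c(5000L, 8000L, 20000L, 23000L),
                      end = c(5500L, 9000L, 20600L, 24000L),
                      stringsAsFactors = FALSE)
  gene_annotation(genes, exons)
}
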