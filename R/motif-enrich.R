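# Motif enrichment between sequence sets (AME-style, sequence-level Fisher
# test with Bonferroni correction) and k-mer seeded de novo discovery
# (STREME-style stand-in: Fisher-scored seeds, 1-mismatch site collection,
# information-content widening, masking, iteration).

#' Test known motifs for enrichment in foreground vs background sequences
#'
#' A sequence "has" a motif when it contains at least one scan hit.  Per
#' motif, a one-sided Fisher exact test asks whether foreground sequences
#' have the motif more often than background sequences; p-values are
#' Bonferroni-corrected across the motif set and motifs with adjusted
#' p >= 0.05 are flagged not enriched (the table's NA-equivalent).
#'
#' @param fg_sequences,bg_sequences character vectors of sequences.
#' @param pwms list of `pwm` objects.
#' @param threshold_bits,threshold_frac scan threshold, see [scan_pwm()].
#' @return data frame `motif, fg_hits, fg_total, bg_hits, bg_total,
#'   odds_ratio, p_value, p_adjusted, enriched`.
#' @export
motif_enrichment <- function(fg_sequences, bg_sequences, pwms,
                             threshold_bits = NULL, threshold_frac = 0.6) {
  if (length(pwms) == 0) stop("empty motif list")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (length(fg_sequences) == 0 || length(bg_sequences) == 0) {
    stop("foreground and background sequence sets must be non-empty")
  }
  if (is.null(names(fg_sequences))) names(fg_sequences) <- paste0("fg", seq_along(fg_sequences))
  if (is.null(names(bg_sequences))) names(bg_sequences) <- paste0("bg", seq_along(bg_sequences))
  n_fg <- length(fg_sequences); n_bg <- length(bg_sequences)
  rows <- lapply(pwms, function(pwm) {
    fg_hit <- length(unique(scan_pwm(fg_sequences, pwm, threshold_bits,
                                     threshold_frac)$sequence_id))
    bg_hit <- length(unique(scan_pwm(bg_sequences, pwm, threshold_bits,
                                     threshold_frac)$sequence_id))
    tab <- matrix(c(fg_hit, n_fg - fg_hit, bg_hit, n_bg - bg_hit), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    or <- (fg_hit + 0.5) / (n_fg - fg_hit + 0.5) /
      ((bg_hit + 0.5) / (n_bg - bg_hit + 0.5))
    data.frame(motif = pwm$name, fg_hits = fg_hit, fg_total = n_fg,
               bg_hits = bg_hit, bg_total = n_bg, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out$enriched <- out$p_adjusted < 0.05
  rownames(out) <- NULL
  out
}

# --- k-mer machinery -------------------------------------------------------

rev_string <- function(s) {
  vapply(s, function(x) intToUtf8(rev(utf8ToInt(x))), character(1), USE.NAMES = FALSE)
}

revcomp_fast <- function(s) rev_string(chartr("ACGT", "TGCA", s))

# canonical (strand-collapsed) k-mers occurring in one sequence
seq_kmers <- function(s, rc_s, k, unique_only = TRUE) {
  L <- nchar(s)
  if (L < k) return(character(0))
  i <- seq_len(L - k + 1L)
  win <- substring(s, i, i + k - 1L)
  rcwin <- substring(rc_s, L - (i + k - 1L) + 1L, L - i + 1L)
  canon <- pmin(win, rcwin)
  canon <- canon[!grepl("N", canon, fixed = TRUE)]
  if (unique_only) unique(canon) else canon
}

# per-kmer number of sequences containing it (canonical, either strand)
kmer_sequence_counts <- function(seqs, k_values) {
  rc <- revcomp_fast(seqs)
  all <- unlist(lapply(seq_along(seqs), function(i) {
    unlist(lapply(k_values, function(k) seq_kmers(seqs[[i]], rc[[i]], k)))
  }))
  if (length(all) == 0) return(integer(0))
  tab <- table(all)
  setNames(as.integer(tab), names(tab))
}

# one-sided Fisher (hypergeometric tail) for fg over-representation,
# vectorized over seeds
fisher_tail <- function(a, n_fg, b, n_bg) {
  stats::phyper(a - 1, a + b, n_fg + n_bg - a - b, n_fg, lower.tail = FALSE)
}

#' De novo motif discovery by seeded k-mer extension
#'
#' Iterative discovery: (1) every canonical k-mer (k in `k_min..k_max`,
#' collapsed over strands) is scored by a one-sided Fisher exact test of
#' sequence-level occurrence in foreground vs background; (2) the best seed's
#' foreground occurrences within one mismatch (either strand) are collected
#' and aligned into a PWM (pseudocount 0.5), which is widened by one column
#' per side while the added column's information content is >= 0.3 bits;
#' (3) the matched sites are masked (replaced by N) in the foreground and the
#' search repeats, until `n_motifs` motifs are found or the best seed's
#' Bonferroni-adjusted p (across the evaluated seed set) is >= 0.05.
#'
#' @param fg_sequences,bg_sequences character vectors; at least 10 foreground
#'   sequences are required.
#' @param k_min,k_max seed k-mer lengths (defaults 6 and 10).
#' @param n_motifs maximal number of motifs to report (default 5).
#' @param seed RNG seed (recorded; the algorithm itself is deterministic).
#' @param min_seed_count minimal foreground sequence count for a k-mer to be
#'   evaluated as seed.
#' @param max_extend maximal widening per side (columns).
#' @return data frame `rank, seed, consensus, width, n_sites, p_value,
#'   p_adjusted` with attribute `pwms` (list of discovered `pwm` objects).
#' @export
discover_motifs <- function(fg_sequences, bg_sequences, k_min = 6, k_max = 10,
                            n_motifs = 5, seed = 1, min_seed_count = 3,
                            max_extend = 3) {
  if (length(fg_sequences) < 10) {
    stop("fewer than 10 foreground sequences: discovery power too low")
  }
  set.seed(seed)
  fg <- Biostrings::DNAStringSet(toupper(fg_sequences))
  if (is.null(names(fg))) names(fg) <- paste0("fg", seq_along(fg))
  n_fg <- length(fg); n_bg <- length(bg_sequences)
  k_values <- seq.int(k_min, k_max)
  bg_counts <- kmer_sequence_counts(toupper(bg_sequences), k_values)
  results <- list(); pwms <- list()
  for (rank in seq_len(n_motifs)) {
    fg_chr <- as.character(fg)
    fg_counts <- kmer_sequence_counts(fg_chr, k_values)
    fg_counts <- fg_counts[fg_counts >= min_seed_count]
    if (length(fg_counts) == 0) break
    b <- bg_counts[names(fg_counts)]
    b[is.na(b)] <- 0L
    p <- fisher_tail(fg_counts, n_fg, b, n_bg)
    n_seeds <- length(p)
    ord <- order(p, names(p))
    best <- names(p)[ord[1]]
    p_best <- p[[ord[1]]]
    p_adj <- min(1, p_best * n_seeds)
    if (p_adj >= 0.05) break
    site <- collect_sites(fg, best, max_extend)
    if (nrow(site$occ) == 0) break
    pwm <- build_site_pwm(site, nchar(best), max_extend,
                          name = sprintf("discovered_%d", rank))
    results[[rank]] <- data.frame(rank = rank, seed = best,
                                  consensus = pwm_consensus(pwm),
                                  width = pwm_width(pwm),
                                  n_sites = nrow(site$occ),
                                  p_value = p_best, p_adjusted = p_adj,
                                  stringsAsFactors = FALSE)
    pwms[[pwm$name]] <- pwm
    fg <- mask_sites(fg, site$occ)
  }
  out <- if (length(results) == 0) {
    data.frame(rank = integer(0), seed = character(0), consensus = character(0),
               width = integer(0), n_sites = integer(0), p_value = numeric(0),
               p_adjusted = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, results)
  }
  rownames(out) <- NULL
  attr(out, "pwms") <- pwms
  attr(out, "seed") <- seed
  out
}

# all foreground occurrences of `word` within 1 mismatch, both strands,
# with up to `pad` bases of oriented flanking context
collect_sites <- function(fg, word, pad) {
  k <- nchar(word)
  hit_tab <- function(pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, fg, max.mismatch = 1, fixed = TRUE)
    idx <- rep(seq_along(m), lengths(m))
    if (length(idx) == 0) {
      return(data.frame(seq = integer(0), start = integer(0), end = integer(0),
                        strand = character(0)))
    }
    r <- unlist(m)
    data.frame(seq = idx, start = IRanges::start(r), end = IRanges::end(r),
               strand = strand, stringsAsFactors = FALSE)
  }
  occ <- hit_tab(word, "+")
  rc <- revcomp(word)
  if (rc != word) occ <- rbind(occ, hit_tab(rc, "-"))
  occ <- occ[occ$start >= 1 & occ$end <= Biostrings::width(fg)[occ$seq], , drop = FALSE]
  if (nrow(occ) == 0) return(list(occ = occ, ctx = character(0), avail = NULL))
  L <- Biostrings::width(fg)[occ$seq]
  left <- pmin(pad, occ$start - 1L)
  right <- pmin(pad, L - occ$end)
  ctx <- as.character(Biostrings::subseq(fg[occ$seq], occ$start - left,
                                         occ$end + right))
  neg <- occ$strand == "-"
  ctx[neg] <- revcomp(ctx[neg])
  avail <- cbind(left = ifelse(neg, right, left), right = ifelse(neg, left, right))
  list(occ = occ, ctx = ctx, avail = avail)
}

# aligned-site PWM with information-content widening
build_site_pwm <- function(site, k, pad, name) {
  ctx <- site$ctx; avail <- site$avail
  n <- length(ctx)
  # place each context into a (2*pad + k) character frame
  frame <- matrix(NA_character_, nrow = n, ncol = k + 2 * pad)
  for (i in seq_len(n)) {
    chars <- strsplit(ctx[i], "")[[1]]
    from <- pad - avail[i, "left"] + 1L
    frame[i, from:(from + length(chars) - 1L)] <- chars
  }
  col_counts <- function(j) {
    obs <- frame[, j]
    obs <- obs[!is.na(obs) & obs %in% .bases]
    vapply(.bases, function(b) sum(obs == b), numeric(1))
  }
  col_ic <- function(counts) {
    if (sum(counts) < 2) return(0)
    p <- (counts + 0.5) / sum(counts + 0.5)
    2 + sum(p * log2(p))
  }
  lo <- pad + 1L; hi <- pad + k
  while (lo > 1) {
    cc <- col_counts(lo - 1L)
    if (sum(cc) >= length(ctx) / 2 && col_ic(cc) >= 0.3) lo <- lo - 1L else break
  }
  while (hi < k + 2 * pad) {
    cc <- col_counts(hi + 1L)
    if (sum(cc) >= length(ctx) / 2 && col_ic(cc) >= 0.3) hi <- hi + 1L else break
  }
  counts <- vapply(lo:hi, col_counts, numeric(4))
  pwm_from_counts(counts, pseudocount = 0.5, name = name)
}

# replace matched site windows with N (per-sequence ranges merged first)
mask_sites <- function(fg, occ) {
  for (i in unique(occ$seq)) {
    r <- IRanges::reduce(IRanges::IRanges(occ$start[occ$seq == i],
                                          occ$end[occ$seq == i]))
    fg[[i]] <- Biostrings::replaceAt(fg[[i]], r,
                                     vapply(IRanges::width(r),
                                            function(w) paste(rep("N", w), collapse = ""),
                                            character(1)))
  }
  fg
}

#' Distribution of motif hits over location labels
#'
#' Maps scan hits back to their source peaks and tallies, per motif, the
#' fraction of hits falling in each genomic-location class.
#'
#' @param hits hit table from [scan_pwm()] whose `sequence_id`s are peak ids;
#'   an optional `motif` column separates motifs.
#' @param locations data frame `peak_id, location` (e.g. peak ids with their
#'   [classify_location()] labels).
#' @return data frame `motif, location, n_hits, fraction`; fractions sum to 1
#'   per motif.  Motifs without hits are omitted (with a message).
#' @export
motif_location_distribution <- function(hits, locations) {
  if (!"motif" %in% names(hits)) hits$motif <- "motif"
  m <- match(hits$sequence_id, locations$peak_id)
  if (anyNA(m)) stop("hit sequence_id(s) missing from the location table")
  hits$location <- locations$location[m]
  out <- do.call(rbind, lapply(split(hits, hits$motif), function(h) {
    tab <- table(factor(h$location, levels = .priority_levels))
    data.frame(motif = h$motif[1], location = names(tab),
               n_hits = as.integer(tab), fraction = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
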