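# Cross-tissue comparison: gene categories, binding frequency, the 2 kb
# peak subdivision, and the occupancy-matrix correlation / PCA surrogate.

#' Categorize genes as commonly or tissue-specifically bound
#'
#' A gene bound (>= 1 assigned peak) in both tissues is `common`; a gene
#' bound in only one is specific to that tissue.
#'
#' @param assignments_a,assignments_b assignment tables from
#'   [assign_peaks_to_genes()] for the two tissues, over the same annotation.
#' @param labels names of the two tissues, used to build the category labels.
#' @return data frame `gene_id, category` with attributes `counts` and
#'   `percentages` (integer percents, half-up rounding).
#' @export
categorize_genes <- function(assignments_a, assignments_b,
                             labels = c("A", "B")) {
  ga <- unique(assignments_a$gene_id[!is.na(assignments_a$gene_id)])
  gb <- unique(assignments_b$gene_id[!is.na(assignments_b$gene_id)])
  if (length(ga) == 0 && length(gb) > 0) {
    warning(sprintf("no genes bound in tissue %s; all bound genes are %s-specific",
                    labels[1], labels[2]))
  }
  if (length(gb) == 0 && length(ga) > 0) {
    warning(sprintf("no genes bound in tissue %s; all bound genes are %s-specific",
                    labels[2], labels[1]))
  }
  cats <- c("common", paste0(labels[1], "_specific"), paste0(labels[2], "_specific"))
  all_genes <- sort(union(ga, gb))
  category <- ifelse(all_genes %in% ga & all_genes %in% gb, cats[1],
                     ifelse(all_genes %in% ga, cats[2], cats[3]))
  out <- data.frame(gene_id = all_genes, category = category,
                    stringsAsFactors = FALSE)
  counts <- setNames(as.integer(table(factor(category, levels = cats))), cats)
  attr(out, "counts") <- counts
  attr(out, "percentages") <- category_percentages(counts)
  out
}

#' Integer percentages from category counts
#'
#' Shares of each category in percent, rounded half-up to the nearest integer
#' (display convention of the category bar plots).
#'
#' @param counts named integer vector of category counts.
#' @return named numeric vector of integer percents.
#' @export
category_percentages <- function(counts) {
  if (sum(counts) == 0) return(setNames(rep(NA_real_, length(counts)), names(counts)))
  round_half_up(100 * counts / sum(counts))
}

#' Per-gene binding frequency
#'
#' Counts the distinct peaks assigned to each gene and classifies genes as
#' `singlePeak` (one peak) or `multiPeak` (more than one).
#'
#' @param assignments assignment table from [assign_peaks_to_genes()].
#' @param genes optional character vector restricting the genes considered.
#' @return data frame `gene_id, n_peaks, class` with attribute `histogram`
#'   (table of genes per peak count).
#' @export
binding_frequency <- function(assignments, genes = NULL) {
  a <- assignments[!is.na(assignments$gene_id), ]
  if (!is.null(genes)) a <- a[a$gene_id %in% genes, ]
  if (nrow(a) == 0) {
    out <- data.frame(gene_id = character(0), n_peaks = integer(0),
                      class = character(0), stringsAsFactors = FALSE)
    attr(out, "histogram") <- table(integer(0))
    return(out)
  }
  n <- tapply(a$peak_id, a$gene_id, function(p) length(unique(p)))
  out <- data.frame(gene_id = names(n), n_peaks = as.integer(n),
                    class = ifelse(n == 1, "singlePeak", "multiPeak"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "histogram") <- table(out$n_peaks)
  out
}

#' Subdivide cross-tissue peaks into tissue-specific and shared elements
#'
#' Cross-tissue peak pairs on the same chromosome whose distance is at most
#' `gap` (default 2 kb; overlapping peaks have distance 0) are matched
#' greedily by increasing distance, each peak entering at most one pair;
#' matched peaks are `shared_2kb`, the rest `A_only` / `B_only`.
#'
#' When `assignments_a`/`assignments_b` and `common_genes` are supplied, the
#' input is first restricted to peaks assigned to a common gene at an
#' enhancer-class location (distal_enhancer, intron or intergenic), the peak
#' population on which the subdivision is defined.
#'
#' @param peaks_a,peaks_b peak sets of the two tissues.
#' @param gap maximal distance in bp (>= 0).
#' @param distance `"edge"` (edge-to-edge gap; overlap counts 0) or
#'   `"midpoint"`.
#' @param assignments_a,assignments_b optional assignment tables used for the
#'   enhancer/common-gene restriction.
#' @param common_genes optional character vector of common gene ids.
#' @return data frame `peak_id, tissue, category, partner_peak_id` covering
#'   every (restricted) input peak exactly once, with attribute
#'   `fraction_specific` (fraction of peaks not in a shared pair).
#' @export
subdivide_common_peaks <- function(peaks_a, peaks_b, gap = 2000,
                                   distance = c("edge", "midpoint"),
                                   assignments_a = NULL, assignments_b = NULL,
                                   common_genes = NULL) {
  distance <- match.arg(distance)
  if (gap < 0) stop("gap must be non-negative")
  validate_peaks(peaks_a); validate_peaks(peaks_b)
  enh <- c("distal_enhancer", "intron", "intergenic")
  restrict <- function(p, a) {
    if (is.null(a) || is.null(common_genes)) return(p)
    keep <- a$peak_id[!is.na(a$gene_id) & a$gene_id %in% common_genes &
                        a$location %in% enh]
    p[p$peak_id %in% keep, , drop = FALSE]
  }
  pa <- restrict(peaks_a, assignments_a)
  pb <- restrict(peaks_b, assignments_b)
  pair_a <- setNames(rep(NA_character_, nrow(pa)), pa$peak_id)
  pair_b <- setNames(rep(NA_character_, nrow(pb)), pb$peak_id)
  if (nrow(pa) > 0 && nrow(pb) > 0) {
    gra <- as_granges(pa); grb <- as_granges(pb)
    ov <- find_overlaps(gra, grb, maxgap = gap, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    if (length(qi) > 0) {
      d <- if (distance == "edge") {
        edge_gap(pa$start[qi], pa$end[qi], pb$start[si], pb$end[si])
      } else {
        abs(floor((pa$start[qi] + pa$end[qi]) / 2) -
              floor((pb$start[si] + pb$end[si]) / 2))
      }
      keep <- d <= gap
      cand <- data.frame(a = qi[keep], b = si[keep], d = d[keep])
      cand <- cand[order(cand$d, pa$peak_id[cand$a], pb$peak_id[cand$b]), ]
      taken_a <- logical(nrow(pa)); taken_b <- logical(nrow(pb))
      for (r in seq_len(nrow(cand))) {
        i <- cand$a[r]; j <- cand$b[r]
        if (!taken_a[i] && !taken_b[j]) {
          taken_a[i] <- TRUE; taken_b[j] <- TRUE
          pair_a[i] <- pb$peak_id[j]; pair_b[j] <- pa$peak_id[i]
        }
      }
    }
  }
  out <- rbind(
    data.frame(peak_id = pa$peak_id, tissue = pa$tissue,
               category = ifelse(is.na(pair_a), "A_only", "shared_2kb"),
               partner_peak_id = unname(pair_a), stringsAsFactors = FALSE),
    data.frame(peak_id = pb$peak_id, tissue = pb$tissue,
               category = ifelse(is.na(pair_b), "B_only", "shared_2kb"),
               partner_peak_id = unname(pair_b), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "fraction_specific") <-
    if (nrow(out) == 0) NA_real_ else mean(out$category != "shared_2kb")
  out
}

#' Build an occupancy matrix over consensus regions
#'
#' Consensus regions are the union of all peaks merged at overlap; entry
#' (region, sample) is 1 when the sample has a peak overlapping the region
#' (`value = "binary"`) or the maximal score of its overlapping peaks
#' (`value = "score"`).
#'
#' @param peak_sets named list of >= 2 peak data frames (one per sample).
#' @param value `"binary"` or `"score"`.
#' @return numeric matrix; rows named `chrom:start-end` (0-based half-open),
#'   columns in the order of `peak_sets`.
#' @export
occupancy_matrix <- function(peak_sets, value = c("binary", "score")) {
  value <- match.arg(value)
  stopifnot(is.list(peak_sets), length(peak_sets) >= 2)
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets)))) {
    names(peak_sets) <- paste0("sample", seq_along(peak_sets))
  }
  all_peaks <- do.call(rbind, lapply(peak_sets, function(p) {
    validate_peaks(p); p[, c("chrom", "start", "end")]
  }))
  if (nrow(all_peaks) == 0) stop("empty peak union: no consensus regions")
  consensus <- GenomicRanges::reduce(as_granges(all_peaks))
  m <- matrix(0, nrow = length(consensus), ncol = length(peak_sets),
              dimnames = list(sprintf("%s:%d-%d",
                                      as.character(GenomicRanges::seqnames(consensus)),
                                      GenomicRanges::start(consensus) - 1L,
                                      GenomicRanges::end(consensus)),
                              names(peak_sets)))
  for (k in seq_along(peak_sets)) {
    p <- peak_sets[[k]]
    if (nrow(p) == 0) next
    ov <- find_overlaps(consensus, as_granges(p), ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov)
    if (value == "binary") {
      m[unique(qi), k] <- 1
    } else if (length(qi) > 0) {
      sc <- tapply(p$score[S4Vectors::subjectHits(ov)], qi, max)
      m[as.integer(names(sc)), k] <- as.numeric(sc)
    }
  }
  m
}

#' Pairwise sample correlation of an occupancy matrix
#'
#' Symmetric Pearson correlation between sample columns.  Columns with zero
#' variance yield `NA` (undefined), not 0.
#'
#' @param matrix numeric matrix, samples in columns.
#' @return correlation matrix with unit diagonal for valid columns.
#' @export
sample_correlation <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2, nrow(matrix) >= 2)
  v <- apply(matrix, 2, stats::var)
  C <- suppressWarnings(stats::cor(matrix))
  C[v == 0, ] <- NA_real_
  C[, v == 0] <- NA_real_
  diag(C) <- ifelse(v > 0, 1, NA_real_)
  C
}

#' Principal component scores of samples
#'
#' PCA of the samples (columns) of an occupancy matrix; the matrix is
#' centered internally.  Sign convention: within each component the loading
#' of largest magnitude is made positive.
#'
#' @param matrix numeric matrix, samples in columns, regions in rows.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained_variance`
#'   (fractions for the returned components) and `loadings`.
#' @export
pca_scores <- function(matrix, n_components = 2) {
  stopifnot(is.matrix(matrix))
  if (n_components > min(dim(matrix))) {
    stop("n_components exceeds matrix rank bound min(dim(matrix))")
  }
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  evfrac <- if (sum(ev) > 0) ev / sum(ev) else ev
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  for (j in k) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, explained_variance = evfrac[k], loadings = loadings)
}
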