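# Histone-mark coverage over peaks and the four-way cross-tissue mark
# classification:
#   active_shared        H3K27ac in focal AND other tissue
#   active_focal_only    H3K27ac in focal tissue only
#   repressed_shared     H3K27me3 in focal AND other tissue
#   repressed_focal_only H3K27me3 in focal tissue only
#   unclassified         neither or both marks in the focal tissue

#' Fraction of each peak covered by a mark track
#'
#' (covered bases of the peak interval) / (peak length); the track is merged
#' internally so overlapping track intervals are not double-counted.
#'
#' @param peaks peak data frame.
#' @param track interval data frame `chrom, start, end`.
#' @return numeric vector of fractions in [0, 1], one per peak.
#' @export
coverage_fraction <- function(peaks, track) {
  validate_peaks(peaks)
  if (nrow(peaks) == 0) return(numeric(0))
  if (any(peaks$end - peaks$start <= 0)) stop("zero-length peak")
  cov <- numeric(nrow(peaks))
  track <- merge_intervals(track)
  if (nrow(track) == 0) return(cov)
  pg <- as_granges(peaks)
  tg <- as_granges(track)
  ov <- find_overlaps(pg, tg, ignore.strand = TRUE)
  if (length(ov) > 0) {
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    inter <- pmin(peaks$end[qi], track$end[si]) - pmax(peaks$start[qi], track$start[si])
    covered <- tapply(inter, qi, sum) # track merged: intersections disjoint
    cov[as.integer(names(covered))] <- as.numeric(covered)
  }
  cov / (peaks$end - peaks$start)
}

#' Cross-tissue histone-mark classification of tissue-specific peaks
#'
#' Each focal-tissue-specific peak is binarized as marked/unmarked for
#' H3K27ac and H3K27me3 in the focal and the other tissue (coverage fraction
#' >= `threshold`), then classified:  a peak acetylated in the focal tissue
#' is `active_shared` when also acetylated in the other tissue, else
#' `active_focal_only`; a peak trimethylated in the focal tissue is
#' `repressed_shared` when also trimethylated in the other tissue, else
#' `repressed_focal_only`; peaks with neither or both marks in the focal
#' tissue are `unclassified`.
#'
#' @param peaks tissue-specific peak data frame (focal tissue).
#' @param tracks nested list `tracks[[tissue]][[mark]]` of interval data
#'   frames, for marks `H3K27ac` and `H3K27me3` in both tissues.
#' @param focal_tissue,other_tissue names into `tracks`.
#' @param threshold coverage fraction at which a peak counts as marked
#'   (default 0.25).
#' @return data frame `peak_id, class` plus the four coverage-fraction and
#'   marked columns, with attribute `counts` (class counts).
#' @export
classify_cross_tissue <- function(peaks, tracks, focal_tissue, other_tissue,
                                  threshold = 0.25) {
  marks <- c("H3K27ac", "H3K27me3")
  for (tis in c(focal_tissue, other_tissue)) {
    for (mk in marks) {
      if (is.null(tracks[[tis]]) || is.null(tracks[[tis]][[mk]])) {
        stop(sprintf("missing mark track: (%s, %s)", mk, tis))
      }
    }
  }
  cov <- list(
    ac_focal = coverage_fraction(peaks, tracks[[focal_tissue]]$H3K27ac),
    me3_focal = coverage_fraction(peaks, tracks[[focal_tissue]]$H3K27me3),
    ac_other = coverage_fraction(peaks, tracks[[other_tissue]]$H3K27ac),
    me3_other = coverage_fraction(peaks, tracks[[other_tissue]]$H3K27me3))
  mk <- lapply(cov, function(x) x >= threshold)
  class <- mark_class(mk$ac_focal, mk$me3_focal, mk$ac_other, mk$me3_other)
  out <- data.frame(peak_id = peaks$peak_id, class = class,
                    cov_ac_focal = cov$ac_focal, cov_me3_focal = cov$me3_focal,
                    cov_ac_other = cov$ac_other, cov_me3_other = cov$me3_other,
                    marked_ac_focal = mk$ac_focal, marked_me3_focal = mk$me3_focal,
                    marked_ac_other = mk$ac_other, marked_me3_other = mk$me3_other,
                    stringsAsFactors = FALSE)
  lv <- c("active_shared", "active_focal_only", "repressed_shared",
          "repressed_focal_only", "unclassified")
  attr(out, "counts") <- setNames(as.integer(table(factor(class, levels = lv))), lv)
  n_un <- sum(class == "unclassified")
  if (n_un > 0) message(sprintf("%d peak(s) unclassified (neither or both marks in the focal tissue)", n_un))
  out
}

# pure function of the four marked booleans
mark_class <- function(ac_focal, me3_focal, ac_other, me3_other) {
  ifelse(ac_focal & !me3_focal,
         ifelse(ac_other, "active_shared", "active_focal_only"),
         ifelse(me3_focal & !ac_focal,
                ifelse(me3_other, "repressed_shared", "repressed_focal_only"),
                "unclassified"))
}

#' Mean mark coverage profile around peak centers
#'
#' Bins the window [center - flank, center + flank) of every peak into
#' `n_bins` equal bins and averages per-bin coverage over peaks,
#' strand-agnostic.  Near a chromosome edge the flank is clipped and the bin
#' normalized by its available bases.
#'
#' @param peaks peak data frame.
#' @param track interval data frame.
#' @param flank half-window size in bp (> 0).
#' @param n_bins number of bins (>= 2).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right-edge clipping (the left edge is always clipped at 0).
#' @return numeric vector of length `n_bins` of mean coverage fractions.
#' @export
aggregate_mark_profile <- function(peaks, track, flank = 1000, n_bins = 20,
                                   chrom_lengths = NULL) {
  stopifnot(flank > 0, n_bins >= 2)
  validate_peaks(peaks)
  track <- merge_intervals(track)
  centers <- floor((peaks$start + peaks$end) / 2)
  edges <- round(seq(-flank, flank, length.out = n_bins + 1))
  prof <- matrix(NA_real_, nrow = nrow(peaks), ncol = n_bins)
  tg <- if (nrow(track) > 0) as_granges(track) else NULL
  for (i in seq_len(nrow(peaks))) {
    bin_start <- centers[i] + edges[-(n_bins + 1)]
    bin_end <- centers[i] + edges[-1]
    cl_start <- pmax(bin_start, 0L)
    cl_end <- bin_end
    if (!is.null(chrom_lengths) && peaks$chrom[i] %in% names(chrom_lengths)) {
      cl_end <- pmin(cl_end, chrom_lengths[[peaks$chrom[i]]])
    }
    avail <- pmax(cl_end - cl_start, 0L)
    covered <- numeric(n_bins)
    ok <- avail > 0
    if (any(ok) && !is.null(tg)) {
      bg <- GenomicRanges::GRanges(rep(peaks$chrom[i], sum(ok)),
                                   IRanges::IRanges(cl_start[ok] + 1L, cl_end[ok]))
      ov <- find_overlaps(bg, tg, ignore.strand = TRUE)
      if (length(ov) > 0) {
        qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
        inter <- pmin(cl_end[ok][qi], track$end[si]) -
          pmax(cl_start[ok][qi], track$start[si])
        csum <- tapply(inter, qi, sum)
        covered[which(ok)[as.integer(names(csum))]] <- as.numeric(csum)
      }
    }
    prof[i, ok] <- covered[ok] / avail[ok]
  }
  colMeans(prof, na.rm = TRUE)
}
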