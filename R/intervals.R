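# Internal interval helpers.  Convention everywhere in this package:
# 0-based, half-open [start, end) on a named chromosome, strand in {+, -, *}.

validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s table lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(as.character(df$chrom)))) {
    stop(sprintf("%s: chromosome names must be non-empty", what))
  }
  if (any(df$start < 0)) stop(sprintf("%s: start must be >= 0", what))
  bad <- which(df$end <= df$start)
  if (length(bad) > 0) {
    stop(sprintf("%s: end must exceed start (first offending row: %d)", what, bad[1]))
  }
  invisible(df)
}

validate_peaks <- function(peaks) {
  validate_intervals(peaks, "peak")
  if (!"peak_id" %in% names(peaks)) stop("peak table lacks a peak_id column")
  if (anyDuplicated(peaks$peak_id)) stop("peak ids must be unique within a peak set")
  if ("summit" %in% names(peaks) && nrow(peaks) > 0) {
    s <- peaks$summit
    ok <- is.na(s) | (s >= 0 & s < peaks$end - peaks$start)
    if (!all(ok)) stop("summit offsets must lie in [0, peak length)")
  }
  invisible(peaks)
}

# 0-based half-open -> GRanges (1-based closed)
as_granges <- function(df, strand = NULL) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  s <- if (!is.null(strand)) strand else if ("strand" %in% names(df)) df$strand else "*"
  s[is.na(s) | !s %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(as.character(df$chrom),
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = s)
}

points_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(as.character(chrom), IRanges::IRanges(pos + 1L, pos + 1L))
}

#' Representative point of a peak
#'
#' The single base used for peak-to-gene association and location
#' classification: the summit when one was called, otherwise the floor of the
#' interval midpoint.
#'
#' @param peaks peak data frame (see [read_peaks()]).
#' @return integer vector of 0-based positions, one per peak.
#' @export
representative_point <- function(peaks) {
  mid <- floor((peaks$start + peaks$end) / 2)
  if ("summit" %in% names(peaks)) {
    ifelse(is.na(peaks$summit), mid, peaks$start + peaks$summit)
  } else {
    mid
  }
}

# edge-to-edge gap between two half-open intervals on one chromosome;
# overlapping or touching intervals have gap 0
edge_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

# merge a set of intervals on possibly several chromosomes into a
# non-overlapping sorted set (data frame in, data frame out)
merge_intervals <- function(df) {
  validate_intervals(df, "track")
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges(df))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# findOverlaps without the "no sequence levels in common" noise: disjoint
# chromosome sets are a legitimate state (e.g. peaks on chromosomes absent
# from a track)
find_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}
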