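#' Read a peak set from BED / narrowPeak
#'
#' Accepts BED3, BED6 and ENCODE narrowPeak (BED6+4).  Coordinates in the file
#' are 0-based half-open and are kept as such.  For narrowPeak input, column 10
#' (point-source offset) becomes the peak summit when it is non-negative.
#'
#' @param path file path.
#' @param tissue,stage labels attached to every peak (e.g. "meso", "10-13").
#' @return data frame with columns `peak_id, chrom, start, end, strand,
#'   tissue, stage, score, summit` (summit is `NA` when absent).
#' @export
read_peaks <- function(path, tissue = NA_character_, stage = NA_character_) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(empty_peaks(tissue, stage))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    bad <- idx[which(ncols < 3)[1]]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated columns",
                 bad, path))
  }
  nc <- min(ncols)
  get_col <- function(j) vapply(fields, `[[`, character(1), j)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates", bad, path))
  }
  if (any(end <= start)) {
    bad <- idx[which(end <= start)[1]]
    stop(sprintf("invalid interval at line %d in %s: end <= start", bad, path))
  }
  n <- length(start)
  name <- if (nc >= 4) get_col(4) else rep(".", n)
  score <- if (nc >= 5) suppressWarnings(as.numeric(get_col(5))) else rep(0, n)
  score[is.na(score)] <- 0
  if (any(score < 0)) stop("peak scores must be non-negative")
  strand <- if (nc >= 6) get_col(6) else rep("*", n)
  strand[!strand %in% c("+", "-")] <- "*"
  summit <- rep(NA_integer_, n)
  if (nc >= 10) {
    sm <- suppressWarnings(as.integer(get_col(10)))
    summit <- ifelse(!is.na(sm) & sm >= 0, sm, NA_integer_)
  }
  ids <- name
  if (all(ids == ".") || anyDuplicated(ids)) {
    prefix <- if (is.na(tissue)) "peak" else tissue
    ids <- sprintf("%s_%05d", prefix, seq_len(n))
  }
  peaks <- data.frame(peak_id = ids, chrom = get_col(1), start = start, end = end,
                      strand = strand, tissue = tissue, stage = stage,
                      score = score, summit = summit, stringsAsFactors = FALSE)
  validate_peaks(peaks)
}

empty_peaks <- function(tissue = NA_character_, stage = NA_character_) {
  data.frame(peak_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             tissue = character(0), stage = character(0),
             score = numeric(0), summit = integer(0), stringsAsFactors = FALSE)
}

#' Write a peak set to BED / narrowPeak
#'
#' @param peaks peak data frame.
#' @param path output file.
#' @param format `"narrowPeak"` (10 columns, preserves summits) or `"bed6"`.
#' @param name_field column used for the BED name field (default `peak_id`).
#' @return the path, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "bed6"),
                        name_field = "peak_id") {
  format <- match.arg(format)
  validate_peaks(peaks)
  strand <- peaks$strand
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  base <- data.frame(peaks$chrom, peaks$start, peaks$end,
                     peaks[[name_field]], peaks$score, strand)
  if (format == "narrowPeak") {
    summit <- if ("summit" %in% names(peaks)) peaks$summit else NA_integer_
    base <- cbind(base, peaks$score, -1, -1, ifelse(is.na(summit), -1L, summit))
  }
  write.table(base, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a plain interval track as BED3
#'
#' @param track data frame with `chrom`, `start`, `end`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bed3 <- function(track, path) {
  validate_intervals(track, "track")
  write.table(track[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file as a plain interval track
#'
#' Used for histone-mark interval tracks; intervals are merged so the result
#' is non-overlapping.
#'
#' @param path file path.
#' @param merge merge overlapping intervals (default TRUE).
#' @return data frame with `chrom`, `start`, `end`.
#' @export
read_track <- function(path, merge = TRUE) {
  p <- read_peaks(path)
  df <- p[, c("chrom", "start", "end")]
  if (merge) merge_intervals(df) else df
}
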