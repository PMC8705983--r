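# Relative binding-affinity scoring under a position-specific affinity
# matrix (PSAM) and rank-based comparison of affinity distributions.
# The PSAM product model: every column's maximum is 1 (the consensus base),
# a window's relative affinity is the product of its per-position entries,
# so the consensus window scores exactly 1 and any substitution multiplies
# the score by that position's (<= 1) entry.

#' Convert a PWM to a position-specific affinity matrix
#'
#' Each column of the probability matrix is divided by its maximum, giving
#' relative affinities in (0, 1] with column maxima exactly 1.
#'
#' @param pwm a `pwm`.
#' @return object of class `psam`: list with `name`, `matrix` (4 x width),
#'   `width`.
#' @export
psam_from_pwm <- function(pwm) {
  validate_pwm(pwm)
  m <- sweep(pwm$matrix, 2, apply(pwm$matrix, 2, max), "/")
  structure(list(name = pwm$name, matrix = m, width = ncol(m)), class = "psam")
}

#' Read a PSAM from a 4-column TSV
#'
#' One row per motif position, columns A, C, G, T of relative affinities;
#' columns are renormalized so each position's maximum is exactly 1.
#'
#' @param path TSV file (header optional, detected from the first line).
#' @param name motif name.
#' @return a `psam`.
#' @export
read_psam <- function(path, name = "psam") {
  first <- readLines(path, n = 1)
  header <- grepl("[ACGTacgt]", substr(first, 1, 1)) &&
    !grepl("^[0-9.]", trimws(first))
  m <- as.matrix(read.table(path, header = header, sep = "\t"))
  if (ncol(m) != 4) stop("PSAM TSV must have 4 columns (A, C, G, T)")
  m <- t(m)
  rownames(m) <- .bases
  if (any(m <= 0)) stop("PSAM entries must be positive")
  m <- sweep(m, 2, apply(m, 2, max), "/")
  structure(list(name = name, matrix = m, width = ncol(m)), class = "psam")
}

#' Relative affinity of a single window
#'
#' Product over positions of the PSAM entry for the observed base; the
#' consensus window scores exactly 1.  Windows containing N return `NA`
#' (callers skip them).
#'
#' @param window string of length equal to the PSAM width.
#' @param psam a `psam`.
#' @return relative affinity in (0, 1], or NA.
#' @export
window_affinity <- function(window, psam) {
  stopifnot(inherits(psam, "psam"))
  codes <- base_codes(window)
  if (length(codes) != psam$width) {
    stop("window length must equal the PSAM width")
  }
  if (anyNA(codes)) return(NA_real_)
  prod(psam$matrix[cbind(codes, seq_along(codes))])
}

# affinities of all window starts (1-based) of one coded sequence
window_affinities <- function(codes, psam) {
  w <- psam$width
  n <- length(codes) - w + 1L
  if (n < 1) return(numeric(0))
  lg <- log(psam$matrix)
  s <- numeric(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    s <- s + ifelse(is.na(cj), NA_real_, lg[cbind(cj, j)])
  }
  exp(s)
}

#' Relative binding affinity of a sequence
#'
#' Scans both strands.  Mode `"max"` returns the best single window affinity
#' with its offset and strand (the default; one best site per region); mode
#' `"sum"` returns the occupancy-style total over all windows on both
#' strands.
#'
#' @param sequence DNA string (longer than the PSAM width).
#' @param psam a `psam`.
#' @param mode `"max"` or `"sum"`.
#' @return list with `score`, and for mode `"max"` also `offset` (0-based,
#'   forward coordinates) and `strand`.
#' @export
sequence_affinity <- function(sequence, psam, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(psam, "psam"))
  if (nchar(sequence) < psam$width) {
    stop("sequence shorter than the PSAM width")
  }
  fw <- window_affinities(base_codes(sequence), psam)
  rv <- window_affinities(base_codes(revcomp(sequence)), psam)
  if (mode == "sum") {
    return(list(score = sum(fw, na.rm = TRUE) + sum(rv, na.rm = TRUE)))
  }
  L <- nchar(sequence); w <- psam$width
  best <- list(score = 0, offset = NA_integer_, strand = NA_character_)
  if (any(!is.na(fw))) {
    i <- which.max(ifelse(is.na(fw), -Inf, fw))
    best <- list(score = fw[i], offset = i - 1L, strand = "+")
  }
  if (any(!is.na(rv))) {
    j <- which.max(ifelse(is.na(rv), -Inf, rv))
    if (rv[j] > best$score) {
      best <- list(score = rv[j], offset = L - (j - 1L) - w, strand = "-")
    }
  }
  best
}

#' Affinity scores for a set of sequences
#'
#' Vectorized convenience wrapper around [sequence_affinity()].
#'
#' @param sequences named character vector.
#' @param psam a `psam`.
#' @param mode `"max"` or `"sum"`.
#' @param category optional category label column to attach.
#' @return data frame `sequence_id, category, score, offset, strand`.
#' @export
sequence_affinities <- function(sequences, psam, mode = "max",
                                category = NA_character_) {
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  rows <- lapply(seq_along(sequences), function(i) {
    a <- sequence_affinity(sequences[[i]], psam, mode)
    data.frame(sequence_id = names(sequences)[i], category = category,
               score = a$score,
               offset = if (mode == "max") a$offset else NA_integer_,
               strand = if (mode == "max") a$strand else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the combined sample size is below 20 and there are
#' no ties; otherwise the tie-corrected normal approximation (no continuity
#' correction).  Two samples that are identical multisets give p = 1.
#'
#' @param x,y numeric score vectors.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return list with `U` (Mann-Whitney U for `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1) {
    return(list(U = U, p_value = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) < 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Significance stars
#'
#' `"***"` for p < 0.001, `"*"` for p < 0.05, empty otherwise (the display
#' convention of rank-test annotations on affinity box plots).
#'
#' @param p p-value vector.
#' @return character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", ""))
}

#' Compare affinity distributions between peak categories
#'
#' Pairwise Wilcoxon rank-sum tests between all category pairs, with
#' significance stars from the two-sided p-value.
#'
#' @param scores_by_category named list (>= 2 entries) of numeric score
#'   vectors, each with >= 3 scores.
#' @return data frame `group1, group2, n1, n2, U, p_one_sided (group1
#'   greater), p_two_sided, stars`.
#' @export
compare_affinity_distributions <- function(scores_by_category) {
  stopifnot(is.list(scores_by_category), length(scores_by_category) >= 2)
  if (any(lengths(scores_by_category) < 3)) {
    stop("every category needs at least 3 scores")
  }
  prs <- utils::combn(names(scores_by_category), 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    g1 <- prs[1, i]; g2 <- prs[2, i]
    x <- scores_by_category[[g1]]; y <- scores_by_category[[g2]]
    two <- rank_sum_test(x, y, "two.sided")
    one <- rank_sum_test(x, y, "greater")
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               U = two$U, p_one_sided = one$p_value, p_two_sided = two$p_value,
               stars = significance_stars(two$p_value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
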