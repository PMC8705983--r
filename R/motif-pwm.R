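# Position weight matrices: construction, consensus, MEME minimal I/O.

.bases <- c("A", "C", "G", "T")

#' Build a PWM from a count matrix
#'
#' Adds `pseudocount` to every cell and normalizes each column to a
#' probability distribution over A, C, G, T.
#'
#' @param counts numeric matrix of base counts: 4 rows (A, C, G, T) and one
#'   column per motif position.  A positions-by-4 matrix is transposed.
#' @param pseudocount per-cell pseudocount (>= 0, default 0.5).
#' @param background background base probabilities (A, C, G, T).
#' @param name motif name.
#' @return object of class `pwm`: list with `name`, `matrix` (4 x width,
#'   columns sum to 1), `background`, `pseudocount`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.5,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 && ncol(counts) == 4) counts <- t(counts)
  if (nrow(counts) != 4) stop("count matrix must have 4 rows (A, C, G, T)")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("all-zero column in count matrix")
  rownames(counts) <- .bases
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  bg <- setNames(as.numeric(background) / sum(background), .bases)
  structure(list(name = name, matrix = p, background = bg,
                 pseudocount = pseudocount), class = "pwm")
}

validate_pwm <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  m <- pwm$matrix
  if (any(abs(colSums(m) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  if (any(m <= 0)) stop("PWM entries must be positive (use a pseudocount)")
  invisible(pwm)
}

pwm_width <- function(pwm) ncol(pwm$matrix)

# per-position log2 odds against the background
pwm_log_odds <- function(pwm) log2(pwm$matrix / pwm$background)

#' Maximal achievable log-odds score of a PWM (bits)
#' @param pwm a `pwm`.
#' @return numeric scalar.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm_log_odds(pwm), 2, max))

#' IUPAC consensus of a PWM
#'
#' Per column, the IUPAC code covering all bases whose probability is at
#' least half the column maximum.
#'
#' @param pwm a `pwm`.
#' @return consensus string.
#' @export
pwm_consensus <- function(pwm) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  paste(apply(pwm$matrix, 2, function(col) {
    keep <- .bases[col >= 0.5 * max(col)]
    iupac[[paste(keep, collapse = "")]]
  }), collapse = "")
}

# strict consensus: argmax base per column
pwm_top_word <- function(pwm) {
  paste(.bases[apply(pwm$matrix, 2, which.max)], collapse = "")
}

#' Near-deterministic PWM for a fixed word
#'
#' Utility for planting and testing: the given base gets probability `p` in
#' its column, the rest is spread uniformly.
#'
#' @param word DNA string over A, C, G, T.
#' @param p probability of the word base per column.
#' @param name motif name.
#' @param background background probabilities.
#' @return a `pwm`.
#' @export
word_pwm <- function(word, p = 0.94, name = word,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  chars <- strsplit(toupper(word), "")[[1]]
  stopifnot(all(chars %in% .bases))
  counts <- vapply(chars, function(b) ifelse(.bases == b, round(300 * p),
                                             round(100 * (1 - p))), numeric(4))
  # tiny pseudocount keeps every entry positive even at p near 1
  pwm_from_counts(counts, pseudocount = 0.01, background = background, name = name)
}

#' Hox-like position weight matrix
#'
#' A stand-in PWM for the classical Hox/Ubx motif, built around the
#' degenerate core T(A/T)AT(T/G)(A/G) preceded by a T; its strict consensus
#' is TTAATGA.  Real analyses should supply measured motifs via
#' [read_meme()].
#'
#' @param name motif name.
#' @return a `pwm` of width 7.
#' @export
hox_pwm <- function(name = "hox_classical") {
  fixed <- function(b) ifelse(.bases == b, 91, 3)
  degen <- function(major, minor) {
    out <- rep(4, 4); names(out) <- .bases
    out[major] <- 48; out[minor] <- 44
    out
  }
  counts <- cbind(fixed("T"), fixed("T"), degen("A", "T"), fixed("A"),
                  fixed("T"), degen("G", "T"), degen("A", "G"))
  pwm_from_counts(counts, pseudocount = 0.5, name = name)
}

#' Read motifs from MEME minimal format
#'
#' @param path MEME minimal motif file.
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at + 1]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toks[seq(1, 7, by = 2)]
      bg <- vals[.bases]
    }
  }
  motif_at <- grep("^MOTIF", lines)
  if (length(motif_at) == 0) stop("no MOTIF records in ", path)
  out <- list()
  for (i in seq_along(motif_at)) {
    name <- strsplit(trimws(lines[motif_at[i]]), "\\s+")[[1]][2]
    block_end <- if (i < length(motif_at)) motif_at[i + 1] - 1 else length(lines)
    block <- lines[motif_at[i]:block_end]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) != 1) stop("motif ", name, ": missing letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr]))
    rows <- block[(hdr + 1):(hdr + w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x[1:4]), numeric(4)))
    mat <- t(m) # 4 x width
    rownames(mat) <- .bases
    mat <- pmax(mat, 1e-6)
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[name]] <- structure(list(name = name, matrix = mat, background = bg,
                                  pseudocount = 0), class = "pwm")
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms a `pwm` or list of `pwm` objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (pwm in pwms) {
    writeLines(sprintf("MOTIF %s", pwm$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 100 E= 0",
                       pwm_width(pwm)), con)
    writeLines(apply(pwm$matrix, 2, function(col)
      sprintf("%.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])), con)
    writeLines("", con)
  }
  invisible(path)
}
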