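# PWM scanning and background-sequence shuffling.

# integer base codes; anything outside A/C/G/T (e.g. N) becomes NA
base_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], .bases)
}

# log-odds score of every window start (1-based); windows containing N are NA
window_scores <- function(codes, lom) {
  w <- ncol(lom)
  n <- length(codes) - w + 1L
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    s <- s + ifelse(is.na(cj), NA_real_, lom[cbind(cj, j)])
  }
  s
}

#' Scan sequences with a PWM
#'
#' Reports every window on either strand whose log2-odds score (against the
#' PWM background) reaches the threshold.  Reverse-strand hits are reported
#' in forward coordinates.  Windows containing N are skipped.
#'
#' @param sequences named character vector of DNA sequences.
#' @param pwm a `pwm`.
#' @param threshold_bits absolute score threshold in bits; when `NULL`,
#'   `threshold_frac * pwm_max_score(pwm)` is used.
#' @param threshold_frac fraction of the maximal achievable score
#'   (default 0.6).
#' @return data frame `sequence_id, offset, strand, score`; offsets are
#'   0-based starts of the motif window on the forward strand.
#' @export
scan_pwm <- function(sequences, pwm, threshold_bits = NULL, threshold_frac = 0.6) {
  validate_pwm(pwm)
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  if (is.null(threshold_bits)) threshold_bits <- threshold_frac * pwm_max_score(pwm)
  lom <- pwm_log_odds(pwm)
  w <- ncol(lom)
  res <- vector("list", length(sequences))
  rc <- revcomp(sequences)
  for (i in seq_along(sequences)) {
    hits <- list()
    fw <- window_scores(base_codes(sequences[[i]]), lom)
    keep <- which(!is.na(fw) & fw >= threshold_bits)
    if (length(keep) > 0) {
      hits$f <- data.frame(offset = keep - 1L, strand = "+", score = fw[keep])
    }
    rv <- window_scores(base_codes(rc[[i]]), lom)
    keep <- which(!is.na(rv) & rv >= threshold_bits)
    if (length(keep) > 0) {
      L <- nchar(sequences[[i]])
      hits$r <- data.frame(offset = L - (keep - 1L) - w, strand = "-",
                           score = rv[keep])
    }
    if (length(hits) > 0) {
      h <- do.call(rbind, hits)
      res[[i]] <- cbind(sequence_id = names(sequences)[i], h,
                        stringsAsFactors = FALSE)
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    return(data.frame(sequence_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$sequence_id, out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Composition-preserving sequence shuffle
#'
#' Order 1 permutes the bases of each sequence (mononucleotide composition
#' preserved exactly); order 2 performs a dinucleotide-preserving
#' Euler-path shuffle, so all 16 dinucleotide counts are conserved.
#' Deterministic under `seed`.
#'
#' @param sequences character vector of sequences.
#' @param order 1 or 2.
#' @param seed RNG seed.
#' @return shuffled sequences (same names, same lengths).
#' @export
shuffle_background <- function(sequences, order = 2, seed = 1) {
  stopifnot(order %in% c(1, 2))
  set.seed(seed)
  out <- vapply(sequences, function(s) {
    if (order == 2 && nchar(s) < 3) {
      warning("sequence shorter than 3 bp: falling back to order-1 shuffle")
      return(shuffle1(s))
    }
    if (order == 1) shuffle1(s) else shuffle2(s)
  }, character(1))
  names(out) <- names(sequences)
  out
}

shuffle1 <- function(s) {
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

# Euler-path dinucleotide shuffle (Altschul-Erickson).  Vertices are the
# distinct characters; each adjacent pair is a directed edge.  A random set
# of "last edges" forming a tree into the final character is drawn by
# rejection, the remaining out-edges are permuted, and the Euler path is
# walked from the first character.
shuffle2 <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  verts <- unique(chars)
  if (length(verts) == 1) return(s)
  vi <- match(chars, verts)
  from <- vi[-n]; to <- vi[-1]
  last_v <- vi[n]
  edges <- split(to, from) # out-edge target lists per vertex
  present <- as.integer(names(edges))
  # choose last out-edges forming a tree rooted at last_v
  repeat {
    last_edge <- vapply(edges, function(t) t[sample.int(length(t), 1)], integer(1))
    ok <- TRUE
    for (v in present) {
      if (v == last_v) next
      seen <- integer(0); cur <- v
      while (cur != last_v) {
        if (cur %in% seen || !cur %in% present) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[as.character(cur)]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  shuffled <- lapply(names(edges), function(v) {
    t <- edges[[v]]
    if (v %in% names(last_edge) && as.integer(v) != last_v) {
      le <- last_edge[[v]]
      i <- which(t == le)[1]
      rest <- t[-i]
      c(if (length(rest) > 0) rest[sample.int(length(rest))], le)
    } else {
      t[sample.int(length(t))]
    }
  })
  names(shuffled) <- names(edges)
  ptr <- setNames(rep(1L, length(shuffled)), names(shuffled))
  path <- integer(n)
  path[1] <- vi[1]
  cur <- vi[1]
  for (i in 2:n) {
    k <- as.character(cur)
    nxt <- shuffled[[k]][ptr[[k]]]
    ptr[[k]] <- ptr[[k]] + 1L
    path[i] <- nxt
    cur <- nxt
  }
  paste(verts[path], collapse = "")
}
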