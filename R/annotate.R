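# Peak-to-gene association and genomic-location classification.
#
# Location scheme (relative to the TSS, strand-aware; offsets in bp):
#   promoter        [-1000, +10] plus the 5' UTR
#   distal_enhancer [-2000, -1000) plus the 3' UTR plus a 1 kb window
#                   downstream of the gene 3' end
#   intron          inside the gene body but in no exon
#   other           inside an exon and in none of the classes above
#   intergenic      none of the above
# Priority when windows of several genes overlap:
#   promoter > distal_enhancer > intron > other > intergenic.

# window tables (0-based half-open) for one annotation; each row carries the
# index of its gene in ann$genes
gene_windows <- function(ann) {
  g <- ann$genes
  plus <- g$strand == "+"
  win <- function(start, end, gi) {
    keep <- end > pmax(start, 0)
    data.frame(gene = gi[keep], chrom = g$chrom[gi[keep]],
               start = pmax(start, 0)[keep], end = end[keep],
               stringsAsFactors = FALSE)
  }
  gi <- seq_len(nrow(g))
  promoter <- win(ifelse(plus, g$tss - 1000L, g$tss - 10L),
                  ifelse(plus, g$tss + 11L, g$tss + 1001L), gi)
  distal_up <- win(ifelse(plus, g$tss - 2000L, g$tss + 1001L),
                   ifelse(plus, g$tss - 1000L, g$tss + 2001L), gi)
  downstream <- win(ifelse(plus, g$end, g$start - 1000L),
                    ifelse(plus, g$end + 1000L, g$start), gi)
  add_utr <- function(base, utr) {
    if (is.null(utr) || nrow(utr) == 0) return(base)
    m <- match(utr$gene_id, g$gene_id)
    keep <- !is.na(m)
    rbind(base, data.frame(gene = m[keep], chrom = utr$chrom[keep],
                           start = utr$start[keep], end = utr$end[keep],
                           stringsAsFactors = FALSE))
  }
  promoter <- add_utr(promoter, ann$utr5)
  distal <- add_utr(rbind(distal_up, downstream), ann$utr3)
  exons <- data.frame(gene = match(ann$exons$gene_id, g$gene_id),
                      chrom = ann$exons$chrom, start = ann$exons$start,
                      end = ann$exons$end, stringsAsFactors = FALSE)
  body <- data.frame(gene = gi, chrom = g$chrom, start = g$start, end = g$end,
                     stringsAsFactors = FALSE)
  list(promoter = promoter, distal_enhancer = distal, exons = exons, body = body)
}

# all (peak index, gene index, label) pairs where a window of that gene
# contains the peak's representative point
point_gene_labels <- function(chrom, pos, ann) {
  w <- gene_windows(ann)
  pts <- points_granges(chrom, pos)
  hit_pairs <- function(windows) {
    if (nrow(windows) == 0) {
      return(data.frame(peak = integer(0), gene = integer(0)))
    }
    gr <- as_granges(windows)
    ov <- find_overlaps(pts, gr, ignore.strand = TRUE)
    data.frame(peak = S4Vectors::queryHits(ov),
               gene = windows$gene[S4Vectors::subjectHits(ov)])
  }
  prom <- unique(hit_pairs(w$promoter))
  dist <- unique(hit_pairs(w$distal_enhancer))
  exon <- unique(hit_pairs(w$exons))
  body <- unique(hit_pairs(w$body))
  key <- function(d) paste(d$peak, d$gene)
  intron <- body[!key(body) %in% key(exon), , drop = FALSE]
  lab <- function(d, l) if (nrow(d) == 0) d else cbind(d, label = l)
  out <- rbind(lab(prom, "promoter"), lab(dist, "distal_enhancer"),
               lab(intron, "intron"), lab(exon, "other"))
  if (nrow(out) == 0) {
    return(data.frame(peak = integer(0), gene = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  # one label per (peak, gene): keep the highest-priority one
  out$prio <- match(out$label, .priority_levels)
  out <- out[order(out$peak, out$gene, out$prio), ]
  out[!duplicated(out[, c("peak", "gene")]), c("peak", "gene", "label")]
}

#' Classify peaks by genomic location
#'
#' Assigns each peak exactly one location label (promoter, distal_enhancer,
#' intron, other, intergenic) from the position of its representative point
#' (summit if present, otherwise interval midpoint) relative to the gene
#' annotation.  When windows of several genes overlap the highest-priority
#' label wins.
#'
#' @param peaks peak data frame.
#' @param genes a `gene_annotation`.
#' @return character vector of labels, one per peak.
#' @export
classify_location <- function(peaks, genes) {
  validate_peaks(peaks)
  n <- nrow(peaks)
  if (n == 0) return(character(0))
  if (nrow(genes$genes) == 0) return(rep("intergenic", n))
  off_chrom <- !peaks$chrom %in% genes$genes$chrom
  if (any(off_chrom)) {
    warning(sprintf("%d peak(s) on chromosomes absent from the annotation; labelled intergenic",
                    sum(off_chrom)))
  }
  pos <- representative_point(peaks)
  pairs <- point_gene_labels(peaks$chrom, pos, genes)
  labels <- rep("intergenic", n)
  if (nrow(pairs) > 0) {
    pairs$prio <- match(pairs$label, .priority_levels)
    best <- tapply(pairs$prio, pairs$peak, min)
    labels[as.integer(names(best))] <- .priority_levels[best]
  }
  labels
}

#' Associate peaks with genes
#'
#' A peak is assigned to every gene whose flank-extended body (strand-aware:
#' `flank_up` bp upstream of the TSS, `flank_down` bp downstream of the gene
#' 3' end) contains its representative point.  A peak contained in no
#' extended body is assigned to the nearest TSS within `max_tss_distance` bp;
#' beyond that it stays unassigned (`gene_id` = NA).  Each assignment carries
#' the signed distance to that gene's TSS (negative = upstream, strand-aware)
#' and the location label relative to that gene.
#'
#' @param peaks peak data frame.
#' @param genes a `gene_annotation`.
#' @param flank_up,flank_down extension of the gene body (bp) upstream of the
#'   TSS and downstream of the 3' end.  Defaults 2000 / 1000.
#' @param max_tss_distance maximal distance for the nearest-TSS fallback.
#' @return data frame `peak_id, gene_id, distance_to_tss, location`; peaks
#'   assigned to several genes occupy several rows.
#' @export
assign_peaks_to_genes <- function(peaks, genes, flank_up = 2000,
                                  flank_down = 1000, max_tss_distance = 10000) {
  validate_peaks(peaks)
  g <- genes$genes
  if (nrow(peaks) == 0 || nrow(g) == 0) {
    return(data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                      distance_to_tss = NA_integer_,
                      location = rep("intergenic", nrow(peaks)),
                      stringsAsFactors = FALSE))
  }
  pos <- representative_point(peaks)
  plus <- g$strand == "+"
  ext <- data.frame(gene = seq_len(nrow(g)), chrom = g$chrom,
                    start = pmax(0, ifelse(plus, g$start - flank_up,
                                           g$start - flank_down)),
                    end = ifelse(plus, g$end + flank_down, g$end + flank_up),
                    stringsAsFactors = FALSE)
  pts <- points_granges(peaks$chrom, pos)
  ov <- find_overlaps(pts, as_granges(ext), ignore.strand = TRUE)
  contained <- data.frame(peak = S4Vectors::queryHits(ov),
                          gene = ext$gene[S4Vectors::subjectHits(ov)])
  labels <- point_gene_labels(peaks$chrom, pos, genes)
  lkey <- paste(labels$peak, labels$gene)
  rows <- list()
  if (nrow(contained) > 0) {
    m <- match(paste(contained$peak, contained$gene), lkey)
    loc <- ifelse(is.na(m), "intergenic", labels$label[m])
    rows$contained <- data.frame(peak = contained$peak, gene = contained$gene,
                                 location = loc, stringsAsFactors = FALSE)
  }
  orphan <- setdiff(seq_len(nrow(peaks)), unique(contained$peak))
  if (length(orphan) > 0) {
    near <- nearest_tss(peaks$chrom[orphan], pos[orphan], g, max_tss_distance)
    ok <- !is.na(near)
    if (any(ok)) {
      rows$nearest <- data.frame(peak = orphan[ok], gene = near[ok],
                                 location = "intergenic", stringsAsFactors = FALSE)
    }
    if (any(!ok)) {
      rows$unassigned <- data.frame(peak = orphan[!ok], gene = NA_integer_,
                                    location = "intergenic", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$peak, res$gene), ]
  d <- ifelse(is.na(res$gene), NA_integer_, {
    tss <- g$tss[res$gene]
    ifelse(g$strand[res$gene] == "+", pos[res$peak] - tss, tss - pos[res$peak])
  })
  out <- data.frame(peak_id = peaks$peak_id[res$peak],
                    gene_id = ifelse(is.na(res$gene), NA_character_,
                                     g$gene_id[res$gene]),
                    distance_to_tss = as.integer(d),
                    location = res$location, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# index of the gene with the nearest TSS (|pos - tss| minimal, <= max_dist)
# on the same chromosome; ties broken by lexicographic gene_id; NA if none
nearest_tss <- function(chrom, pos, g, max_dist) {
  ord <- order(g$gene_id)
  vapply(seq_along(pos), function(i) {
    cand <- ord[g$chrom[ord] == chrom[i]]
    if (length(cand) == 0) return(NA_integer_)
    d <- abs(pos[i] - g$tss[cand])
    j <- which.min(d) # first of ties = smallest gene_id, cand is id-sorted
    if (d[j] <= max_dist) cand[j] else NA_integer_
  }, integer(1))
}
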