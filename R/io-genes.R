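#' Read gene models from a GTF annotation
#'
#' Parses `gene` and `exon` features (plus `five_prime_utr` /
#' `three_prime_utr` when present) into one gene model per `gene_id`.
#' GTF coordinates are 1-based inclusive and are converted to the package's
#' 0-based half-open convention.  The TSS is the body start on the + strand
#' and body end − 1 on the − strand.
#'
#' Genes without exon records are kept with the gene body as a single exon
#' (with a warning).  Genes on an unknown strand are rejected.  Exons are
#' sorted and overlapping exons merged, so the stored exon set is always a
#' sorted non-overlapping partition within the gene body.
#'
#' @param path GTF file.
#' @return an object of class `gene_annotation`: a list with data frames
#'   `genes` (`gene_id, chrom, start, end, strand, tss, tes`), `exons`,
#'   `utr5`, `utr3`.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% names(S4Vectors::mcols(gr))) {
    stop("GTF lacks gene_id attributes")
  }
  type <- as.character(gr$type)
  df <- data.frame(gene_id = as.character(gr$gene_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = type, stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", ]
  exons <- df[df$type == "exon", ]
  if (nrow(genes) == 0) {
    # derive bodies from exon extents when the annotation has no gene rows
    if (nrow(exons) == 0) stop("GTF contains neither gene nor exon features")
    sp <- split(exons, exons$gene_id)
    genes <- do.call(rbind, lapply(sp, function(e) {
      data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
                 start = min(e$start), end = max(e$end),
                 strand = e$strand[1], type = "gene", stringsAsFactors = FALSE)
    }))
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!genes$strand %in% c("+", "-")]
    stop(sprintf("gene(s) with unknown strand rejected: %s",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation; one model per gene is required")
  }
  no_exons <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exons) > 0) {
    warning(sprintf("%d gene(s) without exon records; gene body used as a single exon",
                    length(no_exons)))
    extra <- genes[genes$gene_id %in% no_exons, ]
    extra$type <- "exon"
    exons <- rbind(exons, extra)
  }
  exons <- normalize_exons(exons, genes)
  utr5 <- df[df$type %in% c("five_prime_utr", "5UTR"), setdiff(names(df), "type")]
  utr3 <- df[df$type %in% c("three_prime_utr", "3UTR"), setdiff(names(df), "type")]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  genes$type <- NULL
  rownames(genes) <- NULL
  ann <- list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3)
  class(ann) <- "gene_annotation"
  validate_annotation(ann)
}

normalize_exons <- function(exons, genes) {
  e <- exons[order(exons$gene_id, exons$start), c("gene_id", "chrom", "start", "end")]
  if (nrow(e) == 0) { rownames(e) <- NULL; return(e) }
  # merge overlapping/touching exons within each gene in one linear pass
  keep <- logical(nrow(e))
  out_end <- integer(nrow(e))
  last <- 0L
  for (i in seq_len(nrow(e))) {
    if (last > 0 && e$gene_id[i] == e$gene_id[last] &&
        e$start[i] <= out_end[last]) {
      out_end[last] <- max(out_end[last], e$end[i])
    } else {
      keep[i] <- TRUE
      out_end[i] <- e$end[i]
      last <- i
    }
  }
  e$end <- out_end
  e <- e[keep, ]
  rownames(e) <- NULL
  e
}

validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  validate_intervals(ann$genes, "gene body")
  validate_intervals(ann$exons, "exon")
  g <- ann$genes
  tss_ok <- ifelse(g$strand == "+", g$tss == g$start, g$tss == g$end - 1L)
  if (!all(tss_ok)) stop("TSS inconsistent with strand convention")
  m <- match(ann$exons$gene_id, g$gene_id)
  if (anyNA(m)) stop("exon with unknown gene_id")
  within <- ann$exons$start >= g$start[m] & ann$exons$end <= g$end[m]
  if (!all(within)) stop("exon outside its gene body")
  ann
}

#' Construct a gene annotation from data frames
#'
#' Programmatic counterpart of [read_genes()] for annotations built in code
#' (e.g. by the synthetic-data generator).
#'
#' @param genes data frame with `gene_id, chrom, start, end, strand`
#'   (0-based half-open); `tss`/`tes` are derived if absent.
#' @param exons data frame with `gene_id, chrom, start, end`; defaults to the
#'   gene bodies.
#' @param utr5,utr3 optional UTR interval data frames.
#' @return a `gene_annotation` object.
#' @export
gene_annotation <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!"tss" %in% names(genes)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  }
  if (!"tes" %in% names(genes)) {
    genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  }
  if (is.null(exons)) {
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
  }
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  ann <- list(genes = genes,
              exons = normalize_exons(exons, genes),
              utr5 = if (is.null(utr5)) empty else utr5,
              utr3 = if (is.null(utr3)) empty else utr3)
  class(ann) <- "gene_annotation"
  validate_annotation(ann)
}

#' Write a gene annotation as GTF
#'
#' Emits `gene` and `exon` rows with 1-based inclusive coordinates.
#'
#' @param ann `gene_annotation` object.
#' @param path output file.
#' @param source source field for column 2.
#' @return the path, invisibly.
#' @export
write_gtf <- function(ann, path, source = "crossbind") {
  stopifnot(inherits(ann, "gene_annotation"))
  g <- ann$genes
  gene_lines <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                        g$chrom, source, g$start + 1L, g$end, g$strand, g$gene_id)
  e <- ann$exons
  st <- g$strand[match(e$gene_id, g$gene_id)]
  exon_lines <- sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                        e$chrom, source, e$start + 1L, e$end, st, e$gene_id)
  writeLines(c(gene_lines, exon_lines), path)
  invisible(path)
}
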