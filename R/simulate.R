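# Synthetic-data generator: toy genome, two tissue peak sets with controlled
# gene-category / binding-frequency / shared-peak structure, embedded motif
# instances, histone-mark tracks realizing the four cross-tissue classes, and
# a truth manifest recording every planted feature.
#
# Geometry guarantees (so downstream recovery is exact up to sampling noise):
#  - flank-extended gene bodies never overlap (intergenic gaps > flank sum),
#    so every peak is assigned to exactly the gene it was planted in;
#  - non-paired cross-tissue enhancer peaks are separated by more than the
#    2 kb pairing gap, while planted shared pairs sit closer than 2 kb.

#' Simulation configuration
#'
#' Default proportions mirror the tissue-comparative study design the
#' generator emulates: 35/29/36 percent common / A-specific / B-specific
#' bound genes, 90 percent of common genes bound multiply (2-5 peaks),
#' about 75 percent of common-gene enhancer peaks tissue-specific (shared
#' fraction 0.25), motif planting at rate 0.7 (classical motif in B-only and
#' shared peaks, a divergent AT-rich variant in A-only peaks), and an AT-rich
#' (0.3/0.2/0.2/0.3) background that stresses AT-rich motif discovery.
#'
#' @param seed RNG seed; every simulate_* stage derives its stream from it.
#' @param n_genes number of genes (all bound in at least one tissue).
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length fixed length per chromosome, or NULL to auto-size
#'   to the placed genes.
#' @param exon_count_range,exon_length_range,intron_length_range gene
#'   structure ranges (bp).
#' @param intergenic_gap_range gap between consecutive extended gene
#'   territories (bp); must exceed flank_up + flank_down of the association
#'   step for unambiguous assignment.
#' @param gene_category_props proportions (sum 1) of common / A_specific /
#'   B_specific genes.
#' @param tissue_labels named character vector `c(A = ..., B = ...)`.
#' @param stage stage label attached to peaks.
#' @param singlepeak_common probability that a common gene is a singlePeak
#'   gene (one promoter peak per tissue) rather than multiPeak.
#' @param singlepeak_specific same for tissue-specific genes.
#' @param multipeak_range peak count range per gene and tissue for multiPeak
#'   genes.
#' @param shared_fraction target fraction of common-gene enhancer peaks that
#'   are members of a cross-tissue shared (< 2 kb) pair.
#' @param distal_fraction probability that one enhancer peak of a
#'   tissue-specific multiPeak gene is placed in the distal-enhancer window
#'   instead of an intron.
#' @param peak_width_range peak widths (bp).
#' @param pair_gap_range edge-to-edge gap of planted shared pairs (bp,
#'   < 2000).
#' @param min_peak_separation minimal edge gap between non-paired enhancer
#'   peaks (bp, > 2000).
#' @param background_freqs background base composition (A, C, G, T).
#' @param motifs named list of `pwm` objects available for planting.
#' @param embed_plan data frame `motif, category, rate`: per subdivision
#'   category, the fraction of peaks receiving a planted motif instance.
#' @param mark_class_props named list (per tissue key "A"/"B") of proportions
#'   over the four cross-tissue mark classes for that tissue's specific
#'   peaks.
#' @param mark_threshold coverage threshold used downstream.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              n_chromosomes = 4L,
                              chromosome_length = NULL,
                              exon_count_range = c(3L, 4L),
                              exon_length_range = c(150L, 300L),
                              intron_length_range = c(5400L, 8000L),
                              intergenic_gap_range = c(4200L, 5800L),
                              gene_category_props = c(common = 0.35,
                                                      A_specific = 0.29,
                                                      B_specific = 0.36),
                              tissue_labels = c(A = "meso", B = "neuro"),
                              stage = "10-13",
                              singlepeak_common = 0.10,
                              singlepeak_specific = 0.375,
                              multipeak_range = c(2L, 5L),
                              shared_fraction = 0.25,
                              distal_fraction = 0.15,
                              peak_width_range = c(200L, 600L),
                              pair_gap_range = c(0L, 1200L),
                              min_peak_separation = 2100L,
                              background_freqs = c(A = 0.3, C = 0.2,
                                                   G = 0.2, T = 0.3),
                              motifs = NULL,
                              embed_plan = NULL,
                              mark_class_props = NULL,
                              mark_threshold = 0.25) {
  if (is.null(motifs)) {
    motifs <- list(classical = hox_pwm(),
                   divergent = word_pwm("TAAATAA", name = "divergent"))
  }
  if (is.null(embed_plan)) {
    embed_plan <- data.frame(
      motif = c("classical", "classical", "divergent"),
      category = c("B_only", "shared_2kb", "A_only"),
      rate = 0.7, stringsAsFactors = FALSE)
  }
  if (is.null(mark_class_props)) {
    mark_class_props <- list(
      A = c(active_shared = 0.45, repressed_focal_only = 0.45,
            active_focal_only = 0.05, repressed_shared = 0.05),
      B = c(active_focal_only = 0.45, repressed_shared = 0.45,
            active_shared = 0.05, repressed_focal_only = 0.05))
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              exon_count_range = exon_count_range,
              exon_length_range = exon_length_range,
              intron_length_range = intron_length_range,
              intergenic_gap_range = intergenic_gap_range,
              gene_category_props = gene_category_props,
              tissue_labels = tissue_labels, stage = stage,
              singlepeak_common = singlepeak_common,
              singlepeak_specific = singlepeak_specific,
              multipeak_range = multipeak_range,
              shared_fraction = shared_fraction,
              distal_fraction = distal_fraction,
              peak_width_range = peak_width_range,
              pair_gap_range = pair_gap_range,
              min_peak_separation = min_peak_separation,
              background_freqs = background_freqs,
              motifs = motifs, embed_plan = embed_plan,
              mark_class_props = mark_class_props,
              mark_threshold = mark_threshold)
  class(cfg) <- "simulation_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  props <- cfg$gene_category_props
  if (abs(sum(props) - 1) > 1e-9 || any(props < 0)) {
    stop("gene_category_props must be non-negative and sum to 1")
  }
  for (p in cfg$mark_class_props) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("each mark_class_props entry must be non-negative and sum to 1")
    }
  }
  rates <- c(cfg$singlepeak_common, cfg$singlepeak_specific,
             cfg$shared_fraction, cfg$distal_fraction, cfg$embed_plan$rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  ranges <- list(cfg$exon_count_range, cfg$exon_length_range,
                 cfg$intron_length_range, cfg$intergenic_gap_range,
                 cfg$multipeak_range, cfg$peak_width_range, cfg$pair_gap_range)
  if (any(vapply(ranges, function(r) length(r) != 2 || r[2] < r[1], logical(1)))) {
    stop("all ranges must be length-2 with max >= min")
  }
  if (max(cfg$pair_gap_range) >= 2000) stop("pair gaps must stay below 2 kb")
  if (cfg$min_peak_separation <= 2000) {
    stop("min_peak_separation must exceed the 2 kb pairing gap")
  }
  if (cfg$intergenic_gap_range[1] <= 4000) {
    # flank-extended bodies of adjacent (-,+) gene pairs span up to
    # 2 x flank_up = 4 kb of the gap; overlap would break unambiguous
    # peak-to-gene assignment
    stop("intergenic gaps must exceed 4 kb so extended gene bodies never overlap")
  }
  if (!setequal(names(cfg$tissue_labels), c("A", "B"))) {
    stop("tissue_labels must be named A and B")
  }
  cfg
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else sample(range[1]:range[2], n, TRUE)
}

random_dna <- function(n, freqs) {
  idx <- sample.int(4, n, replace = TRUE, prob = freqs)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[idx])
}

#' Simulate a toy genome with gene models
#'
#' Places non-overlapping multi-exon genes on both strands across the
#' configured chromosomes and draws the background sequence from the
#' configured base composition.  Deterministic under the config seed.
#'
#' @param config a `simulation_config`.
#' @return list of class `sim_genome` with `sequences` (DNAStringSet),
#'   `annotation` (`gene_annotation`), `chrom_lengths`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  m_exons <- runif_int(n, config$exon_count_range)
  structures <- lapply(seq_len(n), function(i) {
    m <- m_exons[i]
    ex <- runif_int(m, config$exon_length_range)
    intr <- runif_int(m - 1, config$intron_length_range)
    list(exons = ex, introns = intr, length = sum(ex) + sum(intr))
  })
  strand <- sample(c("+", "-"), n, TRUE)
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), n))
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  gene_rows <- vector("list", n)
  exon_rows <- vector("list", n)
  chrom_len <- setNames(integer(config$n_chromosomes), chrom_names)
  gi <- 0
  for (ci in seq_len(config$n_chromosomes)) {
    cursor <- runif_int(1, config$intergenic_gap_range)
    for (i in which(chrom_of == ci)) {
      gi <- gi + 1
      st <- structures[[i]]
      gstart <- cursor
      gend <- gstart + st$length
      gid <- sprintf("g%04d", gi)
      gene_rows[[gi]] <- data.frame(gene_id = gid, chrom = chrom_names[ci],
                                    start = gstart, end = gend,
                                    strand = strand[i], stringsAsFactors = FALSE)
      pos <- gstart
      ex <- vector("list", length(st$exons))
      for (k in seq_along(st$exons)) {
        ex[[k]] <- data.frame(gene_id = gid, chrom = chrom_names[ci],
                              start = pos, end = pos + st$exons[k],
                              stringsAsFactors = FALSE)
        pos <- pos + st$exons[k]
        if (k < length(st$exons)) pos <- pos + st$introns[k]
      }
      exon_rows[[gi]] <- do.call(rbind, ex)
      cursor <- gend + runif_int(1, config$intergenic_gap_range)
    }
    chrom_len[ci] <- cursor + 2000L
  }
  if (!is.null(config$chromosome_length)) {
    if (any(chrom_len > config$chromosome_length)) {
      stop("genes cannot be placed without overlap; increase chromosome_length")
    }
    chrom_len[] <- config$chromosome_length
  }
  ann <- gene_annotation(do.call(rbind, gene_rows), do.call(rbind, exon_rows))
  seqs <- Biostrings::DNAStringSet(vapply(chrom_len, random_dna,
                                          character(1), freqs = config$background_freqs))
  names(seqs) <- chrom_names
  structure(list(sequences = seqs, annotation = ann, chrom_lengths = chrom_len),
            class = "sim_genome")
}

# introns of one gene as a start/end matrix (possibly 0 rows)
gene_introns <- function(exons_of_gene) {
  e <- exons_of_gene[order(exons_of_gene$start), ]
  if (nrow(e) < 2) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = e$end[-nrow(e)], end = e$start[-1])
}

#' Simulate two tissue peak sets with known structure
#'
#' Draws each gene into a category (common / A_specific / B_specific), a
#' binding-frequency class (singlePeak genes get one promoter peak per bound
#' tissue; multiPeak genes get 2-5 enhancer peaks), and plants the configured
#' fraction of common-gene enhancer peaks as cross-tissue shared pairs with
#' an edge gap below 2 kb.  Non-paired cross-tissue peaks are kept more than
#' 2 kb apart.  Units that do not fit the gene's introns are dropped (count
#' reported in the manifest).
#'
#' @param config a `simulation_config`.
#' @param genome a `sim_genome`.
#' @return list with `peaks_a`, `peaks_b` (peak data frames) and `manifest`
#'   (list: `genes`, `peaks`, `dropped_units`, `seed`).
#' @export
simulate_peaks <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"), inherits(genome, "sim_genome"))
  set.seed(config$seed + 1L)
  g <- genome$annotation$genes
  exons_by_gene <- split(genome$annotation$exons, genome$annotation$exons$gene_id)
  cats <- names(config$gene_category_props)
  category <- sample(cats, nrow(g), TRUE, config$gene_category_props)
  counters <- c(A = 0L, B = 0L)
  peak_rows <- list(); manifest_rows <- list()
  dropped <- 0L
  new_peak <- function(tk, gene, chrom, start, end, summit, location, subdivision) {
    counters[tk] <<- counters[tk] + 1L
    id <- sprintf("%s_%06d", config$tissue_labels[[tk]], counters[[tk]])
    peak_rows[[length(peak_rows) + 1]] <<- data.frame(
      peak_id = id, chrom = chrom, start = start, end = end, strand = "*",
      tissue = config$tissue_labels[[tk]], stage = config$stage,
      score = round(runif(1, 30, 1000)), summit = summit,
      tissue_key = tk, stringsAsFactors = FALSE)
    manifest_rows[[length(manifest_rows) + 1]] <<- data.frame(
      peak_id = id, tissue_key = tk, tissue = config$tissue_labels[[tk]],
      gene_id = gene, location_class = location, subdivision = subdivision,
      partner_peak_id = NA_character_, motif = NA_character_,
      motif_offset = NA_integer_, motif_strand = NA_character_,
      mark_class = NA_character_, stringsAsFactors = FALSE)
    id
  }
  point_peak <- function(tk, gene_row, offset_range, location, subdivision) {
    d <- runif_int(1, offset_range)
    pos <- if (gene_row$strand == "+") gene_row$tss + d else gene_row$tss - d
    w <- runif_int(1, config$peak_width_range)
    start <- max(0L, pos - w %/% 2L)
    new_peak(tk, gene_row$gene_id, gene_row$chrom, start, start + w,
             pos - start, location, subdivision)
  }
  n_genes_a <- integer(nrow(g)); n_genes_b <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    grow <- g[i, ]
    grow$tss <- g$tss[i]
    cat_i <- category[i]
    bound <- switch(cat_i, common = c("A", "B"),
                    A_specific = "A", B_specific = "B")
    single <- runif(1) < if (cat_i == "common") config$singlepeak_common else
      config$singlepeak_specific
    if (single) {
      for (tk in bound) point_peak(tk, grow, c(-800L, 0L), "promoter", NA_character_)
      n_cnt <- setNames(as.integer(c("A" %in% bound, "B" %in% bound)), c("A", "B"))
    } else {
      n_per <- setNames(rep(0L, 2), c("A", "B"))
      for (tk in bound) n_per[tk] <- runif_int(1, config$multipeak_range)
      s <- 0L
      if (length(bound) == 2) {
        x <- config$shared_fraction * sum(n_per) / 2
        s <- min(floor(x) + rbinom(1, 1, x - floor(x)), n_per["A"], n_per["B"])
      }
      subdiv <- if (cat_i == "common") c(A = "A_only", B = "B_only") else
        c(A = NA_character_, B = NA_character_)
      units <- c(rep(list(c("A", "B")), s),
                 rep(list("A"), n_per["A"] - s), rep(list("B"), n_per["B"] - s))
      if (length(units) > 1) units <- units[sample.int(length(units))]
      # optionally one distal-enhancer peak for tissue-specific genes
      distal_done <- cat_i == "common" || runif(1) >= config$distal_fraction
      introns <- gene_introns(exons_by_gene[[grow$gene_id]])
      cursor <- if (nrow(introns) > 0) introns[1, "start"] + 150L else NA
      intron_idx <- 1L
      placed <- setNames(c(0L, 0L), c("A", "B"))
      for (u in units) {
        if (!distal_done && length(u) == 1) {
          point_peak(u, grow, c(-1800L, -1200L), "distal_enhancer", subdiv[[u]])
          placed[u] <- placed[u] + 1L
          distal_done <- TRUE
          next
        }
        w <- runif_int(length(u), config$peak_width_range)
        gapAB <- if (length(u) == 2) runif_int(1, config$pair_gap_range) else 0L
        content <- sum(w) + gapAB
        ok <- FALSE
        while (intron_idx <= nrow(introns)) {
          ps <- max(cursor, introns[intron_idx, "start"] + 150L)
          if (ps + content <= introns[intron_idx, "end"] - 150L) {
            ok <- TRUE
            break
          }
          intron_idx <- intron_idx + 1L
        }
        if (!ok) { dropped <- dropped + 1L; next }
        if (length(u) == 1) {
          new_peak(u, grow$gene_id, grow$chrom, ps, ps + w, w %/% 2L,
                   "intron", subdiv[[u]])
          placed[u] <- placed[u] + 1L
        } else {
          ord <- sample(u) # which tissue sits left
          id1 <- new_peak(ord[1], grow$gene_id, grow$chrom, ps, ps + w[1],
                          w[1] %/% 2L, "intron", "shared_2kb")
          id2 <- new_peak(ord[2], grow$gene_id, grow$chrom, ps + w[1] + gapAB,
                          ps + w[1] + gapAB + w[2], w[2] %/% 2L, "intron",
                          "shared_2kb")
          k <- length(manifest_rows)
          manifest_rows[[k - 1]]$partner_peak_id <- id2
          manifest_rows[[k]]$partner_peak_id <- id1
          placed <- placed + 1L
        }
        cursor <- ps + content + config$min_peak_separation
      }
      # a bound tissue must keep at least one peak even if its enhancer
      # units were dropped for lack of intron space
      for (tk in bound) {
        if (placed[tk] == 0L) {
          point_peak(tk, grow, c(-800L, 0L), "promoter", NA_character_)
          placed[tk] <- 1L
        }
      }
      n_cnt <- placed
    }
    n_genes_a[i] <- n_cnt["A"]; n_genes_b[i] <- n_cnt["B"]
  }
  peaks <- do.call(rbind, peak_rows)
  manifest_peaks <- do.call(rbind, manifest_rows)
  genes_tab <- data.frame(gene_id = g$gene_id, category = category,
                          n_peaks_A = n_genes_a, n_peaks_B = n_genes_b,
                          stringsAsFactors = FALSE)
  split_cols <- c("peak_id", "chrom", "start", "end", "strand", "tissue",
                  "stage", "score", "summit")
  list(peaks_a = peaks[peaks$tissue_key == "A", split_cols],
       peaks_b = peaks[peaks$tissue_key == "B", split_cols],
       manifest = list(genes = genes_tab, peaks = manifest_peaks,
                       dropped_units = dropped, seed = config$seed))
}

# draw one word from a PWM, column by column
sample_pwm_word <- function(pwm) {
  paste(apply(pwm$matrix, 2, function(col) sample(.bases, 1, prob = col)),
        collapse = "")
}

#' Plant motif instances into peak sequences
#'
#' For each peak whose subdivision category appears in the embed plan, with
#' the configured rate, a word sampled from the motif's PWM is written at a
#' uniform offset on a random strand inside the peak; the manifest records
#' the exact plant.  Colliding plants are re-drawn (error after 100 tries).
#'
#' @param sequences genome `DNAStringSet`.
#' @param peaks combined peak data frame (both tissues).
#' @param manifest manifest list from [simulate_peaks()].
#' @param config a `simulation_config`.
#' @return list with modified `sequences` and updated `manifest`.
#' @export
embed_motifs <- function(sequences, peaks, manifest, config) {
  set.seed(config$seed + 2L)
  mp <- manifest$peaks
  plants <- list()
  for (r in seq_len(nrow(config$embed_plan))) {
    plan <- config$embed_plan[r, ]
    pwm <- config$motifs[[plan$motif]]
    if (is.null(pwm)) stop("embed plan references unknown motif: ", plan$motif)
    wm <- pwm_width(pwm)
    idx <- which(!is.na(mp$subdivision) & mp$subdivision == plan$category)
    idx <- idx[runif(length(idx)) < plan$rate]
    if (length(idx) == 0) next
    m <- match(mp$peak_id[idx], peaks$peak_id)
    len <- peaks$end[m] - peaks$start[m]
    if (any(len <= wm)) stop("motif wider than peak")
    words <- vapply(idx, function(j) sample_pwm_word(pwm), character(1))
    offsets <- vapply(len - wm, function(u) runif_int(1, c(0L, u)), integer(1))
    strands <- sample(c("+", "-"), length(idx), TRUE)
    neg <- strands == "-"
    if (any(neg)) words[neg] <- revcomp(words[neg])
    plants[[length(plants) + 1]] <- data.frame(
      row = idx, chrom = peaks$chrom[m], start = peaks$start[m] + offsets,
      width = wm, word = words, motif = plan$motif, offset = offsets,
      strand = strands, stringsAsFactors = FALSE)
  }
  if (length(plants) > 0) {
    pl <- do.call(rbind, plants)
    for (chrom in unique(pl$chrom)) {
      sel <- pl[pl$chrom == chrom, ]
      at <- IRanges::IRanges(sel$start + 1L, width = sel$width)
      if (length(IRanges::reduce(at)) < length(at)) {
        stop("colliding motif plants within one peak region")
      }
      sequences[[chrom]] <- Biostrings::replaceAt(sequences[[chrom]], at,
                                                  Biostrings::DNAStringSet(sel$word))
    }
    mp$motif[pl$row] <- pl$motif
    mp$motif_offset[pl$row] <- pl$offset
    mp$motif_strand[pl$row] <- pl$strand
  }
  manifest$peaks <- mp
  list(sequences = sequences, manifest = manifest)
}

#' Simulate histone-mark tracks realizing the cross-tissue classes
#'
#' Each tissue-specific (A_only / B_only) peak is assigned a cross-tissue
#' mark class per the configured proportions, and mark intervals covering the
#' peak (coverage 1.0) are emitted to the corresponding (mark, tissue)
#' tracks; no bivalent plants are produced.
#'
#' @param config a `simulation_config`.
#' @param peaks combined peak data frame.
#' @param manifest manifest list.
#' @return list with `tracks` (nested list `tracks[[tissue]][[mark]]`) and
#'   updated `manifest`.
#' @export
simulate_marks <- function(config, peaks, manifest) {
  set.seed(config$seed + 3L)
  mp <- manifest$peaks
  tl <- config$tissue_labels
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  tracks <- setNames(lapply(tl, function(x) list(H3K27ac = empty, H3K27me3 = empty)),
                     unname(tl))
  spec <- which(!is.na(mp$subdivision) & mp$subdivision %in% c("A_only", "B_only"))
  if (length(spec) > 0) {
    key <- substr(mp$subdivision[spec], 1, 1)
    cls <- vapply(key, function(k) {
      p <- config$mark_class_props[[k]]
      sample(names(p), 1, prob = p)
    }, character(1))
    mp$mark_class[spec] <- cls
    m <- match(mp$peak_id[spec], peaks$peak_id)
    iv <- data.frame(chrom = peaks$chrom[m], start = peaks$start[m],
                     end = peaks$end[m], stringsAsFactors = FALSE)
    for (tk in c("A", "B")) {
      focal <- key == tk
      ac <- (focal & cls %in% c("active_shared", "active_focal_only")) |
        (!focal & cls == "active_shared")
      me3 <- (focal & cls %in% c("repressed_shared", "repressed_focal_only")) |
        (!focal & cls == "repressed_shared")
      tissue <- tl[[tk]]
      if (any(ac)) tracks[[tissue]]$H3K27ac <- merge_intervals(iv[ac, ])
      if (any(me3)) tracks[[tissue]]$H3K27me3 <- merge_intervals(iv[me3, ])
    }
  }
  manifest$peaks <- mp
  list(tracks = tracks, manifest = manifest)
}

#' Run the full generator in memory
#'
#' Composes [simulate_genome()], [simulate_peaks()], [embed_motifs()] and
#' [simulate_marks()] into one deterministic dataset.
#'
#' @param config a `simulation_config`.
#' @return list with `sequences`, `annotation`, `chrom_lengths`, `peaks_a`,
#'   `peaks_b`, `tracks`, `manifest`, `config`.
#' @export
simulate_dataset <- function(config) {
  genome <- simulate_genome(config)
  pk <- simulate_peaks(config, genome)
  all_peaks <- rbind(pk$peaks_a, pk$peaks_b)
  emb <- embed_motifs(genome$sequences, all_peaks, pk$manifest, config)
  mk <- simulate_marks(config, all_peaks, emb$manifest)
  list(sequences = emb$sequences, annotation = genome$annotation,
       chrom_lengths = genome$chrom_lengths,
       peaks_a = pk$peaks_a, peaks_b = pk$peaks_b,
       tracks = mk$tracks, manifest = mk$manifest, config = config)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits FASTA, GTF, per-tissue narrowPeak, per-(mark, tissue) BED, the motif
#' set in MEME minimal format, the truth manifest as JSON and the
#' configuration as YAML, and returns a run configuration pointing at the
#' files, ready for [run_full_analysis()].
#'
#' @param config a `simulation_config`.
#' @param dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return run-config list (invisibly also written as `run_config.yaml`).
#' @export
make_fixture <- function(config, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("output directory is not empty (use overwrite = TRUE)")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(config)
  tl <- config$tissue_labels
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "genes.gtf"),
                peaks_a = file.path(dir, sprintf("peaks_%s.narrowPeak", tl[["A"]])),
                peaks_b = file.path(dir, sprintf("peaks_%s.narrowPeak", tl[["B"]])),
                motifs = file.path(dir, "motifs.meme"),
                manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(ds$sequences, paths$fasta)
  write_gtf(ds$annotation, paths$gtf)
  write_peaks(ds$peaks_a, paths$peaks_a)
  write_peaks(ds$peaks_b, paths$peaks_b)
  mark_paths <- list()
  for (tissue in unname(tl)) {
    for (mk in c("H3K27ac", "H3K27me3")) {
      p <- file.path(dir, sprintf("%s_%s.bed", tissue, mk))
      write_bed3(ds$tracks[[tissue]][[mk]], p)
      mark_paths[[tissue]][[mk]] <- p
    }
  }
  write_meme(config$motifs, paths$motifs)
  jsonlite::write_json(ds$manifest, paths$manifest, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  cfg_out <- config
  cfg_out$motifs <- lapply(config$motifs, pwm_consensus)
  class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  rc <- list(peaks_a = paths$peaks_a, peaks_b = paths$peaks_b,
             tissue_a = tl[["A"]], tissue_b = tl[["B"]], stage = config$stage,
             gtf = paths$gtf, fasta = paths$fasta, marks = mark_paths,
             motif_file = paths$motifs, out_dir = file.path(dir, "results"),
             params = list(flank_up = 2000, flank_down = 1000,
                           max_tss_distance = 10000, gap = 2000,
                           scan_threshold_frac = 0.9,
                           mark_threshold = config$mark_threshold,
                           shuffle_order = 2, seed = config$seed,
                           n_discover = 3, k_min = 6, k_max = 10))
  yaml::write_yaml(rc, file.path(dir, "run_config.yaml"))
  rc
}
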