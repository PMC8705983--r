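# End-to-end orchestration: annotation -> cross-tissue comparison ->
# motif enrichment / discovery -> affinity scoring -> mark classification,
# with every stage's tables written to the output directory and a summary
# JSON aggregating the headline quantities.

#' Validate a run configuration
#'
#' @param rc run-config list (see [make_fixture()] for the layout).
#' @return the config, invisibly; stops on missing fields or paths.
#' @export
validate_run_config <- function(rc) {
  need <- c("peaks_a", "peaks_b", "tissue_a", "tissue_b", "gtf", "fasta",
            "marks", "motif_file", "out_dir", "params")
  miss <- setdiff(need, names(rc))
  if (length(miss) > 0) {
    stop("run config lacks field(s): ", paste(miss, collapse = ", "))
  }
  files <- c(rc$peaks_a, rc$peaks_b, rc$gtf, rc$fasta, rc$motif_file,
             unlist(rc$marks))
  missing_files <- files[!file.exists(files)]
  if (length(missing_files) > 0) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  if (is.null(rc$params$seed)) stop("run config must fix params$seed")
  invisible(rc)
}

default_params <- function(params) {
  # scan_threshold_frac 0.9: sequence-level enrichment counting of short
  # degenerate AT-rich motifs on AT-rich genomes saturates at permissive
  # thresholds (nearly every 200-600 bp window contains a weak hit)
  def <- list(flank_up = 2000, flank_down = 1000, max_tss_distance = 10000,
              gap = 2000, scan_threshold_frac = 0.9, mark_threshold = 0.25,
              shuffle_order = 2, seed = 1, n_discover = 3, k_min = 6,
              k_max = 10, min_category_seqs = 5)
  def[names(params)] <- params
  def
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# peak sequences from the genome, named by peak id
extract_peak_seqs <- function(genome, peaks) {
  if (nrow(peaks) == 0) return(setNames(character(0), character(0)))
  setNames(as.character(Biostrings::subseq(genome[peaks$chrom],
                                           peaks$start + 1L, peaks$end)),
           peaks$peak_id)
}

#' Run the full comparative binding analysis
#'
#' Executes annotation, cross-tissue comparison, the 2 kb peak subdivision,
#' motif enrichment and discovery, affinity scoring and histone-mark
#' classification on the inputs named in the run config, writes per-stage
#' TSV/BED tables plus a `summary.json` under `out_dir`, and returns the
#' report invisibly.  Any stage failure aborts with the stage name; outputs
#' of completed stages are retained.
#'
#' @param rc run-config list, see [validate_run_config()].
#' @param quiet suppress stage messages.
#' @return report list (also serialized as `summary.json`), invisibly.
#' @export
run_full_analysis <- function(rc, quiet = FALSE) {
  validate_run_config(rc)
  par <- default_params(rc$params)
  out <- rc$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    say("stage %s ...", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  report <- list(package_version = as.character(utils::packageVersion("crossbind")),
                 config_hash = fnv1a(rc),
                 tissues = c(A = rc$tissue_a, B = rc$tissue_b))

  # --- annotation ----------------------------------------------------------
  ann <- NULL; peaks_a <- NULL; peaks_b <- NULL; asg_a <- NULL; asg_b <- NULL
  stage("annotate", {
    ann <- read_genes(rc$gtf)
    peaks_a <- read_peaks(rc$peaks_a, tissue = rc$tissue_a, stage = rc$stage)
    peaks_b <- read_peaks(rc$peaks_b, tissue = rc$tissue_b, stage = rc$stage)
    if (length(intersect(peaks_a$peak_id, peaks_b$peak_id)) > 0) {
      say("peak ids collide between tissues; prefixing with tissue labels")
      peaks_a$peak_id <- paste(rc$tissue_a, peaks_a$peak_id, sep = ":")
      peaks_b$peak_id <- paste(rc$tissue_b, peaks_b$peak_id, sep = ":")
    }
    asg_a <- assign_peaks_to_genes(peaks_a, ann, par$flank_up, par$flank_down,
                                    par$max_tss_distance)
    asg_b <- assign_peaks_to_genes(peaks_b, ann, par$flank_up, par$flank_down,
                                    par$max_tss_distance)
    write_tsv(asg_a, file.path(out, sprintf("assignments_%s.tsv", rc$tissue_a)))
    write_tsv(asg_b, file.path(out, sprintf("assignments_%s.tsv", rc$tissue_b)))
    for (p in list(list(peaks_a, rc$tissue_a), list(peaks_b, rc$tissue_b))) {
      pk <- p[[1]]
      pk$location <- classify_location(pk, ann)
      write_peaks(pk, file.path(out, sprintf("peaks_%s_annotated.bed", p[[2]])),
                  format = "bed6", name_field = "location")
    }
    report$n_peaks <- c(A = nrow(peaks_a), B = nrow(peaks_b))
  })

  # --- cross-tissue comparison --------------------------------------------
  cats <- NULL; subdiv <- NULL
  stage("compare", {
    cats <- categorize_genes(asg_a, asg_b, labels = c("A", "B"))
    write_tsv(cats, file.path(out, "gene_categories.tsv"))
    report$gene_category_counts <- as.list(attr(cats, "counts"))
    report$gene_category_percentages <- as.list(attr(cats, "percentages"))
    freq <- list()
    for (t in list(list(asg_a, "A"), list(asg_b, "B"))) {
      bf <- binding_frequency(t[[1]])
      bf$tissue <- report$tissues[[t[[2]]]]
      bf$category <- cats$category[match(bf$gene_id, cats$gene_id)]
      freq[[t[[2]]]] <- bf
    }
    bf_all <- do.call(rbind, freq)
    write_tsv(bf_all, file.path(out, "binding_frequency.tsv"))
    pct_multi <- vapply(split(bf_all, bf_all$category), function(d)
      round_half_up(100 * mean(d$class == "multiPeak")), numeric(1))
    report$pct_multipeak_by_category <- as.list(pct_multi)
    occ <- occupancy_matrix(setNames(list(peaks_a, peaks_b),
                                     c(rc$tissue_a, rc$tissue_b)))
    corr <- sample_correlation(occ)
    write_tsv(as.data.frame(corr), file.path(out, "sample_correlation.tsv"))
    pca <- pca_scores(occ, n_components = 2)
    write_tsv(data.frame(sample = rownames(pca$scores), pca$scores),
              file.path(out, "pca_scores.tsv"))
    report$occupancy <- list(n_consensus_regions = nrow(occ),
                              cross_correlation = unname(corr[1, 2]),
                              pca_explained_variance = pca$explained_variance)
    common <- cats$gene_id[cats$category == "common"]
    subdiv <- subdivide_common_peaks(peaks_a, peaks_b, gap = par$gap,
                                      assignments_a = asg_a, assignments_b = asg_b,
                                      common_genes = common)
    write_tsv(subdiv, file.path(out, "peak_subdivision.tsv"))
    for (cat in unique(subdiv$category)) {
      ids <- subdiv$peak_id[subdiv$category == cat]
      pk <- rbind(peaks_a[peaks_a$peak_id %in% ids, ],
                  peaks_b[peaks_b$peak_id %in% ids, ])
      write_peaks(pk, file.path(out, sprintf("subdivision_%s.bed", cat)),
                  format = "bed6")
    }
    report$subdivision_counts <- as.list(table(subdiv$category))
    report$pct_tissue_specific_peaks <-
      round_half_up(100 * attr(subdiv, "fraction_specific"))
  })

  # --- motif analysis ------------------------------------------------------
  genome <- NULL; pwms <- NULL; cat_seqs <- NULL
  stage("motifs", {
    genome <- Biostrings::readDNAStringSet(rc$fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    pwms <- read_meme(rc$motif_file)
    all_peaks <- rbind(peaks_a, peaks_b)
    cat_seqs <- lapply(split(subdiv$peak_id, subdiv$category), function(ids) {
      extract_peak_seqs(genome, all_peaks[all_peaks$peak_id %in% ids, ])
    })
    enr <- list()
    for (cat in names(cat_seqs)) {
      fg <- cat_seqs[[cat]]
      if (length(fg) < par$min_category_seqs) next
      bg <- shuffle_background(fg, order = par$shuffle_order, seed = par$seed)
      e <- motif_enrichment(fg, bg, pwms, threshold_frac = par$scan_threshold_frac)
      e$category <- cat
      enr[[cat]] <- e
    }
    if (length(enr) > 0) {
      enr_tab <- do.call(rbind, enr)
      rownames(enr_tab) <- NULL
      write_tsv(enr_tab, file.path(out, "motif_enrichment.tsv"))
      report$enrichment <- enr_tab[, c("motif", "category", "p_adjusted",
                                        "enriched")]
    }
    fg <- cat_seqs[["A_only"]]
    if (!is.null(fg) && length(fg) >= 10) {
      bg <- shuffle_background(fg, order = par$shuffle_order, seed = par$seed + 1)
      disc <- discover_motifs(fg, bg, k_min = par$k_min, k_max = par$k_max,
                              n_motifs = par$n_discover, seed = par$seed)
      write_tsv(disc, file.path(out, "discovered_motifs.tsv"))
      report$discovered_motifs <- disc$consensus
    } else {
      say("discovery skipped: fewer than 10 A_only sequences")
    }
    # location distribution of classical-motif hits across categories
    locs <- list()
    for (p in list(peaks_a, peaks_b)) {
      locs[[length(locs) + 1]] <- data.frame(peak_id = p$peak_id,
                                             location = classify_location(p, ann),
                                             stringsAsFactors = FALSE)
    }
    locs <- do.call(rbind, locs)
    hit_list <- list()
    for (cat in names(cat_seqs)) {
      if (length(cat_seqs[[cat]]) == 0) next
      h <- scan_pwm(cat_seqs[[cat]], pwms[[1]],
                    threshold_frac = par$scan_threshold_frac)
      if (nrow(h) > 0) {
        h$motif <- paste(pwms[[1]]$name, cat, sep = "|")
        hit_list[[cat]] <- h
      }
    }
    if (length(hit_list) > 0) {
      dist_tab <- motif_location_distribution(do.call(rbind, hit_list), locs)
      write_tsv(dist_tab, file.path(out, "motif_location_distribution.tsv"))
    }
  })

  # --- affinity ------------------------------------------------------------
  stage("affinity", {
    psam <- psam_from_pwm(pwms[[1]])
    score_list <- list()
    for (cat in names(cat_seqs)) {
      s <- cat_seqs[[cat]]
      s <- s[nchar(s) >= psam$width]
      if (length(s) < 3) next
      score_list[[cat]] <- sequence_affinities(s, psam, mode = "max",
                                               category = cat)
    }
    if (length(score_list) > 0) {
      scores <- do.call(rbind, score_list)
      write_tsv(scores, file.path(out, "affinity_scores.tsv"))
      if (length(score_list) >= 2) {
        tests <- compare_affinity_distributions(lapply(score_list, `[[`, "score"))
        write_tsv(tests, file.path(out, "affinity_tests.tsv"))
        report$affinity_tests <- tests
      }
    }
  })

  # --- chromatin marks -----------------------------------------------------
  stage("marks", {
    tracks <- lapply(rc$marks, function(tt) lapply(tt, read_track))
    mk_counts <- list()
    cls_list <- list()
    for (side in list(list("A_only", peaks_a, rc$tissue_a, rc$tissue_b),
                      list("B_only", peaks_b, rc$tissue_b, rc$tissue_a))) {
      ids <- subdiv$peak_id[subdiv$category == side[[1]]]
      pk <- side[[2]][side[[2]]$peak_id %in% ids, ]
      if (nrow(pk) == 0) {
        mk_counts[[side[[1]]]] <- list()
        next
      }
      cls <- classify_cross_tissue(pk, tracks, focal_tissue = side[[3]],
                                   other_tissue = side[[4]],
                                   threshold = par$mark_threshold)
      cls$focal_tissue <- side[[3]]
      cls_list[[side[[1]]]] <- cls
      mk_counts[[side[[1]]]] <- as.list(attr(cls, "counts"))
    }
    if (length(cls_list) > 0) {
      write_tsv(do.call(rbind, cls_list), file.path(out, "mark_classes.tsv"))
    }
    report$mark_class_counts <- mk_counts
    # gene lists per mark class, for external GO tooling
    if (length(cls_list) > 0) {
      all_cls <- do.call(rbind, cls_list)
      asg <- rbind(asg_a, asg_b)
      gl <- asg[!is.na(asg$gene_id) & asg$peak_id %in% all_cls$peak_id,
                c("peak_id", "gene_id")]
      gl$class <- all_cls$class[match(gl$peak_id, all_cls$peak_id)]
      write_tsv(unique(gl[, c("class", "gene_id")]),
                file.path(out, "mark_class_genes.tsv"))
    }
  })

  jsonlite::write_json(report, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  say("done; summary written to %s", file.path(out, "summary.json"))
  invisible(report)
}
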