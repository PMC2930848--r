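# Pooling of hits across a gene's selected alternative promoters, the
# user-defined filter cascade, and the overrepresentation statistics:
# observed/expected TFBS and gene counts, folds, z-score p-values against
# the fold distribution over all matrices, proportion p-values, and the
# CpG-island comparison of the query set against the genome.

#' Filter parameters derived from a run configuration
#'
#' Same analysis fields as [run_config()], with the conservation threshold
#' converted from percent to a fraction.
#'
#' @param cfg `run_config` object.
#' @return List of class `filter_params`.
#' @export
filter_params <- function(cfg) {
  structure(list(conservation_threshold = cfg$conservation_threshold / 100,
                 top_percent_conserved = cfg$top_percent_conserved,
                 max_conserved_tfbs = cfg$max_conserved_tfbs,
                 coding_mode = cfg$coding_mode,
                 upstream_len = cfg$upstream_len,
                 downstream_len = cfg$downstream_len),
            class = "filter_params")
}

# genomic footprint (0-based start) and genomic strand of each hit
.hit_genomic <- function(hits, promoter) {
  L <- hits$width
  if (promoter$strand == "+") {
    gstart <- promoter$win_start + hits$offset
    gstrand <- hits$strand
  } else {
    gstart <- promoter$win_end - hits$offset - L
    gstrand <- ifelse(hits$strand == "+", "-", "+")
  }
  list(gstart = gstart, gstrand = gstrand)
}

#' Apply the filter cascade to one gene's hits and pool across its promoters
#'
#' Filters, in order: (1) window -- the hit footprint must lie within
#' `[-upstream_len, +downstream_len)` of the TSS; (2) coding mode; (3) hit
#' conservation at or above the threshold; (4) per promoter, keep the top
#' `top_percent_conserved` percent of surviving hits ranked by conservation
#' (count = ceiling of percent x n, over the pooled hits of all matrices);
#' (5) per promoter, keep at most `max_conserved_tfbs` highest-conservation
#' hits. Pooled hits with identical genomic footprints (same matrix, start
#' and genomic strand, arising from overlapping windows of two selected TSSs
#' of the same gene) are counted once.
#'
#' The effective length is the number of distinct genomic bases (union over
#' the gene's promoters) surviving the region-level filters (window, coding
#' mode, per-base conservation at or above threshold); the rank filters
#' (4)-(5) have no natural length and do not shrink it.
#'
#' @param hits Hit data.frame for one gene (all matrices, all selected
#'   promoters).
#' @param promoters List of the gene's `promoter_sequence` objects.
#' @param params `filter_params` object.
#' @return List with `hits` (kept hits) and `effective_length` (bp).
#' @export
filter_hits <- function(hits, promoters, params) {
  names(promoters) <- vapply(promoters, function(p) as.character(p$tss_index), "")
  kept <- list()
  eff_positions <- list()
  for (pr in promoters) {
    key <- as.character(pr$tss_index)
    h <- hits[hits$tss_index == pr$tss_index, , drop = FALSE]
    # oriented relative coordinates of the window bases: index i (0-based)
    # corresponds to TSS-relative position i - up_eff
    nwin <- nchar(pr$seq)
    relpos <- seq_len(nwin) - 1L - pr$up_eff
    in_window <- relpos >= -params$upstream_len & relpos < params$downstream_len
    keep_base <- in_window
    if (params$coding_mode == "coding") keep_base <- keep_base & pr$coding
    if (params$coding_mode == "noncoding") keep_base <- keep_base & !pr$coding
    keep_base <- keep_base & (pr$conservation >= params$conservation_threshold)
    idx0 <- which(keep_base) - 1L
    eff_positions[[key]] <- promoter_index_to_genomic(pr, idx0)

    if (nrow(h) == 0L) next
    # (1) window filter on the whole footprint
    rel_start <- h$offset - pr$up_eff
    ok <- rel_start >= -params$upstream_len &
      (rel_start + h$width) <= params$downstream_len
    h <- h[ok, , drop = FALSE]
    # (2) coding mode
    if (params$coding_mode == "coding") h <- h[h$coding, , drop = FALSE]
    if (params$coding_mode == "noncoding") h <- h[!h$coding, , drop = FALSE]
    # (3) conservation threshold (inclusive)
    h <- h[h$conservation >= params$conservation_threshold, , drop = FALSE]
    if (nrow(h) == 0L) next
    # deterministic conservation ranking for (4) and (5)
    ord <- order(-h$conservation, -h$rel_score, h$matrix_id, h$offset, h$strand)
    h <- h[ord, , drop = FALSE]
    # (4) top percent of conserved hits, pooled over all matrices
    n_keep <- ceiling(params$top_percent_conserved / 100 * nrow(h))
    h <- h[seq_len(n_keep), , drop = FALSE]
    # (5) cap on the number of most conserved hits per promoter
    if (is.finite(params$max_conserved_tfbs) &&
        nrow(h) > params$max_conserved_tfbs) {
      h <- h[seq_len(params$max_conserved_tfbs), , drop = FALSE]
    }
    g <- .hit_genomic(h, pr)
    h$gstart <- g$gstart
    h$gstrand <- g$gstrand
    kept[[key]] <- h
  }
  effective_length <- length(unique(unlist(eff_positions, use.names = FALSE)))
  if (length(kept) == 0L) {
    return(list(hits = cbind(hits[0, , drop = FALSE],
                             gstart = integer(0), gstrand = character(0)),
                effective_length = effective_length))
  }
  pooled <- do.call(rbind, kept)
  dup <- duplicated(paste(pooled$matrix_id, pooled$gstart, pooled$gstrand))
  pooled <- pooled[!dup, , drop = FALSE]
  pooled <- pooled[order(pooled$matrix_id, pooled$tss_index, pooled$offset,
                         pooled$strand), , drop = FALSE]
  rownames(pooled) <- NULL
  list(hits = pooled, effective_length = effective_length)
}

#' Expected number of hits by chance
#' @param effective_length_bp Total filtered sequence length in bp.
#' @param bg_freq_per_mbp Background hit rate, hits per Mbp.
#' @return Expected hit count.
#' @export
expected_hits <- function(effective_length_bp, bg_freq_per_mbp) {
  stopifnot(effective_length_bp >= 0, bg_freq_per_mbp >= 0)
  effective_length_bp / 1e6 * bg_freq_per_mbp
}

#' Expected number of genes with at least one chance hit
#'
#' Poisson model: each gene contributes `1 - exp(-lambda)` with
#' `lambda = length/1e6 * bg_freq`.
#'
#' @param effective_lengths_bp Per-gene filtered lengths in bp.
#' @param bg_freq_per_mbp Background hit rate, hits per Mbp.
#' @return Expected gene count.
#' @export
expected_genes <- function(effective_lengths_bp, bg_freq_per_mbp) {
  stopifnot(all(effective_lengths_bp >= 0), bg_freq_per_mbp >= 0)
  lambda <- effective_lengths_bp / 1e6 * bg_freq_per_mbp
  sum(1 - exp(-lambda))
}

#' Folds, z-scores and upper-tail p-values over a matrix repertoire
#'
#' The fold of each matrix is observed/expected; z-scores standardize the
#' folds against their distribution over all matrices (sample sd, n-1), and
#' the p-value is the upper normal tail `1 - Phi(z)` (the tool reports
#' overrepresentation only). A degenerate all-equal fold distribution gives
#' p = 0.5 everywhere.
#'
#' @param observed Observed counts per matrix (>= 3 matrices).
#' @param expected Expected counts per matrix (all > 0).
#' @return Data.frame with fold, z, p.
#' @export
fold_and_z <- function(observed, expected) {
  if (length(observed) < 3L)
    stopf("fold distribution undefined for fewer than 3 matrices")
  if (length(expected) != length(observed))
    stopf("observed and expected lengths differ")
  if (any(expected <= 0))
    stopf("expected counts must be positive")
  fold <- observed / expected
  s <- stats::sd(fold)
  if (s == 0) {
    return(data.frame(fold = fold, z = rep(0, length(fold)),
                      p = rep(0.5, length(fold))))
  }
  z <- (fold - mean(fold)) / s
  data.frame(fold = fold, z = z, p = 1 - stats::pnorm(z))
}

#' Proportion p-value
#'
#' The proportion of observed hits explainable by chance: expected/observed,
#' capped at 1; defined as 1 when nothing was observed.
#'
#' @param observed Observed hit count.
#' @param expected Expected hit count.
#' @return Probability in `[0, 1]`.
#' @export
proportion_p <- function(observed, expected) {
  stopifnot(observed >= 0, expected >= 0)
  if (observed == 0) return(1)
  min(1, expected / observed)
}

#' Compare query CpG-island lengths against the genome distribution
#'
#' One-sided z-test of the query mean per-gene island length against the
#' genome mean: `z = (mean_q - mean_G) / (sd_G / sqrt(n))`,
#' `p = 1 - Phi(z)`.
#'
#' @param query_lengths Per-gene island lengths of the query set (n >= 2).
#' @param genome_mean,genome_sd Genome-wide per-gene mean and sd.
#' @return List with query_mean, genome_mean, z, p.
#' @export
cpg_comparison <- function(query_lengths, genome_mean, genome_sd) {
  n <- length(query_lengths)
  if (n < 2L) stopf("cpg_comparison: need at least 2 query genes")
  mq <- mean(query_lengths)
  if (genome_sd <= 0) {
    warnf("genome island-length sd is 0; comparison p undefined, reporting 1")
    return(list(query_mean = mq, genome_mean = genome_mean, z = NA_real_, p = 1))
  }
  z <- (mq - genome_mean) / (genome_sd / sqrt(n))
  list(query_mean = mq, genome_mean = genome_mean, z = z,
       p = 1 - stats::pnorm(z))
}

# per-repertoire enrichment table
.enrich_table <- function(pwms, thresholds, bg_table, gene_hits, eff_lengths) {
  total_mbp <- attr(bg_table, "total_length") / 1e6
  rows <- lapply(seq_along(pwms), function(k) {
    pwm <- pwms[[k]]
    freq <- bg_freq_at(bg_table, pwm$id, thresholds[[pwm$id]])
    # floor at half a hit over the background so folds stay finite for
    # matrices never seen in the background scan
    if (freq <= 0) freq <- 0.5 / total_mbp
    per_gene_n <- vapply(gene_hits, function(h) {
      sum(h$matrix_id == pwm$id)
    }, numeric(1))
    genes_with <- names(per_gene_n)[per_gene_n > 0]
    data.frame(matrix_id = pwm$id, tf_name = pwm$name,
               info_content = pwm$info_content,
               threshold = thresholds[[pwm$id]], bg_freq_per_mbp = freq,
               genes = paste(genes_with, collapse = ","),
               tfbs_number = sum(per_gene_n),
               tfbs_expected = expected_hits(sum(eff_lengths), freq),
               genes_number = length(genes_with),
               genes_expected = expected_genes(eff_lengths, freq),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fz <- fold_and_z(tab$tfbs_number, tab$tfbs_expected)
  tab$tfbs_fold <- fz$fold
  tab$tfbs_z <- fz$z
  tab$tfbs_fold_p <- fz$p
  gz <- fold_and_z(tab$genes_number, tab$genes_expected)
  tab$genes_fold <- gz$fold
  tab$genes_z <- gz$z
  tab$genes_fold_p <- gz$p
  tab$proportion_p <- mapply(proportion_p, tab$tfbs_number, tab$tfbs_expected)
  tab$tfbs_fold_p_bonf <- pmin(1, tab$tfbs_fold_p * nrow(tab))
  tab <- tab[order(tab$tfbs_fold_p, -tab$tfbs_fold, tab$matrix_id), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Run the full overrepresentation analysis
#'
#' Resolves the query genes, clusters and (optionally) CAGE-remaps TSSs,
#' annotates CpG islands, applies the TSS selection mode, extracts promoter
#' windows, optimizes one score threshold per matrix against the background
#' frequency table, scans, filters, and computes every result table.
#'
#' @param gene_ids Character vector of query gene ids.
#' @param genome Named character vector of chromosome sequences.
#' @param annotation `genome_annotation` data.frame.
#' @param conservation `conservation_track` (or NULL).
#' @param pwms Primary matrix repertoire (list of `pwm`; >= 3).
#' @param bg_table `bg_freq_table` covering every matrix.
#' @param config `run_config`.
#' @param cage Optional `cage_clusters` data.frame.
#' @param pwms_extra Optional second repertoire, reported as its own table.
#' @return List of class `enrichment_result` with elements `params`
#'   (parameter echo), `per_gene` (per-gene hit counts), `enrichment` (main
#'   repertoire table, sorted by tfbs_fold_p), `enrichment_extra` (second
#'   repertoire or NULL), `cpg` (query vs genome island comparison), and
#'   `meta` (thresholds, selected TSSs, effective lengths).
#' @export
run_enrichment <- function(gene_ids, genome, annotation, conservation, pwms,
                           bg_table, config, cage = NULL, pwms_extra = NULL) {
  stopifnot(inherits(config, "run_config"))
  known <- unique(annotation$gene_id)
  unresolved <- setdiff(gene_ids, known)
  if (length(unresolved) == length(gene_ids))
    stopf("no query gene resolves against the annotation: %s",
          paste(unresolved, collapse = ", "))
  if (length(unresolved) > 0L)
    warnf("unresolved gene id(s) dropped: %s", paste(unresolved, collapse = ", "))
  gene_ids <- gene_ids[gene_ids %in% known]

  tss <- cluster_tss(annotation)
  if (!is.null(cage)) tss <- remap_tss_with_cage(tss, cage)
  tss <- annotate_tss_islands(tss, genome)
  selected <- select_tss(tss, config$tss_mode)

  # genome-wide island distribution over all genes under the same selection;
  # genes whose every TSS is dropped by the mode contribute 0
  gsel <- selected
  dropped <- setdiff(known, unique(gsel$gene_id))
  if (length(dropped) > 0L) {
    pad <- gsel[rep(1L, length(dropped)), , drop = FALSE]
    pad$gene_id <- dropped
    pad$cpg_island_total_len <- 0
    gsel <- rbind(gsel, pad)
  }
  gstats <- genome_island_stats(gsel)

  query_tss <- selected[selected$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(query_tss) == 0L)
    stopf("tss_mode '%s' leaves no TSS for the query genes", config$tss_mode)

  all_pwms <- c(pwms, pwms_extra %||% list())
  thresholds <- vapply(all_pwms, function(p) {
    optimize_threshold(bg_table, p$id, config$random_occurrence)
  }, numeric(1))
  names(thresholds) <- vapply(all_pwms, function(p) p$id, "")

  params <- filter_params(config)
  query_genes <- unique(query_tss$gene_id)
  gene_hits <- list()
  eff_lengths <- numeric(0)
  for (g in query_genes) {
    rows <- which(query_tss$gene_id == g)
    promoters <- lapply(rows, function(i) {
      extract_promoter(genome, conservation, annotation, query_tss[i, ],
                       config$upstream_len, config$downstream_len)
    })
    hits <- scan_all(all_pwms, promoters, thresholds)
    fh <- filter_hits(hits, promoters, params)
    gene_hits[[g]] <- fh$hits
    eff_lengths[g] <- fh$effective_length
  }

  main <- .enrich_table(pwms, as.list(thresholds), bg_table, gene_hits,
                        eff_lengths)
  extra <- if (!is.null(pwms_extra) && length(pwms_extra) > 0L) {
    .enrich_table(pwms_extra, as.list(thresholds), bg_table, gene_hits,
                  eff_lengths)
  } else NULL

  query_lengths <- vapply(split(query_tss$cpg_island_total_len,
                                query_tss$gene_id)[query_genes],
                          sum, numeric(1))
  cpg <- if (length(query_lengths) >= 2L) {
    cpg_comparison(query_lengths, gstats$mean, gstats$sd)
  } else {
    list(query_mean = unname(query_lengths)[1] %||% NA_real_,
         genome_mean = gstats$mean, z = NA_real_, p = NA_real_)
  }

  per_gene <- data.frame(
    gene_id = query_genes,
    tfbs_number = vapply(gene_hits, nrow, integer(1))[query_genes],
    effective_length = unname(eff_lengths[query_genes]),
    cpg_island_total_len = unname(query_lengths[query_genes]),
    stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL

  param_echo <- data.frame(parameter = names(unclass(config)),
                           value = vapply(names(unclass(config)), function(k) {
                             v <- config[[k]]
                             if (is.numeric(v) && is.infinite(v)) "unlimited"
                             else as.character(v)
                           }, ""), stringsAsFactors = FALSE)
  rownames(param_echo) <- NULL

  structure(list(params = param_echo, per_gene = per_gene,
                 enrichment = main, enrichment_extra = extra, cpg = cpg,
                 meta = list(thresholds = thresholds,
                             selected_tss = query_tss,
                             effective_lengths = eff_lengths,
                             genome_island_mean = gstats$mean,
                             genome_island_sd = gstats$sd,
                             config = config)),
            class = "enrichment_result")
}

#' Write the five result tables of an enrichment run
#'
#' Emits params.tsv, per_gene.tsv, enrichment_jaspar.tsv,
#' enrichment_extra.tsv and cpg.tsv into `dir`, each with a commented
#' provenance header (tool version, configuration echo, seed, timestamp).
#'
#' @param res `enrichment_result` from [run_enrichment()].
#' @param dir Output directory (created if missing).
#' @param seed Optional seed to record in the header.
#' @return The directory, invisibly.
#' @export
write_enrichment_result <- function(res, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$meta$config
  header <- c(
    sprintf("# tool: promenrich %s", as.character(utils::packageVersion("promenrich"))),
    sprintf("# config: %s", paste(vapply(names(unclass(cfg)), function(k) {
      v <- cfg[[k]]
      v <- if (is.numeric(v) && is.infinite(v)) "unlimited" else as.character(v)
      paste0(k, "=", v)
    }, ""), collapse = " ")),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    sprintf("# timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  emit <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(header, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  emit(res$params, "params.tsv")
  emit(res$per_gene, "per_gene.tsv")
  emit(res$enrichment, "enrichment_jaspar.tsv")
  extra <- res$enrichment_extra %||%
    res$enrichment[0, , drop = FALSE]
  emit(extra, "enrichment_extra.tsv")
  cpg_df <- data.frame(query_mean = res$cpg$query_mean,
                       genome_mean = res$cpg$genome_mean,
                       z = res$cpg$z, p = res$cpg$p)
  emit(cpg_df, "cpg.tsv")
  invisible(dir)
}
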