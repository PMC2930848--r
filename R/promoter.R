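# Strand-oriented promoter windows around transcription start sites,
# CAGE-based TSS refinement, and the five alternative-TSS selection modes.

#' Cluster transcripts into distinct transcription start sites
#'
#' All transcripts of a gene sharing the same start position (5'-most base in
#' gene orientation) collapse into one TSS record. Records are ordered 5' to
#' 3' in gene orientation, so `tss_index` 1 is the most distal TSS.
#'
#' @param annotation `genome_annotation` data.frame.
#' @return Data.frame with columns gene_id, chrom, strand, position,
#'   tss_index, transcripts (comma-joined ids), tpm (-1 until CAGE
#'   remapping), cpg_island_total_len (NA until island annotation).
#' @export
cluster_tss <- function(annotation) {
  sp <- split(seq_len(nrow(annotation)), annotation$gene_id)
  sp <- sp[unique(annotation$gene_id)]  # preserve input gene order
  rows <- lapply(names(sp), function(g) {
    idx <- sp[[g]]
    strand <- annotation$strand[idx[1]]
    pos <- if (strand == "+") annotation$tx_start[idx] else annotation$tx_end[idx] - 1L
    upos <- sort(unique(pos), decreasing = (strand == "-"))
    tx <- vapply(upos, function(p) {
      paste(annotation$transcript_id[idx][pos == p], collapse = ",")
    }, "")
    data.frame(gene_id = g, chrom = annotation$chrom[idx[1]], strand = strand,
               position = as.integer(upos), tss_index = seq_along(upos),
               transcripts = tx, tpm = -1, cpg_island_total_len = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Refine TSS positions with CAGE tag clusters
#'
#' For each TSS, the closest same-chromosome, same-strand tag cluster within
#' 200 bp (minimum distance from the TSS to the cluster interval; 0 if
#' inside) supplies the new position: the in-cluster position with the
#' highest tag count (ties resolved to the most 5' position in gene
#' orientation). The TPM becomes the cluster's maximum per-tissue TPM. With
#' no cluster in range the position is unchanged and TPM stays -1. When two
#' TSSs of one gene collapse onto the same position, the duplicate with the
#' lower TPM is dropped.
#'
#' @param tss TSS data.frame from [cluster_tss()].
#' @param clusters `cage_clusters` data.frame.
#' @return The updated TSS data.frame.
#' @export
remap_tss_with_cage <- function(tss, clusters) {
  if (nrow(tss) == 0L || is.null(clusters) || nrow(clusters) == 0L) return(tss)
  for (i in seq_len(nrow(tss))) {
    sel <- clusters$chrom == tss$chrom[i] & clusters$strand == tss$strand[i]
    if (!any(sel)) next
    cand <- clusters[sel, , drop = FALSE]
    pos <- tss$position[i]
    d <- ifelse(pos < cand$start, cand$start - pos,
                ifelse(pos >= cand$end, pos - (cand$end - 1L), 0L))
    inrange <- d <= 200
    if (!any(inrange)) next
    cand <- cand[inrange, , drop = FALSE]
    d <- d[inrange]
    tot <- vapply(cand$counts, sum, numeric(1))
    # closest cluster wins; equidistant ties go to the higher total tag count
    ord <- order(d, -tot, cand$start)
    best <- cand[ord[1], , drop = FALSE]
    counts <- best$counts[[1]]
    peak <- which(counts == max(counts))
    peak <- if (tss$strand[i] == "+") min(peak) else max(peak)  # most 5'
    tss$position[i] <- as.integer(best$start + peak - 1L)
    tss$tpm[i] <- max(best$tpms[[1]])
  }
  # collapse duplicates created by remapping (same gene, same position)
  keep <- rep(TRUE, nrow(tss))
  key <- paste(tss$gene_id, tss$position)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    keep[idx[-which.max(tss$tpm[idx])]] <- FALSE
  }
  tss <- tss[keep, , drop = FALSE]
  # re-index 5' to 3' per gene
  out <- lapply(split(tss, tss$gene_id)[unique(tss$gene_id)], function(d) {
    d <- d[order(d$position, decreasing = (d$strand[1] == "-")), , drop = FALSE]
    d$tss_index <- seq_len(nrow(d))
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract a strand-oriented promoter window
#'
#' The window covers `upstream_len` bases 5' of the TSS and `downstream_len`
#' bases from the TSS downstream (position `upstream_len` in the oriented
#' sequence is the TSS base). Minus-strand promoters are reverse-complemented
#' so increasing index means downstream. The window is truncated, never
#' padded, at chromosome ends.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param conservation `conservation_track` (or NULL for all-zero scores).
#' @param annotation `genome_annotation` used to build the coding mask (any
#'   exon of any transcript of any gene counts as coding).
#' @param tss One row of a TSS data.frame.
#' @param upstream_len,downstream_len Window lengths in bp.
#' @return Object of class `promoter_sequence`: list with seq, conservation,
#'   coding, genomic window coordinates and effective up/down lengths.
#' @export
extract_promoter <- function(genome, conservation, annotation, tss,
                             upstream_len, downstream_len) {
  chrom <- tss$chrom
  if (!chrom %in% names(genome)) stopf("TSS on unknown chromosome %s", chrom)
  clen <- nchar(genome[[chrom]])
  if (tss$position < 0 || tss$position >= clen)
    stopf("TSS position %d outside chromosome %s", tss$position, chrom)
  w <- oriented_window_coords(tss$position, tss$strand, upstream_len,
                              downstream_len, clen)
  seq <- orient_seq(seq_slice(genome[[chrom]], w$start, w$end), tss$strand)
  cons <- if (is.null(conservation)) {
    numeric(w$end - w$start)
  } else {
    orient_vec(conservation[[chrom]][seq2(w$start + 1L, w$end)], tss$strand)
  }
  mask <- .coding_mask(annotation, chrom, w$start, w$end)
  mask <- orient_vec(mask, tss$strand)
  structure(list(gene_id = tss$gene_id, tss_index = tss$tss_index,
                 chrom = chrom, strand = tss$strand, tss_pos = tss$position,
                 up = upstream_len, down = downstream_len,
                 up_eff = w$up_eff, down_eff = w$down_eff,
                 win_start = w$start, win_end = w$end,
                 truncated = (w$up_eff < upstream_len ||
                                w$down_eff < downstream_len),
                 seq = seq, conservation = cons, coding = mask),
            class = "promoter_sequence")
}

# 1-based inclusive sequence helper that yields integer(0) for empty ranges
seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

.coding_mask <- function(annotation, chrom, start, end) {
  mask <- logical(max(0L, end - start))
  if (length(mask) == 0L || is.null(annotation)) return(mask)
  rows <- which(annotation$chrom == chrom & annotation$tx_start < end &
                  annotation$tx_end > start)
  for (i in rows) {
    es <- annotation$exon_starts[[i]]
    ee <- annotation$exon_ends[[i]]
    for (k in seq_along(es)) {
      a <- max(es[k], start)
      b <- min(ee[k], end)
      if (b > a) mask[(a - start + 1L):(b - start)] <- TRUE
    }
  }
  mask
}

# genomic position (0-based) of oriented promoter index i (0-based)
promoter_index_to_genomic <- function(promoter, i) {
  if (promoter$strand == "+") promoter$win_start + i else promoter$win_end - 1L - i
}

#' Select alternative TSSs of one gene (or per gene) by mode
#'
#' Modes: `all` keeps everything; `most_distal` keeps the single 5'-most TSS
#' in gene orientation (ties to the smallest genomic coordinate);
#' `highest_tpm` keeps the TSS with the maximum TPM (the -1 sentinel ranks
#' below any real value; ties go to the most distal; if every TPM is -1 the
#' mode falls back to `most_distal` with a warning); `with_cpg` /
#' `without_cpg` keep TSSs with positive / zero total CpG-island length.
#'
#' @param tss TSS data.frame (one or more genes; selection is per gene).
#' @param mode One of the `tss_mode` values of [run_config()].
#' @return The selected subset of `tss`.
#' @export
select_tss <- function(tss, mode) {
  if (!mode %in% .tss_modes)
    stopf("unknown tss_mode '%s'", mode)
  if (nrow(tss) == 0L || mode == "all") return(tss)
  parts <- lapply(split(tss, tss$gene_id)[unique(tss$gene_id)], function(d) {
    .select_tss_one(d, mode)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

.most_distal_idx <- function(d) {
  if (d$strand[1] == "+") {
    which(d$position == min(d$position))[1]
  } else {
    cand <- which(d$position == max(d$position))
    cand[which.min(d$position[cand])]
  }
}

.select_tss_one <- function(d, mode) {
  if (mode == "most_distal") {
    return(d[.most_distal_idx(d), , drop = FALSE])
  }
  if (mode == "highest_tpm") {
    if (all(d$tpm == -1)) {
      warnf("gene %s: no CAGE support on any TSS; falling back to most_distal",
            d$gene_id[1])
      return(d[.most_distal_idx(d), , drop = FALSE])
    }
    cand <- which(d$tpm == max(d$tpm))
    if (length(cand) > 1L) {
      sub <- d[cand, , drop = FALSE]
      return(sub[.most_distal_idx(sub), , drop = FALSE])
    }
    return(d[cand, , drop = FALSE])
  }
  if (anyNA(d$cpg_island_total_len))
    stopf("gene %s: cpg_island_total_len not filled; run annotate_tss_islands() first",
          d$gene_id[1])
  if (mode == "with_cpg") return(d[d$cpg_island_total_len > 0, , drop = FALSE])
  d[d$cpg_island_total_len == 0, , drop = FALSE]
}
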