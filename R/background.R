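# Background sequence models, per-matrix hit-frequency tables at integer
# score thresholds 60..100, and selection of the optimized matrix score
# threshold for a target random-occurrence rate.

#' Generate a random background sequence
#'
#' I.i.d. uniform bases (equal expected numbers of all four nucleotides)
#' from a seeded generator.
#'
#' @param length_bp Sequence length; at least 1000.
#' @param seed Integer seed.
#' @return Character string.
#' @export
generate_random_background <- function(length_bp, seed) {
  if (!is_scalar_number(length_bp) || length_bp < 1000)
    stopf("random background length must be >= 1000 bp")
  with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
          collapse = "")
  })
}

#' Build the core-promoter background
#'
#' Concatenation, in annotation order, of the oriented 200-bp window
#' immediately 5' of each gene's start position (truncated at chromosome
#' edges).
#'
#' @param annotation `genome_annotation` data.frame.
#' @param genome Named character vector of chromosome sequences.
#' @param width Window width in bp (default 200).
#' @return Character string.
#' @export
build_core_background <- function(annotation, genome, width = 200L) {
  gs <- gene_starts(annotation)
  parts <- character(nrow(gs))
  for (i in seq_len(nrow(gs))) {
    clen <- nchar(genome[[gs$chrom[i]]])
    p <- gs$gene_start[i]
    if (gs$strand[i] == "+") {
      a <- max(0L, p - width); b <- max(a, min(clen, p))
      parts[i] <- seq_slice(genome[[gs$chrom[i]]], a, b)
    } else {
      a <- min(clen, p + 1L); b <- min(clen, p + 1L + width)
      parts[i] <- revcomp(seq_slice(genome[[gs$chrom[i]]], a, b))
    }
  }
  paste(parts, collapse = "")
}

#' Build the conserved-promoter background
#'
#' Concatenation of the maximal runs of bases with conservation score
#' strictly above `cutoff` within each gene's promoter window (oriented;
#' default 10 kb upstream, 5 kb downstream of the gene start).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param conservation `conservation_track`.
#' @param annotation `genome_annotation` data.frame.
#' @param cutoff Conservation cutoff, strict (default 0.75).
#' @param upstream,downstream Promoter window in bp.
#' @return Character string (possibly empty if nothing is conserved).
#' @export
build_conserved_background <- function(genome, conservation, annotation,
                                       cutoff = 0.75, upstream = 10000,
                                       downstream = 5000) {
  gs <- gene_starts(annotation)
  parts <- character(0)
  for (i in seq_len(nrow(gs))) {
    chrom <- gs$chrom[i]
    clen <- nchar(genome[[chrom]])
    w <- oriented_window_coords(gs$gene_start[i], gs$strand[i], upstream,
                                downstream, clen)
    if (w$end <= w$start) next
    seq <- orient_seq(seq_slice(genome[[chrom]], w$start, w$end), gs$strand[i])
    cons <- orient_vec(conservation[[chrom]][seq2(w$start + 1L, w$end)],
                       gs$strand[i])
    keep <- cons > cutoff
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run <- which(r$values)
    parts <- c(parts, vapply(run, function(k) {
      substr(seq, starts[k], ends[k])
    }, ""))
  }
  paste(parts, collapse = "")
}

#' Precompute a per-matrix background hit-frequency table
#'
#' The background is scanned once per matrix at threshold 60 on both strands;
#' hits are bucketed by the integer floor of their relative score, giving the
#' hits-per-Mbp frequency at every integer threshold 60..100 in one pass.
#'
#' @param background Background sequence string (>= 1000 bp and at least as
#'   long as the widest matrix).
#' @param pwms List of `pwm` objects.
#' @param background_type Label: `"random"`, `"core"` or `"conserved"`.
#' @return Data.frame of class `bg_freq_table` (matrix_id, threshold,
#'   hits_per_mbp) with attributes `background_type` and `total_length`;
#'   frequency is non-increasing in threshold for every matrix.
#' @export
compute_frequency_table <- function(background, pwms,
                                    background_type = "random") {
  n <- nchar(background)
  if (n < 1000) stopf("background shorter than 1000 bp")
  widths <- vapply(pwms, function(p) p$width, numeric(1))
  if (n < max(widths))
    stopf("background (%d bp) shorter than widest matrix (%d bp)", n, max(widths))
  mbp <- n / 1e6
  thresholds <- 60:100
  parts <- lapply(pwms, function(pwm) {
    rel <- .window_rel_scores(pwm, background)
    b <- floor(c(rel$fwd, rel$rev) + .score_eps)
    counts <- vapply(thresholds, function(t) sum(b >= t), numeric(1))
    data.frame(matrix_id = pwm$id, threshold = thresholds,
               hits_per_mbp = counts / mbp, stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, parts)
  rownames(tbl) <- NULL
  attr(tbl, "background_type") <- background_type
  attr(tbl, "total_length") <- n
  class(tbl) <- c("bg_freq_table", "data.frame")
  tbl
}

#' Optimize the matrix score threshold for a target random-occurrence rate
#'
#' Returns the integer threshold in 60..100 whose background frequency is
#' least distant (absolute difference on the hits-per-Mbp scale) from the
#' target; exact ties are broken toward the higher (more restrictive)
#' threshold.
#'
#' @param table `bg_freq_table` from [compute_frequency_table()].
#' @param matrix_id Matrix to optimize.
#' @param target_freq Target rate in hits per Mbp (1 hit/Mbp = 1;
#'   1 hit/100 bp = 10000).
#' @return Integer threshold.
#' @export
optimize_threshold <- function(table, matrix_id, target_freq) {
  sub <- table[table$matrix_id == matrix_id, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("matrix %s absent from frequency table", matrix_id)
  sub <- sub[order(sub$threshold), , drop = FALSE]
  d <- abs(sub$hits_per_mbp - target_freq)
  best <- which(d == min(d))
  as.integer(sub$threshold[max(best)])
}

# background frequency of one matrix at one threshold
bg_freq_at <- function(table, matrix_id, threshold) {
  v <- table$hits_per_mbp[table$matrix_id == matrix_id &
                            table$threshold == threshold]
  if (length(v) == 0L)
    stopf("no frequency for matrix %s at threshold %d", matrix_id, threshold)
  v[1]
}
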