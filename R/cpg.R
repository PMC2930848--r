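# Gardiner-Garden CpG island detection. A CpG island is a region longer than
# 200 bp with G+C content above 50% and an observed/expected CpG dinucleotide
# ratio above 0.6 (all inequalities strict). Detection slides 200-bp frames
# (step 1 bp by default), merges runs of overlapping qualifying frames, and
# re-validates the merged region's own aggregate statistics, which prevents
# two barely-passing frames bridged by AT-rich sequence from forming an
# island.

#' GC content and CpG observed/expected ratio of a sequence
#'
#' `obs_exp = N_CG * L / (N_C * N_G)` with overlapping CG dinucleotides
#' counted; defined as 0 when the sequence has no C or no G. N bases never
#' count toward C, G or CG.
#'
#' @param seq Sequence string of length >= 2.
#' @return List with `gc_pct` (percent) and `obs_exp`.
#' @export
cpg_window_stats <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) stopf("cpg_window_stats: sequence must have length >= 2")
  v <- encode_dna(seq)
  nC <- sum(v == 2L)
  nG <- sum(v == 3L)
  nCG <- sum(v[-n] == 2L & v[-1L] == 3L)
  list(gc_pct = 100 * (nC + nG) / n,
       obs_exp = if (nC == 0L || nG == 0L) 0 else nCG * n / (nC * nG))
}

#' Detect CpG islands in a sequence window
#'
#' @param seq Sequence string (typically the oriented 5 kb upstream / 10 kb
#'   downstream window around a TSS; note the opposite asymmetry to the
#'   promoter scan window).
#' @param frame Frame width in bp (default 200).
#' @param step Frame step in bp (default 1 for maximal sensitivity).
#' @param min_len Minimum merged-island length, strict (default 200).
#' @param gc_min Minimum GC percent, strict (default 50).
#' @param oe_min Minimum CpG observed/expected ratio, strict (default 0.6).
#' @return Data.frame with columns start, end (0-based half-open within
#'   `seq`), length, gc_pct, obs_exp; one row per island.
#' @export
detect_cpg_islands <- function(seq, frame = 200L, step = 1L, min_len = 200L,
                               gc_min = 50, oe_min = 0.6) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_pct = numeric(0),
                      obs_exp = numeric(0))
  n <- nchar(seq)
  if (n < frame) return(empty)
  v <- encode_dna(seq)
  isC <- as.integer(v == 2L)
  isG <- as.integer(v == 3L)
  isCG <- as.integer(v[-n] == 2L & v[-1L] == 3L)
  csC <- c(0L, cumsum(isC))
  csG <- c(0L, cumsum(isG))
  csCG <- c(0L, cumsum(isCG))
  starts <- seq.int(1L, n - frame + 1L, by = step)  # 1-based frame starts
  nC <- csC[starts + frame] - csC[starts]
  nG <- csG[starts + frame] - csG[starts]
  # CG dinucleotide start positions inside [s, s + frame - 2]
  nCG <- csCG[starts + frame - 1L] - csCG[starts]
  gc <- 100 * (nC + nG) / frame
  oe <- ifelse(nC > 0L & nG > 0L, nCG * frame / (nC * nG), 0)
  qual <- which(gc > gc_min & oe > oe_min)
  if (length(qual) == 0L) return(empty)
  qs <- starts[qual]
  grp <- cumsum(c(1L, as.integer(diff(qs) >= frame)))  # split where frames no longer overlap
  rows <- lapply(split(qs, grp), function(s) {
    a <- min(s)
    b <- max(s) + frame - 1L  # 1-based inclusive end
    len <- b - a + 1L
    if (len <= min_len) return(NULL)
    st <- cpg_window_stats(substr(seq, a, b))
    if (!(st$gc_pct > gc_min && st$obs_exp > oe_min)) return(NULL)
    data.frame(start = a - 1L, end = b, length = len,
               gc_pct = st$gc_pct, obs_exp = st$obs_exp)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Total CpG-island length of one TSS window
#' @param islands Island data.frame from [detect_cpg_islands()].
#' @return Total bp of island (0 when none).
#' @export
tss_island_summary <- function(islands) {
  if (is.null(islands) || nrow(islands) == 0L) return(0)
  sum(islands$length)
}

#' Annotate TSS records with their CpG-island content
#'
#' Extracts the island window (default 5 kb upstream, 10 kb downstream of
#' each TSS, in transcript orientation), detects islands and fills
#' `cpg_island_total_len`.
#'
#' @param tss TSS data.frame from [cluster_tss()].
#' @param genome Named character vector of chromosome sequences.
#' @param upstream,downstream Island window lengths in bp.
#' @param step Frame step passed to [detect_cpg_islands()].
#' @param keep_islands If TRUE, also return per-TSS island tables.
#' @return The TSS data.frame with `cpg_island_total_len` filled; when
#'   `keep_islands`, a list with elements `tss` and `islands`.
#' @export
annotate_tss_islands <- function(tss, genome, upstream = 5000,
                                 downstream = 10000, step = 1L,
                                 keep_islands = FALSE) {
  all_islands <- list()
  for (i in seq_len(nrow(tss))) {
    chrom <- tss$chrom[i]
    clen <- nchar(genome[[chrom]])
    w <- oriented_window_coords(tss$position[i], tss$strand[i], upstream,
                                downstream, clen)
    seq <- orient_seq(seq_slice(genome[[chrom]], w$start, w$end), tss$strand[i])
    isl <- detect_cpg_islands(seq, step = step)
    tss$cpg_island_total_len[i] <- tss_island_summary(isl)
    if (keep_islands && nrow(isl) > 0L) {
      isl$gene_id <- tss$gene_id[i]
      isl$tss_index <- tss$tss_index[i]
      all_islands[[length(all_islands) + 1L]] <- isl
    }
  }
  if (!keep_islands) return(tss)
  islands <- if (length(all_islands) > 0L) do.call(rbind, all_islands) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               gc_pct = numeric(0), obs_exp = numeric(0),
               gene_id = character(0), tss_index = integer(0))
  list(tss = tss, islands = islands)
}

#' Genome-wide per-gene CpG island statistics
#'
#' The per-gene value is the total CpG-island length summed over the gene's
#' (selected) TSS records; genes without islands contribute 0.
#'
#' @param tss TSS data.frame with `cpg_island_total_len` filled.
#' @return List with `mean`, `sd` (sample sd over genes) and the per-gene
#'   data.frame.
#' @export
genome_island_stats <- function(tss) {
  if (anyNA(tss$cpg_island_total_len))
    stopf("cpg_island_total_len not filled; run annotate_tss_islands() first")
  per_gene <- vapply(split(tss$cpg_island_total_len, tss$gene_id)[unique(tss$gene_id)],
                     sum, numeric(1))
  if (length(per_gene) < 2L)
    stopf("genome_island_stats: need at least 2 genes")
  s <- stats::sd(per_gene)
  list(mean = mean(per_gene), sd = if (is.na(s)) 0 else s,
       per_gene = data.frame(gene_id = names(per_gene),
                             cpg_island_total_len = unname(per_gene),
                             stringsAsFactors = FALSE))
}
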