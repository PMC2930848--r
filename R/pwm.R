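# Position weight matrix construction and promoter scanning. Scores follow
# the classical log-odds convention: log2 of the pseudocounted base frequency
# over a uniform 0.25 background, with a per-column pseudocount of
# sqrt(column total) by default. Relative score of a window is
# 100 * (raw - min) / (max - min) where min/max are the column-wise extreme
# sums. N bases contribute the column-minimum weight (mismatch-worst).
#
# Floating-point guard: threshold comparisons use rel >= t - 1e-9 and integer
# bucketing uses floor(rel + 1e-9), so that a consensus window whose relative
# score evaluates to 99.999...9 still counts at threshold 100.

.score_eps <- 1e-9

#' Convert a position frequency matrix to a position weight matrix
#'
#' @param pfm A `pfm` object.
#' @param pseudocount Either a function of the column total (default `sqrt`)
#'   or a fixed nonnegative number; the pseudocount is distributed over bases
#'   according to the background.
#' @param background Base composition of the null model (A, C, G, T); default
#'   uniform.
#' @return Object of class `pwm` with log2 weights, min/max raw scores and
#'   information content in bits (computed from raw frequencies, no
#'   pseudocount).
#' @export
pfm_to_pwm <- function(pfm, pseudocount = sqrt, background = rep(0.25, 4)) {
  stopifnot(inherits(pfm, "pfm"))
  counts <- pfm$counts
  L <- ncol(counts)
  totals <- colSums(counts)
  if (any(totals <= 0)) stopf("matrix %s: zero-total column", pfm$id)
  p <- if (is.function(pseudocount)) pseudocount(totals) else rep(pseudocount, L)
  w <- matrix(0, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) {
    freq <- (counts[, j] + p[j] * background) / (totals[j] + p[j])
    w[, j] <- log2(freq / background)
  }
  colmin <- apply(w, 2, min)
  colmax <- apply(w, 2, max)
  f <- sweep(counts, 2, totals, "/")
  plogp <- ifelse(f > 0, f * log2(f), 0)
  ic <- sum(2 + colSums(plogp))
  w5 <- rbind(w, N = colmin)
  # reverse-complement weights: complement rows, reverse columns; the N row
  # of the rc matrix is again the per-column minimum by symmetry
  w5_rc <- w5[c("T", "G", "C", "A", "N"), rev(seq_len(L)), drop = FALSE]
  rownames(w5_rc) <- c("A", "C", "G", "T", "N")
  structure(list(id = pfm$id, name = pfm$name, width = L, weights = w,
                 weights5 = w5, weights5_rc = w5_rc,
                 min_score = sum(colmin), max_score = sum(colmax),
                 info_content = ic,
                 degenerate = (sum(colmax) - sum(colmin)) < .score_eps),
            class = "pwm")
}

#' Consensus word of a matrix (argmax base per column, ties to A<C<G<T)
#' @param x A `pfm` or `pwm` object.
#' @return Character string of length equal to the matrix width.
#' @export
consensus_word <- function(x) {
  m <- if (inherits(x, "pfm")) x$counts else x$weights
  paste(rownames(m)[apply(m, 2, which.max)], collapse = "")
}

#' Relative score of a single window
#'
#' @param pwm A `pwm` object.
#' @param window String of length equal to the matrix width over A,C,G,T,N.
#' @return Percent in `[0, 100]`. A degenerate matrix (max == min raw score)
#'   scores every window 100 with a warning.
#' @export
relative_score <- function(pwm, window) {
  if (nchar(window) != pwm$width)
    stopf("window length %d != matrix width %d", nchar(window), pwm$width)
  if (pwm$degenerate) {
    warnf("matrix %s is degenerate (min == max score); relative score defined as 100", pwm$id)
    return(100)
  }
  idx <- encode_dna(window)
  raw <- sum(pwm$weights5[cbind(idx, seq_len(pwm$width))])
  100 * (raw - pwm$min_score) / (pwm$max_score - pwm$min_score)
}

# relative scores of every window on both strands; returns list(fwd, rev)
# of numeric vectors of length n - L + 1 (forward-coordinate offsets)
.window_rel_scores <- function(pwm, seq) {
  n <- nchar(seq)
  L <- pwm$width
  m <- n - L + 1L
  if (m < 1L) return(list(fwd = numeric(0), rev = numeric(0)))
  idx <- encode_dna(seq)
  W <- pwm$weights5
  Wrc <- pwm$weights5_rc
  raw_f <- numeric(m)
  raw_r <- numeric(m)
  for (j in seq_len(L)) {
    col <- idx[j:(j + m - 1L)]
    raw_f <- raw_f + W[col, j]
    raw_r <- raw_r + Wrc[col, j]
  }
  if (pwm$degenerate) {
    warnf("matrix %s is degenerate (min == max score); relative score defined as 100", pwm$id)
    return(list(fwd = rep(100, m), rev = rep(100, m)))
  }
  span <- pwm$max_score - pwm$min_score
  list(fwd = unname(100 * (raw_f - pwm$min_score) / span),
       rev = unname(100 * (raw_r - pwm$min_score) / span))
}

#' Scan a bare sequence with one matrix on both strands
#'
#' Reverse-strand matches are reported at the forward-coordinate offset of
#' the matched footprint. Ties at exactly the threshold are included.
#'
#' @param pwm A `pwm` object.
#' @param seq Sequence string (A,C,G,T,N).
#' @param threshold Relative-score threshold percent in `[60, 100]` (values
#'   down to 0 are accepted for diagnostic scans).
#' @return Data.frame with columns offset (0-based), strand, rel_score.
#' @export
scan_sequence <- function(pwm, seq, threshold) {
  rel <- .window_rel_scores(pwm, seq)
  thr <- threshold - .score_eps
  of <- which(rel$fwd >= thr)
  or <- which(rel$rev >= thr)
  out <- data.frame(
    offset = c(of, or) - 1L,
    strand = rep(c("+", "-"), c(length(of), length(or))),
    rel_score = c(rel$fwd[of], rel$rev[or]),
    stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan a promoter with one matrix
#'
#' Adds the per-hit mean conservation over the footprint and a coding flag
#' (any footprint base exonic) to each match.
#'
#' @param pwm A `pwm` object.
#' @param promoter A `promoter_sequence` from [extract_promoter()].
#' @param threshold Relative-score threshold percent.
#' @return Data.frame with columns matrix_id, gene_id, tss_index, offset,
#'   strand, rel_score, conservation, coding, width.
#' @export
scan_promoter <- function(pwm, promoter, threshold) {
  hits <- scan_sequence(pwm, promoter$seq, threshold)
  L <- pwm$width
  if (nrow(hits) == 0L) {
    return(data.frame(matrix_id = character(0), gene_id = character(0),
                      tss_index = integer(0), offset = integer(0),
                      strand = character(0), rel_score = numeric(0),
                      conservation = numeric(0), coding = logical(0),
                      width = integer(0), stringsAsFactors = FALSE))
  }
  cs <- c(0, cumsum(promoter$conservation))
  cb <- c(0L, cumsum(as.integer(promoter$coding)))
  o <- hits$offset  # 0-based; footprint covers indices o+1 .. o+L (1-based)
  data.frame(matrix_id = pwm$id, gene_id = promoter$gene_id,
             tss_index = promoter$tss_index, offset = o,
             strand = hits$strand, rel_score = hits$rel_score,
             conservation = (cs[o + L + 1L] - cs[o + 1L]) / L,
             coding = (cb[o + L + 1L] - cb[o + 1L]) > 0L,
             width = L, stringsAsFactors = FALSE)
}

#' Batch scan: all matrices over all promoters
#'
#' @param pwms List of `pwm` objects.
#' @param promoters List of `promoter_sequence` objects.
#' @param thresholds Either a single threshold or a named numeric vector
#'   keyed by matrix id.
#' @return One hit data.frame ordered by (matrix_id, gene_id, tss_index,
#'   offset, strand).
#' @export
scan_all <- function(pwms, promoters, thresholds) {
  parts <- list()
  for (pwm in pwms) {
    thr <- if (length(thresholds) == 1L && is.null(names(thresholds))) {
      thresholds
    } else {
      t <- thresholds[[pwm$id]]
      if (is.null(t) || is.na(t)) stopf("no threshold for matrix %s", pwm$id)
      t
    }
    for (pr in promoters) {
      parts[[length(parts) + 1L]] <- scan_promoter(pwm, pr, thr)
    }
  }
  out <- if (length(parts) > 0L) {
    do.call(rbind, parts)
  } else {
    data.frame(matrix_id = character(0), gene_id = character(0),
               tss_index = integer(0), offset = integer(0),
               strand = character(0), rel_score = numeric(0),
               conservation = numeric(0), coding = logical(0),
               width = integer(0), stringsAsFactors = FALSE)
  }
  out[order(out$matrix_id, out$gene_id, out$tss_index, out$offset, out$strand),
      , drop = FALSE]
}
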