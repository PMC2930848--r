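# Independent brute-force oracles. These deliberately avoid the package's
# vectorized scanning/bucketing code paths: scores are recomputed per window
# with scalar loops over an explicitly reverse-complemented sequence.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# raw log-odds score of one window under a pwm, scalar loop; N scores the
# column minimum
oracle_raw_score <- function(pwm, window) {
  chars <- strsplit(window, "")[[1]]
  total <- 0
  for (j in seq_along(chars)) {
    b <- chars[j]
    total <- total + if (b %in% c("A", "C", "G", "T")) {
      pwm$weights[b, j]
    } else {
      min(pwm$weights[, j])
    }
  }
  unname(total)
}

oracle_rel_score <- function(pwm, window) {
  100 * (oracle_raw_score(pwm, window) - pwm$min_score) /
    (pwm$max_score - pwm$min_score)
}

# naive both-strand scan; reverse-strand windows are taken from the
# reverse-complemented sequence and mapped back to forward offsets
oracle_scan <- function(pwm, seq, threshold) {
  n <- nchar(seq)
  L <- pwm$width
  if (n < L) {
    return(data.frame(offset = integer(0), strand = character(0),
                      rel_score = numeric(0), stringsAsFactors = FALSE))
  }
  rc <- oracle_revcomp(seq)
  rows <- list()
  for (o in 0:(n - L)) {
    w <- substr(seq, o + 1, o + L)
    r <- oracle_rel_score(pwm, w)
    if (r >= threshold - 1e-9) {
      rows[[length(rows) + 1L]] <- data.frame(offset = o, strand = "+",
                                              rel_score = r)
    }
    wr <- substr(rc, n - L - o + 1, n - o)  # rc window at forward offset o
    rr <- oracle_rel_score(pwm, wr)
    if (rr >= threshold - 1e-9) {
      rows[[length(rows) + 1L]] <- data.frame(offset = o, strand = "-",
                                              rel_score = rr)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(offset = integer(0), strand = character(0),
               rel_score = numeric(0))
  out[order(out$offset, out$strand), , drop = FALSE]
}

# per-character window stats for CpG checks
oracle_window_stats <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  nC <- sum(chars == "C")
  nG <- sum(chars == "G")
  nCG <- 0
  for (i in seq_len(n - 1)) {
    if (chars[i] == "C" && chars[i + 1] == "G") nCG <- nCG + 1
  }
  list(gc_pct = 100 * (nC + nG) / n,
       obs_exp = if (nC == 0 || nG == 0) 0 else nCG * n / (nC * nG))
}

random_dna <- function(n, seed, probs = rep(0.25, 4)) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
          collapse = "")
  })
}

toy_pwms <- function(seed = 101, n = 5, widths = c(4, 6, 8, 10, 12)) {
  pfms <- make_decoy_pwms(max(3L, n), widths = widths, seed = seed)
  lapply(pfms[seq_len(n)], pfm_to_pwm)
}

# single toy matrix of a given width
one_pwm <- function(width, seed) toy_pwms(seed = seed, n = 1, widths = width)[[1]]
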