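# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open; R string/vector indexing is converted at the
# last possible moment.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# byte lookup: A/a=1 C/c=2 G/g=3 T/t=4, anything else (incl. N)=5
.dna_lut <- local({
  l <- rep(5L, 256L)
  l[utf8ToInt("A")] <- 1L; l[utf8ToInt("a")] <- 1L
  l[utf8ToInt("C")] <- 2L; l[utf8ToInt("c")] <- 2L
  l[utf8ToInt("G")] <- 3L; l[utf8ToInt("g")] <- 3L
  l[utf8ToInt("T")] <- 4L; l[utf8ToInt("t")] <- 4L
  l
})

# encode a DNA string as integers 1..5 (5 = N / unknown)
encode_dna <- function(s) {
  if (!nzchar(s)) return(integer(0))
  .dna_lut[as.integer(charToRaw(s))]
}

# reverse complement of an ACGTN string (case preserved for ACGT upper only)
revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", s))))
}

# deterministic child seed derived from (seed, tag); stays below 2^31
split_seed <- function(seed, tag) {
  h <- 5381
  for (k in utf8ToInt(as.character(tag))) h <- (h * 33 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) withr::with_seed(seed, code)

# substring of a chromosome, 0-based half-open coordinates
seq_slice <- function(chrom_seq, start, end) {
  if (end <= start) return("")
  substr(chrom_seq, start + 1L, end)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Oriented window around a genomic anchor `pos` (0-based) on `strand`:
# covers `up` bases 5' of the anchor and `down` bases from the anchor
# downstream (anchor base itself is the first downstream base). Truncated,
# never padded, at chromosome ends.
oriented_window_coords <- function(pos, strand, up, down, chrom_len) {
  if (strand == "+") {
    start <- pos - up
    end <- pos + down
  } else {
    start <- pos - down + 1
    end <- pos + up + 1
  }
  start_c <- max(0, start)
  end_c <- min(chrom_len, end)
  if (end_c < start_c) end_c <- start_c
  if (strand == "+") {
    up_eff <- pos - start_c
    down_eff <- end_c - pos
  } else {
    up_eff <- end_c - pos - 1
    down_eff <- pos - start_c + 1
  }
  # anchor outside chromosome: degenerate empty window
  if (pos < 0 || pos >= chrom_len) {
    up_eff <- max(0, up_eff)
    down_eff <- max(0, down_eff)
  }
  list(start = start_c, end = end_c, up_eff = up_eff, down_eff = down_eff)
}

orient_seq <- function(s, strand) if (strand == "-") revcomp(s) else s
orient_vec <- function(v, strand) if (strand == "-") rev(v) else v
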