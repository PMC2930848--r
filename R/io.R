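# Readers and writers for every external format the engine touches, plus the
# run configuration. All dialects are plain text; coordinates are 0-based
# half-open throughout, so BED export needs no shifts.

#' Read a genome from a FASTA file
#'
#' Sequences must be over the alphabet A, C, G, T, N (case-insensitive);
#' they are returned uppercased, keyed by the first whitespace-delimited
#' token of each record header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) {
        line <- .first_bad_fasta_line(path)
        stopf("malformed FASTA at %s line %d: %s", path, line, conditionMessage(e))
      }
    ),
    # Biostrings silently drops invalid letters with a warning; that is a
    # parse error under the ACGTN contract
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        line <- .first_bad_fasta_line(path)
        stopf("malformed FASTA at %s line %d: invalid sequence character",
              path, line)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(set) == 0L) stopf("malformed FASTA at %s line 1: no records", path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    line <- .first_bad_fasta_line(path)
    stopf("malformed FASTA at %s line %d: non-ACGTN character", path, line)
  }
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

.first_bad_fasta_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(1L)
  for (i in seq_along(lines)) {
    l <- lines[[i]]
    if (!nzchar(l) || startsWith(l, ">")) next
    if (grepl("[^ACGTNacgtn]", l)) return(i)
  }
  1L
}

#' Write a genome to a FASTA file
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct a position frequency matrix
#'
#' @param id Matrix identifier.
#' @param name Factor name.
#' @param counts 4 x L nonnegative numeric matrix, rows A, C, G, T.
#' @return Object of class `pfm`.
#' @export
new_pfm <- function(id, name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stopf("PFM %s: counts must have 4 rows (A,C,G,T)", id)
  if (ncol(counts) < 1L) stopf("PFM %s: zero-width matrix", id)
  if (any(counts < 0)) stopf("PFM %s: negative counts", id)
  if (any(colSums(counts) <= 0)) stopf("PFM %s: zero-total column", id)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(id = id, name = name, counts = counts), class = "pfm")
}

#' Read JASPAR-format position frequency matrices
#'
#' Each record is a `>ID name` header followed by four labelled count rows
#' (A, C, G, T), with or without the JASPAR 2016 bracket style.
#'
#' @param path Path to a JASPAR PFM text file.
#' @return List of `pfm` objects.
#' @export
read_jaspar_pfms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty PFM file: %s", path)
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0L) stopf("no matrix records in %s", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1L) paste(toks[-1], collapse = " ") else id
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    rows <- list()
    for (l in body) {
      toks <- strsplit(trimws(gsub("[][]", " ", l)), "\\s+")[[1]]
      base <- toupper(toks[1])
      if (!base %in% c("A", "C", "G", "T"))
        stopf("matrix %s: unexpected row label '%s'", id, toks[1])
      vals <- suppressWarnings(as.numeric(toks[-1]))
      if (anyNA(vals)) stopf("matrix %s: non-numeric count in row %s", id, base)
      rows[[base]] <- vals
    }
    missing <- setdiff(c("A", "C", "G", "T"), names(rows))
    if (length(missing) > 0L)
      stopf("matrix %s: missing base row(s) %s", id, paste(missing, collapse = ","))
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) != 1L)
      stopf("matrix %s: row-length mismatch (%s)", id,
            paste(lens[c("A", "C", "G", "T")], collapse = ","))
    counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
    out[[i]] <- new_pfm(id, name, counts)
  }
  out
}

#' Write position frequency matrices in JASPAR format
#' @param pfms List of `pfm` objects.
#' @param path Output path.
#' @export
write_jaspar_pfms <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a transcript annotation table
#'
#' Dialect: tab-delimited with header columns gene_id, transcript_id, chrom,
#' strand, tx_start, tx_end, exon_starts, exon_ends (exon columns are
#' comma-joined 0-based half-open coordinates). One row per transcript.
#'
#' @param path Path to the annotation table.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   validate coordinates.
#' @return A data.frame of class `genome_annotation` with list columns
#'   `exon_starts` and `exon_ends`.
#' @export
read_annotation <- function(path, chrom_lengths = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = c(
                                          "gene_id", "transcript_id", "chrom",
                                          "strand", "exon_starts", "exon_ends"))))
  need <- c("gene_id", "transcript_id", "chrom", "strand", "tx_start",
            "tx_end", "exon_starts", "exon_ends")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stopf("annotation %s: missing column(s) %s", path, paste(missing, collapse = ","))
  df$exon_starts <- lapply(strsplit(as.character(df$exon_starts), ","),
                           function(x) as.integer(x[nzchar(x)]))
  df$exon_ends <- lapply(strsplit(as.character(df$exon_ends), ","),
                         function(x) as.integer(x[nzchar(x)]))
  new_annotation(df, chrom_lengths = chrom_lengths)
}

#' Validate and classify an annotation data.frame
#' @param df Transcript table (see [read_annotation()] for columns).
#' @param chrom_lengths Optional named chromosome lengths for bounds checks.
#' @return The validated `genome_annotation` data.frame.
#' @export
new_annotation <- function(df, chrom_lengths = NULL) {
  if (!all(df$strand %in% c("+", "-")))
    stopf("annotation: strand must be '+' or '-'")
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    if (length(es) != length(ee))
      stopf("annotation record %s: exon start/end count mismatch", df$transcript_id[i])
    if (length(es) > 0L &&
        (any(es < df$tx_start[i]) || any(ee > df$tx_end[i]) || any(ee <= es)))
      stopf("annotation record %s: exon outside transcript bounds", df$transcript_id[i])
    if (df$tx_end[i] <= df$tx_start[i])
      stopf("annotation record %s: tx_end <= tx_start", df$transcript_id[i])
    if (!is.null(chrom_lengths)) {
      len <- chrom_lengths[[df$chrom[i]]]
      if (is.null(len) || is.na(len))
        stopf("annotation record %s: unknown chromosome %s",
              df$transcript_id[i], df$chrom[i])
      if (df$tx_start[i] < 0 || df$tx_end[i] > len)
        stopf("annotation record %s: coordinates outside chromosome %s",
              df$transcript_id[i], df$chrom[i])
    }
  }
  class(df) <- c("genome_annotation", "data.frame")
  df
}

#' Write a transcript annotation table
#' @param ann `genome_annotation` data.frame.
#' @param path Output path.
#' @export
write_annotation <- function(ann, path) {
  out <- data.frame(
    gene_id = ann$gene_id, transcript_id = ann$transcript_id,
    chrom = ann$chrom, strand = ann$strand,
    tx_start = ann$tx_start, tx_end = ann$tx_end,
    exon_starts = vapply(ann$exon_starts, paste, "", collapse = ","),
    exon_ends = vapply(ann$exon_ends, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# 5'-most base of each gene in gene orientation (the "gene start")
gene_starts <- function(ann) {
  sp <- split(seq_len(nrow(ann)), ann$gene_id)
  rows <- lapply(names(sp), function(g) {
    idx <- sp[[g]]
    strand <- ann$strand[idx[1]]
    gs <- if (strand == "+") min(ann$tx_start[idx]) else max(ann$tx_end[idx]) - 1L
    data.frame(gene_id = g, chrom = ann$chrom[idx[1]], strand = strand,
               gene_start = gs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[match(unique(ann$gene_id), out$gene_id), , drop = FALSE]
}

#' Read a per-base conservation track
#'
#' Two dialects are supported: a tab-delimited table with header columns
#' chrom, pos (0-based), score; or fixed-step wiggle blocks
#' (`fixedStep chrom=... start=... step=...` with 1-based starts). Bases not
#' covered by the file carry score 0.
#'
#' @param path Path to the track file.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A `conservation_track`: named list of numeric vectors in `[0,1]`.
#' @export
read_conservation <- function(path, chrom_lengths) {
  track <- lapply(chrom_lengths, function(n) numeric(n))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 1L && grepl("^fixedStep", first)) {
    lines <- readLines(path, warn = FALSE)
    chrom <- NULL; pos <- NA_integer_; step <- 1L
    for (i in seq_along(lines)) {
      l <- trimws(lines[[i]])
      if (!nzchar(l)) next
      if (startsWith(l, "fixedStep")) {
        chrom <- sub(".*chrom=([^ ]+).*", "\\1", l)
        pos <- as.integer(sub(".*start=([0-9]+).*", "\\1", l)) - 1L  # wig 1-based
        step <- if (grepl("step=", l)) as.integer(sub(".*step=([0-9]+).*", "\\1", l)) else 1L
        if (is.null(track[[chrom]])) stopf("conservation line %d: unknown chromosome %s", i, chrom)
      } else {
        v <- as.numeric(l)
        .check_cons_value(v, i, path)
        if (pos < 0 || pos >= length(track[[chrom]]))
          stopf("conservation line %d: position %d outside chromosome %s", i, pos, chrom)
        track[[chrom]][pos + 1L] <- v
        pos <- pos + step
      }
    }
  } else {
    df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                          colClasses = list(character = "chrom")))
    need <- c("chrom", "pos", "score")
    if (!all(need %in% names(df)))
      stopf("conservation %s: expected columns chrom, pos, score", path)
    for (chrom in unique(df$chrom)) {
      if (is.null(track[[chrom]]))
        stopf("conservation record: unknown chromosome %s", chrom)
      sub <- df[df$chrom == chrom, ]
      if (any(sub$score < 0 | sub$score > 1))
        stopf("conservation record on %s: score outside [0,1]", chrom)
      if (any(sub$pos < 0 | sub$pos >= length(track[[chrom]])))
        stopf("conservation record on %s: position outside chromosome", chrom)
      track[[chrom]][sub$pos + 1L] <- sub$score
    }
  }
  structure(track, class = "conservation_track")
}

.check_cons_value <- function(v, line, path) {
  if (is.na(v) || v < 0 || v > 1)
    stopf("conservation %s line %d: score outside [0,1]", path, line)
}

#' Write a conservation track (tab-delimited dialect)
#' @param track `conservation_track` list.
#' @param path Output path.
#' @param nonzero_only Write only bases with score > 0 (default); uncovered
#'   bases are implicitly 0 on read.
#' @export
write_conservation <- function(track, path, nonzero_only = TRUE) {
  parts <- lapply(names(track), function(chrom) {
    v <- track[[chrom]]
    idx <- if (nonzero_only) which(v > 0) else seq_along(v)
    if (length(idx) == 0L) return(NULL)
    data.frame(chrom = chrom, pos = idx - 1L, score = v[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(chrom = character(0), pos = integer(0),
                                      score = numeric(0))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a CAGE tag-cluster table
#'
#' Dialect: tab-delimited with header columns chrom, strand, start, end,
#' tag_counts (comma-joined per-position counts, length end-start) and tpms
#' (comma-joined per-tissue TPM values, optionally `tissue=value` pairs).
#'
#' @param path Path to the cluster table.
#' @param chrom_lengths Optional named chromosome lengths for bounds checks.
#' @return Data.frame of class `cage_clusters` with list columns `counts`
#'   and `tpms`.
#' @export
read_cage_clusters <- function(path, chrom_lengths = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = c(
                                          "chrom", "strand", "tag_counts", "tpms"))))
  need <- c("chrom", "strand", "start", "end", "tag_counts", "tpms")
  if (!all(need %in% names(df)))
    stopf("CAGE table %s: expected columns %s", path, paste(need, collapse = ", "))
  df$counts <- lapply(strsplit(df$tag_counts, ","), as.numeric)
  df$tpms <- lapply(strsplit(df$tpms, ","), function(x) {
    as.numeric(sub("^[^=]*=", "", x))
  })
  df$tag_counts <- NULL
  for (i in seq_len(nrow(df))) {
    if (df$end[i] <= df$start[i])
      stopf("CAGE record %d: end <= start", i)
    if (length(df$counts[[i]]) != df$end[i] - df$start[i])
      stopf("CAGE record %d: tag_counts length != cluster width", i)
    if (any(df$counts[[i]] < 0))
      stopf("CAGE record %d: negative tag count", i)
    if (!df$strand[i] %in% c("+", "-"))
      stopf("CAGE record %d: bad strand", i)
    if (!is.null(chrom_lengths)) {
      len <- chrom_lengths[[df$chrom[i]]]
      if (is.null(len) || df$start[i] < 0 || df$end[i] > len)
        stopf("CAGE record %d: coordinates outside chromosome %s", i, df$chrom[i])
    }
  }
  class(df) <- c("cage_clusters", "data.frame")
  df
}

#' Write a CAGE tag-cluster table
#' @param clusters `cage_clusters` data.frame.
#' @param path Output path.
#' @export
write_cage_clusters <- function(clusters, path) {
  out <- data.frame(
    chrom = clusters$chrom, strand = clusters$strand,
    start = clusters$start, end = clusters$end,
    tag_counts = vapply(clusters$counts, paste, "", collapse = ","),
    tpms = vapply(clusters$tpms, function(x) paste(format(x, trim = TRUE),
                                                   collapse = ","), ""),
    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one id per line)
#' @param path Path to the list.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write a plain-text gene list
#' @param genes Character vector of gene ids.
#' @param path Output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

.coding_modes <- c("coding", "noncoding", "both")
.background_types <- c("random", "core", "conserved")
.tss_modes <- c("all", "most_distal", "highest_tpm", "with_cpg", "without_cpg")

#' Build a run configuration
#'
#' @param conservation_threshold Conservation percentage in `[60, 90]`; hits
#'   (and bases, for the effective length) below this per-base conservation
#'   are discarded.
#' @param top_percent_conserved Keep only this top percentage (by
#'   conservation) of surviving hits per promoter, in `[1, 100]`.
#' @param max_conserved_tfbs Cap on hits per promoter (most conserved kept);
#'   `Inf` means unlimited.
#' @param coding_mode One of `"coding"`, `"noncoding"`, `"both"`.
#' @param upstream_len Bases upstream of the TSS analyzed, `[0, 10000]`.
#' @param downstream_len Bases downstream of the TSS analyzed, `[0, 5000]`.
#' @param random_occurrence Target random hit rate, expected hits per Mbp of
#'   background; the supported range 1 hit/Mbp .. 1 hit/100 bp maps to
#'   `[1, 10000]`.
#' @param background_type One of `"random"`, `"core"`, `"conserved"`.
#' @param tss_mode One of `"all"`, `"most_distal"`, `"highest_tpm"`,
#'   `"with_cpg"`, `"without_cpg"`.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(conservation_threshold = 60,
                       top_percent_conserved = 100,
                       max_conserved_tfbs = Inf,
                       coding_mode = "both",
                       upstream_len = 10000,
                       downstream_len = 5000,
                       random_occurrence = 100,
                       background_type = "random",
                       tss_mode = "all") {
  cfg <- list(conservation_threshold = as.numeric(conservation_threshold),
              top_percent_conserved = as.numeric(top_percent_conserved),
              max_conserved_tfbs = as.numeric(max_conserved_tfbs),
              coding_mode = coding_mode,
              upstream_len = as.numeric(upstream_len),
              downstream_len = as.numeric(downstream_len),
              random_occurrence = as.numeric(random_occurrence),
              background_type = background_type,
              tss_mode = tss_mode)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stopf("run_config: %s", msg)
  chk(is_scalar_number(cfg$conservation_threshold) &&
        cfg$conservation_threshold >= 60 && cfg$conservation_threshold <= 90,
      "conservation_threshold must be in [60, 90]")
  chk(is_scalar_number(cfg$top_percent_conserved) &&
        cfg$top_percent_conserved >= 1 && cfg$top_percent_conserved <= 100,
      "top_percent_conserved must be in [1, 100]")
  chk(is.numeric(cfg$max_conserved_tfbs) && length(cfg$max_conserved_tfbs) == 1L &&
        (is.infinite(cfg$max_conserved_tfbs) ||
           (cfg$max_conserved_tfbs >= 1 &&
              cfg$max_conserved_tfbs == floor(cfg$max_conserved_tfbs))),
      "max_conserved_tfbs must be a positive integer or Inf")
  chk(cfg$coding_mode %in% .coding_modes,
      sprintf("coding_mode must be one of %s", paste(.coding_modes, collapse = ", ")))
  chk(is_scalar_number(cfg$upstream_len) &&
        cfg$upstream_len >= 0 && cfg$upstream_len <= 10000,
      "upstream_len must be in [0, 10000]")
  chk(is_scalar_number(cfg$downstream_len) &&
        cfg$downstream_len >= 0 && cfg$downstream_len <= 5000,
      "downstream_len must be in [0, 5000]")
  chk(is_scalar_number(cfg$random_occurrence) &&
        cfg$random_occurrence >= 1 && cfg$random_occurrence <= 10000,
      "random_occurrence must be in [1, 10000] hits per Mbp")
  chk(cfg$background_type %in% .background_types,
      sprintf("background_type must be one of %s", paste(.background_types, collapse = ", ")))
  chk(cfg$tss_mode %in% .tss_modes,
      sprintf("tss_mode must be one of %s", paste(.tss_modes, collapse = ", ")))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat key=value file
#'
#' Keys equal the CLI flag names; `max_conserved_tfbs` accepts `unlimited`.
#' @param path Path to the config file.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stopf("config %s: malformed line '%s'", path, lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  cfg <- as.list(formals(run_config))
  cfg <- lapply(cfg, eval)
  unknown <- setdiff(keys, names(cfg))
  if (length(unknown) > 0L)
    stopf("config %s: unknown key(s) %s", path, paste(unknown, collapse = ", "))
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    cfg[[k]] <- if (k %in% c("coding_mode", "background_type", "tss_mode")) {
      v
    } else if (k == "max_conserved_tfbs" && v %in% c("unlimited", "Inf")) {
      Inf
    } else {
      as.numeric(v)
    }
  }
  do.call(run_config, cfg)
}

#' Write a run configuration to a flat key=value file
#' @param cfg `run_config` object.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- function(k) {
    v <- cfg[[k]]
    if (k == "max_conserved_tfbs" && is.infinite(v)) return("unlimited")
    if (is.numeric(v)) format(v, trim = TRUE, scientific = FALSE) else as.character(v)
  }
  writeLines(vapply(names(cfg), function(k) paste0(k, "=", fmt(k)), ""), path)
  invisible(path)
}

#' Write TFBS hits as BED6
#'
#' chrom is `gene_id|tss_index`, start/end are promoter offsets (0-based
#' half-open), name is the matrix id, score is the relative score times 10
#' (rounded), strand is the match strand relative to promoter orientation.
#'
#' @param hits Hit data.frame from [scan_promoter()] / [scan_all()].
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, path) {
  out <- data.frame(
    chrom = paste0(hits$gene_id, "|", hits$tss_index),
    start = hits$offset,
    end = hits$offset + hits$width,
    name = hits$matrix_id,
    score = round(hits$rel_score * 10),
    strand = hits$strand, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write CpG islands as BED4 plus stats columns
#' @param islands Island data.frame (with gene_id/tss_index columns).
#' @param path Output path.
#' @export
write_islands_bed <- function(islands, path) {
  name <- paste0(islands$gene_id, "|", islands$tss_index)
  out <- data.frame(chrom = name, start = islands$start, end = islands$end,
                    name = name, gc_pct = islands$gc_pct,
                    obs_exp = islands$obs_exp, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write selected TSS records as BED6
#'
#' Score is the rounded TPM; the no-CAGE sentinel (-1) is encoded as score 0
#' with a `|noTPM` flag appended to the name.
#' @param tss TSS data.frame from [cluster_tss()].
#' @param path Output path.
#' @export
write_tss_bed <- function(tss, path) {
  flag <- ifelse(tss$tpm < 0, "|noTPM", "")
  out <- data.frame(
    chrom = tss$chrom, start = tss$position, end = tss$position + 1L,
    name = paste0(tss$gene_id, "|", tss$tss_index, flag),
    score = pmax(0, round(tss$tpm)), strand = tss$strand,
    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a background frequency table
#' @param tbl `bg_freq_table` data.frame from [compute_frequency_table()].
#' @param path Output path.
#' @export
write_bg_freq_table <- function(tbl, path) {
  out <- data.frame(matrix_id = tbl$matrix_id, threshold = tbl$threshold,
                    hits_per_mbp = tbl$hits_per_mbp,
                    background_type = attr(tbl, "background_type"),
                    total_length = attr(tbl, "total_length"),
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a background frequency table
#' @param path Path written by [write_bg_freq_table()].
#' @return `bg_freq_table` data.frame.
#' @export
read_bg_freq_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = c(
                                          "matrix_id", "background_type"))))
  tbl <- df[, c("matrix_id", "threshold", "hits_per_mbp")]
  attr(tbl, "background_type") <- df$background_type[1]
  attr(tbl, "total_length") <- df$total_length[1]
  class(tbl) <- c("bg_freq_table", "data.frame")
  tbl
}
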