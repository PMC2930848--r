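# Deterministic synthetic toy genomes for testing and benchmarking: genes on
# both strands with 1-4 alternative TSSs, exonic masks, CpG-rich island
# blocks over a CpG-depleted background, elevated-conservation stretches,
# CAGE tag clusters, and planted motif instances. All randomness flows from
# one seed through per-component child seeds, so adding genes never perturbs
# earlier genes' sequences.

#' Describe a synthetic genome fixture
#'
#' Defaults describe the standard benchmark scale: 50 genes over 2
#' chromosomes with 16-kb gene spacing (room for full 10 kb + 5 kb promoter
#' windows), base GC fraction 0.5 matching the equal-nucleotide random
#' background model, a CpG-depleted intergenic background, 600-bp CpG-island
#' blocks at GC 0.7 on island-bearing genes, conservation 0.2 background
#' with a 500-bp 0.9 stretch in each promoter, and CAGE clusters on a subset
#' of genes.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes.
#' @param gene_spacing Distance between gene anchors in bp.
#' @param gc Background GC fraction.
#' @param island_prob Probability a gene carries a CpG island block.
#' @param island_len Island block length in bp.
#' @param island_gc Island block GC fraction.
#' @param cons_background Baseline conservation level.
#' @param cons_level Conservation inside the elevated promoter stretch.
#' @param cons_run_len Length of the elevated stretch (bp), placed at
#'   TSS-relative `[-600, -600 + cons_run_len)`.
#' @param cage_prob Probability a gene's primary TSS has a CAGE cluster.
#' @param cage_width CAGE cluster width in bp.
#' @param tpm_max Upper bound of the uniform per-tissue TPM draw.
#' @param seed Mandatory integer seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 50L, n_chroms = 2L, gene_spacing = 16000L,
                         gc = 0.5, island_prob = 0.5, island_len = 600L,
                         island_gc = 0.7, cons_background = 0.2,
                         cons_level = 0.9, cons_run_len = 500L,
                         cage_prob = 0.6, cage_width = 8L, tpm_max = 50,
                         seed) {
  if (missing(seed)) stopf("fixture_spec: seed is mandatory")
  probs <- c(island_prob, cage_prob)
  if (any(probs < 0 | probs > 1)) stopf("fixture_spec: probabilities must be in [0,1]")
  if (gene_spacing < 6000L) stopf("fixture_spec: gene_spacing below 6000 bp would overlap genes")
  structure(list(n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
                 gene_spacing = as.integer(gene_spacing), gc = gc,
                 island_prob = island_prob, island_len = as.integer(island_len),
                 island_gc = island_gc, cons_background = cons_background,
                 cons_level = cons_level, cons_run_len = as.integer(cons_run_len),
                 cage_prob = cage_prob, cage_width = as.integer(cage_width),
                 tpm_max = tpm_max, seed = as.integer(seed)),
            class = "fixture_spec")
}

# exact-composition random DNA: the requested GC fraction holds exactly
# (up to rounding), then CpG dinucleotides are depleted by composition-
# preserving swaps so the Gardiner-Garden obs/exp test genuinely fails on
# background sequence, as in real intergenic DNA
.random_dna_depleted <- function(n, gc, seed, deplete = TRUE) {
  with_seed(seed, {
    n_gc <- round(n * gc)
    n_g <- n_gc %/% 2L
    n_c <- n_gc - n_g
    n_at <- n - n_gc
    n_a <- n_at %/% 2L
    n_t <- n_at - n_a
    v <- sample(rep(c("A", "C", "G", "T"), c(n_a, n_c, n_g, n_t)))
    if (deplete) {
      for (pass in 1:4) {
        cg <- which(v[-n] == "C" & v[-1L] == "G")
        if (length(cg) < max(2L, n %/% 5000L)) break
        at <- which(v %in% c("A", "T"))
        at <- at[!(at %in% (cg + 1L))]
        k <- min(length(cg), length(at))
        if (k < 1L) break
        tgt <- sample(at, k)
        src <- cg[seq_len(k)] + 1L  # the G of each CpG
        tmp <- v[tgt]
        v[tgt] <- v[src]
        v[src] <- tmp
      }
    }
    paste(v, collapse = "")
  })
}

# island block: iid GC-rich sequence (obs/exp ~ 1 by construction)
.island_block <- function(len, gc, seed) {
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  })
}

.replace_slice <- function(chrom_seq, start, replacement) {
  # 0-based start
  substr(chrom_seq, start + 1L, start + nchar(replacement)) <- replacement
  chrom_seq
}

#' Generate a synthetic genome bundle
#'
#' Builds chromosome sequences, a transcript annotation (genes on both
#' strands, TSS counts cycling 1,2,3,4 so at least one gene always has four
#' alternative TSSs), a conservation track, CAGE clusters, and per-gene
#' metadata. Deterministic given the spec seed; optionally writes the bundle
#' files (genome.fa, annotation.tsv, conservation.tsv, cage.tsv) in the
#' package dialects.
#'
#' @param spec `fixture_spec`.
#' @param out_dir Optional output directory for the bundle files.
#' @return List of class `fixture_bundle`: genome, annotation, conservation,
#'   cage, genes (metadata), spec, paths.
#' @export
make_genome <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  margin <- 12000L
  per_chrom <- ceiling(spec$n_genes / spec$n_chroms)
  chrom_len <- per_chrom * spec$gene_spacing + 2L * margin
  chrom_names <- paste0("chr", seq_len(spec$n_chroms))
  genome <- setNames(vapply(seq_len(spec$n_chroms), function(ci) {
    .random_dna_depleted(chrom_len, spec$gc,
                         split_seed(spec$seed, paste0("chrom", ci)))
  }, ""), chrom_names)
  cons <- setNames(lapply(seq_len(spec$n_chroms), function(ci) {
    with_seed(split_seed(spec$seed, paste0("consbg", ci)), {
      pmin(0.99, pmax(0.01, spec$cons_background +
                        stats::runif(chrom_len, -0.05, 0.05)))
    })
  }), chrom_names)

  ann_rows <- list()
  cage_rows <- list()
  gene_meta <- list()
  tss_spacing <- 800L
  gene_len <- 4000L
  for (gi in seq_len(spec$n_genes)) {
    ci <- ((gi - 1L) %% spec$n_chroms) + 1L
    slot <- (gi - 1L) %/% spec$n_chroms
    chrom <- chrom_names[ci]
    base <- margin + slot * spec$gene_spacing
    strand <- if (gi %% 2L == 1L) "+" else "-"
    n_tss <- ((gi - 1L) %% 4L) + 1L
    gene_id <- sprintf("G%03d", gi)
    # P0 = most distal (5'-most) TSS; TSS j moves 3' by tss_spacing steps
    if (strand == "+") {
      p0 <- base
      tss_pos <- p0 + (seq_len(n_tss) - 1L) * tss_spacing
      gene_end3 <- p0 + gene_len
    } else {
      p0 <- base + gene_len
      tss_pos <- p0 - (seq_len(n_tss) - 1L) * tss_spacing
      gene_end3 <- base
    }
    for (j in seq_len(n_tss)) {
      tid <- sprintf("%s.T%d", gene_id, j)
      if (strand == "+") {
        tx_start <- tss_pos[j]; tx_end <- gene_end3
        es <- c(tx_start, tx_end - 400L)
        ee <- c(tx_start + 200L, tx_end)
      } else {
        tx_start <- gene_end3; tx_end <- tss_pos[j] + 1L
        es <- c(tx_start, tx_end - 200L)
        ee <- c(tx_start + 400L, tx_end)
      }
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = gene_id, transcript_id = tid, chrom = chrom,
        strand = strand, tx_start = tx_start, tx_end = tx_end,
        exon_starts = I(list(es)), exon_ends = I(list(ee)),
        stringsAsFactors = FALSE)
    }
    # elevated conservation stretch in every TSS promoter: oriented
    # [-600, -600 + run_len)
    for (j in seq_len(n_tss)) {
      run <- spec$cons_run_len
      if (strand == "+") {
        a <- tss_pos[j] - 600L
        b <- a + run
      } else {
        b <- tss_pos[j] + 600L + 1L
        a <- b - run
      }
      a <- max(0L, a); b <- min(chrom_len, b)
      if (b > a) {
        lvl <- with_seed(split_seed(spec$seed, paste0("consrun", gi, ".", j)), {
          pmin(0.99, spec$cons_level + stats::runif(b - a, -0.03, 0.03))
        })
        cons[[chrom]][(a + 1L):b] <- lvl
      }
    }
    has_island <- with_seed(split_seed(spec$seed, paste0("isl", gi)), {
      stats::runif(1) < spec$island_prob
    })
    if (has_island) {
      block <- .island_block(spec$island_len, spec$island_gc,
                             split_seed(spec$seed, paste0("islseq", gi)))
      # island covers the primary TSS: oriented [-200, island_len - 200)
      if (strand == "+") a <- tss_pos[1] - 200L else
        a <- tss_pos[1] + 200L - spec$island_len + 1L
      a <- max(0L, min(a, chrom_len - spec$island_len))
      genome[[chrom]] <- .replace_slice(genome[[chrom]], a, block)
    }
    has_cage <- with_seed(split_seed(spec$seed, paste0("cage", gi)), {
      stats::runif(1) < spec$cage_prob
    })
    if (has_cage) {
      w <- spec$cage_width
      cstart <- tss_pos[1] - w %/% 2L
      seedc <- split_seed(spec$seed, paste0("cageclu", gi))
      cage_rows[[length(cage_rows) + 1L]] <- with_seed(seedc, {
        counts <- stats::rpois(w, 2) + 1
        counts[w %/% 2L + 1L] <- max(counts) + stats::rpois(1, 20) + 5
        data.frame(chrom = chrom, strand = strand, start = cstart,
                   end = cstart + w,
                   counts = I(list(counts)),
                   tpms = I(list(round(stats::runif(2, 0.5, spec$tpm_max), 2))),
                   stringsAsFactors = FALSE)
      })
    }
    gene_meta[[gi]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                  strand = strand, n_tss = n_tss,
                                  primary_tss = tss_pos[1],
                                  has_island = has_island,
                                  has_cage = has_cage,
                                  stringsAsFactors = FALSE)
  }
  annotation <- new_annotation(do.call(rbind, ann_rows))
  cage <- if (length(cage_rows) > 0L) {
    df <- do.call(rbind, cage_rows)
    class(df) <- c("cage_clusters", "data.frame")
    df
  } else NULL
  class(cons) <- "conservation_track"
  bundle <- structure(list(genome = genome, annotation = annotation,
                           conservation = cons, cage = cage,
                           genes = do.call(rbind, gene_meta), spec = spec,
                           paths = NULL),
                      class = "fixture_bundle")
  if (!is.null(out_dir)) bundle <- write_bundle(bundle, out_dir)
  bundle
}

#' Write a fixture bundle to disk in the package dialects
#' @param bundle `fixture_bundle`.
#' @param out_dir Output directory.
#' @return The bundle with `paths` filled.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                annotation = file.path(out_dir, "annotation.tsv"),
                conservation = file.path(out_dir, "conservation.tsv"),
                cage = file.path(out_dir, "cage.tsv"))
  write_genome(bundle$genome, paths$genome)
  write_annotation(bundle$annotation, paths$annotation)
  write_conservation(bundle$conservation, paths$conservation)
  if (!is.null(bundle$cage)) write_cage_clusters(bundle$cage, paths$cage) else
    paths$cage <- NULL
  bundle$paths <- paths
  bundle
}

#' Plant motif instances into promoters of a fixture bundle
#'
#' Writes the matrix consensus word (or words sampled column-wise from the
#' PFM frequencies) at TSS-relative offsets in the oriented promoters of the
#' given genes, elevates conservation over every planted footprint to 0.95,
#' and returns the updated bundle plus a planting manifest.
#'
#' @param bundle `fixture_bundle`.
#' @param pwm `pwm` or `pfm` whose sites are planted.
#' @param gene_ids Genes to plant into.
#' @param sites_per_promoter Number of sites per promoter.
#' @param offsets Optional TSS-relative oriented offsets (0 = TSS base) of
#'   the site starts; default draws non-overlapping offsets inside the
#'   elevated-conservation stretch `[-580, -120)`.
#' @param tss_index Which TSS record of each gene receives the sites
#'   (1 = most distal).
#' @param exact Plant the exact consensus (default) or PFM-sampled words.
#' @param seed Seed for random placement/sampling; defaults to a child of
#'   the bundle's spec seed.
#' @return List with `bundle` (updated) and `manifest` (gene_id, tss_index,
#'   matrix_id, offset, strand, genomic_start).
#' @export
plant_motifs <- function(bundle, pwm, gene_ids, sites_per_promoter = 2L,
                         offsets = NULL, tss_index = 1L, exact = TRUE,
                         seed = NULL) {
  if (length(gene_ids) == 0L)
    return(list(bundle = bundle, manifest = data.frame(
      gene_id = character(0), tss_index = integer(0), matrix_id = character(0),
      offset = integer(0), strand = character(0), genomic_start = integer(0))))
  seed <- seed %||% split_seed(bundle$spec$seed, "plant")
  L <- if (inherits(pwm, "pfm")) ncol(pwm$counts) else pwm$width
  word_of <- function(s) {
    if (exact) return(consensus_word(pwm))
    m <- if (inherits(pwm, "pfm")) pwm$counts else 2^pwm$weights
    with_seed(s, {
      paste(vapply(seq_len(L), function(j) {
        sample(rownames(m), 1L, prob = m[, j] / sum(m[, j]))
      }, ""), collapse = "")
    })
  }
  tss <- cluster_tss(bundle$annotation)
  manifest <- list()
  for (g in gene_ids) {
    rec <- tss[tss$gene_id == g & tss$tss_index == tss_index, , drop = FALSE]
    if (nrow(rec) == 0L) stopf("gene %s has no TSS index %d", g, tss_index)
    offs <- offsets
    if (is.null(offs)) {
      offs <- with_seed(split_seed(seed, paste0("place", g)), {
        grid <- seq(-580L, -120L - L, by = L + 4L)
        sort(sample(grid, sites_per_promoter))
      })
    }
    if (length(offs) != sites_per_promoter)
      stopf("gene %s: %d offsets for %d sites", g, length(offs), sites_per_promoter)
    if (any(diff(sort(offs)) < L))
      stopf("gene %s: placement collision (sites overlap)", g)
    chrom <- rec$chrom
    clen <- nchar(bundle$genome[[chrom]])
    for (k in seq_along(offs)) {
      r <- offs[k]
      word <- word_of(split_seed(seed, paste0("word", g, ".", k)))
      if (rec$strand == "+") {
        gstart <- rec$position + r
        insert <- word
      } else {
        gstart <- rec$position - r - L + 1L
        insert <- revcomp(word)
      }
      if (gstart < 0L || gstart + L > clen)
        stopf("gene %s: planted site outside chromosome", g)
      bundle$genome[[chrom]] <- .replace_slice(bundle$genome[[chrom]], gstart, insert)
      bundle$conservation[[chrom]][(gstart + 1L):(gstart + L)] <- 0.95
      manifest[[length(manifest) + 1L]] <- data.frame(
        gene_id = g, tss_index = tss_index,
        matrix_id = if (inherits(pwm, "pfm")) pwm$id else pwm$id,
        offset = r, strand = "+", genomic_start = gstart,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(bundle$paths)) {
    write_genome(bundle$genome, bundle$paths$genome)
    write_conservation(bundle$conservation, bundle$paths$conservation)
  }
  list(bundle = bundle, manifest = do.call(rbind, manifest))
}

#' Generate decoy position frequency matrices
#'
#' Random PFMs with varied information content (per-matrix Dirichlet
#' concentration), deterministic per seed.
#'
#' @param n Number of matrices (>= 3).
#' @param widths Candidate widths.
#' @param seed Integer seed.
#' @return List of `pfm` objects with ids `DCY001`, `DCY002`, ...
#' @export
make_decoy_pwms <- function(n, widths = 8:12, seed) {
  if (n < 3L) stopf("make_decoy_pwms: need n >= 3")
  lapply(seq_len(n), function(i) {
    with_seed(split_seed(seed, paste0("decoy", i)), {
      L <- if (length(widths) == 1L) widths else sample(widths, 1L)
      alpha <- stats::runif(1, 0.1, 1.5)  # small alpha -> peaked columns
      counts <- vapply(seq_len(L), function(j) {
        p <- stats::rgamma(4, alpha)
        p <- p / sum(p)
        as.numeric(stats::rmultinom(1, 100, p))
      }, numeric(4))
      new_pfm(sprintf("DCY%03d", i), sprintf("decoy_%03d", i), counts)
    })
  })
}

#' Example CRE-like matrix
#'
#' A strongly specified 8-column matrix with the TGACG-core consensus
#' TGACGTAA, used in examples and fixtures as a stand-in for a cAMP response
#' element matrix. The consensus is deliberately non-palindromic so that a
#' planted site yields a single-strand match (the canonical palindromic CRE
#' would always match both strands at once).
#'
#' @return A `pfm` object with id `CRE01`.
#' @export
cre_like_pfm <- function() {
  word <- "TGACGTAA"
  counts <- matrix(1, 4, nchar(word), dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- encode_dna(word)
  for (j in seq_along(idx)) counts[idx[j], j] <- 97
  new_pfm("CRE01", "CRE-like", counts)
}
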