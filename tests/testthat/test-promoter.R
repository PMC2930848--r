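make_ann <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(gene_id = r$gene, transcript_id = r$tx, chrom = r$chrom,
                    strand = r$strand, tx_start = r$start, tx_end = r$end,
                    stringsAsFactors = FALSE)
    d$exon_starts <- list(r$es %||% r$start)
    d$exon_ends <- list(r$ee %||% r$end)
    d
  }))
  promenrich::new_annotation(df)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("transcripts sharing a start collapse into one TSS record", {
  ann <- make_ann(list(
    list(gene = "g1", tx = "t1", chrom = "c1", strand = "+", start = 100L, end = 500L),
    list(gene = "g1", tx = "t2", chrom = "c1", strand = "+", start = 100L, end = 700L),
    list(gene = "g1", tx = "t3", chrom = "c1", strand = "+", start = 250L, end = 700L),
    list(gene = "g2", tx = "t4", chrom = "c1", strand = "-", start = 900L, end = 1200L)))
  tss <- cluster_tss(ann)
  g1 <- tss[tss$gene_id == "g1", ]
  expect_identical(nrow(g1), 2L)
  expect_identical(g1$position, c(100L, 250L))
  expect_identical(g1$transcripts, c("t1,t2", "t3"))
  g2 <- tss[tss$gene_id == "g2", ]
  expect_identical(g2$position, 1199L)  # minus strand: 5'-most base is tx_end - 1
  expect_true(all(tss$tpm == -1))
})

test_that("a four-start gene yields four TSS records ordered 5' to 3'", {
  rows <- lapply(1:4, function(j) {
    list(gene = "g", tx = paste0("t", j), chrom = "c1", strand = "-",
         start = 100L, end = 1000L + j * 300L)
  })
  tss <- cluster_tss(make_ann(rows))
  expect_identical(nrow(tss), 4L)
  expect_identical(tss$position, as.integer(c(2199, 1899, 1599, 1299)))
  expect_identical(tss$tss_index, 1:4)
})

test_that("CAGE remapping picks the closest cluster's strongest position", {
  tss <- data.frame(gene_id = "g", chrom = "c1", strand = "+",
                    position = 1000L, tss_index = 1L, transcripts = "t1",
                    tpm = -1, cpg_island_total_len = NA_real_,
                    stringsAsFactors = FALSE)
  clusters <- data.frame(chrom = "c1", strand = "+", start = 1005L, end = 1012L,
                         stringsAsFactors = FALSE)
  clusters$counts <- list(c(12, 0, 0, 0, 0, 30, 0))  # 1005:12, 1010:30
  clusters$tpms <- list(c(liver = 4.2, brain = 7.5))
  class(clusters) <- c("cage_clusters", "data.frame")
  out <- remap_tss_with_cage(tss, clusters)
  expect_identical(out$position, 1010L)
  expect_equal(out$tpm, 7.5)
})

test_that("no cluster within 200 bp leaves the TSS with the -1 sentinel", {
  tss <- data.frame(gene_id = "g", chrom = "c1", strand = "+",
                    position = 1000L, tss_index = 1L, transcripts = "t1",
                    tpm = -1, cpg_island_total_len = NA_real_,
                    stringsAsFactors = FALSE)
  clusters <- data.frame(chrom = "c1", strand = "+", start = 1300L, end = 1310L,
                         stringsAsFactors = FALSE)
  clusters$counts <- list(rep(1, 10))
  clusters$tpms <- list(5)
  class(clusters) <- c("cage_clusters", "data.frame")
  out <- remap_tss_with_cage(tss, clusters)
  expect_identical(out$position, 1000L)
  expect_equal(out$tpm, -1)
  # opposite-strand clusters never match
  clusters2 <- clusters
  clusters2$start <- 1001L; clusters2$end <- 1011L; clusters2$strand <- "-"
  out2 <- remap_tss_with_cage(tss, clusters2)
  expect_equal(out2$tpm, -1)
})

test_that("of two in-range clusters the closer one wins", {
  tss <- data.frame(gene_id = "g", chrom = "c1", strand = "+",
                    position = 1000L, tss_index = 1L, transcripts = "t1",
                    tpm = -1, cpg_island_total_len = NA_real_,
                    stringsAsFactors = FALSE)
  clusters <- data.frame(chrom = c("c1", "c1"), strand = "+",
                         start = c(1050L, 1120L), end = c(1055L, 1125L),
                         stringsAsFactors = FALSE)
  clusters$counts <- list(c(0, 0, 9, 0, 0), c(100, 0, 0, 0, 0))
  clusters$tpms <- list(1.5, 99)
  class(clusters) <- c("cage_clusters", "data.frame")
  out <- remap_tss_with_cage(tss, clusters)
  expect_identical(out$position, 1052L)  # distance 50 beats distance 120
  expect_equal(out$tpm, 1.5)
})

test_that("remapping never moves a TSS farther than 200 bp plus the cluster width", {
  spec <- fixture_spec(n_genes = 10, seed = 29)
  b <- make_genome(spec)
  tss <- cluster_tss(b$annotation)
  out <- remap_tss_with_cage(tss, b$cage)
  moved <- merge(tss, out, by = c("gene_id", "position"))
  common <- intersect(paste(tss$gene_id, tss$transcripts),
                      paste(out$gene_id, out$transcripts))
  for (k in common) {
    a <- tss[paste(tss$gene_id, tss$transcripts) == k, ]
    z <- out[paste(out$gene_id, out$transcripts) == k, ]
    w <- max(b$cage$end - b$cage$start)
    expect_lte(abs(a$position - z$position), 200 + w)
  }
})

test_that("plus-strand promoter extraction is plain coordinate arithmetic", {
  genome <- c(c1 = paste(rep("ACGT", 5000), collapse = ""))
  ann <- make_ann(list(list(gene = "g", tx = "t", chrom = "c1", strand = "+",
                            start = 10000L, end = 12000L)))
  tss <- cluster_tss(ann)
  pr <- extract_promoter(genome, NULL, ann, tss[1, ], 10, 5)
  expect_identical(pr$seq, substr(genome[["c1"]], 9991, 10005))
  expect_identical(pr$up_eff, 10)
  # the base at index upstream_len is the genomic TSS base
  expect_identical(substr(pr$seq, 11, 11), substr(genome[["c1"]], 10001, 10001))
})

test_that("minus-strand promoters reverse-complement the window [pos-down+1, pos+up+1)", {
  genome <- c(c1 = random_dna(20000, 8))
  ann <- make_ann(list(list(gene = "g", tx = "t", chrom = "c1", strand = "-",
                            start = 8000L, end = 10001L)))
  tss <- cluster_tss(ann)
  expect_identical(tss$position, 10000L)
  pr <- extract_promoter(genome, NULL, ann, tss[1, ], 10, 5)
  expect_identical(pr$seq, oracle_revcomp(substr(genome[["c1"]], 9997, 10011)))
  # oriented index up_eff carries the TSS base (complemented)
  expect_identical(substr(pr$seq, 11, 11),
                   oracle_revcomp(substr(genome[["c1"]], 10001, 10001)))
})

test_that("windows truncate (never pad) at chromosome edges", {
  genome <- c(c1 = "ACGTACGTACGTACGTACGT")
  ann <- make_ann(list(list(gene = "g", tx = "t", chrom = "c1", strand = "+",
                            start = 3L, end = 15L)))
  tss <- cluster_tss(ann)
  pr <- extract_promoter(genome, NULL, ann, tss[1, ], 10, 5)
  expect_identical(nchar(pr$seq), 3L + 5L)
  expect_true(pr$truncated)
  expect_identical(pr$up_eff, 3)
})

test_that("conservation and coding mask are oriented with the sequence", {
  spec <- fixture_spec(n_genes = 4, seed = 37)
  b <- make_genome(spec)
  tss <- cluster_tss(b$annotation)
  minus <- tss[tss$strand == "-", ][1, ]
  pr <- extract_promoter(b$genome, b$conservation, b$annotation, minus, 700, 300)
  expect_identical(length(pr$conservation), nchar(pr$seq))
  expect_identical(length(pr$coding), nchar(pr$seq))
  # elevated stretch sits at oriented [-600, -100): check a base inside it
  expect_gt(pr$conservation[pr$up_eff - 350 + 1], 0.8)
  # the TSS base starts the first exon of the minus-strand transcript
  expect_true(pr$coding[pr$up_eff + 1])
})

test_that("TSS selection modes behave per definition", {
  d <- data.frame(gene_id = "g", chrom = "c1", strand = "+",
                  position = c(100L, 250L, 400L), tss_index = 1:3,
                  transcripts = c("a", "b", "c"), tpm = c(-1, 3, 7.5),
                  cpg_island_total_len = c(0, 0, 512),
                  stringsAsFactors = FALSE)
  expect_identical(select_tss(d, "all"), d)
  expect_identical(select_tss(d, "most_distal")$position, 100L)
  expect_equal(select_tss(d, "highest_tpm")$tpm, 7.5)
  expect_identical(select_tss(d, "with_cpg")$position, 400L)
  expect_identical(select_tss(d, "without_cpg")$position, c(100L, 250L))
  # with_cpg and without_cpg partition the records
  expect_identical(nrow(select_tss(d, "with_cpg")) +
                     nrow(select_tss(d, "without_cpg")), nrow(d))

  # minus strand: most distal is the largest coordinate
  dm <- d; dm$strand <- "-"
  expect_identical(select_tss(dm, "most_distal")$position, 400L)

  # all TPMs -1: fall back to most_distal with a warning
  d2 <- d; d2$tpm <- -1
  expect_warning(sel <- select_tss(d2, "highest_tpm"), "most_distal")
  expect_identical(sel$position, 100L)

  # TPM tie goes to the more distal record
  d3 <- d; d3$tpm <- c(5, 5, 1)
  expect_identical(select_tss(d3, "highest_tpm")$position, 100L)
})
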