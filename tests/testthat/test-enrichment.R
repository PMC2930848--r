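# helper: a ready-to-use scanned fixture for filter tests
scanned_gene <- function(seed = 67, up = 1000, down = 200) {
  spec <- fixture_spec(n_genes = 6, seed = seed)
  b <- make_genome(spec)
  tss <- cluster_tss(b$annotation)
  g <- tss$gene_id[tss$gene_id == "G003"]  # a 3-TSS gene
  rows <- which(tss$gene_id == "G003")
  promoters <- lapply(rows, function(i) {
    extract_promoter(b$genome, b$conservation, b$annotation, tss[i, ], up, down)
  })
  pwms <- toy_pwms(seed = 91, n = 3, widths = c(6, 8, 8))
  hits <- scan_all(pwms, promoters, 70)
  list(bundle = b, promoters = promoters, hits = hits, pwms = pwms)
}

test_that("conservation threshold, coding mode and window filters drop hits as defined", {
  sc <- scanned_gene()
  p_all <- filter_params(run_config(upstream_len = 1000, downstream_len = 200))
  f_all <- filter_hits(sc$hits, sc$promoters, p_all)
  expect_true(all(f_all$hits$conservation >= 0.6))
  # a fabricated mix: 3 conserved of 10 survive at threshold 0.8
  h <- sc$hits[1:10, ]
  h$conservation <- c(rep(0.9, 3), rep(0.5, 7))
  p80 <- filter_params(run_config(conservation_threshold = 80,
                                  upstream_len = 1000, downstream_len = 200))
  expect_identical(nrow(filter_hits(h, sc$promoters, p80)$hits), 3L)

  p_cod <- filter_params(run_config(coding_mode = "coding",
                                    upstream_len = 1000, downstream_len = 200))
  p_non <- filter_params(run_config(coding_mode = "noncoding",
                                    upstream_len = 1000, downstream_len = 200))
  f_cod <- filter_hits(sc$hits, sc$promoters, p_cod)
  f_non <- filter_hits(sc$hits, sc$promoters, p_non)
  expect_true(all(f_cod$hits$coding))
  expect_true(all(!f_non$hits$coding))

  # narrowing the window never keeps a hit outside it
  p_narrow <- filter_params(run_config(upstream_len = 300, downstream_len = 0))
  f_nar <- filter_hits(sc$hits, sc$promoters, p_narrow)
  for (i in seq_len(nrow(f_nar$hits))) {
    pr <- sc$promoters[[f_nar$hits$tss_index[i]]]
    rel <- f_nar$hits$offset[i] - pr$up_eff
    expect_gte(rel, -300)
    expect_lte(rel + f_nar$hits$width[i], 0)
  }
  expect_lte(f_nar$effective_length, f_all$effective_length)
})

test_that("top-percent keeps ceiling(pct x n) most conserved hits per promoter", {
  sc <- scanned_gene()
  one_tss <- sc$hits[sc$hits$tss_index == 1, ][1:5, ]
  one_tss$conservation <- c(0.95, 0.9, 0.85, 0.8, 0.75)
  p50 <- filter_params(run_config(top_percent_conserved = 50,
                                  upstream_len = 1000, downstream_len = 200))
  kept <- filter_hits(one_tss, sc$promoters[1], p50)$hits
  expect_identical(nrow(kept), 3L)  # ceiling(2.5)
  expect_setequal(kept$conservation, c(0.95, 0.9, 0.85))
})

test_that("the max-conserved-TFBS cap keeps an equal number per promoter", {
  sc <- scanned_gene()
  p2 <- filter_params(run_config(max_conserved_tfbs = 2,
                                 upstream_len = 1000, downstream_len = 200))
  f <- filter_hits(sc$hits, sc$promoters, p2)
  by_tss <- table(f$hits$tss_index)
  expect_true(all(by_tss <= 2))
  # with enough surviving hits each promoter is capped at exactly 2
  raw <- filter_hits(sc$hits, sc$promoters,
                     filter_params(run_config(upstream_len = 1000,
                                              downstream_len = 200)))
  busy <- names(table(raw$hits$tss_index))[table(raw$hits$tss_index) >= 2]
  expect_true(all(by_tss[busy] == 2))
})

test_that("overlapping promoter windows of one gene count a physical site once", {
  spec <- fixture_spec(n_genes = 6, seed = 73)
  b <- make_genome(spec)
  tss <- cluster_tss(b$annotation)
  rows <- which(tss$gene_id == "G003")  # TSSs 800 bp apart: 5-kb windows overlap
  promoters <- lapply(rows, function(i) {
    extract_promoter(b$genome, b$conservation, b$annotation, tss[i, ], 5000, 200)
  })
  pwms <- toy_pwms(seed = 83, n = 2, widths = c(6, 8))
  hits <- scan_all(pwms, promoters, 65)
  params <- filter_params(run_config(upstream_len = 5000, downstream_len = 200))
  f <- filter_hits(hits, promoters, params)
  key <- paste(f$hits$matrix_id, f$hits$gstart, f$hits$gstrand)
  expect_identical(anyDuplicated(key), 0L)
  # raw pooled hits DO repeat across the overlapping windows
  expect_gt(nrow(hits[hits$conservation >= 0.6, ]), nrow(f$hits))
})

test_that("expected hit and gene counts follow the closed forms", {
  expect_equal(expected_hits(1.5e6, 10), 15)
  expect_equal(expected_hits(0, 10), 0)
  expect_equal(expected_genes(rep(1000, 10), 100), 10 * (1 - exp(-0.1)))
  expect_equal(expected_genes(rep(1000, 10), 100), 0.9516, tolerance = 1e-4)
  expect_equal(expected_genes(rep(1000, 10), 0), 0)
  # saturating limit: expected genes approaches the gene count
  expect_equal(expected_genes(rep(1e6, 5), 1e6), 5, tolerance = 1e-6)
})

test_that("fold z-scores standardize against the repertoire fold distribution", {
  fz <- fold_and_z(c(3, 1, 1, 1, 1), rep(1, 5))
  expect_equal(mean(fz$fold), 1.4)
  expect_equal(stats::sd(fz$fold), 0.8944, tolerance = 1e-4)
  expect_equal(fz$z[1], 1.789, tolerance = 1e-3)
  expect_lt(abs(fz$p[1] - 0.0368), 1e-4)
  # z-scores have mean 0 and sample sd 1 by construction
  expect_equal(mean(fz$z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(fz$z), 1, tolerance = 1e-9)
  # below-mean folds are never reported as enriched
  expect_true(all(fz$p[fz$fold < mean(fz$fold)] > 0.5))
  # degenerate all-equal folds
  flat <- fold_and_z(rep(2, 4), rep(1, 4))
  expect_true(all(flat$p == 0.5))
  expect_error(fold_and_z(c(1, 2), c(1, 1)), "3 matrices")
})

test_that("proportion p is expected/observed capped at 1", {
  expect_equal(proportion_p(45, 15), 1 / 3)
  expect_equal(proportion_p(10, 25), 1)
  expect_equal(proportion_p(0, 5), 1)
})

test_that("CpG comparison is a one-sided z-test against the genome distribution", {
  out <- cpg_comparison(rep(500, 10), 500, 200)
  expect_equal(out$z, 0)
  expect_equal(out$p, 0.5)
  n <- 16
  shifted <- cpg_comparison(rep(500 + 3 * 200 / sqrt(n), n), 500, 200)
  expect_equal(shifted$p, 1 - stats::pnorm(3), tolerance = 1e-9)
  expect_error(cpg_comparison(500, 500, 200), "2 query")
  expect_warning(flat <- cpg_comparison(c(1, 2), 500, 0), "sd")
  expect_equal(flat$p, 1)
})

test_that("run_enrichment recovers a motif planted in every query promoter", {
  spec <- fixture_spec(n_genes = 16, seed = 97)
  b <- make_genome(spec)
  pwms <- c(list(pfm_to_pwm(cre_like_pfm())),
            lapply(make_decoy_pwms(9, seed = 103), pfm_to_pwm))
  query <- b$genes$gene_id[1:8]
  pl <- plant_motifs(b, pwms[[1]], query, sites_per_promoter = 2)
  b <- pl$bundle
  tbl <- compute_frequency_table(generate_random_background(100000, 7), pwms)
  cfg <- run_config(upstream_len = 1000, downstream_len = 200,
                    random_occurrence = 1000, tss_mode = "most_distal")
  res <- run_enrichment(query, b$genome, b$annotation, b$conservation, pwms,
                        tbl, cfg, cage = b$cage)
  expect_identical(res$enrichment$matrix_id[1], "CRE01")
  expect_gte(res$enrichment$tfbs_number[1], 2 * length(query))
  expect_true(all(res$enrichment$tfbs_fold >= 0))
  expect_true(all(res$enrichment$tfbs_fold_p >= 0 & res$enrichment$tfbs_fold_p <= 1))
  # z identities hold on the emitted table
  expect_equal(mean(res$enrichment$tfbs_z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(res$enrichment$tfbs_z), 1, tolerance = 1e-9)
  # per-gene table covers the query and the CpG table compares means
  expect_setequal(res$per_gene$gene_id, query)
  expect_true(is.finite(res$cpg$p))

  # determinism: identical reruns produce identical tables
  res2 <- run_enrichment(query, b$genome, b$annotation, b$conservation, pwms,
                         tbl, cfg, cage = b$cage)
  expect_identical(res$enrichment, res2$enrichment)

  # unresolved ids error when nothing resolves
  expect_error(run_enrichment(c("nope1", "nope2"), b$genome, b$annotation,
                              b$conservation, pwms, tbl, cfg),
               "no query gene")
})

test_that("restricting filters never increases the pooled hit count", {
  sc <- scanned_gene(seed = 109)
  base <- filter_params(run_config(upstream_len = 1000, downstream_len = 200))
  n_base <- nrow(filter_hits(sc$hits, sc$promoters, base)$hits)
  stricter <- list(
    filter_params(run_config(conservation_threshold = 85,
                             upstream_len = 1000, downstream_len = 200)),
    filter_params(run_config(top_percent_conserved = 20,
                             upstream_len = 1000, downstream_len = 200)),
    filter_params(run_config(max_conserved_tfbs = 1,
                             upstream_len = 1000, downstream_len = 200)),
    filter_params(run_config(upstream_len = 400, downstream_len = 0)))
  for (p in stricter) {
    expect_lte(nrow(filter_hits(sc$hits, sc$promoters, p)$hits), n_base)
  }
})

test_that("result tables are written with headers and reproduce ignoring timestamps", {
  spec <- fixture_spec(n_genes = 8, seed = 113)
  b <- make_genome(spec)
  pwms <- lapply(make_decoy_pwms(5, seed = 127), pfm_to_pwm)
  tbl <- compute_frequency_table(generate_random_background(50000, 3), pwms)
  cfg <- run_config(upstream_len = 800, downstream_len = 100,
                    random_occurrence = 1000)
  res <- run_enrichment(b$genes$gene_id[1:4], b$genome, b$annotation,
                        b$conservation, pwms, tbl, cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_enrichment_result(res, d1, seed = 1)
  write_enrichment_result(res, d2, seed = 1)
  files <- c("params.tsv", "per_gene.tsv", "enrichment_jaspar.tsv",
             "enrichment_extra.tsv", "cpg.tsv")
  for (f in files) {
    l1 <- readLines(file.path(d1, f))
    l2 <- readLines(file.path(d2, f))
    expect_identical(grep("^# timestamp", l1, value = TRUE, invert = TRUE),
                     grep("^# timestamp", l2, value = TRUE, invert = TRUE))
    expect_true(any(startsWith(l1, "# tool:")))
    expect_true(any(startsWith(l1, "# config:")))
  }
})
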