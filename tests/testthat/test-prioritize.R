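test_that("variant scores follow the per-consequence rule table", {
  v <- tibble::tibble(
    gene_id = c("a", "b", "c", "c", "d"),
    chrom = "1", pos_mb = 1:5,
    consequence = c("stop-gain", "nonsynonymous", "splicing", "nonsynonymous",
                    "other"),
    damage_prob = c(NA, 1.0, NA, 0.5, NA)
  )
  sc <- variant_gene_score(v)
  expect_equal(sc$variant_score[sc$gene_id == "a"], 10)
  expect_equal(sc$variant_score[sc$gene_id == "b"], 10)
  expect_equal(sc$variant_score[sc$gene_id == "c"], 15)  # splicing + 10 * 0.5
  expect_equal(sc$variant_score[sc$gene_id == "d"], 0)
  expect_warning(variant_gene_score(tibble::tibble(
    gene_id = "x", chrom = "1", pos_mb = 1,
    consequence = "mystery", damage_prob = NA
  )), "unknown consequence")
})

test_that("normalization maps p-values through -log10 min-max as computed by hand", {
  s <- normalize_scores(c(1e-8, 1e-2, 0.5), kind = "p", winsor_q = NULL)
  expect_equal(s, c(1, (2 - (-log10(0.5))) / (8 - (-log10(0.5))), 0),
               tolerance = 1e-12)
  expect_equal(normalize_scores(rep(0.2, 4), "p"), rep(0, 4))
  expect_error(normalize_scores(c(1, NaN), "score"), "non-finite")
  # winsorization tames a single extreme outlier
  raw <- c(100, 8, 6, 4, 2, rep(1, 15))
  no_w <- normalize_scores(raw, "score", winsor_q = NULL)
  with_w <- normalize_scores(raw, "score", winsor_q = 0.95)
  expect_lt(no_w[2], 0.1)
  expect_gt(with_w[2], 0.5)
  expect_equal(max(with_w), 1)
})

test_that("the QTL-curve score uses the best of center / cis / variant positions", {
  mk <- tibble::tibble(
    marker_id = paste0("m", 1:5), chrom = "2",
    pos_mb = c(10, 20, 30, 40, 50),
    adj_p = c(0.5, 0.3, 0.001, 0.3, 0.5), lod = c(1, 2, 6, 2, 1)
  )
  gene <- tibble::tibble(gene_id = "g", chrom = "2", start_mb = 48,
                         end_mb = 50, center_mb = 49)
  # only candidate: the center, sitting on the low flank
  expect_equal(assign_qtl_score(gene, mk), -log10(0.5))
  # cis marker at the peak wins (the Naa30-style configuration)
  expect_equal(assign_qtl_score(gene, mk, cis_pos_mb = 30), -log10(0.001))
  # variant near the peak likewise enters the max
  expect_equal(assign_qtl_score(gene, mk, variant_pos_mb = 31), -log10(0.001))
  # all candidates at the same marker: that marker's value
  expect_equal(assign_qtl_score(gene, mk, cis_pos_mb = 49, variant_pos_mb = 50),
               -log10(0.5))
  # nearest-marker step function, ties to the left marker
  gene_mid <- gene; gene_mid$center_mb <- 25   # equidistant m2/m3
  expect_equal(assign_qtl_score(gene_mid, mk), -log10(0.3))
  expect_error(assign_qtl_score(gene, mk, region = c(0, 5)), "no candidate")
})

test_that("henikoff weights match the brute-force 1/(r*k) oracle", {
  expect_equal(henikoff_weights(matrix(2L, 5, 9)), rep(0.2, 5))
  set.seed(17)
  for (i in 1:40) {
    G <- sample(1:6, 1)
    m <- matrix(sample(0L:3L, 5 * G, replace = TRUE), 5, G)
    w <- henikoff_weights(m)
    expect_equal(w, henikoff_oracle(m), tolerance = 1e-12)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("duplicating a score row lowers the duplicated rows' combined share", {
  set.seed(19)
  base <- matrix(sample(0L:4L, 4 * 6, replace = TRUE), 4, 6)
  dup <- rbind(base, base[1, ])
  w <- henikoff_weights(dup)
  distinct_w <- w[2:4]
  expect_lt(w[1] + w[5], 2 * mean(distinct_w) + 1e-12)
  expect_equal(w[1], w[5])
})

test_that("integrated score is the weighted sum with monotone behavior", {
  w <- rep(0.2, 5)
  expect_equal(integrated_score(rep(1, 5), w), 1)
  expect_equal(integrated_score(rep(0, 5), w), 0)
  expect_equal(integrated_score(c(1, 0, 0, 0, 0), w), 0.2)
  s <- matrix(runif(10 * 5), 10, 5)
  base <- integrated_score(s, w)
  s2 <- s; s2[, 3] <- pmin(1, s2[, 3] + 0.1)
  expect_true(all(integrated_score(s2, w) >= base))
  expect_error(integrated_score(rep(1, 4), w), "dimension mismatch")
  expect_error(integrated_score(rep(1, 5), rep(0.3, 5)), "sum to 1")
})

test_that("the permutation threshold is deterministic, gene-label invariant, and grows with G", {
  set.seed(23)
  s <- matrix(runif(20 * 5), 20, 5)
  a <- prioritization_fdr(s, n_perm = 400, seed = 5)
  b <- prioritization_fdr(s, n_perm = 400, seed = 5)
  expect_identical(a$threshold, b$threshold)
  perm <- sample(20)
  c_ <- prioritization_fdr(s[perm, ], n_perm = 400, seed = 5)
  expect_equal(c_$threshold, a$threshold)
  thr_small <- median(replicate(10, {
    prioritization_fdr(matrix(runif(4 * 5), 4, 5), n_perm = 200,
                       seed = sample.int(1e6, 1))$threshold
  }))
  thr_big <- median(replicate(10, {
    prioritization_fdr(matrix(runif(60 * 5), 60, 5), n_perm = 200,
                       seed = sample.int(1e6, 1))$threshold
  }))
  expect_gt(thr_big, thr_small)
  expect_warning(one <- prioritization_fdr(matrix(runif(5), 1, 5), n_perm = 50),
                 "single-gene")
  expect_true(is.na(one$threshold))
  expect_false(any(one$significant))
})

test_that("a fully dominant gene is flagged while its decoys are not", {
  set.seed(29)
  s <- matrix(runif(31 * 5, 0, 0.4), 31, 5)
  s[7, ] <- 1
  fdr <- prioritization_fdr(s, n_perm = 500, seed = 3)
  expect_true(fdr$significant[7])
  expect_lte(sum(fdr$significant), 2)
})

test_that("prioritize_region recovers the planted gene end-to-end", {
  sc <- simulate_candidate_scenario(seed = 31)
  scan <- qtl_scan(sc$trait, sc$geno, n_perm = 500, seed = 31)
  cis <- cis_scan(sc$expr_sd, sc$geno, sc$genes, n_perm = 500, seed = 31)
  de <- differential_expression(sc$expr_sd, sc$expr_ctr)
  corr <- trait_molecule_correlation(sc$trait, sc$expr_sd)
  pr <- prioritize_region(scan, sc$genes, cis = cis, variants = sc$variants,
                          de = de, corr = corr,
                          region = sc$truth$region_mb,
                          chrom = sc$truth$region_chrom,
                          n_perm = 1000, seed = 31)
  expect_equal(attr(pr, "top_gene"), sc$truth$causal_gene)
  expect_equal(pr$gene_id[pr$rank == 1], sc$truth$causal_gene)
  expect_true(pr$significant[pr$rank == 1])
  expect_gte(nrow(pr), 31)
  expect_equal(sum(attr(pr, "weights")), 1, tolerance = 1e-12)
  # ablation: with its expression shuffled the planted gene loses the top rank
  sc2 <- sc
  set.seed(99)
  causal <- sc$truth$causal_gene
  sc2$expr_sd$log_cpm[causal, ] <- sample(sc2$expr_sd$log_cpm[causal, ])
  sc2$expr_ctr$log_cpm[causal, ] <- sample(sc2$expr_ctr$log_cpm[causal, ])
  cis2 <- cis_scan(sc2$expr_sd, sc2$geno, sc2$genes, n_perm = 500, seed = 31)
  de2 <- differential_expression(sc2$expr_sd, sc2$expr_ctr)
  corr2 <- trait_molecule_correlation(sc2$trait, sc2$expr_sd)
  pr2 <- prioritize_region(scan, sc2$genes, cis = cis2, variants = NULL,
                           de = de2, corr = corr2,
                           region = sc$truth$region_mb,
                           chrom = sc$truth$region_chrom,
                           n_perm = 500, seed = 31)
  expect_lt(pr2$integrated[pr2$gene_id == causal],
            pr$integrated[pr$gene_id == causal])
  # missing upstream table errors by name
  expect_error(prioritize_region(NULL, sc$genes), "scan")
})

test_that("a single-gene region is returned ranked but unflagged", {
  sc <- simulate_candidate_scenario(seed = 33)
  scan <- qtl_scan(sc$trait, sc$geno, n_perm = 200, seed = 33)
  causal <- sc$truth$causal_gene
  g1 <- sc$genes[sc$genes$gene_id == causal, ]
  expect_warning(
    pr <- prioritize_region(scan, g1, cis = NULL, variants = sc$variants,
                            de = NULL, corr = NULL,
                            region = sc$truth$region_mb,
                            chrom = "2", n_perm = 100, seed = 1),
    "single-gene"
  )
  expect_equal(pr$rank, 1L)
  expect_false(pr$significant)
})
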