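test_that("qvalues match the hand Benjamini-Hochberg computation at pi0 = 1", {
  q <- qvalues(c(0.01, 0.02, 0.03, 0.5), pi0 = 1)
  expect_equal(q, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(qvalues(rep(1, 6)), rep(1, 6))
  # q respects its lower bound p * pi0 and order is preserved
  set.seed(3)
  p <- runif(200)^2
  q2 <- qvalues(p)
  pi0 <- min(1, sum(p > 0.5) / (0.5 * length(p)))
  expect_true(all(q2 >= p * pi0 - 1e-12))
  expect_true(all(diff(q2[order(p)]) >= -1e-12))
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_cis_panel <- function(seed, effect = 0, n_genes = 6) {
  g <- simulate_ri_genotypes(panel_spec(n_strains = 30, chrom = "1",
                                        length_mb = 40, n_markers = 20), seed = seed)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n_genes)), chrom = "1",
    center_mb = seq(5, 35, length.out = n_genes)
  )
  genes$start_mb <- genes$center_mb - 0.1
  genes$end_mb <- genes$center_mb + 0.1
  set.seed(seed + 1)
  m <- matrix(rnorm(n_genes * 30, sd = 0.5), n_genes,
              dimnames = list(genes$gene_id, strain_ids(g)))
  if (effect > 0) {
    mk <- which.min(abs(g$map$pos_mb - genes$center_mb[1]))
    m[1, ] <- m[1, ] + effect * g$codes[, mk]
  }
  list(g = g, genes = genes, expr = expr_matrix(m))
}

test_that("cis_scan recovers a planted cis effect and respects the min-p rule", {
  pan <- make_cis_panel(seed = 4, effect = 2)
  res <- cis_scan(pan$expr, pan$g, pan$genes, n_perm = 300, seed = 4)
  expect_true(all(res$testable))
  expect_lt(res$q[res$gene_id == "g01"], 0.05)
  # best marker lies inside the window
  gene1 <- pan$genes[1, ]
  expect_lte(abs(res$pos_mb[1] - gene1$center_mb), 1.0)
  # reported best p equals the minimum over window markers (oracle)
  strains <- strain_ids(pan$g)
  widx <- which(pan$g$map$chrom == "1" &
                  abs(pan$g$map$pos_mb - gene1$center_mb) <= 1.0)
  pvals <- vapply(widx, function(j) {
    x <- pan$g$codes[strains, j]
    summary(lm(pan$expr$log_cpm["g01", strains] ~ x))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(res$p_nominal[1], min(pvals), tolerance = 1e-9)
})

test_that("constant expression yields adjusted p of 1 and beta smoothing tracks the empirical estimator", {
  pan <- make_cis_panel(seed = 6)
  pan$expr$log_cpm[2, ] <- 3.14
  res <- cis_scan(pan$expr, pan$g, pan$genes, n_perm = 200, seed = 6)
  expect_equal(res$p_adj[res$gene_id == "g02"], 1)
  resE <- cis_scan(pan$expr, pan$g, pan$genes, n_perm = 400, beta_fit = FALSE,
                   seed = 7)
  resB <- cis_scan(pan$expr, pan$g, pan$genes, n_perm = 400, beta_fit = TRUE,
                   seed = 7)
  ok <- resE$gene_id != "g02"
  expect_lt(max(abs(resE$p_adj[ok] - resB$p_adj[ok])), 0.2)
})

test_that("genes without window markers are flagged untestable and skip q-values", {
  pan <- make_cis_panel(seed = 8)
  pan$genes$center_mb[3] <- 300            # off the map
  pan$genes$start_mb[3] <- 299.9; pan$genes$end_mb[3] <- 300.1
  res <- cis_scan(pan$expr, pan$g, pan$genes, n_perm = 150, seed = 8)
  expect_false(res$testable[3])
  expect_true(is.na(res$q[3]))
  expect_false(anyNA(res$q[res$testable]))
})

test_that("null panels keep the cis false-discovery fraction calibrated", {
  qs <- unlist(lapply(1:5, function(s) {
    pan <- make_cis_panel(seed = 100 + s, effect = 0, n_genes = 10)
    cis_scan(pan$expr, pan$g, pan$genes, n_perm = 200, seed = s)$q
  }))
  expect_lte(mean(qs < 0.05), 0.05)
})

test_that("trans_scan applies the hard threshold outside the cis window", {
  pan <- make_cis_panel(seed = 12, n_genes = 4)
  # plant a trans hotspot: marker on the far side drives gene g04
  far <- which.max(pan$g$map$pos_mb)
  pan$expr$log_cpm["g04", ] <- pan$expr$log_cpm["g04", ] +
    3 * pan$g$codes[, far]
  hits <- trans_scan(pan$expr, pan$g, pan$genes, p_threshold = 1e-4)
  expect_true(any(hits$gene_id == "g04" &
                    hits$marker_id == marker_ids(pan$g)[far]))
  # no hit may fall inside its gene's cis window
  for (i in seq_len(nrow(hits))) {
    gene <- pan$genes[pan$genes$gene_id == hits$gene_id[i], ]
    expect_gt(abs(hits$pos_mb[i] - gene$center_mb), 1.0)
  }
  expect_equal(nrow(trans_scan(pan$expr, pan$g, pan$genes, p_threshold = 0)), 0)
})

test_that("trans hit counts on a null panel are near the nominal rate", {
  counts <- vapply(1:4, function(s) {
    pan <- make_cis_panel(seed = 200 + s, n_genes = 12)
    nrow(trans_scan(pan$expr, pan$g, pan$genes, p_threshold = 1e-2))
  }, numeric(1))
  pan <- make_cis_panel(seed = 201, n_genes = 12)
  n_tests <- 12 * sum(!is.na(pan$g$map$pos_mb)) # approx: genes x markers (minus windows)
  rate <- sum(counts) / (4 * n_tests)
  expect_lt(rate, 0.03)                        # nominal 1e-2, allow correlation slack
})

test_that("differential cis scan works on the condition contrast", {
  pan <- make_cis_panel(seed = 14)
  same <- cis_scan  # silence lint
  ctr <- pan$expr
  sd_same <- expr_matrix(ctr$log_cpm, condition = "SD")
  res0 <- differential_cis_scan(sd_same, ctr, pan$g, pan$genes,
                                n_perm = 150, seed = 14)
  expect_true(all(res0$p_adj[res0$testable] == 1))
  # planted genotype x condition interaction at gene 1's cis marker
  mk <- which.min(abs(pan$g$map$pos_mb - pan$genes$center_mb[1]))
  m2 <- ctr$log_cpm
  m2["g01", ] <- m2["g01", ] + 2.5 * pan$g$codes[, mk]
  res1 <- differential_cis_scan(expr_matrix(m2, condition = "SD"), ctr,
                                pan$g, pan$genes, n_perm = 300, seed = 15)
  expect_lt(res1$q[res1$gene_id == "g01"], 0.05)
  # disjoint strain sets are an error
  bad <- ctr$log_cpm; colnames(bad) <- paste0("X", seq_len(ncol(bad)))
  expect_error(differential_cis_scan(expr_matrix(bad, condition = "SD"), ctr,
                                     pan$g, pan$genes), "share no strains")
})
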