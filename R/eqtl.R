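#' Storey q-values with Benjamini-Hochberg fallback
#'
#' Monotone step-up q-values `q_(i) = pi0 * n * p_(i) / i` (running minimum
#' from the largest p). `pi0` is estimated by the lambda = 0.5 plug-in
#' `#\{p > 0.5\} / (0.5 n)`, capped at 1; with `pi0 = 1` the procedure reduces
#' to Benjamini-Hochberg.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @param pi0 override for the null proportion; `NULL` (default) estimates it,
#'   `1` forces plain BH.
#' @return q-values, same length and order as `p`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  pv <- p[ok]
  m <- length(pv)
  if (!m) return(p)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(pv > 0.5) / (0.5 * m))
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
  }
  o <- order(pv)
  q <- pi0 * m * pv[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- rep(NA_real_, length(p))
  out[ok][o] <- q
  out
}

cis_window_markers <- function(g, gene, window_mb = 2.0, anchor = c("center", "start")) {
  anchor <- match.arg(anchor)
  pos0 <- if (anchor == "center") gene$center_mb else gene$start_mb
  which(g$map$chrom == gene$chrom & abs(g$map$pos_mb - pos0) <= window_mb / 2)
}

fit_beta_minp <- function(minp) {
  minp <- pmin(pmax(minp, 1e-12), 1 - 1e-12)
  mu <- mean(minp); v <- var(minp)
  if (!is.finite(v) || v <= 0) return(NULL)
  # method-of-moments start, then ML
  common <- mu * (1 - mu) / v - 1
  start <- c(max(mu * common, 1e-3), max((1 - mu) * common, 1e-3))
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(minp, "beta",
                                    start = list(shape1 = start[1], shape2 = start[2]))),
    error = function(e) NULL
  )
  if (is.null(fit) || any(!is.finite(fit$estimate)) || any(fit$estimate <= 0)) return(NULL)
  fit$estimate
}

#' Map cis-eQTLs with permutation-adjusted p-values
#'
#' For each gene, tests the association of log-CPM with the allele code at
#' every marker whose position falls within a `window_mb` window anchored on
#' the gene (center by default). The gene-level statistic is the minimum
#' nominal p across window markers; its null distribution is obtained by
#' permuting expression across strains `n_perm` times and, when the fit
#' succeeds, smoothed by a maximum-likelihood Beta fit to the permutation
#' minima (adjusted p = `pbeta(p_min, a, b)`), otherwise the empirical
#' `(1 + r) / (1 + N)` estimator is used. q-values are computed across
#' testable genes.
#'
#' @param expr an [expr_matrix].
#' @param g a [geno_matrix].
#' @param genes gene annotation tibble.
#' @param window_mb total window width in Mb (default 2).
#' @param anchor `"center"` (default) or `"start"` (TSS-anchored).
#' @param n_perm permutations per gene (default 1000).
#' @param beta_fit smooth adjusted p-values with a Beta fit (default TRUE).
#' @param seed integer seed.
#' @return Tibble of class `cis_eqtl` with one row per gene: `gene_id`,
#'   `marker_id` (best), `pos_mb`, `n_markers`, `p_nominal`, `p_adj`, `q`,
#'   `slope_sign`, `tissue`, `condition`, `testable`.
#' @export
cis_scan <- function(expr, g, genes, window_mb = 2.0, anchor = "center",
                     n_perm = 1000, beta_fit = TRUE, seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  strains <- intersect(colnames(expr$log_cpm), strain_ids(g))
  if (length(strains) < 8) abort("need >= 8 shared strains")
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(length(strains)))
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    widx <- cis_window_markers(g, gene, window_mb, anchor)
    rec <- tibble(
      gene_id = gene$gene_id, marker_id = NA_character_, pos_mb = NA_real_,
      n_markers = length(widx), p_nominal = NA_real_, p_adj = NA_real_,
      q = NA_real_, slope_sign = NA_real_,
      tissue = expr$tissue, condition = expr$condition, testable = FALSE
    )
    if (!length(widx) || !gene$gene_id %in% rownames(expr$log_cpm)) return(rec)
    yobs <- expr$log_cpm[gene$gene_id, strains]
    codes <- g$codes[strains, widx, drop = FALSE]
    ymat <- cbind(unname(yobs), matrix(yobs[perm_idx], nrow = length(strains)))
    res <- marker_assoc_engine(ymat, codes, min_n = 8L)
    pm <- res$p
    if (all(is.na(pm[, 1]))) return(rec)
    minp <- apply(pm, 2, min, na.rm = TRUE)
    best <- which.min(pm[, 1])                 # ties -> first = lowest Mb
    p_obs <- minp[1]
    null_min <- minp[-1]
    p_emp <- (1 + sum(null_min <= p_obs)) / (1 + n_perm)
    p_adj <- p_emp
    if (beta_fit) {
      ab <- fit_beta_minp(null_min)
      if (!is.null(ab)) p_adj <- pbeta(p_obs, ab[1], ab[2])
    }
    if (sd(yobs) == 0) p_adj <- 1
    rec$marker_id <- colnames(codes)[best]
    rec$pos_mb <- g$map$pos_mb[widx[best]]
    rec$p_nominal <- p_obs
    rec$p_adj <- min(max(p_adj, 0), 1)
    rec$slope_sign <- res$sign[best, 1]
    rec$testable <- TRUE
    rec
  })
  out <- bind_rows(rows)
  out$q[out$testable] <- qvalues(out$p_adj[out$testable])
  class(out) <- c("cis_eqtl", class(out))
  out
}

#' Map trans-eQTLs with a hard nominal p threshold
#'
#' Tests every (gene, marker) pair with the marker outside the gene's cis
#' window and keeps pairs with nominal regression p <= `p_threshold`
#' (default 1e-4). Together with [cis_scan()] the cis and trans windows
#' partition each gene's testable markers.
#'
#' @inheritParams cis_scan
#' @param p_threshold hard nominal p-value cutoff.
#' @return Tibble `gene_id`, `marker_id`, `chrom`, `pos_mb`, `p`,
#'   `slope_sign`.
#' @export
trans_scan <- function(expr, g, genes, window_mb = 2.0, anchor = "center",
                       p_threshold = 1e-4) {
  stopifnot(inherits(expr, "expr_matrix"))
  strains <- intersect(colnames(expr$log_cpm), strain_ids(g))
  if (length(strains) < 8) abort("need >= 8 shared strains")
  genes <- genes[genes$gene_id %in% rownames(expr$log_cpm), ]
  ymat <- t(expr$log_cpm[genes$gene_id, strains, drop = FALSE])
  codes <- g$codes[strains, , drop = FALSE]
  res <- marker_assoc_engine(ymat, codes, min_n = 8L)   # markers x genes
  p <- res$p
  for (i in seq_len(nrow(genes))) {
    widx <- cis_window_markers(g, genes[i, ], window_mb, anchor)
    if (length(widx)) p[widx, i] <- NA_real_
  }
  hits <- which(!is.na(p) & p <= p_threshold, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(tibble(gene_id = character(), marker_id = character(),
                  chrom = character(), pos_mb = numeric(),
                  p = numeric(), slope_sign = numeric()))
  }
  tibble(
    gene_id = genes$gene_id[hits[, 2]],
    marker_id = colnames(codes)[hits[, 1]],
    chrom = g$map$chrom[hits[, 1]],
    pos_mb = g$map$pos_mb[hits[, 1]],
    p = p[hits],
    slope_sign = res$sign[hits]
  ) |> arrange(.data$gene_id, .data$p)
}

#' cis-eQTLs of the sleep-deprivation expression response
#'
#' Applies [cis_scan()] to the per-strain SD - Ctr contrast of log-CPM,
#' mapping loci that modulate how strongly a gene responds to sleep
#' deprivation (genotype x condition interactions).
#'
#' @param expr_sd,expr_ctr [expr_matrix] objects sharing strains and genes.
#' @inheritParams cis_scan
#' @return A `cis_eqtl` tibble (condition labelled `"SD-Ctr"`).
#' @export
differential_cis_scan <- function(expr_sd, expr_ctr, g, genes,
                                  window_mb = 2.0, anchor = "center",
                                  n_perm = 1000, beta_fit = TRUE, seed = 1) {
  shared_s <- intersect(colnames(expr_sd$log_cpm), colnames(expr_ctr$log_cpm))
  shared_g <- intersect(rownames(expr_sd$log_cpm), rownames(expr_ctr$log_cpm))
  if (!length(shared_s)) abort("conditions share no strains")
  d <- expr_sd$log_cpm[shared_g, shared_s, drop = FALSE] -
       expr_ctr$log_cpm[shared_g, shared_s, drop = FALSE]
  contrast <- expr_matrix(d, tissue = expr_sd$tissue, condition = "SD-Ctr")
  cis_scan(contrast, g, genes, window_mb = window_mb, anchor = anchor,
           n_perm = n_perm, beta_fit = beta_fit, seed = seed)
}
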