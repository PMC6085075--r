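#' Protein-damage variant score for one gene
#'
#' Sums, over all detected variants of a gene: splicing = 10, stop-gain = 10,
#' stop-loss = 10, frameshift-indel = 10, nonsynonymous = 10 x damage
#' probability (e.g. a PolyPhen-2 score). Genes without variants score 0;
#' an unknown consequence class contributes 0 with a warning.
#'
#' @param variants tibble of variant rows ([read_variants()] layout) for one
#'   gene (or many; scores are summed per `gene_id`).
#' @return Tibble `gene_id`, `variant_score` (one row per gene), or a single
#'   numeric when `variants` has one gene.
#' @export
variant_gene_score <- function(variants) {
  if (is.null(variants) || !nrow(variants)) {
    return(tibble(gene_id = character(), variant_score = numeric()))
  }
  known <- c("splicing", "stop-gain", "stop-loss", "frameshift-indel", "nonsynonymous")
  unknown <- setdiff(unique(variants$consequence), c(known, "other"))
  if (length(unknown)) {
    warn(paste0("unknown consequence class(es) score 0: ", paste(unknown, collapse = ", ")))
  }
  contrib <- dplyr::case_when(
    variants$consequence %in% c("splicing", "stop-gain", "stop-loss", "frameshift-indel") ~ 10,
    variants$consequence == "nonsynonymous" ~ 10 * variants$damage_prob,
    TRUE ~ 0
  )
  tibble(gene_id = variants$gene_id, contrib = contrib) |>
    group_by(.data$gene_id) |>
    summarise(variant_score = sum(.data$contrib), .groups = "drop")
}

#' Winsorized min-max analysis-score normalization
#'
#' Maps a per-gene raw statistic vector to `[0, 1]` analysis scores over the
#' genes of one QTL region. p-like statistics (`kind = "p"`) are transformed
#' to -log10 first; variant scores (`kind = "score"`) and already-transformed
#' values (`kind = "neglogp"`) are used as-is. Values above the upper
#' winsorization quantile are clamped to it before the min-max rescaling so a
#' single extreme gene cannot compress everyone else to ~0. A constant vector
#' maps to all zeros.
#'
#' @param raw numeric vector (one value per gene).
#' @param kind `"p"`, `"neglogp"` or `"score"`.
#' @param winsor_q upper winsorization quantile (default 0.95); `NULL` or 1
#'   disables clamping.
#' @return Normalized scores in `[0, 1]`.
#' @export
normalize_scores <- function(raw, kind = c("p", "neglogp", "score"),
                             winsor_q = 0.95) {
  kind <- match.arg(kind)
  if (any(!is.finite(raw))) {
    abort(paste0("non-finite raw statistic at position ",
                 which(!is.finite(raw))[1]))
  }
  x <- if (kind == "p") -log10(pmax(raw, 1e-300)) else raw
  if (!is.null(winsor_q) && winsor_q < 1 && length(x) > 1) {
    cap <- quantile(x, winsor_q, names = FALSE)
    x <- pmin(x, cap)
  }
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' QTL-curve statistic for a gene
#'
#' Evaluates the scan's score curve (-log10 genome-wide adjusted p, a step
#' function taking the value of the nearest marker, ties toward the left
#' marker) at each candidate position for the gene -- its center, the
#' cis-eQTL marker when the gene has one, and the damaging-variant position
#' when it carries one -- and returns the maximum. Using the best-scoring
#' candidate reproduces both conventions in use: the gene center by default,
#' and the associated marker whenever that evidence places the gene under a
#' stronger part of the QTL curve.
#'
#' @param gene one-row gene annotation tibble.
#' @param scan a `qtl_scan` (restricted to the gene's chromosome internally).
#' @param cis_pos_mb optional cis-eQTL marker position (Mb).
#' @param variant_pos_mb optional damaging-variant position (Mb).
#' @param region optional `c(lo, hi)` Mb bounds; candidate positions outside
#'   are ignored (an error if none remain).
#' @return The maximum -log10 adjusted p over candidate positions.
#' @export
assign_qtl_score <- function(gene, scan, cis_pos_mb = NULL,
                             variant_pos_mb = NULL, region = NULL) {
  mk <- if (inherits(scan, "qtl_scan")) scan$markers else as_tibble(scan)
  mk <- mk[mk$chrom == gene$chrom & !is.na(mk$adj_p), ]
  if (!nrow(mk)) abort("no tested markers on the gene's chromosome")
  cand <- c(center = gene$center_mb,
            if (!is.null(cis_pos_mb)) c(cis = cis_pos_mb),
            if (!is.null(variant_pos_mb)) c(variant = variant_pos_mb))
  if (!is.null(region)) {
    keep <- cand >= region[1] & cand <= region[2]
    if (!any(keep)) abort(paste0("no candidate position inside the region for ", gene$gene_id))
    cand <- cand[keep]
  }
  curve <- -log10(mk$adj_p)
  vals <- vapply(cand, function(pos) {
    d <- abs(mk$pos_mb - pos)
    curve[which.min(d)]            # which.min takes the first = left marker on ties
  }, numeric(1))
  max(vals)
}

# Henikoff position-based diversity weights, batched.
# d: K x G x P integer array (discretized scores; P stacked matrices).
# Per column g of each matrix: a row holding a symbol shared by k of the K
# rows, among r distinct symbols, contributes 1/(r * k); row weight = sum of
# contributions over columns, normalized to sum 1 per matrix.
# Note sum_i 1/k_i = r, which gives r without tabulating symbols.
henikoff_weights_batch <- function(d) {
  stopifnot(length(dim(d)) == 3)
  K <- dim(d)[1]
  kcount <- array(0L, dim = dim(d))
  for (i in seq_len(K)) {
    for (l in seq_len(K)) {
      kcount[i, , ] <- kcount[i, , ] + (d[i, , ] == d[l, , ])
    }
  }
  inv_k <- 1 / kcount
  r <- colSums(inv_k, dims = 1)               # G x P matrix of r values
  contrib <- sweep(inv_k, c(2, 3), r, "/")
  w <- apply(contrib, c(1, 3), sum)           # K x P
  sweep(w, 2, colSums(w), "/")
}

#' Henikoff diversity weights for discretized analysis scores
#'
#' Treats each analysis-score row as a sequence over the gene columns and
#' applies position-based sequence weighting: in each column, a row holding a
#' symbol shared by `k` rows among `r` distinct symbols contributes
#' `1/(r * k)`; row weights are the summed contributions, normalized to sum
#' to 1. Redundant (identical) score rows share their contribution and are
#' down-weighted relative to a row carrying independent information, which is
#' what lets the integrated score correct for intrinsically correlated
#' analyses (e.g. a cis-eQTL inside a phenotype QTL region).
#'
#' @param discretized integer-like matrix, one row per analysis score
#'   (typically 5), one column per gene.
#' @return Numeric weights, one per row, summing to 1.
#' @export
henikoff_weights <- function(discretized) {
  d <- as.matrix(discretized)
  if (!nrow(d) || !ncol(d)) abort("discretized matrix must be non-empty")
  w <- henikoff_weights_batch(array(d, dim = c(nrow(d), ncol(d), 1)))
  as.numeric(w[, 1])
}

#' Discretize normalized scores for Henikoff weighting
#'
#' Equal-width binning of `[0, 1]` scores into `n_bins` bins (default 10).
#'
#' @param s numeric vector or matrix of scores in `[0, 1]`.
#' @param n_bins number of bins.
#' @return Integer bin labels in `0:(n_bins - 1)`, same shape as `s`.
#' @export
discretize_scores <- function(s, n_bins = 10) {
  b <- floor(s * n_bins)
  b[b >= n_bins] <- n_bins - 1L
  b[b < 0] <- 0L
  storage.mode(b) <- "integer"
  b
}

#' Integrated candidate-gene score
#'
#' Weighted sum `I(g) = sum_k w_k * s_k(g)` of the five normalized analysis
#' scores; with weights summing to 1 and scores in `[0, 1]`, `I` lies in
#' `[0, 1]` and is monotone in every component.
#'
#' @param s genes x scores matrix (or 5-vector for one gene) of normalized
#'   scores.
#' @param w weights summing to 1 (one per score column).
#' @return Numeric integrated score per gene.
#' @export
integrated_score <- function(s, w) {
  s <- if (is.null(dim(s))) matrix(s, nrow = 1) else as.matrix(s)
  if (ncol(s) != length(w)) abort("dimension mismatch between scores and weights")
  if (abs(sum(w) - 1) > 1e-8) abort("weights must sum to 1")
  as.numeric(s %*% w)
}

#' Permutation significance threshold for integrated scores
#'
#' Each permutation independently shuffles each of the five normalized score
#' columns across genes, re-discretizes, recomputes the Henikoff weights and
#' the integrated scores, and records the maximum over genes. The
#' significance threshold is the empirical `q` quantile (default 0.95) of
#' those maxima; observed integrated scores strictly above it are flagged.
#'
#' @param s genes x 5 matrix of normalized scores.
#' @param n_perm permutations (default 10000).
#' @param q quantile for the threshold (default 0.95).
#' @param n_bins discretization bins.
#' @param seed integer seed.
#' @return List with `threshold`, `observed` (integrated scores), `weights`
#'   (observed Henikoff weights), `significant` (logical), `perm_max`.
#'   With a single gene the threshold is undefined (`NA`) and the gene is
#'   reported unflagged with a warning.
#' @export
prioritization_fdr <- function(s, n_perm = 10000, q = 0.95, n_bins = 10,
                               seed = 1) {
  s <- as.matrix(s)
  G <- nrow(s); K <- ncol(s)
  w_obs <- henikoff_weights(t(discretize_scores(s, n_bins)))
  i_obs <- integrated_score(s, w_obs)
  if (G < 2) {
    warn("single-gene region: permutation threshold undefined, gene unflagged")
    return(list(threshold = NA_real_, observed = i_obs, weights = w_obs,
                significant = rep(FALSE, G), perm_max = numeric(0)))
  }
  set.seed(seed)
  # s_perm[k][, p] = column k of s shuffled across genes, permutation p
  sp <- array(NA_real_, dim = c(K, G, n_perm))
  for (k in seq_len(K)) {
    idx <- replicate(n_perm, sample.int(G))
    sp[k, , ] <- sort(s[, k])[idx]   # sorted first: relabeling genes cannot change the null
  }
  dp <- discretize_scores(sp, n_bins)
  wp <- henikoff_weights_batch(dp)            # K x P
  # integrated score per gene & permutation: sum_k w_k[p] * sp[k, g, p]
  ip <- matrix(0, nrow = G, ncol = n_perm)
  for (k in seq_len(K)) {
    ip <- ip + sweep(sp[k, , , drop = TRUE], 2, wp[k, ], "*")
  }
  perm_max <- apply(ip, 2, max)
  threshold <- quantile(perm_max, q, names = FALSE)
  list(threshold = threshold, observed = i_obs, weights = w_obs,
       significant = i_obs > threshold, perm_max = perm_max)
}

#' Rank candidate genes in a QTL region by the integrated score
#'
#' Assembles the five per-gene raw statistics for every gene overlapping the
#' region -- (1) the QTL-curve value at the gene's best candidate position
#' ([assign_qtl_score()]), (2) the cis-eQTL q-value, (3) the variant damage
#' score, (4) the differential-expression adjusted p, (5) the
#' expression-phenotype correlation p -- normalizes them
#' ([normalize_scores()]), weights them by Henikoff diversity
#' ([henikoff_weights()]), integrates ([integrated_score()]) and applies the
#' permutation threshold ([prioritization_fdr()]). Genes without a record in
#' an evidence table enter with the null value for that component (p = 1,
#' variant score 0).
#'
#' @param scan a `qtl_scan` for the phenotype or metabolite.
#' @param genes gene annotation tibble.
#' @param cis `cis_eqtl` tibble from [cis_scan()].
#' @param variants variant tibble ([read_variants()] layout), or `NULL`.
#' @param de differential-expression tibble from [differential_expression()].
#' @param corr correlation tibble from [trait_molecule_correlation()]
#'   (rows for the scanned trait are selected by `trait_id`).
#' @param region `c(lo_mb, hi_mb)` on `chrom`; defaults to the 1.5-LOD
#'   support interval of the scan's top peak.
#' @param chrom chromosome of the region; defaults to the top peak's.
#' @param cis_q_max cis-eQTLs with q below this enter the position rule.
#' @param n_perm,q,n_bins,winsor_q,seed passed to the scoring machinery.
#' @return A `priority_table`: tibble with per-gene raw statistics,
#'   normalized scores `s_qtl`, `s_eqtl`, `s_variant`, `s_de`, `s_cor`,
#'   integrated score `integrated`, `rank` and `significant`, ordered by
#'   rank; attributes `weights`, `threshold`, `region`, `trait_id`,
#'   `top_gene` (highest-ranked significant gene or `NA`).
#' @export
prioritize_region <- function(scan, genes, cis = NULL, variants = NULL,
                              de = NULL, corr = NULL, region = NULL,
                              chrom = NULL, cis_q_max = 0.05,
                              n_perm = 10000, q = 0.95, n_bins = 10,
                              winsor_q = 0.95, seed = 1) {
  if (is.null(scan)) abort("missing upstream table: scan")
  if (is.null(genes)) abort("missing upstream table: genes")
  if (is.null(region)) {
    if (!nrow(scan$peaks)) abort("scan has no peaks; supply a region")
    pk <- scan$peaks[1, ]
    region <- c(pk$ci_lo_mb, pk$ci_hi_mb)
    chrom <- pk$chrom
  }
  if (is.null(chrom)) abort("chrom must be given with an explicit region")
  gsel <- genes[genes$chrom == chrom &
                genes$end_mb >= region[1] & genes$start_mb <= region[2], ]
  if (!nrow(gsel)) abort("no gene overlaps the region")

  vscores <- variant_gene_score(variants)
  raw <- purrr::map(seq_len(nrow(gsel)), function(i) {
    gene <- gsel[i, ]
    cis_rec <- if (!is.null(cis)) cis[cis$gene_id == gene$gene_id & cis$testable, ] else NULL
    has_cis <- !is.null(cis_rec) && nrow(cis_rec) > 0 && !is.na(cis_rec$q[1])
    cis_pos <- if (has_cis && cis_rec$q[1] < cis_q_max) cis_rec$pos_mb[1] else NULL
    var_rows <- if (!is.null(variants)) variants[variants$gene_id == gene$gene_id, ] else NULL
    var_pos <- if (!is.null(var_rows) && nrow(var_rows)) var_rows$pos_mb[1] else NULL
    tibble(
      gene_id = gene$gene_id,
      qtl_neglogp = assign_qtl_score(gene, scan, cis_pos, var_pos),
      eqtl_q = if (has_cis) cis_rec$q[1] else 1,
      variant_score = if (gene$gene_id %in% vscores$gene_id)
        vscores$variant_score[match(gene$gene_id, vscores$gene_id)] else 0,
      de_p = if (!is.null(de) && gene$gene_id %in% de$gene_id)
        de$p_adj[match(gene$gene_id, de$gene_id)] else 1,
      cor_p = {
        cp <- 1
        if (!is.null(corr)) {
          rows <- corr[corr$molecule_id == gene$gene_id &
                       corr$trait_id == scan$trait_id, ]
          if (nrow(rows)) cp <- rows$p[1]
        }
        cp
      }
    )
  }) |> bind_rows()

  s <- cbind(
    s_qtl = normalize_scores(raw$qtl_neglogp, "neglogp", winsor_q),
    s_eqtl = normalize_scores(raw$eqtl_q, "p", winsor_q),
    s_variant = normalize_scores(raw$variant_score, "score", winsor_q),
    s_de = normalize_scores(raw$de_p, "p", winsor_q),
    s_cor = normalize_scores(raw$cor_p, "p", winsor_q)
  )
  fdr <- prioritization_fdr(s, n_perm = n_perm, q = q, n_bins = n_bins,
                            seed = seed)
  out <- bind_cols(raw, as_tibble(s)) |>
    mutate(integrated = fdr$observed, significant = fdr$significant) |>
    arrange(dplyr::desc(.data$integrated)) |>
    mutate(rank = dplyr::row_number())
  top <- out$gene_id[out$rank == 1 & out$significant]
  structure(out, class = c("priority_table", class(out)),
            weights = setNames(fdr$weights,
                               c("qtl", "eqtl", "variant", "de", "cor")),
            threshold = fdr$threshold, region = region, chrom = chrom,
            trait_id = scan$trait_id,
            top_gene = if (length(top)) top else NA_character_)
}

#' @export
print.priority_table <- function(x, ...) {
  cat(sprintf(
    "<priority_table> trait '%s', chr%s:%.1f-%.1f Mb, %d genes; threshold %.3f\n",
    attr(x, "trait_id"), attr(x, "chrom"), attr(x, "region")[1],
    attr(x, "region")[2], nrow(x), attr(x, "threshold")
  ))
  cat("weights:", paste(sprintf("%s=%.3f", names(attr(x, "weights")),
                                attr(x, "weights")), collapse = " "), "\n")
  cat("top gene:", attr(x, "top_gene"), "\n")
  NextMethod()
}

#' @export
#' @method glance priority_table
glance.priority_table <- function(x, ...) {
  tibble(
    trait_id = attr(x, "trait_id"), chrom = attr(x, "chrom"),
    region_lo_mb = attr(x, "region")[1], region_hi_mb = attr(x, "region")[2],
    n_genes = nrow(x), threshold = attr(x, "threshold"),
    n_significant = sum(x$significant), top_gene = attr(x, "top_gene")
  )
}
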