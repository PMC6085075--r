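#' Two-group differential expression (SD vs control)
#'
#' Per-gene Welch two-sample t-test on log-CPM across strains, with the log2
#' fold change taken as the mean difference (log-CPM is log2-scaled) and
#' Benjamini-Hochberg adjustment across genes. This is a deliberately plain
#' two-group test: the prioritizer only consumes the adjusted-p column, and a
#' moderated-variance fit can be substituted upstream where desired.
#'
#' @param expr_sd,expr_ctr [expr_matrix] objects; genes are matched by id,
#'   strains need not overlap (groups are independent samples).
#' @return Tibble `gene_id`, `log2fc`, `p`, `p_adj`, `tissue`.
#' @export
differential_expression <- function(expr_sd, expr_ctr) {
  genes <- intersect(rownames(expr_sd$log_cpm), rownames(expr_ctr$log_cpm))
  a <- expr_sd$log_cpm[genes, , drop = FALSE]
  b <- expr_ctr$log_cpm[genes, , drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 3 || n2 < 3) abort("need >= 3 strains per condition")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  p[se2 == 0] <- 1
  tibble(
    gene_id = genes, log2fc = m1 - m2, p = p,
    p_adj = p.adjust(p, method = "BH"), tissue = expr_sd$tissue
  )
}

#' Phenotype-molecule Pearson correlations
#'
#' Pearson correlation (and its two-sided p-value) between each trait and
#' each molecule over shared strains, computed on strain-level values. When a
#' condition pairing is supplied, each trait is correlated against the
#' molecular dataset matching its condition: baseline (`bsl`) phenotypes pair
#' with control (`Ctr`) molecular data, recovery (`rec`) and
#' recovery-contrast (`contrast`) phenotypes with the sleep-deprivation
#' (`SD`) data.
#'
#' @param traits wide tibble: `strain_id` plus one numeric column per trait.
#' @param molecules an [expr_matrix], a molecules x strains matrix, or a
#'   named list of them keyed by condition (`Ctr`, `SD`) when `pairing` is
#'   used.
#' @param trait_conditions optional named vector mapping trait ids to
#'   `bsl` / `rec` / `SD` / `contrast`.
#' @param pairing named vector mapping trait conditions to molecular
#'   conditions.
#' @param min_shared minimum shared strains per pair (default 5); pairs below
#'   it are skipped with a warning.
#' @return Tibble `trait_id`, `molecule_id`, `r`, `p`, `n`,
#'   `molecule_condition`.
#' @export
trait_molecule_correlation <- function(traits, molecules,
                                       trait_conditions = NULL,
                                       pairing = c(bsl = "Ctr", rec = "SD",
                                                   SD = "SD", contrast = "SD"),
                                       min_shared = 5L) {
  traits <- as_tibble(traits)
  trait_ids <- setdiff(names(traits), c("strain_id", "animal"))
  mol_sets <- if (inherits(molecules, "expr_matrix")) {
    setNames(list(molecules$log_cpm), molecules$condition)
  } else if (is.list(molecules) && !is.matrix(molecules)) {
    lapply(molecules, function(m) if (inherits(m, "expr_matrix")) m$log_cpm else as.matrix(m))
  } else {
    list(any = as.matrix(molecules))
  }
  out <- purrr::map(trait_ids, function(tid) {
    cond <- if (!is.null(trait_conditions) && tid %in% names(trait_conditions)) {
      unname(pairing[trait_conditions[[tid]]])
    } else NA_character_
    mol <- if (!is.na(cond) && cond %in% names(mol_sets)) mol_sets[[cond]]
           else mol_sets[[1]]
    used_cond <- if (!is.na(cond) && cond %in% names(mol_sets)) cond else names(mol_sets)[1]
    shared <- intersect(traits$strain_id[!is.na(traits[[tid]])], colnames(mol))
    if (length(shared) < min_shared) {
      warn(sprintf("trait %s: only %d shared strains, skipped", tid, length(shared)))
      return(NULL)
    }
    tv <- traits[[tid]][match(shared, traits$strain_id)]
    mm <- mol[, shared, drop = FALSE]
    nn <- length(shared)
    r <- as.numeric(cor(tv, t(mm)))
    r[!is.finite(r)] <- NA_real_
    tstat <- abs(r) * sqrt((nn - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(tstat, df = nn - 2, lower.tail = FALSE)
    p[!is.na(r) & abs(r) >= 1] <- 0
    tibble(trait_id = tid, molecule_id = rownames(mm), r = r, p = p,
           n = nn, molecule_condition = used_cond)
  })
  bind_rows(out)
}

#' Partial correlation given a genotype covariate
#'
#' Correlation of the residuals of `x` and `y` after regressing each on `z`,
#' used to strip cis-eQTL-driven confounding from gene-gene correlations: two
#' genes under the same locus correlate through the genotype even without any
#' direct relationship.
#'
#' @param x,y numeric vectors.
#' @param z covariate (e.g. allele codes); if constant, the plain Pearson
#'   correlation is returned with a warning.
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(x, y, z) {
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  if (length(x) < 5) abort("need >= 5 complete observations")
  if (sd(z) == 0) {
    warn("covariate is constant; returning plain Pearson correlation")
    return(cor(x, y))
  }
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  if (sd(rx) == 0 || sd(ry) == 0) return(0)
  cor(rx, ry)
}

#' Data-driven quantile threshold on absolute correlations
#'
#' The `(1 - top_fraction)` empirical quantile of `|values|`, using the
#' "higher" order-statistic convention so that the set selected at the
#' threshold is never larger than the nominal fraction.
#'
#' @param values numeric vector (absolute values are taken).
#' @param top_fraction fraction of values to keep above the cutoff.
#' @return The cutoff value.
#' @export
quantile_threshold <- function(values, top_fraction) {
  values <- abs(values[!is.na(values)])
  if (!length(values)) abort("no values supplied")
  if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must be in (0, 1]")
  v <- sort(values)
  idx <- max(1L, ceiling(length(v) * (1 - top_fraction)))
  v[idx]
}
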