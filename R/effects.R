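#' Closed-form QTL effect size (Method 1)
#'
#' Fraction of strain-level variance explained by a single QTL, computed from
#' its LOD score alone as `1 - 10^(-(2/n) * LOD)`, where `n` is the number of
#' lines entering the scan. Ignores any other QTL for the trait. The fraction
#' refers to the between-strain (genetic) portion of the variance, not the
#' total including within-strain variability.
#'
#' @param lod LOD score(s), >= 0.
#' @param n number of lines used in the scan (>= 2).
#' @return Variance fraction(s) in `[0, 1)`; 0 at LOD 0, increasing to 1 as
#'   LOD grows.
#' @examples
#' effect_size_closed_form(3.87, 33)  # ~0.42
#' @export
effect_size_closed_form <- function(lod, n) {
  if (any(lod < 0)) abort("lod must be >= 0")
  if (any(n < 2)) abort("n must be >= 2")
  1 - 10^(-(2 / n) * lod)
}

#' Drop-one-term QTL effect sizes (Method 2)
#'
#' Fits the full additive linear model on all peak markers jointly, then
#' estimates each QTL's contribution as the R-squared lost when that marker is
#' removed from the model. With linked (correlated) QTLs the per-QTL fractions
#' sum to less than the full-model R-squared; with orthogonal markers they sum
#' to it exactly.
#'
#' @inheritParams lod_scan
#' @param peak_markers character vector of marker ids (the QTL peaks).
#' @return A `drop_one_fit`: list with `effects` (tibble `marker_id`,
#'   `var_frac`), `r2_full`, `n`, `method = "drop_one"`.
#' @export
effect_size_drop_one <- function(trait, g, peak_markers, trait_id = NULL) {
  y <- extract_trait(trait, trait_id, g)
  missing_m <- setdiff(peak_markers, marker_ids(g))
  if (length(missing_m)) abort(paste0("unknown marker: ", missing_m[1]))
  X <- g$codes[y$strains, peak_markers, drop = FALSE]
  cc <- complete.cases(X)
  X <- X[cc, , drop = FALSE]
  yv <- y$values[cc]
  if (length(yv) < length(peak_markers) + 2) abort("too few strains to fit the full model")
  if (length(peak_markers) > 1) {
    cm <- suppressWarnings(cor(X))
    cm[!is.finite(cm)] <- 1
    diag(cm) <- 0
    hit <- which(abs(cm) >= 1 - 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      abort(sprintf("markers %s and %s are collinear over the available strains",
                    peak_markers[hit[1, 1]], peak_markers[hit[1, 2]]))
    }
  }
  df <- data.frame(y = yv, X)
  r2 <- function(fit) summary(fit)$r.squared
  full <- lm(y ~ ., data = df)
  r2_full <- r2(full)
  fracs <- vapply(seq_along(peak_markers), function(i) {
    red <- lm(y ~ ., data = df[, -(i + 1), drop = FALSE])
    r2_full - r2(red)
  }, numeric(1))
  structure(list(
    effects = tibble(marker_id = peak_markers, var_frac = fracs),
    r2_full = r2_full, n = length(yv), method = "drop_one"
  ), class = "drop_one_fit")
}

#' @export
print.drop_one_fit <- function(x, ...) {
  cat(sprintf("<drop_one_fit> full additive model R2 = %.3f over %d strains\n",
              x$r2_full, x$n))
  print(as.data.frame(x$effects))
  invisible(x)
}

#' @export
#' @method tidy drop_one_fit
tidy.drop_one_fit <- function(x, ...) x$effects

#' @export
#' @method glance drop_one_fit
glance.drop_one_fit <- function(x, ...) {
  tibble(r2_full = x$r2_full, n = x$n, n_qtl = nrow(x$effects),
         sum_var_frac = sum(x$effects$var_frac))
}

#' Narrow-sense heritability from replicate-level values
#'
#' One-way ANOVA intraclass estimate across strains:
#' `h2 = (MSB - MSW) / (MSB + (kbar - 1) * MSW)`, clipped to `[0, 1]`, with
#' `kbar` the harmonic mean number of replicates per strain. For an inbred
#' panel the between-strain variance component is entirely genetic, so the
#' intraclass correlation estimates narrow-sense heritability of the
#' replicate-level trait.
#'
#' @param replicates data frame with columns `strain_id` and a trait value
#'   column (named by `trait_id`, or the single remaining numeric column).
#' @param trait_id trait column name.
#' @return `h2` in `[0, 1]`.
#' @export
heritability <- function(replicates, trait_id = NULL) {
  replicates <- as_tibble(replicates)
  if (!"strain_id" %in% names(replicates)) abort("replicates need a strain_id column")
  if (is.null(trait_id)) {
    cand <- setdiff(names(replicates), c("strain_id", "animal"))
    if (length(cand) != 1) abort("trait_id must be given")
    trait_id <- cand
  }
  v <- replicates[[trait_id]]
  keep <- !is.na(v)
  v <- v[keep]; s <- replicates$strain_id[keep]
  k <- table(s)
  if (sum(k >= 2) < 2) abort("need >= 2 strains with >= 2 replicates")
  groups <- split(v, s)
  ni <- lengths(groups)
  grand <- mean(v)
  ssb <- sum(ni * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  a <- length(groups)
  msb <- ssb / (a - 1)
  msw <- ssw / (length(v) - a)
  kbar <- length(ni) / sum(1 / ni)          # harmonic mean replicates
  if (msw == 0) return(if (msb > 0) 1 else 0)
  h2 <- (msb - msw) / (msb + (kbar - 1) * msw)
  min(1, max(0, h2))
}
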