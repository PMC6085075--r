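# Vectorised single-marker association engine shared by the phenotype scan,
# the permutation null, and the cis/trans eQTL maps.
#
# Model per marker m over the n_m strains with an observed genotype call:
#   y ~ a + b * allele_code,  LOD = (n_m / 2) * log10(RSS0 / RSS1)
# For simple regression RSS1 = RSS0 * (1 - r^2), so LOD, the t statistic and
# the nominal p-value are all functions of (r^2, n_m), computed here from
# masked sufficient statistics so that one matrix product serves every
# phenotype column (observed trait, permuted traits, or gene expression).

# y_mat: strains x P numeric (no NA); codes: strains x M in {0, 1, NA}.
# Returns list of M x P matrices: r2, lod, p, sign, plus n (length M).
marker_assoc_engine <- function(y_mat, codes, min_n = 8L, lod_max = 50) {
  stopifnot(is.matrix(y_mat), is.matrix(codes), nrow(y_mat) == nrow(codes))
  if (anyNA(y_mat)) {
    abort("phenotype matrix passed to the association engine contains NA; subset strains first")
  }
  mask <- !is.na(codes)
  x0 <- codes
  x0[!mask] <- 0
  storage.mode(x0) <- "double"
  mask_d <- mask
  storage.mode(mask_d) <- "double"

  n  <- colSums(mask_d)                       # strains usable per marker
  sx  <- colSums(x0)
  sxx <- colSums(x0 * x0)
  sy  <- crossprod(mask_d, y_mat)             # M x P
  syy <- crossprod(mask_d, y_mat * y_mat)
  sxy <- crossprod(x0, y_mat)

  num  <- n * sxy - sx * sy
  varx <- n * sxx - sx * sx                   # length M, recycled down columns
  vary <- n * syy - sy * sy
  den  <- varx * vary
  r2 <- num * num / den
  r2[den <= 0] <- 0
  r2 <- pmin(pmax(r2, 0), 1)

  lod <- (n / 2) * log10(1 / pmax(1 - r2, 10^(-2 * lod_max / pmax(n, 1))))
  lod <- pmin(lod, lod_max)

  df <- pmax(n - 2, 0)                        # per-marker, recycled down columns
  tval <- sqrt(r2 * df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tval, df = pmax(df, 1), lower.tail = FALSE)
  p[df == 0, ] <- NA_real_
  p[r2 >= 1] <- 0
  p[den <= 0] <- 1                            # monomorphic marker or constant trait

  untested <- n < min_n | varx <= 0
  lod[untested, ] <- NA_real_
  p[untested, ] <- NA_real_

  list(r2 = r2, lod = lod, p = p, sign = sign(num), n = n, untested = untested)
}

# Permute the rows of a vector P times; returns strains x P matrix.
permute_columns <- function(y, n_perm) {
  vapply(seq_len(n_perm), function(i) y[sample.int(length(y))], numeric(length(y)))
}
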