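#' Single-marker LOD scan of a strain-level trait
#'
#' Regresses the trait on the allele code at every marker over the strains
#' with both a trait value and a genotype call there, and reports
#' `LOD = (n_m / 2) * log10(RSS0 / RSS1)`. For fully informative inbred lines
#' this marker regression gives the same LOD at marker positions as interval
#' mapping. Markers with fewer than `min_n` usable strains are flagged
#' untested (`NA`). A perfect fit (`RSS1 = 0`) is capped at `lod_max` to keep
#' the ordering of peaks without infinities.
#'
#' @param trait data frame with columns `strain_id` and the trait value
#'   column named by `trait_id` (or, if `trait_id` is `NULL`, the single
#'   non-id numeric column).
#' @param g a [geno_matrix].
#' @param trait_id which trait column to scan.
#' @param min_n minimum usable strains per marker (default 8).
#' @param lod_max LOD cap when the marker model fits perfectly.
#' @return Tibble `marker_id`, `chrom`, `pos_mb`, `n`, `lod`.
#' @export
lod_scan <- function(trait, g, trait_id = NULL, min_n = 8L, lod_max = 50) {
  y <- extract_trait(trait, trait_id, g)
  if (length(y$values) < min_n) {
    abort(sprintf("only %d strains with trait and genotypes (need >= %d)",
                  length(y$values), min_n))
  }
  codes <- g$codes[y$strains, , drop = FALSE]
  res <- marker_assoc_engine(matrix(y$values, ncol = 1), codes,
                             min_n = min_n, lod_max = lod_max)
  tibble(
    marker_id = colnames(codes),
    chrom = g$map$chrom, pos_mb = g$map$pos_mb,
    n = as.integer(res$n), lod = as.numeric(res$lod)
  )
}

extract_trait <- function(trait, trait_id, g) {
  trait <- as_tibble(trait)
  if (!"strain_id" %in% names(trait)) abort("trait table needs a strain_id column")
  if (is.null(trait_id)) {
    cand <- setdiff(names(trait), c("strain_id", "animal"))
    if (length(cand) != 1) abort("trait_id must be given when several trait columns exist")
    trait_id <- cand
  }
  if (!trait_id %in% names(trait)) abort(paste0("no trait column: ", trait_id))
  keep <- trait$strain_id %in% strain_ids(g) & !is.na(trait[[trait_id]])
  list(strains = trait$strain_id[keep], values = trait[[trait_id]][keep],
       trait_id = trait_id)
}

tier_labels <- c("significant", "highly suggestive", "suggestive", "none")

assign_tiers <- function(adj_p, tiers = c(0.05, 0.10, 0.63)) {
  out <- rep("none", length(adj_p))
  out[adj_p <= tiers[3]] <- "suggestive"
  out[adj_p <= tiers[2]] <- "highly suggestive"
  out[adj_p <= tiers[1]] <- "significant"
  out[is.na(adj_p)] <- NA_character_
  factor(out, levels = tier_labels)
}

#' Genome-wide QTL scan with permutation significance tiers
#'
#' Runs [lod_scan()], then shuffles the trait values across strains `n_perm`
#' times, recording the genome-wide maximum LOD of each shuffle. The
#' genome-wide adjusted p-value of a marker is `(1 + #[perm max >= LOD]) /
#' (1 + n_perm)` (never zero). Tier labels follow the panel convention:
#' adjusted p <= 0.05 "significant", (0.05, 0.10] "highly suggestive",
#' (0.10, 0.63] "suggestive"; these cutoffs are often reported as FDR tiers,
#' but the quantity is a per-trait genome-wide adjusted p-value. Peaks are the
#' per-chromosome LOD maxima (ties broken toward the lowest Mb position), each
#' with a 1.5-LOD support interval.
#'
#' @inheritParams lod_scan
#' @param n_perm number of shuffles (default 1000; < 100 draws a warning).
#' @param tiers adjusted-p cutoffs for the three tiers.
#' @param drop LOD drop defining support intervals.
#' @param seed integer seed for the shuffles.
#' @return A `qtl_scan` object: list with `markers` (tibble `marker_id`,
#'   `chrom`, `pos_mb`, `n`, `lod`, `adj_p`, `tier`), `peaks` (tibble with
#'   support intervals), `perm_max` (numeric vector), `trait_id`, `n_perm`,
#'   `seed`.
#' @export
qtl_scan <- function(trait, g, trait_id = NULL, n_perm = 1000,
                     tiers = c(0.05, 0.10, 0.63), drop = 1.5,
                     min_n = 8L, lod_max = 50, seed = 1) {
  if (n_perm < 100) warn("n_perm < 100: permutation p-values will be coarse")
  y <- extract_trait(trait, trait_id, g)
  if (length(y$values) < min_n) {
    abort(sprintf("only %d strains with trait and genotypes (need >= %d)",
                  length(y$values), min_n))
  }
  codes <- g$codes[y$strains, , drop = FALSE]
  set.seed(seed)
  ymat <- cbind(y$values, permute_columns(y$values, n_perm))
  res <- marker_assoc_engine(ymat, codes, min_n = min_n, lod_max = lod_max)
  lod <- res$lod[, 1]
  perm_max <- apply(res$lod[, -1, drop = FALSE], 2, max, na.rm = TRUE)
  perm_max[!is.finite(perm_max)] <- 0
  adj_p <- vapply(lod, function(l) {
    if (is.na(l)) return(NA_real_)
    (1 + sum(perm_max >= l)) / (1 + n_perm)
  }, numeric(1))

  markers <- tibble(
    marker_id = colnames(codes), chrom = g$map$chrom, pos_mb = g$map$pos_mb,
    n = as.integer(res$n), lod = lod, adj_p = adj_p,
    tier = assign_tiers(adj_p, tiers)
  )
  out <- structure(list(
    markers = markers, perm_max = perm_max, trait_id = y$trait_id,
    n_perm = n_perm, tiers = tiers, seed = seed
  ), class = "qtl_scan")
  out$peaks <- find_peaks(out, drop = drop)
  out
}

find_peaks <- function(scan, drop = 1.5) {
  mk <- scan$markers[!is.na(scan$markers$lod), ]
  if (!nrow(mk)) return(tibble())
  peaks <- mk |>
    group_by(.data$chrom) |>
    filter(.data$lod == max(.data$lod)) |>
    arrange(.data$pos_mb) |>
    slice(1) |>
    ungroup() |>
    arrange(dplyr::desc(.data$lod))
  ivs <- purrr::map(peaks$marker_id, ~ support_interval(scan, .x, drop = drop))
  peaks$ci_lo_mb <- purrr::map_dbl(ivs, 1)
  peaks$ci_hi_mb <- purrr::map_dbl(ivs, 2)
  peaks
}

#' 1.5-LOD support interval around a peak
#'
#' The interval spans the contiguous run of markers around the peak with
#' `LOD >= peak - drop`, extended outwards to the first flanking marker that
#' falls below the cutoff (its position becomes the endpoint), and clipped at
#' the chromosome ends.
#'
#' @param scan a `qtl_scan` (or a tibble with `marker_id`, `chrom`, `pos_mb`,
#'   `lod`).
#' @param peak_marker marker id of the peak.
#' @param drop LOD units defining the interval (default 1.5).
#' @return Numeric `c(start_mb, end_mb)`.
#' @export
support_interval <- function(scan, peak_marker, drop = 1.5) {
  mk <- if (inherits(scan, "qtl_scan")) scan$markers else as_tibble(scan)
  i <- match(peak_marker, mk$marker_id)
  if (is.na(i)) abort(paste0("unknown marker: ", peak_marker))
  chr <- mk$chrom[i]
  cm <- mk[mk$chrom == chr & !is.na(mk$lod), ]
  cm <- cm[order(cm$pos_mb), ]
  j <- match(peak_marker, cm$marker_id)
  cutoff <- cm$lod[j] - drop
  lo <- j
  while (lo > 1 && cm$lod[lo - 1] >= cutoff) lo <- lo - 1
  hi <- j
  while (hi < nrow(cm) && cm$lod[hi + 1] >= cutoff) hi <- hi + 1
  # extend to first flanking marker below the cutoff
  if (lo > 1) lo <- lo - 1
  if (hi < nrow(cm)) hi <- hi + 1
  c(cm$pos_mb[lo], cm$pos_mb[hi])
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("<qtl_scan> trait '%s': %d markers, %d permutations\n",
              x$trait_id, nrow(x$markers), x$n_perm))
  top <- x$peaks[x$peaks$tier != "none", , drop = FALSE]
  if (nrow(top)) {
    cat("peaks above the suggestive tier:\n")
    print(as.data.frame(top[c("marker_id", "chrom", "pos_mb", "lod", "adj_p",
                              "tier", "ci_lo_mb", "ci_hi_mb")]))
  } else cat("no peaks above the suggestive tier\n")
  invisible(x)
}

#' @export
#' @method tidy qtl_scan
tidy.qtl_scan <- function(x, ...) x$markers

#' @export
#' @method glance qtl_scan
glance.qtl_scan <- function(x, ...) {
  best <- x$markers[which.max(x$markers$lod), ]
  tibble(
    trait_id = x$trait_id, n_markers = nrow(x$markers), n_perm = x$n_perm,
    max_lod = best$lod, peak_marker = best$marker_id,
    peak_adj_p = best$adj_p, peak_tier = as.character(best$tier)
  )
}

#' Permutation-adjusted p-values and tier labels for one trait
#'
#' Convenience wrapper around [qtl_scan()] returning just the per-marker
#' genome-wide adjusted p-values and tier labels.
#'
#' @inheritParams qtl_scan
#' @return Tibble `marker_id`, `chrom`, `pos_mb`, `lod`, `adj_p`, `tier`.
#' @export
permutation_tiers <- function(trait, g, trait_id = NULL, n_perm = 1000,
                              tiers = c(0.05, 0.10, 0.63), seed = 1) {
  sc <- qtl_scan(trait, g, trait_id = trait_id, n_perm = n_perm,
                 tiers = tiers, seed = seed)
  sc$markers[c("marker_id", "chrom", "pos_mb", "lod", "adj_p", "tier")]
}
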