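#' Specification of a synthetic recombinant inbred panel
#'
#' Defaults emulate a BXD-like panel: 33 inbred lines segregating two parental
#' alleles in recombination blocks across a small multi-chromosome genome.
#'
#' @param n_strains number of RI lines (default 33, >= 4).
#' @param chrom chromosome labels.
#' @param length_cm,length_mb chromosome lengths (recycled across `chrom`).
#' @param n_markers markers per chromosome (recycled, >= 2 each).
#' @param allele_freq expected frequency of the second-parent (D) allele;
#'   0.5 gives the balanced panel, other values plant a measurable imbalance.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_strains = 33, chrom = c("1", "2"),
                       length_cm = 80, length_mb = 100,
                       n_markers = 40, allele_freq = 0.5) {
  if (n_strains < 4) abort("n_strains must be >= 4")
  n_markers <- rep_len(n_markers, length(chrom))
  if (any(n_markers < 2)) abort("need >= 2 markers per chromosome")
  structure(list(
    n_strains = n_strains, chrom = chrom,
    length_cm = rep_len(length_cm, length(chrom)),
    length_mb = rep_len(length_mb, length(chrom)),
    n_markers = n_markers, allele_freq = allele_freq
  ), class = "panel_spec")
}

# Haldane map function and the RI-by-sibling-mating expansion: markers d cM
# apart recombine at r = (1 - exp(-2d/100))/2 per meiosis, and the fixed RI
# genomes switch parental origin with probability R = 4r/(1 + 6r).
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

#' RI-line recombination fraction between adjacent markers
#'
#' @param d_cm genetic distance in cM.
#' @return Switch probability `R = 4r/(1 + 6r)` with `r` from Haldane's map
#'   function; `R = 0.5` for unlinked markers.
#' @export
ri_switch_prob <- function(d_cm) {
  r <- haldane_r(d_cm)
  4 * r / (1 + 6 * r)
}

#' Simulate genotypes for a recombinant inbred panel
#'
#' Each strain is an independent homozygous mosaic of the two parental
#' genomes: along a chromosome, allele identity follows a two-state Markov
#' chain whose switch probability between markers `d` cM apart is
#' [ri_switch_prob()] (RI-by-sibling-mating expansion of Haldane's map
#' function). Marker positions are evenly spaced.
#'
#' @param spec a [panel_spec()].
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return A [geno_matrix].
#' @export
simulate_ri_genotypes <- function(spec = panel_spec(), seed = 1) {
  set.seed(seed)
  maps <- purrr::pmap(
    list(spec$chrom, spec$length_cm, spec$length_mb, spec$n_markers),
    function(ch, lcm, lmb, nm) {
      tibble(
        marker_id = sprintf("rs%s_%03d", ch, seq_len(nm)),
        chrom = ch,
        pos_cm = seq(0, lcm, length.out = nm),
        pos_mb = seq(0, lmb, length.out = nm)
      )
    }
  )
  map <- bind_rows(maps)
  codes <- matrix(NA_integer_, nrow = spec$n_strains, ncol = nrow(map),
                  dimnames = list(sprintf("RI%03d", seq_len(spec$n_strains)),
                                  map$marker_id))
  col0 <- 0L
  for (k in seq_along(spec$chrom)) {
    nm <- spec$n_markers[k]
    d <- diff(maps[[k]]$pos_cm)
    sw <- ri_switch_prob(d)
    f <- spec$allele_freq
    first <- as.integer(runif(spec$n_strains) < f)
    chr_codes <- matrix(NA_integer_, nrow = spec$n_strains, ncol = nm)
    chr_codes[, 1] <- first
    for (j in seq_len(nm - 1)) {
      # state-dependent switch rates keep the stationary D-allele frequency at
      # f while the unconditional switch probability stays R (detailed balance)
      p01 <- min(1, sw[j] / (2 * (1 - f)))
      p10 <- min(1, sw[j] / (2 * f))
      pr <- ifelse(chr_codes[, j] == 0L, p01, p10)
      flip <- runif(spec$n_strains) < pr
      chr_codes[, j + 1] <- ifelse(flip, 1L - chr_codes[, j], chr_codes[, j])
    }
    codes[, col0 + seq_len(nm)] <- chr_codes
    col0 <- col0 + nm
  }
  geno_matrix(codes, map[c("marker_id", "chrom", "pos_mb", "pos_cm")])
}

#' Simulate a strain-level phenotype with planted additive QTLs
#'
#' The strain genetic value is a sum of additive marker effects, each scaled
#' (against the empirical marker variance) so that QTL `i` contributes its
#' stated fraction of the strain-level phenotypic variance; residual
#' strain-level noise tops variance up to 1. Per-animal replicates add
#' Gaussian environmental noise sized so the intraclass heritability of the
#' replicate-level data equals `h2_target`.
#'
#' @param g a [geno_matrix].
#' @param qtls tibble/data.frame with columns `marker_id` and `var_frac`
#'   (fractions must sum to < 1); may be empty for a pure-noise trait.
#' @param h2_target narrow-sense heritability of replicate-level values.
#' @param n_replicates animals per strain (1 = strain-level values only).
#' @param trait_id column name for the simulated trait.
#' @param seed integer seed.
#' @return List with `strain_means` (tibble `strain_id`, `<trait_id>`),
#'   `replicates` (tibble `strain_id`, `animal`, `<trait_id>`; `NULL` when
#'   `n_replicates == 1`) and `truth` (planted QTLs and scaling used).
#' @export
simulate_phenotype <- function(g, qtls = NULL, h2_target = 0.7,
                               n_replicates = 1, trait_id = "trait",
                               seed = 1) {
  set.seed(seed)
  qtls <- if (is.null(qtls)) tibble(marker_id = character(), var_frac = numeric())
          else as_tibble(qtls)
  if (sum(qtls$var_frac) >= 1) abort("planted variance fractions must sum to < 1")
  missing_m <- setdiff(qtls$marker_id, marker_ids(g))
  if (length(missing_m)) abort(paste0("unknown marker: ", missing_m[1]))
  if (h2_target <= 0 || h2_target > 1) abort("h2_target must be in (0, 1]")
  n <- nrow(g$codes)
  gval <- numeric(n)
  for (i in seq_len(nrow(qtls))) {
    x <- g$codes[, qtls$marker_id[i]]
    x[is.na(x)] <- round(mean(x, na.rm = TRUE))
    sdx <- sd(x)
    if (sdx == 0) abort(sprintf("marker %s is monomorphic; requested fraction infeasible",
                                qtls$marker_id[i]))
    if (qtls$var_frac[i] > 0) {
      gval <- gval + sqrt(qtls$var_frac[i]) * (x - mean(x)) / sdx
    }
  }
  resid_frac <- 1 - sum(qtls$var_frac)
  strain_val <- gval + rnorm(n, sd = sqrt(resid_frac))
  strain_means <- tibble(strain_id = strain_ids(g), !!trait_id := strain_val)

  replicates <- NULL
  if (n_replicates > 1) {
    sigma_e <- sqrt(max(0, (1 - h2_target) / h2_target))   # strain variance ~ 1
    replicates <- tibble(
      strain_id = rep(strain_ids(g), each = n_replicates),
      animal = rep(seq_len(n_replicates), times = n),
      !!trait_id := rep(strain_val, each = n_replicates) +
        rnorm(n * n_replicates, sd = sigma_e)
    )
  }
  list(
    strain_means = strain_means,
    replicates = replicates,
    truth = list(trait_id = trait_id, qtls = qtls, h2_target = h2_target)
  )
}

#' Simulate paired control / sleep-deprivation expression matrices
#'
#' Per gene, log-CPM = baseline + allele x cis effect + condition x
#' log2-fold-change + lambda x (linked phenotype) + Gaussian noise; both
#' conditions share the strain genotypes. Cis effects must reference a marker
#' within `window_mb` of the gene center (the window the cis-eQTL mapper
#' scans).
#'
#' @param g a [geno_matrix].
#' @param genes gene annotation tibble ([read_gene_bed()] layout).
#' @param cis_effects tibble `gene_id`, `marker_id`, `effect` (log-CPM units
#'   per D allele); optional.
#' @param sd_lfc named numeric vector of planted log2 fold changes (SD vs
#'   Ctr) per gene; unnamed genes get 0.
#' @param pheno_links tibble `gene_id`, `trait_id`, `lambda` plus a
#'   `traits` tibble (strain_id + trait columns) supplying the linked values.
#' @param traits wide trait tibble used by `pheno_links`.
#' @param noise_sd residual log-CPM standard deviation.
#' @param baseline_mean mean baseline abundance.
#' @param window_mb maximum |marker - gene center| distance for a cis effect.
#' @param tissue tissue label for both matrices.
#' @param seed integer seed.
#' @return List with `ctr` and `sd` ([expr_matrix] each) and `truth`.
#' @export
simulate_expression <- function(g, genes, cis_effects = NULL, sd_lfc = NULL,
                                pheno_links = NULL, traits = NULL,
                                noise_sd = 0.5, baseline_mean = 6,
                                window_mb = 1.0, tissue = "cortex", seed = 1) {
  set.seed(seed)
  n <- nrow(g$codes)
  gn <- nrow(genes)
  base <- rnorm(gn, mean = baseline_mean, sd = 1.5)
  make <- function(condition) {
    m <- matrix(rnorm(gn * n, sd = noise_sd), nrow = gn,
                dimnames = list(genes$gene_id, strain_ids(g)))
    m + base
  }
  ctr <- make("Ctr"); sdm <- make("SD")

  if (!is.null(cis_effects)) {
    cis_effects <- as_tibble(cis_effects)
    for (i in seq_len(nrow(cis_effects))) {
      gid <- cis_effects$gene_id[i]; mid <- cis_effects$marker_id[i]
      if (!gid %in% genes$gene_id) abort(paste0("unknown gene: ", gid))
      if (!mid %in% marker_ids(g)) abort(paste0("unknown marker: ", mid))
      gene <- genes[genes$gene_id == gid, ]
      mpos <- g$map$pos_mb[match(mid, g$map$marker_id)]
      mchr <- g$map$chrom[match(mid, g$map$marker_id)]
      if (mchr != gene$chrom || abs(mpos - gene$center_mb) > window_mb) {
        abort(sprintf("cis effect for %s references marker %s outside its %g Mb window",
                      gid, mid, window_mb))
      }
      x <- g$codes[, mid]; x[is.na(x)] <- 0L
      add <- cis_effects$effect[i] * x
      ctr[gid, ] <- ctr[gid, ] + add
      sdm[gid, ] <- sdm[gid, ] + add
    }
  }
  if (!is.null(sd_lfc) && length(sd_lfc)) {
    unknown <- setdiff(names(sd_lfc), genes$gene_id)
    if (length(unknown)) abort(paste0("unknown gene in sd_lfc: ", unknown[1]))
    sdm[names(sd_lfc), ] <- sdm[names(sd_lfc), , drop = FALSE] + sd_lfc
  }
  if (!is.null(pheno_links)) {
    pheno_links <- as_tibble(pheno_links)
    if (is.null(traits)) abort("pheno_links requires a traits table")
    for (i in seq_len(nrow(pheno_links))) {
      tid <- pheno_links$trait_id[i]
      if (!tid %in% names(traits)) abort(paste0("link to unknown phenotype: ", tid))
      tv <- traits[[tid]][match(strain_ids(g), traits$strain_id)]
      tv <- (tv - mean(tv)) / sd(tv)
      add <- pheno_links$lambda[i] * tv
      gid <- pheno_links$gene_id[i]
      ctr[gid, ] <- ctr[gid, ] + add
      sdm[gid, ] <- sdm[gid, ] + add
    }
  }
  list(
    ctr = expr_matrix(ctr, tissue = tissue, condition = "Ctr"),
    sd = expr_matrix(sdm, tissue = tissue, condition = "SD"),
    truth = list(cis_effects = cis_effects, sd_lfc = sd_lfc,
                 pheno_links = pheno_links)
  )
}

#' Simulate a fully-evidenced candidate gene among decoys
#'
#' Builds the benchmark scenario the pipeline is validated on: one
#' metabolite-like trait with a planted QTL on the focal chromosome; inside
#' the QTL support region, one causal gene carries all five lines of evidence
#' (position near the peak, a strong cis-eQTL at the peak marker, a damaging
#' variant, a sleep-deprivation expression response, and strong
#' expression-trait correlation) while >= 30 decoy genes carry none or only
#' partial evidence. The returned truth bundle names the planted gene so
#' recovery can be scored.
#'
#' @param seed integer seed.
#' @param n_strains panel size (default 33).
#' @param n_decoys decoy genes in the region (default 30).
#' @param qtl_frac planted fraction of strain-level trait variance.
#' @param scramble if `TRUE`, the causal gene's evidence is scattered across
#'   random decoys instead (negative control: no gene should integrate all
#'   five components).
#' @return List with `geno`, `trait` (strain means tibble), `genes`,
#'   `expr_ctr`, `expr_sd`, `variants`, and `truth` (causal gene, planted
#'   marker, region).
#' @export
simulate_candidate_scenario <- function(seed = 1, n_strains = 33,
                                        n_decoys = 30, qtl_frac = 0.6,
                                        scramble = FALSE) {
  set.seed(seed)
  spec <- panel_spec(n_strains = n_strains, chrom = c("1", "2"),
                     length_cm = c(60, 80), length_mb = c(80, 100),
                     n_markers = c(25, 60))
  g <- simulate_ri_genotypes(spec, seed = seed)

  peak_id <- g$map$marker_id[g$map$chrom == "2"][31]   # mid-chromosome marker
  peak_mb <- g$map$pos_mb[match(peak_id, g$map$marker_id)]
  ph <- simulate_phenotype(
    g, qtls = tibble(marker_id = peak_id, var_frac = qtl_frac),
    trait_id = "metabolite1", seed = seed + 101
  )
  traits <- ph$strain_means

  # genes tiled across ~20 Mb around the peak
  n_genes <- n_decoys + 1L
  centers <- seq(peak_mb - 10, peak_mb + 10, length.out = n_genes)
  causal_idx <- which.min(abs(centers - peak_mb))
  gene_ids <- sprintf("Gene%02d", seq_len(n_genes))
  causal <- gene_ids[causal_idx]
  genes <- tibble(
    gene_id = gene_ids, chrom = "2",
    start_mb = centers - 0.15, end_mb = centers + 0.15,
    center_mb = centers
  )

  pick_decoys <- function(k) sample(setdiff(gene_ids, causal), k)
  cis_gene <- if (scramble) pick_decoys(1) else causal
  lfc_gene <- if (scramble) pick_decoys(1) else causal
  cor_gene <- if (scramble) pick_decoys(1) else causal
  var_gene <- if (scramble) pick_decoys(1) else causal

  # partial-evidence decoys: a mild cis effect and a mild SD response elsewhere
  partial <- pick_decoys(3)
  nearest_marker <- function(gid) {
    gc <- genes$center_mb[genes$gene_id == gid]
    chr2 <- g$map[g$map$chrom == "2", ]
    chr2$marker_id[which.min(abs(chr2$pos_mb - gc))]
  }
  cis_effects <- bind_rows(
    tibble(gene_id = cis_gene,
           marker_id = if (scramble) nearest_marker(cis_gene) else peak_id,
           effect = 1.5),
    tibble(gene_id = partial[1], marker_id = nearest_marker(partial[1]), effect = 0.5)
  )
  sd_lfc <- c(2.0, 0.6)
  names(sd_lfc) <- c(lfc_gene, partial[2])
  links <- tibble(gene_id = cor_gene, trait_id = "metabolite1", lambda = 1.2)

  ex <- simulate_expression(
    g, genes, cis_effects = cis_effects, sd_lfc = sd_lfc,
    pheno_links = links, traits = traits, noise_sd = 0.4,
    tissue = "liver", seed = seed + 202
  )

  variants <- validate_variants(bind_rows(
    tibble(gene_id = var_gene, chrom = "2",
           pos_mb = genes$center_mb[genes$gene_id == var_gene],
           consequence = "nonsynonymous", damage_prob = 1.0),
    tibble(gene_id = partial[3], chrom = "2",
           pos_mb = genes$center_mb[genes$gene_id == partial[3]],
           consequence = "nonsynonymous", damage_prob = 0.05)
  ))

  list(
    geno = g, trait = traits, genes = genes,
    expr_ctr = ex$ctr, expr_sd = ex$sd, variants = variants,
    truth = list(
      causal_gene = if (scramble) NA_character_ else causal,
      qtl_marker = peak_id, qtl_frac = qtl_frac,
      region_chrom = "2", region_mb = c(peak_mb - 10, peak_mb + 10),
      trait_id = "metabolite1", scramble = scramble,
      evidence_genes = c(cis = cis_gene, lfc = lfc_gene,
                         cor = cor_gene, variant = var_gene)
    )
  )
}
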