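#' One-command end-to-end pipeline demo on simulated data
#'
#' Simulates the planted-candidate benchmark panel, then runs the full
#' pipeline -- QTL scan, cis-eQTL map, differential expression,
#' phenotype-molecule correlation, candidate prioritization, hiveplot
#' construction -- writing every intermediate as TSV/JSON under `outdir`
#' together with a summary comparing detections against the planted truth.
#'
#' @param outdir writable output directory (created if missing).
#' @param seed integer seed driving every stage.
#' @param n_perm permutations for the scan / cis / prioritization stages
#'   (kept moderate so the demo runs in seconds).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_demo <- function(outdir, seed = 1, n_perm = 1000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(outdir, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) abort(paste0("output directory is not writable: ", outdir))
  unlink(probe)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  sc <- stage("simulate", simulate_candidate_scenario(seed = seed))
  write_geno(sc$geno, file.path(outdir, "panel.geno"))
  write_trait_table(sc$trait, file.path(outdir, "traits.tsv"))
  write_gene_bed(sc$genes, file.path(outdir, "genes.bed"))
  write_expression(sc$expr_ctr, file.path(outdir, "expr_ctr.tsv"))
  write_expression(sc$expr_sd, file.path(outdir, "expr_sd.tsv"))
  write_variants(sc$variants, file.path(outdir, "variants.tsv"))

  scan <- stage("scan", qtl_scan(sc$trait, sc$geno, n_perm = n_perm, seed = seed))
  readr::write_tsv(scan$markers, file.path(outdir, "scan.tsv"))
  jsonlite::write_json(scan$peaks, file.path(outdir, "peaks.json"),
                       digits = NA, dataframe = "rows")

  cis <- stage("ciseqtl", cis_scan(sc$expr_sd, sc$geno, sc$genes,
                                   n_perm = n_perm, seed = seed))
  readr::write_tsv(as_tibble(cis), file.path(outdir, "cis_eqtl.tsv"))

  de <- stage("de", differential_expression(sc$expr_sd, sc$expr_ctr))
  readr::write_tsv(de, file.path(outdir, "de.tsv"))

  corr <- stage("correlate",
                trait_molecule_correlation(sc$trait, sc$expr_sd))
  readr::write_tsv(corr, file.path(outdir, "correlations.tsv"))

  pr <- stage("prioritize",
              prioritize_region(scan, sc$genes, cis = cis,
                                variants = sc$variants, de = de, corr = corr,
                                region = sc$truth$region_mb,
                                chrom = sc$truth$region_chrom,
                                n_perm = n_perm, seed = seed))
  readr::write_tsv(as_tibble(pr), file.path(outdir, "prioritization.tsv"))

  hg <- stage("hivegraph", {
    responses <- tibble(molecule_id = de$gene_id, axis = sc$expr_sd$tissue,
                        log2fc = de$log2fc)
    build_hivegraph(attr(pr, "trait_id"), corr, responses,
                    molecule_values = list(sc$expr_sd), eqtls = cis,
                    g = sc$geno, include_top = 0.05, gene_gene_top = 0.05)
  })
  export_hivegraph(hg, file.path(outdir, "hivegraph.json"))

  summary <- list(
    seed = seed, n_perm = n_perm,
    planted_gene = sc$truth$causal_gene,
    planted_marker = sc$truth$qtl_marker,
    peak_marker = scan$peaks$marker_id[1],
    peak_tier = as.character(scan$peaks$tier[1]),
    effect_closed_form = unname(effect_size_closed_form(
      scan$peaks$lod[1], sum(!is.na(sc$trait[[2]])))),
    top_gene = attr(pr, "top_gene"),
    top_gene_significant = isTRUE(pr$significant[pr$rank == 1]),
    recovered = identical(attr(pr, "top_gene"), sc$truth$causal_gene)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  message(sprintf("planted gene %s; top-ranked gene %s (%s)",
                  summary$planted_gene, summary$top_gene,
                  if (summary$recovered) "recovered" else "missed"))
  invisible(summary)
}
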