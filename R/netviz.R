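#' Cluster phenotypes into correlation modules
#'
#' Cross-correlates all phenotypes with Spearman correlations, clusters the
#' distance `1 - |rho|` with average linkage, and cuts the dendrogram at
#' `cut_height` (default 0.3, pairing naturally with the `|rho| >= 0.7` edge
#' rule of [module_network()]). Using `|rho|` makes module membership
#' invariant to monotone transformation and sign of any phenotype.
#' Zero-variance phenotypes are excluded with a warning. Phenotypes in the
#' same module but different (sub)categories are counted separately in the
#' split module count.
#'
#' @param traits wide tibble: `strain_id` plus one numeric column per
#'   phenotype.
#' @param cut_height dendrogram cut height on the `1 - |rho|` scale.
#' @param categories optional named vector mapping phenotype ids to
#'   (sub)category labels, used for the split count.
#' @return A `phenotype_modules` object: list with `modules` (tibble
#'   `trait_id`, `module`, `category`), `n_modules`, `n_modules_split`,
#'   `rho` (Spearman matrix), `cut_height`.
#' @export
phenotype_modules <- function(traits, cut_height = 0.3, categories = NULL) {
  traits <- as_tibble(traits)
  ids <- setdiff(names(traits), c("strain_id", "animal"))
  if (length(ids) < 2) abort("need >= 2 phenotypes")
  m <- as.matrix(traits[ids])
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    bad <- ids[sds == 0 | is.na(sds)]
    warn(paste0("zero-variance phenotype(s) excluded: ", paste(bad, collapse = ", ")))
    ids <- setdiff(ids, bad)
    if (length(ids) < 2) abort("fewer than 2 phenotypes with variance")
    m <- m[, ids, drop = FALSE]
  }
  rho <- suppressWarnings(cor(m, method = "spearman", use = "pairwise.complete.obs"))
  d <- as.dist(1 - abs(rho))
  hc <- hclust(d, method = "average")
  module <- cutree(hc, h = cut_height)
  cat_of <- if (is.null(categories)) rep(NA_character_, length(ids))
            else unname(categories[ids])
  modules <- tibble(trait_id = ids, module = as.integer(module), category = cat_of)
  n_split <- nrow(distinct(modules, .data$module,
                           category = ifelse(is.na(.data$category), "", .data$category)))
  structure(list(
    modules = modules, n_modules = length(unique(module)),
    n_modules_split = n_split, rho = rho, cut_height = cut_height
  ), class = "phenotype_modules")
}

#' @export
print.phenotype_modules <- function(x, ...) {
  cat(sprintf("<phenotype_modules> %d phenotypes in %d modules (%d with subclass split)\n",
              nrow(x$modules), x$n_modules, x$n_modules_split))
  invisible(x)
}

#' @export
#' @method tidy phenotype_modules
tidy.phenotype_modules <- function(x, ...) x$modules

#' Filtered phenotype correlation network and superclusters
#'
#' Edges connect phenotype pairs with `|Spearman rho| >= edge_cut` (default
#' 0.7). Superclusters are the connected components of this graph that span
#' more than one module.
#'
#' @param modules a [phenotype_modules()] result.
#' @param edge_cut absolute Spearman threshold (inclusive).
#' @return List with `edges` (tibble `from`, `to`, `rho`) and `superclusters`
#'   (tibble `trait_id`, `supercluster`; `NA` for phenotypes outside any
#'   multi-module component).
#' @export
module_network <- function(modules, edge_cut = 0.7) {
  rho <- modules$rho
  ids <- rownames(rho)
  ut <- which(upper.tri(rho) & abs(rho) >= edge_cut, arr.ind = TRUE)
  edges <- tibble(from = ids[ut[, 1]], to = ids[ut[, 2]], rho = rho[ut])
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(gr)
  member <- comp$membership
  mod_of <- setNames(modules$modules$module, modules$modules$trait_id)
  multi <- vapply(seq_len(comp$no), function(k) {
    length(unique(mod_of[names(member)[member == k]])) > 1
  }, logical(1))
  sc_ids <- cumsum(multi)
  supercluster <- ifelse(multi[member], sc_ids[member], NA_integer_)
  list(
    edges = edges,
    superclusters = tibble(trait_id = names(member),
                           supercluster = as.integer(supercluster))
  )
}

#' Build a four-axis hiveplot graph for one phenotype
#'
#' Nodes are the molecules (genes per tissue, metabolites) whose absolute
#' correlation with the phenotype reaches the inclusion threshold, placed on
#' their axis (`cortex`, `liver`, `metabolite`) with a radial coordinate equal
#' to the within-axis rank of their SD response (log2 fold change) scaled to
#' `(0, 1]` -- the most down-regulated included molecule sits closest to the
#' center. Cross-molecule edges keep the pairs passing their own quantile
#' thresholds (gene-gene associations use cis-eQTL-corrected partial
#' correlations when genotypes are supplied); eQTL edges link the genetic axis
#' to included genes with a significant cis-eQTL; trait-inclusion edges record
#' each node's correlation with the phenotype.
#'
#' @param trait_id the phenotype the plot is built for.
#' @param corr tibble from [trait_molecule_correlation()] covering this
#'   phenotype against all molecules (used both for inclusion and for the
#'   data-driven threshold).
#' @param responses tibble `molecule_id`, `axis`, `log2fc` giving each
#'   molecule's SD response and axis (`cortex`, `liver`, `metabolite`).
#' @param molecule_values named list of molecules x strains matrices (or
#'   [expr_matrix]) per axis, used to compute cross-molecule edges.
#' @param eqtls optional `cis_eqtl` tibble; included genes with
#'   `q < eqtl_q_max` gain an edge from the genetic axis.
#' @param g optional [geno_matrix] for partial-correlation correction of
#'   gene-gene edges.
#' @param include_threshold absolute-correlation inclusion cutoff; `NULL`
#'   (default) derives it from `corr` as the top `include_top` fraction.
#' @param include_top,gene_gene_top,gene_metab_top quantile fractions for the
#'   data-driven thresholds (defaults 0.005, 0.0005, 0.005).
#' @param eqtl_q_max q-value cutoff for eQTL edges.
#' @return A `hive_graph`: list with `nodes` (tibble `id`, `axis`, `radius`,
#'   `log2fc`, `r_trait`), `edges` (tibble `from`, `to`, `weight`, `sign`,
#'   `kind`), `trait_id`, `thresholds`.
#' @export
build_hivegraph <- function(trait_id, corr, responses, molecule_values = NULL,
                            eqtls = NULL, g = NULL, include_threshold = NULL,
                            include_top = 0.005, gene_gene_top = 0.0005,
                            gene_metab_top = 0.005, eqtl_q_max = 0.05) {
  tc <- corr[corr$trait_id == trait_id & !is.na(corr$r), ]
  if (!nrow(tc)) abort(paste0("trait absent from correlation records: ", trait_id))
  if (is.null(include_threshold)) {
    include_threshold <- quantile_threshold(corr$r, include_top)
  }
  inc <- tc[abs(tc$r) >= include_threshold, ]
  nodes <- left_join(
    tibble(id = inc$molecule_id, r_trait = inc$r),
    as_tibble(responses)[c("molecule_id", "axis", "log2fc")],
    by = c(id = "molecule_id")
  )
  nodes$axis[is.na(nodes$axis)] <- "metabolite"
  nodes$log2fc[is.na(nodes$log2fc)] <- 0
  nodes <- nodes |>
    group_by(.data$axis) |>
    mutate(radius = rank(.data$log2fc, ties.method = "first") /
             dplyr::n()) |>
    ungroup() |>
    select("id", "axis", "radius", "log2fc", "r_trait") |>
    arrange(.data$axis, .data$id)

  edges <- tibble(from = character(), to = character(), weight = numeric(),
                  sign = integer(), kind = character())
  get_mat <- function(m) if (inherits(m, "expr_matrix")) m$log_cpm else as.matrix(m)

  if (!is.null(molecule_values) && nrow(nodes) > 1) {
    mats <- lapply(molecule_values, get_mat)
    shared <- Reduce(intersect, lapply(mats, colnames))
    vals <- do.call(rbind, lapply(mats, function(m) m[, shared, drop = FALSE]))
    vals <- vals[rownames(vals) %in% nodes$id, , drop = FALSE]
    if (nrow(vals) > 1) {
      # cis-eQTL correction: residualize each included gene on its best marker
      if (!is.null(g) && !is.null(eqtls)) {
        for (gid in intersect(rownames(vals), eqtls$gene_id[!is.na(eqtls$q) &
                                                            eqtls$q < eqtl_q_max])) {
          mid <- eqtls$marker_id[match(gid, eqtls$gene_id)]
          if (is.na(mid) || !mid %in% marker_ids(g)) next
          z <- g$codes[shared, mid]
          if (length(unique(z[!is.na(z)])) < 2) next
          ok <- !is.na(z)
          vals[gid, ok] <- resid(lm(vals[gid, ok] ~ z[ok]))
        }
      }
      cm <- suppressWarnings(cor(t(vals)))
      axis_of <- setNames(nodes$axis, nodes$id)
      ut <- which(upper.tri(cm), arr.ind = TRUE)
      pair <- tibble(
        from = rownames(cm)[ut[, 1]], to = rownames(cm)[ut[, 2]],
        weight = cm[ut]
      ) |> filter(is.finite(.data$weight))
      pair$kind <- unname(ifelse(
        axis_of[pair$from] != "metabolite" & axis_of[pair$to] != "metabolite",
        "gene-gene",
        ifelse(xor(axis_of[pair$from] == "metabolite",
                   axis_of[pair$to] == "metabolite"),
               "gene-metabolite", "metabolite-metabolite")
      ))
      keep <- logical(nrow(pair))
      for (knd in unique(pair$kind)) {
        sel <- pair$kind == knd
        topf <- if (knd == "gene-gene") gene_gene_top else gene_metab_top
        cut <- quantile_threshold(pair$weight[sel], topf)
        keep[sel] <- abs(pair$weight[sel]) >= cut
      }
      pair <- pair[keep, ]
      if (nrow(pair)) {
        edges <- bind_rows(edges, tibble(
          from = pair$from, to = pair$to, weight = pair$weight,
          sign = as.integer(sign(pair$weight)), kind = pair$kind
        ))
      }
    }
  }
  if (!is.null(eqtls) && nrow(nodes)) {
    eq <- eqtls[!is.na(eqtls$q) & eqtls$q < eqtl_q_max &
                eqtls$gene_id %in% nodes$id, ]
    if (nrow(eq)) {
      edges <- bind_rows(edges, tibble(
        from = paste0("locus:", eq$marker_id), to = eq$gene_id,
        weight = -log10(pmax(eq$q, 1e-300)),
        sign = as.integer(eq$slope_sign), kind = "eQTL-link"
      ))
      loci <- distinct(tibble(id = paste0("locus:", eq$marker_id)))
      loci$axis <- "genetic"; loci$radius <- seq_len(nrow(loci)) / nrow(loci)
      loci$log2fc <- NA_real_; loci$r_trait <- NA_real_
      nodes <- bind_rows(nodes, loci)
    }
  }
  structure(list(
    nodes = nodes, edges = edges, trait_id = trait_id,
    thresholds = list(include = include_threshold,
                      gene_gene_top = gene_gene_top,
                      gene_metab_top = gene_metab_top)
  ), class = "hive_graph")
}

#' @export
print.hive_graph <- function(x, ...) {
  cat(sprintf("<hive_graph> trait '%s': %d nodes on %d axes, %d edges\n",
              x$trait_id, nrow(x$nodes), length(unique(x$nodes$axis)),
              nrow(x$edges)))
  invisible(x)
}

#' Export / import a hiveplot graph
#'
#' `export_hivegraph()` writes the graph as JSON (documented schema: fields
#' `trait_id`, `thresholds`, `nodes`, `edges`) and, with a `.graphml` path or
#' `graphml = TRUE`, additionally as GraphML via igraph. Node and edge order
#' is deterministic. `read_hivegraph()` restores the JSON form.
#'
#' @param gr a `hive_graph`.
#' @param path output path for the JSON file.
#' @param graphml also write `<path without .json>.graphml` (default TRUE).
#' @return `path`, invisibly.
#' @export
export_hivegraph <- function(gr, path, graphml = TRUE) {
  payload <- list(
    trait_id = gr$trait_id, thresholds = gr$thresholds,
    nodes = gr$nodes, edges = gr$edges
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  if (graphml) {
    gml <- sub("\\.json$", ".graphml", path)
    if (gml == path) gml <- paste0(path, ".graphml")
    ig <- igraph::graph_from_data_frame(
      d = if (nrow(gr$edges)) gr$edges else
        data.frame(from = character(), to = character()),
      directed = FALSE,
      vertices = as.data.frame(gr$nodes)
    )
    igraph::write_graph(ig, gml, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_hivegraph
#' @export
read_hivegraph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as_tibble(x$nodes)
  edges <- as_tibble(x$edges)
  if (nrow(edges)) edges$sign <- as.integer(edges$sign)
  if (!nrow(edges)) {
    edges <- tibble(from = character(), to = character(), weight = numeric(),
                    sign = integer(), kind = character())
  }
  structure(list(nodes = nodes, edges = edges, trait_id = x$trait_id,
                 thresholds = x$thresholds), class = "hive_graph")
}
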