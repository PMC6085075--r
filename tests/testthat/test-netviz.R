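make_block_traits <- function(seed = 1, n_strains = 40) {
  # 3 blocks of tightly correlated phenotypes, independent across blocks
  set.seed(seed)
  strains <- sprintf("S%02d", seq_len(n_strains))
  latent <- matrix(rnorm(n_strains * 3), n_strains, 3)
  df <- tibble::tibble(strain_id = strains)
  for (b in 1:3) {
    for (k in 1:3) {
      df[[sprintf("ph%d_%d", b, k)]] <- latent[, b] + rnorm(n_strains, sd = 0.1)
    }
  }
  df
}

test_that("phenotype modules recover a planted block structure", {
  df <- make_block_traits(2)
  pm <- phenotype_modules(df, cut_height = 0.3)
  expect_equal(pm$n_modules, 3)
  mods <- tidy(pm)
  block_of <- sub("_.*", "", mods$trait_id)
  expect_equal(length(unique(paste(block_of, mods$module))), 3)
})

test_that("identical phenotypes share a module; independent ones usually do not", {
  set.seed(4)
  df <- tibble::tibble(strain_id = sprintf("S%d", 1:30),
                       a = rnorm(30))
  df$b <- df$a
  df$c <- rnorm(30)
  pm <- phenotype_modules(df)
  mods <- tidy(pm)
  expect_equal(mods$module[mods$trait_id == "a"], mods$module[mods$trait_id == "b"])
  separate <- vapply(1:20, function(s) {
    set.seed(s)
    d2 <- tibble::tibble(strain_id = sprintf("S%d", 1:30),
                         x = rnorm(30), y = rnorm(30))
    pm2 <- phenotype_modules(d2)
    pm2$n_modules == 2
  }, logical(1))
  expect_gte(mean(separate), 0.95)
})

test_that("module structure is invariant to monotone transforms and counts split by category", {
  df <- make_block_traits(6)
  pm1 <- phenotype_modules(df)
  df2 <- df
  df2$ph1_1 <- exp(df2$ph1_1)          # monotone increasing
  df2$ph2_1 <- -df2$ph2_1              # monotone decreasing (|rho| unchanged)
  pm2 <- phenotype_modules(df2)
  expect_equal(tidy(pm1)$module, tidy(pm2)$module)
  cats <- stats::setNames(rep(c("EEG", "State", "EEG"), each = 3),
                          setdiff(names(df), "strain_id"))
  pm3 <- phenotype_modules(df, categories = cats)
  expect_gte(pm3$n_modules_split, pm3$n_modules)
  expect_warning(phenotype_modules(dplyr::mutate(df, flat = 1)), "zero-variance")
})

test_that("module networks apply the strict |rho| edge rule and find superclusters", {
  df <- make_block_traits(8)
  pm <- phenotype_modules(df)
  net <- module_network(pm, edge_cut = 0.7)
  # within-block pairs are fully connected: 3 blocks x choose(3,2) edges
  expect_equal(nrow(net$edges), 9)
  blocks <- sub("_.*", "", c(net$edges$from, net$edges$to))
  expect_true(all(blocks[1:9] == blocks[10:18]))
  # a pair just below the cutoff gains no edge
  rho <- pm$rho
  expect_true(all(abs(net$edges$rho) >= 0.7))
  pm$rho["ph1_1", "ph2_1"] <- pm$rho["ph2_1", "ph1_1"] <- 0.69
  net2 <- module_network(pm, edge_cut = 0.7)
  expect_false(any(net2$edges$from == "ph1_1" & net2$edges$to == "ph2_1"))
  # merge two modules through one strong cross edge -> one supercluster
  pm$rho["ph1_1", "ph2_1"] <- pm$rho["ph2_1", "ph1_1"] <- 0.95
  net3 <- module_network(pm, edge_cut = 0.7)
  sc <- net3$superclusters
  expect_equal(sc$supercluster[sc$trait_id == "ph1_1"],
               sc$supercluster[sc$trait_id == "ph2_2"])
  expect_true(is.na(sc$supercluster[sc$trait_id == "ph3_1"]))
})

make_hive_inputs <- function(seed = 1) {
  set.seed(seed)
  strains <- sprintf("S%02d", 1:30)
  trait <- rnorm(30)
  genes <- sprintf("g%02d", 1:12)
  metas <- sprintf("met%02d", 1:6)
  gm <- matrix(rnorm(12 * 30, 6, 1), 12, 30, dimnames = list(genes, strains))
  mm <- matrix(rnorm(6 * 30), 6, 30, dimnames = list(metas, strains))
  # hub metabolite tied to the trait and to 5 genes
  mm[1, ] <- trait + rnorm(30, sd = 0.2)
  for (g in 1:5) gm[g, ] <- 6 + trait + rnorm(30, sd = 0.25)
  traits <- tibble::tibble(strain_id = strains, trait = trait)
  corr <- trait_molecule_correlation(
    traits, list(SD = rbind(gm, mm)))
  responses <- tibble::tibble(
    molecule_id = c(genes, metas),
    axis = c(rep("cortex", 12), rep("metabolite", 6)),
    log2fc = c(seq(-2, 2, length.out = 12), seq(-1, 1, length.out = 6))
  )
  list(corr = corr, responses = responses, gm = gm, mm = mm)
}

test_that("hivegraph inclusion, radii and hub edges follow the rules", {
  hi <- make_hive_inputs(3)
  gr <- build_hivegraph("trait", hi$corr, hi$responses,
                        molecule_values = list(cortex = hi$gm,
                                               metabolite = hi$mm),
                        include_threshold = 0.485,
                        gene_gene_top = 0.9, gene_metab_top = 0.9)
  # planted hub present with its gene partners
  expect_true("met01" %in% gr$nodes$id)
  expect_true(all(sprintf("g%02d", 1:5) %in% gr$nodes$id))
  hub_edges <- gr$edges[gr$edges$kind == "gene-metabolite" &
                          (gr$edges$from == "met01" | gr$edges$to == "met01"), ]
  expect_gte(nrow(hub_edges), 3)
  # radial rank rule: most down-regulated node sits innermost per axis
  for (ax in unique(gr$nodes$axis)) {
    nd <- gr$nodes[gr$nodes$axis == ax, ]
    expect_equal(nd$id[which.min(nd$radius)], nd$id[which.min(nd$log2fc)])
    expect_true(all(nd$radius > 0 & nd$radius <= 1))
  }
  # raising the inclusion threshold can only shrink the node set
  gr_hi <- build_hivegraph("trait", hi$corr, hi$responses,
                           include_threshold = 0.8)
  expect_true(all(gr_hi$nodes$id %in% gr$nodes$id))
  expect_lte(nrow(gr_hi$nodes), nrow(gr$nodes))
  # unknown trait errors
  expect_error(build_hivegraph("nope", hi$corr, hi$responses), "absent")
})

test_that("an unreachable inclusion threshold yields an empty but exportable graph", {
  hi <- make_hive_inputs(5)
  gr <- build_hivegraph("trait", hi$corr, hi$responses, include_threshold = 2)
  expect_equal(nrow(gr$nodes), 0)
  f <- withr::local_tempfile(fileext = ".json")
  export_hivegraph(gr, f, graphml = FALSE)
  expect_true(jsonlite::validate(readChar(f, file.size(f))))
})

test_that("hivegraph JSON round-trips and GraphML is readable by igraph", {
  hi <- make_hive_inputs(7)
  gr <- build_hivegraph("trait", hi$corr, hi$responses,
                        molecule_values = list(cortex = hi$gm,
                                               metabolite = hi$mm),
                        include_threshold = 0.485,
                        gene_gene_top = 0.2, gene_metab_top = 0.2)
  f <- withr::local_tempfile(fileext = ".json")
  export_hivegraph(gr, f)
  back <- read_hivegraph(f)
  expect_equal(back$nodes, gr$nodes)
  expect_equal(back$edges, gr$edges)
  expect_equal(back$trait_id, gr$trait_id)
  gml <- sub("\\.json$", ".graphml", f)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(gr$nodes))
  expect_equal(igraph::ecount(ig), nrow(gr$edges))
})
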