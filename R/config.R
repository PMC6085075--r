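# Run configuration for the command-line pipeline: a flat YAML file of
# thresholds, permutation counts and seeds, validated against the keys below.

config_defaults <- function() {
  list(
    n_perm_scan = 1000, n_perm_cis = 1000, n_perm_fdr = 10000,
    seed = 1,
    tier_significant = 0.05, tier_highly_suggestive = 0.10,
    tier_suggestive = 0.63,
    trans_p_threshold = 1e-4,
    cis_window_mb = 2.0,
    lod_drop = 1.5,
    include_top = 0.005, gene_gene_top = 0.0005, gene_metab_top = 0.005,
    winsor_q = 0.95, n_bins = 10,
    module_cut_height = 0.3, module_edge_cut = 0.7,
    tissue = "cortex", condition = "SD"
  )
}

#' Parse and validate a pipeline configuration file
#'
#' Reads a flat YAML key-value file, fills defaults, and validates: unknown
#' keys are an error listing the valid ones; probability-scale thresholds
#' must lie in `(0, 1]`; permutation counts and seeds must be integers.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return A named list of configuration values (class `run_config`).
#' @export
parse_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("no such config file: ", path))
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                     "\nvalid keys: ", paste(names(cfg), collapse = ", ")))
      }
      cfg[names(user)] <- user
    }
  }
  validate_config(cfg)
}

#' @rdname parse_config
#' @param cfg named list of configuration values.
#' @export
validate_config <- function(cfg) {
  prob_keys <- c("tier_significant", "tier_highly_suggestive", "tier_suggestive",
                 "trans_p_threshold", "include_top", "gene_gene_top",
                 "gene_metab_top", "winsor_q")
  for (k in prob_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      abort(sprintf("config key %s must be a number in (0, 1], got %s",
                    k, paste(v, collapse = ",")))
    }
  }
  int_keys <- c("n_perm_scan", "n_perm_cis", "n_perm_fdr", "seed", "n_bins")
  for (k in int_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || v != round(v)) {
      abort(sprintf("config key %s must be an integer", k))
    }
    cfg[[k]] <- as.integer(v)
  }
  if (!cfg$tier_significant <= cfg$tier_highly_suggestive ||
      !cfg$tier_highly_suggestive <= cfg$tier_suggestive) {
    abort("tier thresholds must be ordered significant <= highly suggestive <= suggestive")
  }
  structure(cfg, class = c("run_config", "list"))
}
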