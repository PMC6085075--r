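# Readers/writers for the tabular inputs: strain-level trait tables (TSV),
# log-CPM expression (TSV), gene annotations (BED4), variant tables (TSV).
# All writers emit tab-separated UTF-8 with a deterministic column order so
# read/write round-trips are lossless.

check_numeric_cols <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA")
      if (length(bad)) {
        abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                      v[bad[1]], bad[1], cl, path))
      }
      df[[cl]] <- conv
    }
  }
  df
}

#' Read / write strain-level trait tables
#'
#' A trait table is a wide tibble: a `strain_id` column (plus an optional
#' `animal` column when per-animal replicates are recorded) followed by one
#' numeric column per phenotype or metabolite. Trait condition labels
#' (`bsl`, `SD`, `rec`, `contrast`) may be supplied as a named character
#' vector and travel in the `conditions` attribute.
#'
#' @param path TSV file with a header row.
#' @return A tibble; numeric trait columns are enforced (a non-numeric cell is
#'   an error naming its row and column).
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(.default = "c"))
  id_cols <- intersect(c("strain_id", "animal"), names(df))
  if (!"strain_id" %in% id_cols) abort("trait table must have a strain_id column")
  trait_cols <- setdiff(names(df), id_cols)
  df <- check_numeric_cols(df, trait_cols, path)
  all_na <- vapply(df[trait_cols], function(v) all(is.na(v)), logical(1))
  if (any(all_na)) {
    abort(paste0("trait entirely missing: ", trait_cols[all_na][1]))
  }
  as_tibble(df)
}

#' @rdname read_trait_table
#' @param traits tibble as returned by [read_trait_table()].
#' @export
write_trait_table <- function(traits, path) {
  readr::write_tsv(traits, path)
  invisible(path)
}

#' Expression matrix container
#'
#' Wraps a genes x strains matrix of log counts-per-million together with its
#' tissue and condition labels.
#'
#' @param log_cpm numeric matrix, genes in rows, strains in columns.
#' @param tissue e.g. `"cortex"` or `"liver"`.
#' @param condition `"Ctr"` or `"SD"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(log_cpm, tissue = "cortex", condition = "Ctr") {
  log_cpm <- as.matrix(log_cpm)
  if (is.null(rownames(log_cpm)) || is.null(colnames(log_cpm))) {
    abort("log_cpm needs gene rownames and strain colnames")
  }
  if (any(!is.finite(log_cpm))) abort("expression values must be finite")
  structure(list(log_cpm = log_cpm, tissue = tissue, condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d strains (%s, %s)\n",
              nrow(x$log_cpm), ncol(x$log_cpm), x$tissue, x$condition))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$log_cpm)

#' @export
#' @method tidy expr_matrix
tidy.expr_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x$log_cpm), times = ncol(x$log_cpm)),
    strain_id = rep(colnames(x$log_cpm), each = nrow(x$log_cpm)),
    log_cpm = as.numeric(x$log_cpm),
    tissue = x$tissue, condition = x$condition
  )
}

#' Read / write a log-CPM expression matrix
#'
#' TSV layout: `gene_id` column then one numeric column per strain. Missing
#' cells are not allowed (upstream normalisation yields complete matrices).
#'
#' @param path TSV file.
#' @inheritParams expr_matrix
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, tissue = "cortex", condition = "Ctr") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(.default = "c"))
  if (!"gene_id" %in% names(df)) abort("expression table must have a gene_id column")
  strain_cols <- setdiff(names(df), "gene_id")
  df <- check_numeric_cols(df, strain_cols, path)
  m <- as.matrix(df[strain_cols])
  rownames(m) <- df$gene_id
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing expression value for gene %s, strain %s in %s",
                  rownames(m)[idx[1]], colnames(m)[idx[2]], path))
  }
  expr_matrix(m, tissue = tissue, condition = condition)
}

#' @rdname read_expression
#' @param expr an [expr_matrix].
#' @export
write_expression <- function(expr, path) {
  df <- bind_cols(tibble(gene_id = rownames(expr$log_cpm)),
                  as_tibble(expr$log_cpm))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read gene annotations from BED4
#'
#' BED intervals are 0-based half-open in base pairs; they are converted to Mb
#' on read. The gene center, used to look up QTL-curve scores during
#' prioritization, is the interval midpoint.
#'
#' @param path BED4 file (`chrom  start  end  name`), tab- or space-separated,
#'   no header.
#' @return Tibble with `gene_id`, `chrom`, `start_mb`, `end_mb`, `center_mb`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 4) abort("BED4 requires chrom, start, end, name")
  names(df)[1:4] <- c("chrom", "start", "end", "gene_id")
  if (any(df$start > df$end)) {
    bad <- which(df$start > df$end)[1]
    abort(sprintf("BED interval with start > end at line %d (%s)", bad, df$gene_id[bad]))
  }
  tibble(
    gene_id = as.character(df$gene_id),
    chrom = sub("^chr", "", as.character(df$chrom)),
    start_mb = df$start / 1e6,
    end_mb = df$end / 1e6,
    center_mb = (df$start + df$end) / 2e6
  )
}

#' @rdname read_gene_bed
#' @param genes tibble of gene annotations.
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(
    chrom = paste0("chr", genes$chrom),
    start = format(round(genes$start_mb * 1e6), scientific = FALSE, trim = TRUE),
    end = format(round(genes$end_mb * 1e6), scientific = FALSE, trim = TRUE),
    name = genes$gene_id
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write variant annotation tables
#'
#' Variants carry a consequence class and, for nonsynonymous variants only, a
#' protein-damage probability in `[0, 1]` (e.g. a PolyPhen-2 score) consumed by
#' the variant component of the prioritization score.
#'
#' @param path TSV with columns `gene_id`, `chrom`, `pos_mb`, `consequence`,
#'   `damage_prob`.
#' @return A validated tibble.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(.default = "c"))
  need <- c("gene_id", "chrom", "pos_mb", "consequence", "damage_prob")
  if (!all(need %in% names(df))) {
    abort(paste0("variant table must have columns: ", paste(need, collapse = ", ")))
  }
  df <- check_numeric_cols(df, c("pos_mb", "damage_prob"), path)
  validate_variants(as_tibble(df[need]))
}

validate_variants <- function(v) {
  nonsyn <- v$consequence == "nonsynonymous"
  if (any(nonsyn & is.na(v$damage_prob))) {
    abort("nonsynonymous variants require a damage_prob")
  }
  if (any(!nonsyn & !is.na(v$damage_prob))) {
    abort("damage_prob is only meaningful for nonsynonymous variants")
  }
  if (any(!is.na(v$damage_prob) & (v$damage_prob < 0 | v$damage_prob > 1))) {
    abort("damage_prob must lie in [0, 1]")
  }
  v
}

#' @rdname read_variants
#' @param variants tibble of variants.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}
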