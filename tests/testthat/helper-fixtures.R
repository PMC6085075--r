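# Small hand-built fixtures shared across tests.

make_toy_geno <- function(codes, chrom = NULL, pos_mb = NULL) {
  n_mark <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("1", n_mark)
  if (is.null(pos_mb)) pos_mb <- seq_len(n_mark) * 10
  if (is.null(rownames(codes))) rownames(codes) <- sprintf("S%02d", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("m%02d", seq_len(n_mark))
  geno_matrix(codes, data.frame(marker_id = colnames(codes), chrom = chrom,
                                pos_mb = pos_mb))
}

# naive per-column Henikoff contribution oracle: for each column, count how
# many rows share each symbol (k) and how many distinct symbols there are (r);
# a row contributes 1/(r*k). Row weight = sum over columns, normalized.
henikoff_oracle <- function(mat) {
  contrib <- matrix(0, nrow(mat), ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    tab <- table(col)
    r <- length(tab)
    for (i in seq_len(nrow(mat))) {
      k <- tab[[as.character(col[i])]]
      contrib[i, j] <- 1 / (r * k)
    }
  }
  w <- rowSums(contrib)
  w / sum(w)
}

toy_trait <- function(g, values, trait_id = "trait") {
  df <- tibble::tibble(strain_id = strain_ids(g))
  df[[trait_id]] <- values
  df
}
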