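#' Genotype container for a two-allele recombinant inbred panel
#'
#' A `geno_matrix` couples a strains x markers matrix of allele codes with the
#' marker map. Codes follow the panel convention: `0` = first-parent allele
#' (B, e.g. C57BL/6J), `1` = second-parent allele (D, e.g. DBA/2J), `NA` =
#' heterozygous or unknown call (RI lines are expected homozygous, so
#' heterozygous calls are treated as missing).
#'
#' @param codes integer/numeric matrix (strains x markers) with values in
#'   `{0, 1, NA}`; dimnames give strain and marker ids.
#' @param map data frame with columns `marker_id`, `chrom`, `pos_mb` and
#'   optionally `pos_cm`, one row per column of `codes`.
#' @return An object of class `geno_matrix` with elements `codes` (matrix) and
#'   `map` (tibble sorted by chromosome then physical position; `codes`
#'   columns follow the same order).
#' @export
geno_matrix <- function(codes, map) {
  map <- as_tibble(map)
  required <- c("marker_id", "chrom", "pos_mb")
  if (!all(required %in% names(map))) {
    abort(paste0("map must have columns: ", paste(required, collapse = ", ")))
  }
  if (!"pos_cm" %in% names(map)) map$pos_cm <- NA_real_
  codes <- as.matrix(codes)
  if (ncol(codes) != nrow(map)) abort("ncol(codes) must equal nrow(map)")
  if (is.null(colnames(codes))) colnames(codes) <- map$marker_id
  if (!identical(colnames(codes), as.character(map$marker_id))) {
    codes <- codes[, as.character(map$marker_id), drop = FALSE]
  }
  if (anyDuplicated(map$marker_id)) {
    abort(paste0("duplicate marker id: ", map$marker_id[duplicated(map$marker_id)][1]))
  }
  if (anyDuplicated(rownames(codes))) abort("strain ids must be unique")
  bad <- !(codes %in% c(0, 1) | is.na(codes))
  if (any(bad)) abort("genotype codes must be 0, 1 or NA")
  ord <- order(map$chrom, map$pos_mb)
  map <- map[ord, ]
  codes <- codes[, ord, drop = FALSE]
  storage.mode(codes) <- "integer"
  structure(list(codes = codes, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d strains x %d markers on %d chromosome(s); %.1f%% missing\n",
    nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom)),
    100 * mean(is.na(x$codes))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' @rdname geno_matrix
#' @export
strain_ids <- function(g) rownames(g$codes)

#' @rdname geno_matrix
#' @export
marker_ids <- function(g) colnames(g$codes)

#' Long tibble view of a genotype matrix
#'
#' @param x a [geno_matrix].
#' @param ... unused.
#' @return Tibble with columns `strain_id`, `marker_id`, `chrom`, `pos_mb`,
#'   `code`.
#' @export
#' @method tidy geno_matrix
tidy.geno_matrix <- function(x, ...) {
  out <- tibble(
    strain_id = rep(rownames(x$codes), times = ncol(x$codes)),
    marker_id = rep(colnames(x$codes), each = nrow(x$codes)),
    code = as.integer(x$codes)
  )
  left_join(out, x$map[c("marker_id", "chrom", "pos_mb")], by = "marker_id")
}

#' Read a GeneNetwork-style .geno genotype file
#'
#' Parses the GeneNetwork `.geno` dialect: `#` comment lines, `@`-prefixed
#' metadata (`@mat`, `@pat`, `@het`, `@unk`), then a header line
#' `Chr Locus cM [Mb] <strain...>` followed by one row per marker with
#' per-strain calls in `{B, D, H, U}`. `B` maps to 0, `D` to 1, `H`
#' (heterozygous) and `U` (unknown) to `NA`. Presence of the `Mb` column is
#' auto-detected; without it, physical positions fall back to the cM column.
#'
#' @param path path to a `.geno` file.
#' @return A [geno_matrix].
#' @export
read_geno <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "@")]
  codemap <- c(B = 0L, D = 1L, H = NA_integer_, U = NA_integer_)
  for (m in meta) {
    kv <- strsplit(sub("^@", "", m), ":", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "mat") names(codemap)[1] <- val
      if (key == "pat") names(codemap)[2] <- val
      if (key == "het") names(codemap)[3] <- val
      if (key == "unk") names(codemap)[4] <- val
    }
  }
  body <- lines[!startsWith(lines, "#") & !startsWith(lines, "@") & nzchar(trimws(lines))]
  if (length(body) < 2) abort("no marker rows found")
  fields <- strsplit(body, "\t|[ ]+")
  header <- fields[[1]]
  if (!identical(tolower(header[1:2]), c("chr", "locus"))) {
    abort("header must start with 'Chr Locus'")
  }
  has_mb <- length(header) >= 4 && tolower(header[4]) == "mb"
  n_fixed <- if (has_mb) 4L else 3L
  strains <- header[-seq_len(n_fixed)]
  rows <- fields[-1]
  widths <- lengths(rows)
  bad <- which(widths != length(header))
  if (length(bad)) {
    abort(sprintf("malformed row at line %d: expected %d fields, found %d",
                  bad[1] + 1L, length(header), widths[bad[1]]))
  }
  tab <- do.call(rbind, rows)
  map <- tibble(
    marker_id = tab[, 2],
    chrom = tab[, 1],
    pos_cm = suppressWarnings(as.numeric(tab[, 3])),
    pos_mb = if (has_mb) suppressWarnings(as.numeric(tab[, 4])) else
      suppressWarnings(as.numeric(tab[, 3]))
  )
  calls <- tab[, -seq_len(n_fixed), drop = FALSE]
  unknown <- setdiff(unique(as.vector(calls)), names(codemap))
  if (length(unknown)) {
    abort(paste0("unknown genotype code(s): ", paste(unknown, collapse = ", ")))
  }
  codes <- matrix(codemap[as.vector(calls)], nrow = nrow(calls))
  codes <- t(codes)                      # strains x markers
  rownames(codes) <- strains
  colnames(codes) <- map$marker_id
  geno_matrix(codes, map)
}

#' Write a genotype matrix in the .geno dialect
#'
#' @param g a [geno_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geno <- function(g, path) {
  map <- g$map
  calls <- matrix("U", nrow = ncol(g$codes), ncol = nrow(g$codes))
  tg <- t(g$codes)
  calls[!is.na(tg) & tg == 0L] <- "B"
  calls[!is.na(tg) & tg == 1L] <- "D"
  has_cm <- !all(is.na(map$pos_cm))
  header <- c("Chr", "Locus", "cM", "Mb", rownames(g$codes))
  fmt <- function(x) sprintf("%.12g", x)
  rows <- cbind(as.character(map$chrom), map$marker_id,
                fmt(if (has_cm) map$pos_cm else map$pos_mb),
                fmt(map$pos_mb), calls)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("@mat:B", "@pat:D", "@het:H", "@unk:U",
               paste(header, collapse = "\t"),
               apply(rows, 1, paste, collapse = "\t")), con)
  invisible(path)
}

#' Genotype quality control
#'
#' Drops markers missing in more than `max_missing` of strains, then collapses
#' runs of consecutive markers (within a chromosome) whose strain-distribution
#' patterns are identical, keeping the first marker of each run by position.
#' Redundant patterns carry no extra mapping information, so one representative
#' suffices. An upstream variant-calling QUAL filter is out of scope here; the
#' report carries a `qual_prefiltered` flag so callers can record whether one
#' was applied before import.
#'
#' @param g a [geno_matrix].
#' @param max_missing maximum tolerated missing fraction per marker (default
#'   0.10).
#' @param qual_prefiltered logical flag recorded verbatim in the report.
#' @return A `geno_matrix` with attribute `qc_report`: a list with tibbles
#'   `dropped` (marker, missing fraction) and `collapsed` (marker, kept
#'   representative), plus the flag.
#' @export
genotype_qc <- function(g, max_missing = 0.10, qual_prefiltered = FALSE) {
  miss <- colMeans(is.na(g$codes))
  drop <- miss > max_missing
  dropped <- tibble(marker_id = colnames(g$codes)[drop],
                    missing_fraction = unname(miss[drop]))
  codes <- g$codes[, !drop, drop = FALSE]
  map <- g$map[!drop, ]
  if (ncol(codes) == 0) abort("no markers survive QC")

  # strain-distribution pattern, NA encoded distinctly
  pat <- apply(codes, 2, function(v) paste(ifelse(is.na(v), "U", v), collapse = ""))
  keep <- rep(TRUE, ncol(codes))
  rep_of <- character(0); coll <- character(0)
  for (j in seq_len(ncol(codes))[-1]) {
    same_chr <- map$chrom[j] == map$chrom[j - 1]
    if (same_chr && pat[j] == pat[j - 1] && !keep[j - 1]) {
      # continue a collapsed run: compare to run representative
      keep[j] <- FALSE
    } else if (same_chr && pat[j] == pat[j - 1]) {
      keep[j] <- FALSE
    }
    if (!keep[j]) {
      run_start <- max(which(keep[seq_len(j)]))
      coll <- c(coll, colnames(codes)[j])
      rep_of <- c(rep_of, colnames(codes)[run_start])
    }
  }
  report <- list(
    dropped = dropped,
    collapsed = tibble(marker_id = coll, kept_as = rep_of),
    qual_prefiltered = qual_prefiltered
  )
  out <- geno_matrix(codes[, keep, drop = FALSE], map[keep, ])
  attr(out, "qc_report") <- report
  out
}
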