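## Profile-table dialects (merged taxonomic table, stratified gene-family
## table, pathway tables, sample metadata) and the abundance/coverage gates.

parse_error <- function(path, line, why) {
  stop_skinmwas(sprintf("parse error in '%s' at line %d: %s", path, line, why),
                "skinmwas_error_parse")
}

read_table_lines <- function(path, header_prefix = NULL, id_name = NULL) {
  if (!file.exists(path)) {
    stop_skinmwas(paste0("file not found: ", path), "skinmwas_error_parse")
  }
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  header_at <- if (is.null(header_prefix)) {
    which(!is_comment & nzchar(lines))[1]
  } else {
    which(startsWith(lines, header_prefix))[1]
  }
  if (is.na(header_at)) {
    parse_error(path, 1L, paste0("missing header",
                                 if (!is.null(header_prefix))
                                   paste0(" starting with '", header_prefix,
                                          "'")))
  }
  header <- strsplit(sub("^#\\s*", "", lines[header_at]), "\t")[[1]]
  body_at <- seq_along(lines) > header_at & nzchar(lines) &
    !startsWith(lines, "#")
  body <- lines[body_at]
  body_lineno <- which(body_at)
  if (anyDuplicated(header[-1])) {
    parse_error(path, header_at,
                paste0("duplicated sample column: ",
                       header[-1][duplicated(header[-1])][1]))
  }
  cells <- strsplit(body, "\t")
  ncol_exp <- length(header)
  keys <- character(length(body))
  vals <- matrix(NA_real_, length(body), ncol_exp - 1)
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != ncol_exp) {
      parse_error(path, body_lineno[i],
                  sprintf("expected %d fields, found %d", ncol_exp,
                          length(cells[[i]])))
    }
    keys[i] <- cells[[i]][1]
    v <- suppressWarnings(as.numeric(cells[[i]][-1]))
    if (anyNA(v)) {
      parse_error(path, body_lineno[i], "non-numeric cell")
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(keys)) {
    parse_error(path, body_lineno[which(duplicated(keys))[1]],
                paste0("duplicate row key: ", keys[duplicated(keys)][1]))
  }
  rownames(vals) <- keys
  colnames(vals) <- header[-1]
  vals
}

write_matrix_tsv <- function(x, path, id_header, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c(id_header, colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format_num(x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write a merged taxonomic relative-abundance table
#'
#' Merged-profiler dialect: optional `#` comment lines, a header whose
#' first column is `clade_name`, one column per sample, rows keyed by the
#' full clade string (`k__...|p__...|g__...|s__...`), values in percent.
#'
#' @param path File path.
#' @return For the reader, a numeric matrix taxa x samples with clade-string
#'   row names; the writer returns `path` invisibly.
#' @export
read_taxon_table <- function(path) {
  x <- read_table_lines(path, header_prefix = NULL)
  if (any(x < 0)) {
    stop_skinmwas("taxon table contains negative abundances",
                  "skinmwas_error_parse")
  }
  x
}

#' @rdname read_taxon_table
#' @param taxa Taxa x samples matrix.
#' @export
write_taxon_table <- function(taxa, path) {
  write_matrix_tsv(taxa, path, "clade_name",
                   comment = "merged species relative abundances (percent)")
}

#' Read / write a taxon-stratified gene-family table
#'
#' HUMAnN-style dialect: header line `# Gene Family<TAB>sample...`; rows
#' keyed `FAM_0042` (community total), `FAM_0042|g__Genus.s__Genus_species`
#' (one contributing taxon) or `FAM_0042|unclassified`; values in RPK.
#'
#' @param path File path.
#' @return Numeric matrix with the stratified row keys as row names.
#' @export
read_stratified_gene_table <- function(path) {
  x <- read_table_lines(path, header_prefix = "# Gene Family")
  if (any(x < 0)) {
    stop_skinmwas("gene table contains negative RPK values",
                  "skinmwas_error_parse")
  }
  x
}

#' @rdname read_stratified_gene_table
#' @param genes Stratified matrix as produced by [simulate_gene_tables()].
#' @export
write_stratified_gene_table <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# Gene Family", colnames(genes)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(genes)), function(i) {
    paste(c(rownames(genes)[i], format_num(genes[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Split stratified row keys into gene family and stratum
#'
#' @param keys Row keys of a stratified gene table.
#' @return A tibble with `key`, `gene_family`, `stratum` (`TOTAL` for
#'   unstratified rows, the taxon label or `unclassified` otherwise).
#' @export
parse_strata <- function(keys) {
  has_bar <- grepl("|", keys, fixed = TRUE)
  tibble::tibble(
    key = keys,
    gene_family = ifelse(has_bar, sub("\\|.*", "", keys), keys),
    stratum = ifelse(has_bar, sub("^[^|]*\\|", "", keys), "TOTAL")
  )
}

#' Read / write pathway abundance and coverage tables
#'
#' Dialect: header `# Pathway<TAB>sample...`; one file for abundance
#' (RPK-derived) and one for coverage (0-1).
#'
#' @param abundance_path,coverage_path File paths.
#' @return A `pathway_table` (list of `abundance` and `coverage` matrices).
#' @export
read_pathway_table <- function(abundance_path, coverage_path) {
  ab <- read_table_lines(abundance_path, header_prefix = "# Pathway")
  cov <- read_table_lines(coverage_path, header_prefix = "# Pathway")
  if (any(cov < 0 | cov > 1)) {
    stop_skinmwas("pathway coverage outside [0, 1]", "skinmwas_error_parse")
  }
  if (!identical(dimnames(ab), dimnames(cov))) {
    stop_skinmwas("pathway abundance and coverage tables are not aligned",
                  "skinmwas_error_alignment")
  }
  structure(list(abundance = ab, coverage = cov), class = "pathway_table")
}

#' @rdname read_pathway_table
#' @param pathways A `pathway_table`.
#' @export
write_pathway_table <- function(pathways, abundance_path, coverage_path) {
  con <- file(abundance_path, "w"); on.exit(close(con))
  writeLines(paste(c("# Pathway", colnames(pathways$abundance)),
                   collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(pathways$abundance)), function(i) {
    paste(c(rownames(pathways$abundance)[i],
            format_num(pathways$abundance[i, ])), collapse = "\t")
  }, character(1)), con)
  close(con); on.exit()
  con2 <- file(coverage_path, "w"); on.exit(close(con2))
  writeLines(paste(c("# Pathway", colnames(pathways$coverage)),
                   collapse = "\t"), con2)
  writeLines(vapply(seq_len(nrow(pathways$coverage)), function(i) {
    paste(c(rownames(pathways$coverage)[i],
            format_num(pathways$coverage[i, ])), collapse = "\t")
  }, character(1)), con2)
  invisible(abundance_path)
}

#' Read / write the sample metadata table
#'
#' Plain TSV with the cohort-metadata columns (`sample_id`, `subject_id`,
#' `age_group`, `sex`, `site`, `timepoint`, `odor_intensity`, and the
#' logical odor-character flags). Invariants are checked on read:
#' `(subject, site, timepoint)` unique, at most two timepoints per
#' `(subject, site)`, odor intensity within `[0, 100]`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop_skinmwas(paste0("file not found: ", path), "skinmwas_error_parse")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "subject_id", "age_group", "sex", "site",
            "timepoint", "odor_intensity")
  if (!all(need %in% names(df))) {
    parse_error(path, 1L, paste0("missing columns: ",
                                 paste(setdiff(need, names(df)),
                                       collapse = ", ")))
  }
  for (fl in c("odor_sour", "odor_sulfur", "odor_greasy")) {
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  }
  meta <- tibble::as_tibble(df)
  validate_metadata(meta)
  meta
}

#' @rdname read_metadata
#' @param meta Metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate cohort metadata invariants
#' @param meta Metadata tibble.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta) {
  key <- paste(meta$subject_id, meta$site, meta$timepoint)
  if (anyDuplicated(key)) {
    stop_skinmwas("duplicate (subject, site, timepoint) record",
                  "skinmwas_error_parse")
  }
  tp_per <- table(paste(meta$subject_id, meta$site))
  if (any(tp_per > 2)) {
    stop_skinmwas("more than two timepoints for a (subject, site)",
                  "skinmwas_error_parse")
  }
  if (any(meta$odor_intensity < 0 | meta$odor_intensity > 100)) {
    stop_skinmwas("odor_intensity outside [0, 100]", "skinmwas_error_parse")
  }
  invisible(meta)
}

align_samples <- function(x, meta, what) {
  missing <- setdiff(meta$sample_id, colnames(x))
  if (length(missing)) {
    stop_skinmwas(paste0(what, " is missing metadata samples: ",
                         paste(head(missing, 5), collapse = ", ")),
                  "skinmwas_error_alignment")
  }
  invisible(x)
}

#' Filter taxa by mean relative abundance within an age group
#'
#' Retains taxa whose mean relative abundance across the given samples
#' exceeds `threshold` percent in children **or** in teenagers (strict
#' inequality). Intended to be applied separately per body site; pass
#' metadata already restricted to the site's samples.
#'
#' @param taxa Taxa x samples matrix (percent).
#' @param meta Metadata restricted to one site's samples.
#' @param threshold Mean-abundance gate in percent (default 1).
#' @return The filtered matrix, row order preserved.
#' @export
filter_taxa_by_abundance <- function(taxa, meta, threshold = 1) {
  align_samples(taxa, meta, "taxon table")
  taxa <- taxa[, meta$sample_id, drop = FALSE]
  keep <- rep(FALSE, nrow(taxa))
  for (g in c("children", "teens")) {
    samp <- meta$sample_id[meta$age_group == g]
    if (!length(samp)) {
      stop_skinmwas(paste0("empty stratum '", g, "' in taxon filter"),
                    "skinmwas_error_filter")
    }
    keep <- keep | rowMeans(taxa[, samp, drop = FALSE]) > threshold
  }
  taxa[keep, , drop = FALSE]
}

#' Filter gene families by mean community RPK and renormalize
#'
#' The gate is applied to the unstratified (community) row of each family:
#' mean RPK strictly greater than `min_mean_rpk` across the samples of
#' children **or** of teenagers. Surviving families — all their strata —
#' are renormalized per sample by the sum of the surviving community rows,
#' so community rows sum to 1 per sample and stratified additivity is
#' preserved.
#'
#' @param genes Stratified gene matrix.
#' @param meta Metadata restricted to the relevant samples.
#' @param min_mean_rpk RPK gate (default 10).
#' @return The filtered, renormalized stratified matrix.
#' @export
filter_gene_families <- function(genes, meta, min_mean_rpk = 10) {
  align_samples(genes, meta, "gene table")
  genes <- genes[, meta$sample_id, drop = FALSE]
  strata <- parse_strata(rownames(genes))
  total_idx <- which(strata$stratum == "TOTAL")
  totals <- genes[total_idx, , drop = FALSE]
  keep_fam <- rep(FALSE, nrow(totals))
  for (g in c("children", "teens")) {
    samp <- meta$sample_id[meta$age_group == g]
    if (!length(samp)) {
      stop_skinmwas(paste0("empty stratum '", g, "' in gene-family filter"),
                    "skinmwas_error_filter")
    }
    keep_fam <- keep_fam | rowMeans(totals[, samp, drop = FALSE]) >
      min_mean_rpk
  }
  fams <- strata$gene_family[total_idx][keep_fam]
  if (!length(fams)) {
    stop_skinmwas("all gene families removed by the RPK gate",
                  "skinmwas_error_filter")
  }
  out <- genes[strata$gene_family %in% fams, , drop = FALSE]
  out_strata <- parse_strata(rownames(out))
  denom <- colSums(out[out_strata$stratum == "TOTAL", , drop = FALSE])
  if (any(denom == 0)) {
    stop_skinmwas("a sample has zero total abundance after filtering",
                  "skinmwas_error_filter")
  }
  sweep(out, 2, denom, "/")
}

#' Filter pathways by mean coverage
#'
#' Retains pathway ids whose mean coverage across **all** the given samples
#' (both age groups, both timepoints) is strictly greater than
#' `min_mean_cov`.
#'
#' @param pathways A `pathway_table`.
#' @param meta Metadata restricted to the relevant samples (optional; all
#'   columns used if omitted).
#' @param min_mean_cov Coverage gate (default 0.3).
#' @return Character vector of retained pathway ids.
#' @export
filter_pathways_by_coverage <- function(pathways, meta = NULL,
                                        min_mean_cov = 0.3) {
  cov <- pathways$coverage
  if (!is.null(meta)) {
    align_samples(cov, meta, "pathway table")
    cov <- cov[, meta$sample_id, drop = FALSE]
  }
  rownames(cov)[rowMeans(cov) > min_mean_cov]
}

#' Write the ground-truth ledger as JSON
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    seed = truth$seed,
    effects = truth$effects[, setdiff(names(truth$effects), "linked_kos")],
    linked_kos = stats::setNames(truth$effects$linked_kos,
                                 truth$effects$effect_id),
    registry = truth$registry
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
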