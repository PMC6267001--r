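## Functional MWAS: pooled "bag of genes" vs. taxon-stratified "bag of
## genomes" KO aggregation, the candidate-pathway decision rule, and
## per-(pathway, species) significant-enzyme counts.

#' Build a KO map from two-column tables
#'
#' @param gene_family_to_ko Tibble/data frame with columns `gene_family`,
#'   `ko`.
#' @param ko_to_pathway Tibble/data frame with columns `ko`, `pathway`
#'   (one-to-many allowed).
#' @return A validated `ko_map` list.
#' @export
ko_map <- function(gene_family_to_ko, ko_to_pathway) {
  gf <- tibble::as_tibble(gene_family_to_ko)
  kp <- tibble::as_tibble(ko_to_pathway)
  if (!all(c("gene_family", "ko") %in% names(gf)) ||
      !all(c("ko", "pathway") %in% names(kp))) {
    stop_skinmwas("ko_map: tables need (gene_family, ko) and (ko, pathway)",
                  "skinmwas_error_mapping")
  }
  if (anyDuplicated(gf$gene_family)) {
    stop_skinmwas("ko_map: a gene family maps to more than one KO",
                  "skinmwas_error_mapping")
  }
  dangling <- setdiff(gf$ko, kp$ko)
  if (length(dangling)) {
    stop_skinmwas(paste0("ko_map: KOs with no pathway: ",
                         paste(head(dangling, 5), collapse = ", ")),
                  "skinmwas_error_mapping")
  }
  structure(list(gene_family_to_ko = gf, ko_to_pathway = kp),
            class = "ko_map")
}

#' Aggregate gene families to KO abundances
#'
#' `bag_of_genes` sums the community (unstratified) rows of all families
#' mapping to each KO, discarding taxonomic origin; `bag_of_genomes` sums
#' within each (KO, taxon) stratum, keeping the species identity of genes
#' (the `unclassified` stratum is kept as its own row, so marginalizing the
#' stratified table over strata reproduces the pooled one exactly).
#' Unmapped gene families are dropped; their count is reported via a
#' message and `attr(result, "n_unmapped")`.
#'
#' @param genes Stratified gene matrix (filtered).
#' @param map A `ko_map` (or a list with the same two tables).
#' @param mode `"bag_of_genes"` or `"bag_of_genomes"`.
#' @return Numeric matrix: rows are KO ids (`bag_of_genes`) or
#'   `KO|stratum` keys (`bag_of_genomes`).
#' @export
aggregate_to_ko <- function(genes, map,
                            mode = c("bag_of_genes", "bag_of_genomes")) {
  mode <- match.arg(mode)
  gf <- map$gene_family_to_ko
  if (is.null(gf) || nrow(gf) == 0) {
    stop_skinmwas("aggregate_to_ko: empty gene-family-to-KO mapping",
                  "skinmwas_error_mapping")
  }
  strata <- parse_strata(rownames(genes))
  ko_of <- stats::setNames(gf$ko, gf$gene_family)
  mapped <- strata$gene_family %in% gf$gene_family
  n_unmapped <- length(unique(strata$gene_family[!mapped]))
  if (n_unmapped) {
    rlang::inform(paste0("aggregate_to_ko: dropped ", n_unmapped,
                         " unmapped gene family(ies)"))
  }
  if (mode == "bag_of_genes") {
    idx <- mapped & strata$stratum == "TOTAL"
    key <- unname(ko_of[strata$gene_family[idx]])
  } else {
    idx <- mapped & strata$stratum != "TOTAL"
    key <- paste0(ko_of[strata$gene_family[idx]], "|", strata$stratum[idx])
  }
  if (!any(idx)) {
    stop_skinmwas("aggregate_to_ko: nothing to aggregate",
                  "skinmwas_error_mapping")
  }
  out <- rowsum(genes[idx, , drop = FALSE], key)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Pathway-level dual-mode association across the three strata
#'
#' Associates each coverage-gated pathway's abundance with odor intensity
#' in youth, children and teenagers (Spearman + signed-rank, BH within
#' each (stratum, test) family) and collects the six q-values per pathway.
#'
#' @param pathways A `pathway_table`.
#' @param meta Cohort metadata.
#' @param site Body site.
#' @param min_mean_cov Coverage gate applied first (default 0.3).
#' @param q_threshold Passed through to the candidate rule.
#' @return A list with `assoc` (the long association tibble) and `q_matrix`
#'   (pathways x 6 named comparisons).
#' @export
pathway_association <- function(pathways, meta, site, min_mean_cov = 0.3,
                                q_threshold = 0.1) {
  m <- meta[meta$site == site, ]
  keep <- filter_pathways_by_coverage(pathways, m, min_mean_cov)
  if (!length(keep)) {
    stop_skinmwas("no pathway passes the coverage gate",
                  "skinmwas_error_filter")
  }
  ab <- pathways$abundance[keep, , drop = FALSE]
  # renormalize to per-sample relative abundance before association
  denom <- colSums(ab)
  denom[denom == 0] <- 1
  ab <- sweep(ab, 2, denom, "/")
  assoc <- associate_all_strata(ab, meta, site, q_threshold)
  qm <- matrix(NA_real_, length(keep), 6,
               dimnames = list(keep, paste(
                 rep(c("youth", "children", "teens"), each = 2),
                 rep(c("spearman", "wilcoxon"), 3), sep = "_")))
  for (s in c("youth", "children", "teens")) {
    sub <- assoc[assoc$stratum == s, ]
    qm[sub$feature, paste0(s, "_spearman")] <- sub$q_spearman
    qm[sub$feature, paste0(s, "_wilcoxon")] <- sub$q_wilcoxon
  }
  list(assoc = assoc, q_matrix = qm)
}

#' Candidate-pathway decision rule
#'
#' A pathway is a candidate for gene-level follow-up when its FDR-adjusted
#' p-value is below `q_threshold` in at least `min_hits` of the six
#' comparisons (three age strata x two tests).
#'
#' @param q_matrix Pathways x 6 matrix of q-values, as from
#'   [pathway_association()].
#' @param q_threshold Per-comparison FDR gate (default 0.1).
#' @param min_hits Minimum number of sub-threshold comparisons (default 2).
#' @return A tibble: `pathway`, `n_hits`, `candidate`, plus the six
#'   q-value columns.
#' @export
pathway_candidate_rule <- function(q_matrix, q_threshold = 0.1,
                                   min_hits = 2) {
  if (ncol(q_matrix) != 6) {
    stop_skinmwas(
      paste0("pathway_candidate_rule: expected 6 comparisons (3 strata x ",
             "2 tests), got ", ncol(q_matrix)),
      "skinmwas_error_config")
  }
  if (anyNA(q_matrix)) {
    stop_skinmwas("pathway_candidate_rule: missing stratum/test q-values",
                  "skinmwas_error_config")
  }
  hits <- unname(rowSums(q_matrix < q_threshold))
  tibble::tibble(
    pathway = rownames(q_matrix),
    n_hits = as.integer(hits),
    candidate = hits >= min_hits
  ) |>
    dplyr::bind_cols(tibble::as_tibble(q_matrix))
}

#' Count significant enzymes of a pathway within one species
#'
#' From a bag-of-genomes association result: how many of the pathway's
#' member KOs are present in the species' strata (nonzero in at least one
#' of the site's samples), and how many of those are significantly
#' *positively* correlated with odor intensity (`q < q_threshold`,
#' `rho > rho_threshold`).
#'
#' @param pathway Pathway id.
#' @param species Stratum label of the species
#'   (`g__Genus.s__Genus_species`).
#' @param genomes_assoc Association tibble over the bag-of-genomes matrix
#'   (features keyed `KO|stratum`), one stratum of interest.
#' @param genomes_table The bag-of-genomes abundance matrix (for presence).
#' @param map A `ko_map`.
#' @param q_threshold,rho_threshold Significance gates (defaults 0.1, 0.2).
#' @return A tibble: `pathway`, `species`, `n_kos_present`,
#'   `n_kos_significant`.
#' @export
count_significant_kos <- function(pathway, species, genomes_assoc,
                                  genomes_table, map, q_threshold = 0.1,
                                  rho_threshold = 0.2) {
  kp <- map$ko_to_pathway
  if (!pathway %in% kp$pathway) {
    stop_skinmwas(paste0("unknown pathway: ", pathway),
                  "skinmwas_error_mapping")
  }
  members <- unique(kp$ko[kp$pathway == pathway])
  keys <- paste0(members, "|", species)
  present <- intersect(keys, rownames(genomes_table))
  present <- present[rowSums(genomes_table[present, , drop = FALSE] > 0) > 0]
  sig <- genomes_assoc[genomes_assoc$feature %in% present &
                         !is.na(genomes_assoc$q_spearman) &
                         genomes_assoc$q_spearman < q_threshold &
                         genomes_assoc$rho > rho_threshold, ]
  tibble::tibble(
    pathway = pathway, species = species,
    n_kos_present = length(present),
    n_kos_significant = length(unique(sig$feature))
  )
}

#' Within-pathway association-sign consistency
#'
#' Fraction of a pathway's member KOs whose Spearman correlation with odor
#' shares the majority sign — per species for the bag-of-genomes mode,
#' over the pooled community for the bag-of-genes mode. Values lie in
#' `[0.5, 1]`; groups with fewer than two member KOs with defined rho are
#' flagged `NA`.
#'
#' @param assoc Association tibble over a KO table (features `KO` or
#'   `KO|stratum`).
#' @param map A `ko_map`.
#' @param pathway Pathway id.
#' @param mode `"bag_of_genes"` or `"bag_of_genomes"`.
#' @return A tibble: `pathway`, `group` (species label or `"community"`),
#'   `n_kos`, `consistency`.
#' @export
pathway_sign_consistency <- function(assoc, map, pathway,
                                     mode = c("bag_of_genes",
                                              "bag_of_genomes")) {
  mode <- match.arg(mode)
  kp <- map$ko_to_pathway
  if (!pathway %in% kp$pathway) {
    stop_skinmwas(paste0("unknown pathway: ", pathway),
                  "skinmwas_error_mapping")
  }
  members <- unique(kp$ko[kp$pathway == pathway])
  a <- assoc[!is.na(assoc$rho), ]
  if (mode == "bag_of_genes") {
    a <- a[a$feature %in% members, ]
    a$group <- "community"
  } else {
    ko_part <- sub("\\|.*", "", a$feature)
    a <- a[ko_part %in% members, ]
    a$group <- sub("^[^|]*\\|", "", a$feature)
    a <- a[a$group != "unclassified", ]
  }
  if (nrow(a) == 0) {
    return(tibble::tibble(pathway = character(), group = character(),
                          n_kos = integer(), consistency = numeric()))
  }
  dplyr::summarise(
    dplyr::group_by(a, group),
    n_kos = dplyr::n(),
    consistency = ifelse(dplyr::n() < 2, NA_real_,
                         max(sum(rho > 0), sum(rho < 0)) /
                           sum(rho != 0)),
    .groups = "drop"
  ) |>
    dplyr::mutate(pathway = pathway, .before = 1)
}
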