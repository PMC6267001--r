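## Synthetic-cohort generator: study design, phenotype, taxon composition,
## and taxon-stratified functional tables with a ground-truth ledger.

# lineage strings for the species named in the default planted effects;
# anything else gets a synthetic lineage so tables stay dialect-valid
known_lineages <- c(
  s__Staphylococcus_epidermidis = paste0(
    "k__Bacteria|p__Firmicutes|c__Bacilli|o__Bacillales|",
    "f__Staphylococcaceae|g__Staphylococcus|s__Staphylococcus_epidermidis"),
  s__Staphylococcus_hominis = paste0(
    "k__Bacteria|p__Firmicutes|c__Bacilli|o__Bacillales|",
    "f__Staphylococcaceae|g__Staphylococcus|s__Staphylococcus_hominis"),
  s__Cutibacterium_avidum = paste0(
    "k__Bacteria|p__Actinobacteria|c__Actinobacteria|o__Propionibacteriales|",
    "f__Propionibacteriaceae|g__Cutibacterium|s__Cutibacterium_avidum"),
  s__Cutibacterium_acnes = paste0(
    "k__Bacteria|p__Actinobacteria|c__Actinobacteria|o__Propionibacteriales|",
    "f__Propionibacteriaceae|g__Cutibacterium|s__Cutibacterium_acnes"),
  s__Acinetobacter_schindleri = paste0(
    "k__Bacteria|p__Proteobacteria|c__Gammaproteobacteria|o__Pseudomonadales|",
    "f__Moraxellaceae|g__Acinetobacter|s__Acinetobacter_schindleri")
)

lineage_for <- function(species) {
  ifelse(species %in% names(known_lineages),
         known_lineages[species],
         paste0("k__Bacteria|p__Synthetica|c__Synthetica|o__Synthetales|",
                "f__Synthetaceae|g__", sub("_.*", "", sub("^s__", "", species)),
                "|s__", sub("^s__", "", species)))
}

null_taxon_names <- function(n) {
  genera <- c("Simulibacter", "Nullococcus", "Phantomonas", "Placebobacter")
  sprintf("s__%s_sp_%03d", genera[(seq_len(n) - 1) %% length(genera) + 1],
          seq_len(n))
}

# latent-normal Pearson correlation that yields a given Spearman under a
# Gaussian copula
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# per-(site, age group) odor-contribution weights for the planted effects:
# within a group the latent odor deviation is R = subject + noise + sum(beta*z),
# and corr(z_k, R) = beta_k / sd(R); solving beta_k = r*_k * sd(R) jointly
# gives sd(R) = c / sqrt(1 - sum r*^2)
effect_betas <- function(effects, sites, sigma_subject, sigma_odor) {
  if (nrow(effects) == 0) {
    return(tibble::tibble(effect_id = character(), site = character(),
                          age_group = character(), beta = numeric()))
  }
  c2 <- sigma_subject^2 + sigma_odor^2
  grid <- expand.grid(site = sites, age_group = c("children", "teens"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$site[i]; g <- grid$age_group[i]
    act <- which(effects$site == s &
                   effects$stratum %in% c(g, "both"))
    if (!length(act)) return(NULL)
    rstar <- spearman_to_pearson(effects$target_spearman[act])
    S <- sum(rstar^2)
    # many strong effects stacked on one (site, group) would demand more
    # odor variance than the phenotype has; shrink the odor-side weights
    # jointly (the abundance-side copula coupling is unaffected)
    if (S >= 0.8) {
      rstar <- rstar * sqrt(0.8 / S)
      S <- 0.8
    }
    tibble::tibble(effect_id = effects$effect_id[act], site = s,
                   age_group = g, beta = rstar * sqrt(c2 / (1 - S)))
  })
  dplyr::bind_rows(out)
}

#' Simulate the study cohort: design grid and odor phenotype
#'
#' Builds one record per (subject, site, timepoint) following the study
#' design (two age groups, three sites, two timepoints by default, 180
#' samples). Odor intensity is the site/group/timepoint baseline plus a
#' per-subject random effect, the planted taxa's latent contributions, and
#' Gaussian noise, clipped to the 0-100 perfumer scale. The returned ground
#' truth records the realized effects with their per-group contribution
#' weights, the latent draws behind the odor contributions, and the
#' planted/null feature registry; [simulate_taxon_profiles()] then couples
#' each planted species to the realized odor ranks through a Gaussian
#' copula.
#'
#' @param config A [sim_config()].
#' @return A list with `metadata` (tibble, one row per sample) and `truth`
#'   (a `ground_truth` object: realized effects with their per-group copula
#'   weights and achieved latent Spearman, the latent matrix, and the
#'   planted/null feature registry).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  effects <- config$planted_taxa
  if (nrow(effects)) {
    effects$effect_id <- paste0(effects$taxon, "@", effects$site)
  } else {
    effects$effect_id <- character(0)
  }

  sex_for <- function(n) {
    n1 <- min(n, round(n * config$sex_split[[1]] / sum(config$sex_split)))
    rep(names(config$sex_split), c(n1, n - n1))
  }
  subjects <- tibble::tibble(
    subject_id = c(sprintf("C%02d", seq_len(config$n_children)),
                   sprintf("T%02d", seq_len(config$n_teens))),
    age_group = rep(c("children", "teens"),
                    c(config$n_children, config$n_teens)),
    sex = c(sex_for(config$n_children), sex_for(config$n_teens))
  )

  meta <- tidyr::expand_grid(subjects,
                             site = config$sites,
                             timepoint = config$timepoints)
  meta$sample_id <- paste(meta$subject_id, meta$site, meta$timepoint,
                          sep = "_")
  n <- nrow(meta)

  betas <- effect_betas(effects, config$sites,
                        config$sigma_subject, config$sigma_odor)

  withr::with_seed(derive_seed(config$seed, "cohort"), {
    subj_re <- stats::setNames(rnorm(nrow(subjects), 0, config$sigma_subject),
                               subjects$subject_id)
    Z <- matrix(rnorm(n * max(1, nrow(effects))), nrow = n)
    colnames(Z) <- if (nrow(effects)) effects$effect_id else "unused"
    rownames(Z) <- meta$sample_id
    eps <- rnorm(n, 0, config$sigma_odor)
    char_noise <- matrix(rnorm(2 * n, 0, 3), ncol = 2)
    greasy <- runif(n) < 0.15
  })

  bl <- config$odor_baseline
  key <- paste(meta$site, meta$age_group, meta$timepoint)
  bl_key <- paste(bl$site, bl$age_group, bl$timepoint)
  baseline <- bl$baseline[match(key, bl_key)]

  contrib <- numeric(n)
  contrib_pos <- numeric(n)
  if (nrow(effects)) {
    for (i in seq_len(nrow(betas))) {
      k <- betas$effect_id[i]
      rows <- which(meta$site == betas$site[i] &
                      meta$age_group == betas$age_group[i])
      add <- betas$beta[i] * Z[rows, k]
      contrib[rows] <- contrib[rows] + add
      if (betas$beta[i] > 0) contrib_pos[rows] <- contrib_pos[rows] + add
    }
  }

  raw <- baseline + subj_re[meta$subject_id] + contrib + eps
  meta$odor_intensity <- pmin(100, pmax(0, round(raw, 1)))
  # odor characters from latent sour/sulfur scores driven by the positive
  # planted contributions; descriptive only, no chemical realism claimed
  meta$odor_sour <- (contrib_pos + char_noise[, 1]) > 3
  meta$odor_sulfur <- (0.6 * contrib_pos + char_noise[, 2]) > 4
  meta$odor_greasy <- greasy

  meta <- meta[, c("sample_id", "subject_id", "age_group", "sex", "site",
                   "timepoint", "odor_intensity", "odor_sour", "odor_sulfur",
                   "odor_greasy")]

  # achieved latent rank correlation, per effect, over its applicable samples
  if (nrow(effects)) {
    effects$achieved_latent_spearman <- vapply(
      seq_len(nrow(effects)), function(k) {
        e <- effects[k, ]
        grp <- if (e$stratum == "both") c("children", "teens") else e$stratum
        rows <- which(meta$site == e$site & meta$age_group %in% grp)
        suppressWarnings(cor(Z[rows, e$effect_id], meta$odor_intensity[rows],
                             method = "spearman"))
      }, numeric(1))
  }

  planted_species <- unique(effects$taxon)
  nulls <- null_taxon_names(config$n_taxa - length(planted_species))
  registry <- tibble::tibble(
    taxon = c(planted_species, nulls),
    role = rep(c("planted", "null"),
               c(length(planted_species), length(nulls))),
    clade = unname(lineage_for(c(planted_species, nulls)))
  )

  truth <- structure(
    list(effects = dplyr::left_join(
           effects,
           tidyr::pivot_wider(betas, names_from = age_group,
                              values_from = beta, names_prefix = "beta_",
                              id_cols = c("effect_id", "site")) |>
             dplyr::select(-site),
           by = "effect_id"),
         latents = Z[, effects$effect_id, drop = FALSE],
         registry = registry,
         seed = config$seed),
    class = "ground_truth")
  list(metadata = meta, truth = truth)
}

#' Simulate species relative-abundance profiles
#'
#' Per sample, species relative abundances arise from a logistic-normal
#' composition summing to 100 percent. Planted species re-use the latent
#' normal draws stored in the ground truth, so their realized rank
#' correlation with odor intensity approximates the effect's
#' `target_spearman`; null species get independent latents. The
#' `exercise_shift` multiplies the latent (pre-normalization) abundance at
#' the second timepoint for samples in the effect's site and stratum.
#' Values below `detection_floor` are zeroed and the composition reclosed,
#' emulating profiler sparsity.
#'
#' @param metadata Cohort metadata from [simulate_cohort()].
#' @param truth Matching `ground_truth` object (same seed lineage).
#' @param config The same [sim_config()].
#' @return A numeric matrix, taxa (rows, full clade strings) x samples
#'   (columns), in percent.
#' @export
simulate_taxon_profiles <- function(metadata, truth, config) {
  validate_sim_config(config)
  if (!identical(rownames(truth$latents), metadata$sample_id) &&
      nrow(truth$effects) > 0) {
    stop_skinmwas("metadata and ground truth carry different sample sets",
                  "skinmwas_error_alignment")
  }
  reg <- truth$registry
  n_s <- nrow(metadata)
  n_t <- nrow(reg)
  effects <- truth$effects

  withr::with_seed(derive_seed(config$seed, "taxa"), {
    # planted species sit near the top of the rank-abundance curve, like
    # the dominant staphylococci and cutibacteria on real skin
    mu <- ifelse(reg$role == "planted", 2.2, rnorm(n_t, 0, 1.5))
    eps <- matrix(rnorm(n_s * n_t), nrow = n_s)
  })
  colnames(eps) <- reg$taxon

  # planted species: within the effect's applicable samples, couple the
  # taxon latent to the normal scores of the realized odor ranks (exact
  # Gaussian copula against the pooled phenotype, immune to baseline
  # structure across timepoints and groups); elsewhere keep the
  # independent draw (no phenotype coupling at other sites/strata)
  shift_log <- matrix(0, n_s, n_t, dimnames = list(NULL, reg$taxon))
  for (k in seq_len(nrow(effects))) {
    e <- effects[k, ]
    grp <- if (e$stratum == "both") c("children", "teens") else e$stratum
    rows <- which(metadata$site == e$site & metadata$age_group %in% grp)
    rstar <- spearman_to_pearson(e$target_spearman)
    odor_scores <- stats::qnorm(
      (rank(metadata$odor_intensity[rows]) - 0.5) / length(rows))
    eps[rows, e$taxon] <- rstar * odor_scores +
      sqrt(1 - rstar^2) * eps[rows, e$taxon]
    srows <- rows[metadata$timepoint[rows] == config$timepoints[2]]
    shift_log[srows, e$taxon] <- log(e$exercise_shift)
  }

  w <- matrix(mu, n_s, n_t, byrow = TRUE) +
    config$sigma_log_abundance * eps + shift_log
  expw <- exp(w)
  rel <- 100 * expw / rowSums(expw)
  rel[rel < config$detection_floor] <- 0
  rel <- 100 * rel / rowSums(rel)

  out <- t(rel)
  rownames(out) <- reg$clade
  colnames(out) <- metadata$sample_id
  out
}

species_label <- function(clade) {
  sub(".*\\|", "", clade)
}

genus_species_stratum <- function(clade) {
  parts <- strsplit(clade, "|", fixed = TRUE)
  vapply(parts, function(p) {
    g <- grep("^g__", p, value = TRUE)
    s <- grep("^s__", p, value = TRUE)
    if (length(g) && length(s)) paste0(g[1], ".", s[1]) else tail(p, 1)
  }, character(1))
}

#' Simulate taxon-stratified gene-family and pathway tables
#'
#' Each species carries a fixed binary KO repertoire (its planted linked
#' KOs always included). A carried gene family's stratified abundance in a
#' sample is the species' relative abundance times a per-(family, species)
#' copy factor times multiplicative log-normal noise, in RPK-style units;
#' linked KOs of planted species therefore inherit the species' odor
#' association. An `unclassified` stratum receives a configurable fraction
#' of each family's community total, and the unstratified (community) row
#' is the exact sum of its strata. Pathway coverage per sample is the
#' fraction of the pathway's member KOs with nonzero community abundance;
#' pathway abundance is the sum of member-KO community abundances.
#'
#' @param taxa Taxon table from [simulate_taxon_profiles()].
#' @param config The same [sim_config()].
#' @return A list with `genes` (matrix keyed `FAM`, `FAM|g__G.s__S`,
#'   `FAM|unclassified`) and `pathways` (a `pathway_table`: list of
#'   `abundance` and `coverage` matrices, pathways x samples).
#' @export
simulate_gene_tables <- function(taxa, config) {
  validate_sim_config(config)
  cat_fam <- config$ko_catalog$gene_family_to_ko
  cat_pwy <- config$ko_catalog$ko_to_pathway
  if (!all(cat_fam$ko %in% cat_pwy$ko)) {
    stop_skinmwas("KO catalog references a KO with no pathway",
                  "skinmwas_error_mapping")
  }
  clades <- rownames(taxa)
  species <- species_label(clades)
  strata_lab <- genus_species_stratum(clades)
  n_sam <- ncol(taxa)
  fams <- sprintf("FAM_%04d", seq_len(config$n_gene_families))
  fam_ko <- stats::setNames(cat_fam$ko, cat_fam$gene_family)
  kos <- unique(cat_pwy$ko)

  linked <- config$planted_taxa
  linked_pairs <- if (nrow(linked)) {
    do.call(rbind, lapply(seq_len(nrow(linked)), function(i) {
      ks <- linked$linked_kos[[i]]
      if (!length(ks)) return(NULL)
      cbind(taxon = linked$taxon[i], ko = ks)
    }))
  } else NULL

  withr::with_seed(derive_seed(config$seed, "genes"), {
    carry_ko <- matrix(runif(length(species) * length(kos)) <
                         config$ko_carriage_prob,
                       nrow = length(species),
                       dimnames = list(species, kos))
    carry_unmapped <- matrix(runif(length(species) * length(fams)) <
                               config$ko_carriage_prob,
                             nrow = length(species),
                             dimnames = list(species, fams))
    copy_factor <- matrix(exp(rnorm(length(species) * length(fams),
                                    log(3), 0.6)),
                          nrow = length(species),
                          dimnames = list(species, fams))
    noise_seed <- sample.int(2147483646, 1)
  })
  if (!is.null(linked_pairs)) {
    keep <- linked_pairs[, "taxon"] %in% species
    lp <- linked_pairs[keep, , drop = FALSE]
    if (nrow(lp)) {
      carry_ko[cbind(lp[, "taxon"], lp[, "ko"])] <- TRUE
      # planted enzymes get a fixed per-copy yield so the planted functional
      # signal strength is controlled, not noise-dominated
      for (i in seq_len(nrow(lp))) {
        f_of_ko <- cat_fam$gene_family[cat_fam$ko == lp[i, "ko"]]
        copy_factor[lp[i, "taxon"], f_of_ko] <- 8
      }
    }
  }

  uf <- config$unclassified_fraction
  rel <- t(taxa) / 100  # samples x taxa, proportions
  colnames(rel) <- species

  rows <- list()
  withr::with_seed(noise_seed, {
    for (f in fams) {
      k <- if (f %in% names(fam_ko)) fam_ko[[f]] else NA_character_
      carriers <- if (is.na(k)) species[carry_unmapped[, f]]
                  else species[carry_ko[, k]]
      if (!length(carriers)) next
      strat <- sapply(carriers, function(tx) {
        100 * rel[, tx] * copy_factor[tx, f] *
          exp(rnorm(n_sam, 0, config$sigma_rpk))
      })
      strat <- matrix(strat, nrow = n_sam,
                      dimnames = list(NULL, carriers))
      classified <- rowSums(strat)
      unclass <- uf / (1 - uf) * classified
      total <- classified + unclass
      block <- t(cbind(total, strat, unclass))
      rownames(block) <- c(
        f,
        paste0(f, "|", strata_lab[match(carriers, species)]),
        paste0(f, "|unclassified"))
      rows[[f]] <- block
    }
  })
  genes <- do.call(rbind, rows)
  colnames(genes) <- colnames(taxa)

  # community KO abundance from the unstratified rows
  total_rows <- genes[!grepl("|", rownames(genes), fixed = TRUE), ,
                      drop = FALSE]
  ko_of_row <- fam_ko[rownames(total_rows)]
  pwys <- unique(cat_pwy$pathway)
  ko_abund <- rowsum(total_rows[!is.na(ko_of_row), , drop = FALSE],
                     ko_of_row[!is.na(ko_of_row)])
  abundance <- matrix(0, length(pwys), ncol(genes),
                      dimnames = list(pwys, colnames(genes)))
  coverage <- abundance
  for (p in pwys) {
    members <- cat_pwy$ko[cat_pwy$pathway == p]
    present <- intersect(members, rownames(ko_abund))
    if (length(present)) {
      sub <- ko_abund[present, , drop = FALSE]
      abundance[p, ] <- colSums(sub)
      coverage[p, ] <- colSums(sub > 0) / length(members)
    }
  }
  list(genes = genes,
       pathways = structure(list(abundance = abundance, coverage = coverage),
                            class = "pathway_table"))
}

#' Simulate a complete study: cohort, taxa, genes, pathways
#'
#' Convenience wrapper running [simulate_cohort()],
#' [simulate_taxon_profiles()] and (optionally) [simulate_gene_tables()].
#'
#' @param config A [sim_config()].
#' @param genes Whether to simulate the functional tables too.
#' @return A list with `metadata`, `truth`, `taxa`, and (if requested)
#'   `genes` and `pathways`.
#' @export
simulate_study <- function(config = sim_config(), genes = TRUE) {
  ch <- simulate_cohort(config)
  taxa <- simulate_taxon_profiles(ch$metadata, ch$truth, config)
  out <- list(metadata = ch$metadata, truth = ch$truth, taxa = taxa)
  if (genes) {
    gt <- simulate_gene_tables(taxa, config)
    out$genes <- gt$genes
    out$pathways <- gt$pathways
  }
  out
}

#' Realized planted-effect correlations
#'
#' For each planted effect, the sample Spearman correlation between the
#' species' realized relative abundance and odor intensity over the
#' effect's applicable samples (its site, its stratum, both timepoints
#' pooled) — the quantity the copula targets.
#'
#' @param metadata,truth,taxa Outputs of the simulation stages.
#' @return The effects tibble with a `realized_spearman` column.
#' @export
realized_effect_correlations <- function(metadata, truth, taxa) {
  eff <- truth$effects
  eff$realized_spearman <- vapply(seq_len(nrow(eff)), function(k) {
    e <- eff[k, ]
    grp <- if (e$stratum == "both") c("children", "teens") else e$stratum
    m <- metadata[metadata$site == e$site & metadata$age_group %in% grp, ]
    clade <- truth$registry$clade[match(e$taxon, truth$registry$taxon)]
    suppressWarnings(cor(taxa[clade, m$sample_id], m$odor_intensity,
                         method = "spearman"))
  }, numeric(1))
  eff
}
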