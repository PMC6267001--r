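## Simulation configuration: study design constants, planted effects, and the
## toy KEGG-orthology catalog used by the synthetic cohorts.

#' Declare a planted taxon-phenotype effect
#'
#' A planted effect ties one species, at one body site and in one age
#' stratum, to the latent odor drive through a Gaussian copula so that the
#' realized sample Spearman correlation between the species' relative
#' abundance and odor intensity approximates `target_spearman`. The
#' `exercise_shift` multiplies the species' latent abundance at the
#' post-exercise (second) timepoint before compositional renormalization,
#' which is what the longitudinal signed-rank test and the direction arrow
#' pick up. `linked_kos` lists KEGG-orthology groups carried by this species
#' whose stratified gene-family abundances inherit the taxon's odor
#' association.
#'
#' @param taxon Species label with rank prefix, e.g.
#'   `"s__Staphylococcus_epidermidis"`.
#' @param site Body site the effect acts at (`"underarm"`, `"neck"`, `"head"`).
#' @param stratum `"children"`, `"teens"` or `"both"`.
#' @param target_spearman Signed target rank correlation in `(-0.95, 0.95)`;
#'   its sign is the effect direction.
#' @param exercise_shift Positive multiplier applied to the latent abundance
#'   at the 8 h timepoint (`> 1` enrichment after exercise, `< 1` depletion).
#' @param linked_kos Character vector of KO ids (may be empty).
#' @return A one-row tibble.
#' @export
planted_effect <- function(taxon, site, stratum = "both", target_spearman,
                           exercise_shift = 1, linked_kos = character()) {
  if (abs(target_spearman) > 0.95) {
    stop_skinmwas("planted_effect: |target_spearman| must be <= 0.95",
                  "skinmwas_error_config")
  }
  if (exercise_shift <= 0) {
    stop_skinmwas("planted_effect: exercise_shift must be > 0",
                  "skinmwas_error_config")
  }
  if (!stratum %in% c("children", "teens", "both")) {
    stop_skinmwas("planted_effect: stratum must be children, teens or both",
                  "skinmwas_error_config")
  }
  tibble::tibble(
    taxon = taxon, site = site, stratum = stratum,
    effect_direction = ifelse(target_spearman >= 0, "+", "-"),
    target_spearman = target_spearman,
    exercise_shift = exercise_shift,
    linked_kos = list(linked_kos)
  )
}

#' Default planted effects mirroring the reported association structure
#'
#' Encodes the qualitative structure of the study's species-level findings:
#' positive underarm associations for *S. epidermidis* (branched-chain amino
#' acid degradation and pyruvate-metabolism enzymes, enriched after
#' exercise) and *C. avidum*; a child-specific positive neck association for
#' *S. hominis* carrying sulfur-catabolism enzymes; and negative neck
#' associations for *A. schindleri* and *C. acnes* depleted after exercise.
#' Effect magnitudes are set in the range the study reports for its
#' significant species (|rho| roughly 0.4-0.7).
#'
#' @return A tibble of planted effects, one row per effect.
#' @export
default_planted_effects <- function() {
  dplyr::bind_rows(
    planted_effect("s__Staphylococcus_epidermidis", "underarm", "both", 0.60,
                   1.6, c("K_BCAA_01", "K_BCAA_02", "K_BCAA_03",
                          "K_PYR_01", "K_PYR_02")),
    planted_effect("s__Cutibacterium_avidum", "underarm", "both", 0.50,
                   1.4, c("K_PYR_03")),
    planted_effect("s__Staphylococcus_hominis", "neck", "children", 0.60,
                   1.5, c("K_SUL_01", "K_SUL_02", "K_SUL_03")),
    planted_effect("s__Acinetobacter_schindleri", "neck", "both", -0.45,
                   0.7, character()),
    planted_effect("s__Cutibacterium_acnes", "neck", "children", -0.50,
                   0.8, character())
  )
}

#' Default per-(site, age group, timepoint) odor-intensity baselines
#'
#' Mean odor scores (0-100 perfumer scale) before subject effects, planted
#' contributions and noise. Baselines rise from the 1 h (post-shower) to the
#' 8 h (post-exercise) timepoint at every site, are higher in teenagers than
#' children, and are highest at the underarm, reflecting apocrine-gland
#' activity starting at puberty.
#'
#' @return A tibble with columns `site`, `age_group`, `timepoint`, `baseline`.
#' @export
default_odor_baselines <- function() {
  tibble::tribble(
    ~site,      ~age_group, ~timepoint, ~baseline,
    "underarm", "children", "1h", 35, "underarm", "children", "8h", 48,
    "underarm", "teens",    "1h", 45, "underarm", "teens",    "8h", 62,
    "neck",     "children", "1h", 32, "neck",     "children", "8h", 44,
    "neck",     "teens",    "1h", 36, "neck",     "teens",    "8h", 50,
    "head",     "children", "1h", 30, "head",     "children", "8h", 40,
    "head",     "teens",    "1h", 33, "head",     "teens",    "8h", 45
  )
}

#' Bundled toy KEGG-orthology catalog
#'
#' A small synthetic KO catalog for simulation and tests: five pathways
#' (stand-ins for branched-chain amino acid degradation — the isovaleric
#' acid route —, pyruvate metabolism — the acetic acid route —, sulfur
#' amino acid catabolism, glycolysis, and the TCA cycle; two pyruvate KOs
#' are shared with the TCA pathway, so the KO-to-pathway map is
#' one-to-many). Each KO owns `families_per_ko` UniRef90-style gene
#' families `FAM_####`; families beyond the mapped ones are left unmapped,
#' emulating uncharacterized proteins. Real KEGG mappings can be supplied
#' instead as two-column tables.
#'
#' @param n_gene_families Total number of gene families to name (mapped
#'   first, remainder unmapped).
#' @param families_per_ko Families assigned to each KO.
#' @return A list with tibbles `gene_family_to_ko` (`gene_family`, `ko`) and
#'   `ko_to_pathway` (`ko`, `pathway`).
#' @export
default_ko_catalog <- function(n_gene_families = 120, families_per_ko = 3) {
  kos <- list(
    pwy_bcaa_degradation = sprintf("K_BCAA_%02d", 1:6),
    pwy_pyruvate_metabolism = sprintf("K_PYR_%02d", 1:6),
    pwy_sulfur_catabolism = sprintf("K_SUL_%02d", 1:5),
    pwy_glycolysis = sprintf("K_GLY_%02d", 1:8),
    pwy_tca_cycle = sprintf("K_TCA_%02d", 1:8)
  )
  ko_to_pathway <- dplyr::bind_rows(lapply(names(kos), function(p) {
    tibble::tibble(ko = kos[[p]], pathway = p)
  }))
  # shared KOs: pyruvate KOs 5-6 also sit on the TCA pathway (one-to-many)
  ko_to_pathway <- dplyr::bind_rows(
    ko_to_pathway,
    tibble::tibble(ko = c("K_PYR_05", "K_PYR_06"), pathway = "pwy_tca_cycle")
  )
  all_kos <- unique(ko_to_pathway$ko)
  n_mapped <- length(all_kos) * families_per_ko
  if (n_gene_families < n_mapped) {
    stop_skinmwas(
      paste0("default_ko_catalog: n_gene_families must be >= ", n_mapped),
      "skinmwas_error_config")
  }
  fams <- sprintf("FAM_%04d", seq_len(n_gene_families))
  gene_family_to_ko <- tibble::tibble(
    gene_family = fams[seq_len(n_mapped)],
    ko = rep(all_kos, each = families_per_ko)
  )
  list(gene_family_to_ko = gene_family_to_ko, ko_to_pathway = ko_to_pathway)
}

#' Build a simulation configuration
#'
#' Returns the full parameter set for one synthetic cohort. Defaults mirror
#' the study design: two age groups of 15 subjects each (8 female, 7 male),
#' three body sites, two timepoints (1 h post-shower, 8 h post-exercise),
#' hence 180 samples, with planted effects from
#' [default_planted_effects()].
#'
#' @param n_children,n_teens Subjects per age group (each >= 2).
#' @param sex_split Named counts `c(F = , M = )` applied within each group.
#' @param sites Character vector of body-site labels.
#' @param timepoints Ordered pair of timepoint labels.
#' @param n_taxa Total number of species simulated (planted + null).
#' @param planted_taxa Tibble of planted effects (see [planted_effect()]);
#'   may have zero rows for an all-null cohort.
#' @param n_gene_families Number of UniRef90-style gene families.
#' @param ko_catalog KO catalog as from [default_ko_catalog()].
#' @param sigma_log_abundance Log-scale s.d. of the logistic-normal taxon
#'   composition.
#' @param sigma_subject S.d. of the per-subject odor random effect (score
#'   units).
#' @param sigma_odor S.d. of per-sample odor noise (score units).
#' @param odor_baseline Baseline table as from [default_odor_baselines()].
#' @param detection_floor Relative abundances (percent) below this are set
#'   to zero, emulating profiler sparsity.
#' @param unclassified_fraction Fraction of each gene family's community
#'   total assigned to the `unclassified` stratum.
#' @param sigma_rpk Log-scale s.d. of multiplicative noise on stratified RPK
#'   values.
#' @param ko_carriage_prob Probability a (taxon, KO) pair is in the taxon's
#'   repertoire (planted linked KOs are always carried).
#' @param seed Integer master seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_children = 15, n_teens = 15,
                       sex_split = c(F = 8, M = 7),
                       sites = c("underarm", "neck", "head"),
                       timepoints = c("1h", "8h"),
                       n_taxa = 40,
                       planted_taxa = default_planted_effects(),
                       n_gene_families = 120,
                       ko_catalog = default_ko_catalog(n_gene_families),
                       sigma_log_abundance = 1.0,
                       sigma_subject = 6,
                       sigma_odor = 6,
                       odor_baseline = default_odor_baselines(),
                       detection_floor = 0.001,
                       unclassified_fraction = 0.1,
                       sigma_rpk = 0.3,
                       ko_carriage_prob = 0.15,
                       seed = 1) {
  cfg <- structure(
    list(
      n_children = n_children, n_teens = n_teens, sex_split = sex_split,
      sites = sites, timepoints = timepoints, n_taxa = n_taxa,
      planted_taxa = planted_taxa, n_gene_families = n_gene_families,
      ko_catalog = ko_catalog, sigma_log_abundance = sigma_log_abundance,
      sigma_subject = sigma_subject, sigma_odor = sigma_odor,
      odor_baseline = odor_baseline, detection_floor = detection_floor,
      unclassified_fraction = unclassified_fraction, sigma_rpk = sigma_rpk,
      ko_carriage_prob = ko_carriage_prob, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly, or a configuration error naming the offending
#'   field.
#' @export
validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop_skinmwas(paste0("invalid SimConfig field '", field, "': ", why),
                  "skinmwas_error_config")
  }
  if (!is.numeric(cfg$n_children) || cfg$n_children < 2) {
    bad("n_children", "must be a count >= 2")
  }
  if (!is.numeric(cfg$n_teens) || cfg$n_teens < 2) {
    bad("n_teens", "must be a count >= 2")
  }
  if (length(cfg$timepoints) != 2 || anyDuplicated(cfg$timepoints)) {
    bad("timepoints", "must be an ordered pair of distinct labels")
  }
  if (length(cfg$sites) < 1 || anyDuplicated(cfg$sites)) {
    bad("sites", "must be a non-empty set of distinct labels")
  }
  for (f in c("sigma_log_abundance", "sigma_subject", "sigma_odor",
              "sigma_rpk")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) bad(f, "must be > 0")
  }
  if (cfg$unclassified_fraction < 0 || cfg$unclassified_fraction >= 1) {
    bad("unclassified_fraction", "must be in [0, 1)")
  }
  pe <- cfg$planted_taxa
  if (nrow(pe) > 0) {
    if (anyDuplicated(pe[c("taxon", "site")])) {
      bad("planted_taxa", "duplicate (taxon, site) planted effects")
    }
    if (!all(pe$site %in% cfg$sites)) {
      bad("planted_taxa", "effect site not among configured sites")
    }
    if (any(abs(pe$target_spearman) > 0.95)) {
      bad("planted_taxa", "|target_spearman| must be <= 0.95")
    }
    if (any(pe$exercise_shift <= 0)) {
      bad("planted_taxa", "exercise_shift must be > 0")
    }
  }
  if (cfg$n_taxa < length(unique(pe$taxon))) {
    bad("n_taxa", "fewer taxa than distinct planted species")
  }
  # every planted linked KO must exist in the catalog
  kos <- unique(cfg$ko_catalog$ko_to_pathway$ko)
  linked <- unique(unlist(pe$linked_kos))
  if (length(linked) && !all(linked %in% kos)) {
    bad("planted_taxa",
        paste0("linked_kos not in ko_catalog: ",
               paste(setdiff(linked, kos), collapse = ", ")))
  }
  fam_kos <- unique(cfg$ko_catalog$gene_family_to_ko$ko)
  if (!all(fam_kos %in% kos)) {
    stop_skinmwas("ko_catalog: gene families map to KOs with no pathway",
                  "skinmwas_error_mapping")
  }
  bl <- cfg$odor_baseline
  need <- expand.grid(site = cfg$sites, age_group = c("children", "teens"),
                      timepoint = cfg$timepoints, stringsAsFactors = FALSE)
  hit <- merge(need, bl, by = c("site", "age_group", "timepoint"))
  if (nrow(hit) < nrow(need)) {
    bad("odor_baseline", "missing a (site, age_group, timepoint) baseline")
  }
  invisible(cfg)
}

#' Number of null (unplanted) taxa implied by a configuration
#' @param cfg A `sim_config`.
#' @return Integer count.
#' @export
n_null_taxa <- function(cfg) {
  cfg$n_taxa - length(unique(cfg$planted_taxa$taxon))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  subjects: ", x$n_children, " children + ", x$n_teens, " teens (",
      paste0(names(x$sex_split), "=", x$sex_split, collapse = ", "),
      " per group)\n", sep = "")
  cat("  design:   ", length(x$sites), " sites x ", length(x$timepoints),
      " timepoints -> ",
      (x$n_children + x$n_teens) * length(x$sites) * length(x$timepoints),
      " samples\n", sep = "")
  cat("  taxa:     ", x$n_taxa, " (", nrow(x$planted_taxa),
      " planted effects)\n", sep = "")
  cat("  seed:     ", x$seed, "\n", sep = "")
  invisible(x)
}
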