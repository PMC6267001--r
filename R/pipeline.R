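## Orchestration: simulate -> filter -> associate -> functional MWAS ->
## ordination as one configured, reproducible pipeline run.

#' Build a pipeline configuration
#'
#' Either simulation settings (`sim`) or input paths (`paths`, a list with
#' `metadata`, `taxa`, `genes`, `pathway_abundance`, `pathway_coverage`)
#' must be supplied. All thresholds default to the study's quoted rules:
#' taxa retained above 1% mean relative abundance in either age group,
#' gene families above mean RPK 10, pathways above mean coverage 0.3,
#' significance at FDR-adjusted p < 0.1 with |rho| > 0.2, candidate
#' pathways at 2 of 6 comparisons.
#'
#' @param sim A [sim_config()], or `NULL` when reading from `paths`.
#' @param paths Named list of input file paths, or `NULL` when simulating.
#' @param sites Sites to analyze (default: all in the data).
#' @param taxa_threshold,rpk_threshold,coverage_threshold,q_threshold,rho_threshold,min_hits
#'   Analysis thresholds.
#' @param n_perm CAP permutations (default 999).
#' @param seed Master seed for the run.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed), paths = NULL,
                            sites = NULL, taxa_threshold = 1,
                            rpk_threshold = 10, coverage_threshold = 0.3,
                            q_threshold = 0.1, rho_threshold = 0.2,
                            min_hits = 2, n_perm = 999, seed = 1,
                            out_dir = NULL) {
  cfg <- list(sim = sim, paths = paths, sites = sites,
              taxa_threshold = taxa_threshold, rpk_threshold = rpk_threshold,
              coverage_threshold = coverage_threshold,
              q_threshold = q_threshold, rho_threshold = rho_threshold,
              min_hits = min_hits, n_perm = n_perm, seed = as.integer(seed),
              out_dir = out_dir)
  for (f in c("taxa_threshold", "rpk_threshold", "coverage_threshold",
              "q_threshold", "rho_threshold")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop_skinmwas(paste0("pipeline_config: ", f, " must be nonnegative"),
                    "skinmwas_error_config")
    }
  }
  if (is.null(sim) && is.null(paths)) {
    stop_skinmwas("pipeline_config: supply either sim or paths",
                  "skinmwas_error_config")
  }
  if (!is.null(paths)) {
    need <- c("metadata", "taxa")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop_skinmwas(paste0("pipeline_config: missing paths: ",
                           paste(miss, collapse = ", ")),
                    "skinmwas_error_config")
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) {
        stop_skinmwas(paste0("pipeline_config: input not found: ", p),
                      "skinmwas_error_config")
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]; a `sim:` block (fields of
#' [sim_config()]) requests simulation, a `paths:` block reads existing
#' tables. Planted effects in YAML are a list of records with the fields
#' of [planted_effect()].
#'
#' @param path YAML file path.
#' @param seed Optional override of the file's seed.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$planted_taxa)) {
      sim_args$planted_taxa <- dplyr::bind_rows(lapply(
        sim_args$planted_taxa, function(e) do.call(planted_effect, e)))
    }
    if (!is.null(sim_args$sex_split)) {
      sim_args$sex_split <- unlist(sim_args$sex_split)
    }
    if (!is.null(seed)) sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
  }
  args <- y[setdiff(names(y), c("sim"))]
  args$sim <- sim
  if (!is.null(seed)) args$seed <- seed
  do.call(pipeline_config, args)
}

#' Summarize odor characters per (site, group, timepoint)
#'
#' Counts samples per combination of character flags (e.g. `sour`,
#' `sour+sulfur`, `none`) within each (site, age group, timepoint) cell and
#' reports the mean odor intensity per combination. Counts partition the
#' cell's samples.
#'
#' @param meta Cohort metadata with the odor-character flag columns.
#' @return A tibble: `site`, `age_group`, `timepoint`, `characters`, `n`,
#'   `mean_intensity`.
#' @export
summarize_odor_characters <- function(meta) {
  flags <- c("odor_sour", "odor_sulfur", "odor_greasy")
  have <- intersect(flags, names(meta))
  lab <- apply(as.matrix(meta[, have, drop = FALSE]), 1, function(r) {
    on <- sub("odor_", "", have[which(as.logical(r))])
    if (!length(on)) "none" else paste(on, collapse = "+")
  })
  meta$characters <- lab
  dplyr::summarise(
    dplyr::group_by(meta, site, age_group, timepoint, characters),
    n = dplyr::n(),
    mean_intensity = mean(odor_intensity),
    .groups = "drop"
  )
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the cohort, then per site: applies the abundance
#' gates, runs the taxon-level dual-mode association across the three age
#' strata, the pathway coverage gate and candidate rule, the
#' bag-of-genomes per-(pathway, species) significant-enzyme counts, the
#' CAP ordination against odor intensity, age group, timepoint and sex,
#' and the odor-character summary. With `out_dir` set, writes one TSV per
#' table plus a JSON manifest (seed, thresholds, config hash, package
#' version); a rerun with the same config is bit-identical.
#'
#' @param config A `pipeline_config`.
#' @return A list: `metadata`, `taxa`, `odor_characters`, and per-site
#'   results under `sites` (`taxa_assoc`, `pathway_candidates`,
#'   `species_ko_counts`, `cap`), plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop_skinmwas(paste0("pipeline stage '", name, "' failed: ",
                           conditionMessage(e)),
                    "skinmwas_error_pipeline")
    })
    rlang::inform(sprintf("[%s] done in %.1fs", name,
                          as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))))
    res
  }

  if (!is.null(config$sim)) {
    simdat <- stage("simulate", simulate_study(config$sim))
    meta <- simdat$metadata
    taxa <- simdat$taxa
    genes <- simdat$genes
    pathways <- simdat$pathways
    catalog <- config$sim$ko_catalog
  } else {
    meta <- stage("read", read_metadata(config$paths$metadata))
    taxa <- read_taxon_table(config$paths$taxa)
    genes <- if (!is.null(config$paths$genes))
      read_stratified_gene_table(config$paths$genes) else NULL
    pathways <- if (!is.null(config$paths$pathway_abundance))
      read_pathway_table(config$paths$pathway_abundance,
                         config$paths$pathway_coverage) else NULL
    catalog <- if (!is.null(config$paths$gene_family_to_ko))
      list(gene_family_to_ko = tibble::as_tibble(
             utils::read.delim(config$paths$gene_family_to_ko)),
           ko_to_pathway = tibble::as_tibble(
             utils::read.delim(config$paths$ko_to_pathway))) else NULL
  }
  sites <- config$sites %||% unique(meta$site)
  map <- if (!is.null(catalog)) {
    ko_map(catalog$gene_family_to_ko, catalog$ko_to_pathway)
  } else NULL

  site_results <- lapply(sites, function(s) {
    m <- meta[meta$site == s, ]
    taxa_f <- stage(paste0(s, "/filter_taxa"),
                    filter_taxa_by_abundance(taxa, m,
                                             config$taxa_threshold))
    taxa_assoc <- stage(paste0(s, "/taxa_assoc"),
                        associate_all_strata(taxa_f, meta, s,
                                             config$q_threshold,
                                             config$rho_threshold))
    out <- list(taxa_filtered = taxa_f, taxa_assoc = taxa_assoc)

    if (!is.null(genes) && !is.null(map)) {
      genes_f <- stage(paste0(s, "/filter_genes"),
                       filter_gene_families(genes, m,
                                            config$rpk_threshold))
      genomes <- aggregate_to_ko(genes_f, map, "bag_of_genomes")
      pooled <- aggregate_to_ko(genes_f, map, "bag_of_genes")
      pa <- stage(paste0(s, "/pathways"),
                  pathway_association(pathways, meta, s,
                                      config$coverage_threshold,
                                      config$q_threshold))
      cand <- pathway_candidate_rule(pa$q_matrix, config$q_threshold,
                                     config$min_hits)
      genomes_assoc <- stage(paste0(s, "/genomes_assoc"),
                             associate_features(genomes, meta, s, "youth",
                                                config$q_threshold,
                                                config$rho_threshold))
      cand_ids <- cand$pathway[cand$candidate]
      strata_present <- unique(sub("^[^|]*\\|", "",
                                   rownames(genomes)))
      strata_present <- setdiff(strata_present, "unclassified")
      ko_counts <- dplyr::bind_rows(lapply(cand_ids, function(p) {
        dplyr::bind_rows(lapply(strata_present, function(sp) {
          count_significant_kos(p, sp, genomes_assoc, genomes, map,
                                config$q_threshold, config$rho_threshold)
        }))
      }))
      out$pathway_assoc <- pa$assoc
      out$pathway_candidates <- cand
      out$genomes_assoc <- genomes_assoc
      out$species_ko_counts <- ko_counts
    }

    out$cap <- stage(paste0(s, "/cap"), {
      d <- bray_curtis(t(taxa_f))
      cap_meta <- m[match(labels(d), m$sample_id), ]
      cap_analysis(d, cap_meta,
                   c("odor_intensity", "age_group", "timepoint", "sex"),
                   n_perm = config$n_perm, seed = config$seed)
    })
    out
  })
  names(site_results) <- sites

  characters <- summarize_odor_characters(meta)

  manifest <- list(
    package_version = as.character(utils::packageVersion("skinmwas")),
    seed = config$seed,
    thresholds = config[c("taxa_threshold", "rpk_threshold",
                          "coverage_threshold", "q_threshold",
                          "rho_threshold", "min_hits")],
    n_perm = config$n_perm,
    sites = sites,
    n_samples = nrow(meta),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_metadata(meta, file.path(od, "metadata.tsv"))
    write_tsv_file(characters, file.path(od, "odor_characters.tsv"))
    for (s in sites) {
      r <- site_results[[s]]
      write_tsv_file(r$taxa_assoc,
                     file.path(od, paste0(s, "_taxa_assoc.tsv")))
      write_tsv_file(format_association_table(
        r$taxa_assoc[r$taxa_assoc$significant, ], config$q_threshold),
        file.path(od, paste0(s, "_taxa_table1_style.tsv")))
      if (!is.null(r$pathway_candidates)) {
        write_tsv_file(r$pathway_candidates,
                       file.path(od, paste0(s, "_pathway_candidates.tsv")))
        write_tsv_file(r$species_ko_counts,
                       file.path(od, paste0(s, "_species_ko_counts.tsv")))
      }
      cap_tbl <- tibble::tibble(
        site = s, pseudo_F = r$cap$pseudo_F, p_value = r$cap$p_value,
        constrained_inertia = unname(r$cap$inertia["constrained"]),
        total_inertia = unname(r$cap$inertia["total"]))
      write_tsv_file(cap_tbl, file.path(od, paste0(s, "_cap_summary.tsv")))
    }
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(metadata = meta, taxa = taxa, odor_characters = characters,
       sites = site_results, manifest = manifest)
}
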