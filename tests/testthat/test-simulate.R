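test_that("default design enumerates to the full cohort", {
  cfg <- sim_config(seed = 11)
  ch <- simulate_cohort(cfg)
  expect_equal(nrow(ch$metadata), 180)
  expect_equal(length(unique(ch$metadata$subject_id)), 30)
  # 8 F / 7 M within each age group
  sexes <- table(unique(ch$metadata[, c("subject_id", "age_group", "sex")])[
    , c("age_group", "sex")])
  expect_equal(unname(sexes["children", c("F", "M")]), c(8, 7))
  expect_equal(unname(sexes["teens", c("F", "M")]), c(8, 7))
  # one record per (subject, site, timepoint)
  expect_false(anyDuplicated(
    ch$metadata[, c("subject_id", "site", "timepoint")]) > 0)
  expect_true(all(ch$metadata$odor_intensity >= 0 &
                    ch$metadata$odor_intensity <= 100))
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(sim_config(n_children = 0, n_teens = 0),
               "n_children", class = "skinmwas_error_config")
  expect_error(sim_config(timepoints = c("1h", "1h")),
               "timepoints", class = "skinmwas_error_config")
  expect_error(sim_config(sigma_odor = 0), "sigma_odor",
               class = "skinmwas_error_config")
  expect_error(
    sim_config(planted_taxa = planted_effect(
      "s__X_y", "forearm", "both", 0.5)),
    "site", class = "skinmwas_error_config")
  expect_error(
    sim_config(planted_taxa = planted_effect(
      "s__X_y", "underarm", "both", 0.5, linked_kos = "K_NOPE_01")),
    "K_NOPE_01", class = "skinmwas_error_config")
  expect_error(planted_effect("s__X_y", "underarm", "both", 0.99),
               class = "skinmwas_error_config")
  expect_error(planted_effect("s__X_y", "underarm", "both", 0.5,
                              exercise_shift = 0),
               class = "skinmwas_error_config")
})

test_that("same seed gives byte-identical outputs, different seed differs", {
  cfg <- tiny_sim_config(seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(tiny_sim_config(seed = 5))
  expect_identical(serialize(a$metadata, NULL), serialize(b$metadata, NULL))
  expect_identical(a$taxa, b$taxa)
  expect_identical(a$genes, b$genes)
  c <- simulate_study(tiny_sim_config(seed = 6))
  expect_false(identical(a$taxa, c$taxa))
})

test_that("taxon profiles are compositionally closed and floor-sparse", {
  st <- simulate_study(sim_config(seed = 3), genes = FALSE)
  sums <- colSums(st$taxa)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(st$taxa >= 0))
  # detection floor: no positive value below the floor survives
  pos <- st$taxa[st$taxa > 0]
  expect_true(all(pos >= sim_config()$detection_floor |
                    abs(pos) < 1e-12))
})

test_that("underarm odor rises after exercise and shifted taxa follow", {
  st <- simulate_study(sim_config(seed = 21), genes = FALSE)
  m <- st$metadata[st$metadata$site == "underarm", ]
  expect_gt(mean(m$odor_intensity[m$timepoint == "8h"]),
            mean(m$odor_intensity[m$timepoint == "1h"]))
  # epidermidis (exercise_shift > 1) is enriched at 8 h at the underarm
  clade <- grep("epidermidis", rownames(st$taxa), value = TRUE)
  ab <- st$taxa[clade, m$sample_id]
  expect_gt(mean(ab[m$timepoint == "8h"]), mean(ab[m$timepoint == "1h"]))
})

test_that("ground-truth registry partitions simulated taxa", {
  st <- simulate_study(sim_config(seed = 2), genes = FALSE)
  reg <- st$truth$registry
  expect_equal(sort(reg$clade), sort(rownames(st$taxa)))
  expect_equal(sum(reg$role == "planted") + sum(reg$role == "null"),
               nrow(reg))
  expect_setequal(reg$taxon[reg$role == "planted"],
                  unique(sim_config()$planted_taxa$taxon))
})

test_that("copula calibration: realized rho tracks the target", {
  # small replicate of the design calibration; the acceptance suite runs
  # the full 100-replicate version
  r <- vapply(1:25, function(s) {
    st <- simulate_study(tiny_sim_config(seed = s), genes = FALSE)
    realized_effect_correlations(st$metadata, st$truth,
                                 st$taxa)$realized_spearman
  }, numeric(1))
  expect_lt(abs(mean(r) - 0.8), 0.1)
  expect_gt(mean(abs(r - 0.8) <= 0.2), 0.85)
})

test_that("null taxa stay below the n=30 Spearman critical value", {
  # all-null cohorts: |rho| should exceed the alpha = 0.05 critical value
  # (0.36 at n = 30) at roughly the nominal rate
  hits <- vapply(1:100, function(s) {
    st <- simulate_study(null_sim_config(seed = s), genes = FALSE)
    m <- st$metadata[st$metadata$age_group == "children", ]
    ab <- st$taxa[1, m$sample_id]
    if (length(unique(ab)) < 2) return(NA)
    abs(cor(ab, m$odor_intensity, method = "spearman")) > 0.36
  }, logical(1))
  expect_lt(mean(hits, na.rm = TRUE), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("stratified gene tables are additive with the planted repertoire", {
  st <- simulate_study(tiny_sim_config(seed = 9))
  strata <- parse_strata(rownames(st$genes))
  tot <- st$genes[strata$stratum == "TOTAL", , drop = FALSE]
  parts <- st$genes[strata$stratum != "TOTAL", , drop = FALSE]
  agg <- rowsum(parts, strata$gene_family[strata$stratum != "TOTAL"])
  expect_lt(max(abs(agg[rownames(tot), ] - tot) / pmax(tot, 1e-12)), 1e-6)
  # unclassified share matches the configured fraction
  uncl <- st$genes[strata$stratum == "unclassified", , drop = FALSE]
  fam <- strata$gene_family[strata$stratum == "unclassified"]
  frac <- uncl / tot[fam, ]
  expect_true(all(abs(frac - 0.1) < 1e-9))
  # planted species carries its linked KOs
  ep_rows <- grep("s__Staphylococcus_epidermidis", rownames(st$genes),
                  value = TRUE)
  cat <- tiny_sim_config(1)$ko_catalog
  linked_fams <- cat$gene_family_to_ko$gene_family[
    cat$gene_family_to_ko$ko %in% c("K_BCAA_01", "K_BCAA_02", "K_BCAA_03")]
  expect_true(all(paste0(linked_fams, "|g__Staphylococcus.",
                         "s__Staphylococcus_epidermidis") %in% ep_rows))
})

test_that("taxon absent from a sample contributes zero RPK there", {
  # raised detection floor to guarantee plenty of absences
  cfg <- tiny_sim_config(seed = 13)
  cfg$detection_floor <- 0.05
  st <- simulate_study(cfg)
  strata <- parse_strata(rownames(st$genes))
  sp_rows <- which(!strata$stratum %in% c("TOTAL", "unclassified"))
  reg <- st$truth$registry
  violations <- 0L
  zero_cells <- 0L
  for (i in sp_rows) {
    lab <- sub(".*\\.s__", "s__", strata$stratum[i])
    clade <- reg$clade[match(lab, reg$taxon)]
    zero_samples <- which(st$taxa[clade, ] == 0)
    zero_cells <- zero_cells + length(zero_samples)
    violations <- violations + sum(st$genes[i, zero_samples] != 0)
  }
  expect_gt(zero_cells, 0)  # the detection floor does create absences
  expect_equal(violations, 0L)
})

test_that("pathway coverage counts detected member KOs", {
  st <- simulate_study(tiny_sim_config(seed = 4))
  cov <- st$pathways$coverage
  expect_true(all(cov >= 0 & cov <= 1))
  # with the planted repertoire, the linked pathway is covered somewhere
  expect_gt(mean(cov["pwy_bcaa_degradation", ]), 0)
})
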