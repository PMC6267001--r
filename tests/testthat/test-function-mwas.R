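toy_map <- function() {
  ko_map(
    tibble::tibble(gene_family = c("FAM_A", "FAM_B", "FAM_C"),
                   ko = c("K1", "K1", "K2")),
    tibble::tibble(ko = c("K1", "K2"), pathway = c("pwy1", "pwy1")))
}

test_that("KO aggregation modes agree on totals and preserve the split", {
  # two families of one KO split across two taxa
  genes <- rbind(
    "FAM_A" = c(10, 20),
    "FAM_A|g__X.s__x" = c(6, 12),
    "FAM_A|g__Y.s__y" = c(4, 8),
    "FAM_B" = c(5, 5),
    "FAM_B|g__X.s__x" = c(5, 5),
    "FAM_C" = c(1, 2),
    "FAM_C|g__Y.s__y" = c(1, 2))
  colnames(genes) <- c("s1", "s2")
  pooled <- suppressMessages(aggregate_to_ko(genes, toy_map(),
                                             "bag_of_genes"))
  strat <- suppressMessages(aggregate_to_ko(genes, toy_map(),
                                            "bag_of_genomes"))
  expect_equal(pooled["K1", ], c(s1 = 15, s2 = 25))
  expect_equal(strat["K1|g__X.s__x", ], c(s1 = 11, s2 = 17))
  expect_equal(strat["K1|g__Y.s__y", ], c(s1 = 4, s2 = 8))
  # marginalizing the stratified table over taxa reproduces the pooled one
  ko_of <- sub("\\|.*", "", rownames(strat))
  marg <- rowsum(strat, ko_of)
  expect_equal(marg[rownames(pooled), ], pooled, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("additivity holds on simulator fixtures", {
  st <- simulate_study(tiny_sim_config(seed = 14))
  map <- ko_map(tiny_sim_config(1)$ko_catalog$gene_family_to_ko,
                tiny_sim_config(1)$ko_catalog$ko_to_pathway)
  pooled <- suppressMessages(aggregate_to_ko(st$genes, map, "bag_of_genes"))
  strat <- suppressMessages(aggregate_to_ko(st$genes, map,
                                            "bag_of_genomes"))
  marg <- rowsum(strat, sub("\\|.*", "", rownames(strat)))
  expect_lt(max(abs(marg[rownames(pooled), ] - pooled) /
                  pmax(pooled, 1e-9)), 1e-6)
  # unmapped families present in the table are dropped with a count
  expect_message(aggregate_to_ko(st$genes, map, "bag_of_genes"),
                 "unmapped")
  fams_present <- unique(parse_strata(rownames(st$genes))$gene_family)
  n_unmapped_expected <- length(
    setdiff(fams_present, map$gene_family_to_ko$gene_family))
  expect_equal(attr(pooled, "n_unmapped"), n_unmapped_expected)
  expect_gt(n_unmapped_expected, 0)
})

test_that("empty mapping is a mapping error", {
  genes <- rbind("FAM_A" = c(1, 2)); colnames(genes) <- c("s1", "s2")
  expect_error(
    aggregate_to_ko(genes, list(gene_family_to_ko = NULL), "bag_of_genes"),
    class = "skinmwas_error_mapping")
  expect_error(
    ko_map(tibble::tibble(gene_family = "F", ko = "K9"),
           tibble::tibble(ko = "K1", pathway = "p")),
    "no pathway", class = "skinmwas_error_mapping")
})

test_that("candidate rule fires at two or more of six comparisons", {
  qm <- matrix(1, 3, 6,
               dimnames = list(c("p0", "p1", "p2"),
                               paste0("c", 1:6)))
  qm["p1", 1] <- 0.05
  qm["p2", c(1, 4)] <- 0.05
  cand <- pathway_candidate_rule(qm)
  expect_equal(cand$n_hits, c(0L, 1L, 2L))
  expect_equal(cand$candidate, c(FALSE, FALSE, TRUE))
  # all six significant is a candidate
  qm2 <- matrix(0.01, 1, 6, dimnames = list("pall", paste0("c", 1:6)))
  expect_true(pathway_candidate_rule(qm2)$candidate)
  # monotone: lowering any q never removes candidacy
  withr::local_seed(7)
  for (i in 1:20) {
    q <- matrix(runif(6), 1, 6, dimnames = list("p", paste0("c", 1:6)))
    base <- pathway_candidate_rule(q)$candidate
    j <- sample(6, 1)
    q2 <- q; q2[1, j] <- q2[1, j] / 2
    expect_true(pathway_candidate_rule(q2)$candidate >= base)
  }
  # wrong number of comparisons is a design error
  expect_error(pathway_candidate_rule(qm[, 1:5]), "6 comparisons",
               class = "skinmwas_error_config")
  qm_na <- qm; qm_na["p0", 2] <- NA
  expect_error(pathway_candidate_rule(qm_na),
               class = "skinmwas_error_config")
})

test_that("per-species significant-KO counts recover planted enzymes", {
  # plant 3 of the 6 branched-chain KOs on epidermidis with a strong
  # positive effect; count recovery across seeds
  catalog <- tiny_sim_config(1)$ko_catalog
  map <- ko_map(catalog$gene_family_to_ko, catalog$ko_to_pathway)
  hits <- vapply(1:25, function(s) {
    st <- simulate_study(tiny_sim_config(seed = s))
    genomes <- suppressMessages(
      aggregate_to_ko(st$genes, map, "bag_of_genomes"))
    assoc <- suppressMessages(
      associate_features(genomes, st$metadata, "underarm", "children"))
    ct <- count_significant_kos(
      "pwy_bcaa_degradation",
      "g__Staphylococcus.s__Staphylococcus_epidermidis",
      assoc, genomes, map)
    expect_lte(ct$n_kos_significant, ct$n_kos_present)
    ct$n_kos_significant
  }, numeric(1))
  expect_gte(mean(hits >= 3), 0.9)
})

test_that("species absent from a pathway counts zero", {
  st <- simulate_study(tiny_sim_config(seed = 3))
  cfg <- tiny_sim_config(1)
  map <- ko_map(cfg$ko_catalog$gene_family_to_ko,
                cfg$ko_catalog$ko_to_pathway)
  genomes <- suppressMessages(
    aggregate_to_ko(st$genes, map, "bag_of_genomes"))
  assoc <- suppressMessages(
    associate_features(genomes, st$metadata, "underarm", "children"))
  ct <- count_significant_kos("pwy_bcaa_degradation",
                              "g__Absent.s__Absent_species",
                              assoc, genomes, map)
  expect_equal(ct$n_kos_present, 0L)
  expect_equal(ct$n_kos_significant, 0L)
  expect_error(count_significant_kos("pwy_nope", "g__X.s__x", assoc,
                                     genomes, map),
               class = "skinmwas_error_mapping")
})

test_that("sign consistency separates pooled from per-species views", {
  # hand-built association table: species A's member KOs positive,
  # species B's copies negative
  map <- ko_map(
    tibble::tibble(gene_family = paste0("F", 1:4),
                   ko = c("K1", "K2", "K1", "K2")),
    tibble::tibble(ko = c("K1", "K2"), pathway = "pwy"))
  strat_assoc <- tibble::tibble(
    feature = c("K1|g__A.s__a", "K2|g__A.s__a",
                "K1|g__B.s__b", "K2|g__B.s__b"),
    rho = c(0.7, 0.6, -0.65, -0.55))
  per_species <- pathway_sign_consistency(strat_assoc, map, "pwy",
                                          "bag_of_genomes")
  expect_equal(per_species$consistency,
               c(1, 1))
  pooled_assoc <- tibble::tibble(feature = c("K1", "K2"),
                                 rho = c(0.2, -0.15))
  pooled <- pathway_sign_consistency(pooled_assoc, map, "pwy",
                                     "bag_of_genes")
  expect_equal(pooled$consistency, 0.5)
  # all same sign -> 1; 2 vs 2 -> 0.5 checked above; bounds
  allpos <- tibble::tibble(feature = c("K1", "K2"), rho = c(0.4, 0.1))
  expect_equal(
    pathway_sign_consistency(allpos, map, "pwy", "bag_of_genes")$consistency,
    1)
  # fewer than two usable KOs is flagged undefined
  one <- tibble::tibble(feature = "K1", rho = 0.4)
  expect_true(is.na(
    pathway_sign_consistency(one, map, "pwy", "bag_of_genes")$consistency))
})

test_that("opposed per-species effects cancel in the pooled analysis", {
  # two species carry the same KOs with opposite planted effects; the
  # stratified analysis recovers both, the pooled analysis neither
  opposed <- dplyr::bind_rows(
    planted_effect("s__Staphylococcus_epidermidis", "underarm", "children",
                   0.8, 1.4, c("K_PYR_01", "K_PYR_02")),
    planted_effect("s__Staphylococcus_hominis", "underarm", "children",
                   -0.8, 0.9, c("K_PYR_01", "K_PYR_02")))
  cfg <- tiny_sim_config(seed = 77, planted = opposed, n_taxa = 22)
  st <- simulate_study(cfg)
  map <- ko_map(cfg$ko_catalog$gene_family_to_ko,
                cfg$ko_catalog$ko_to_pathway)
  genomes <- suppressMessages(
    aggregate_to_ko(st$genes, map, "bag_of_genomes"))
  pooled <- suppressMessages(
    aggregate_to_ko(st$genes, map, "bag_of_genes"))
  g_assoc <- suppressMessages(
    associate_features(genomes, st$metadata, "underarm", "children"))
  p_assoc <- suppressMessages(
    associate_features(pooled, st$metadata, "underarm", "children"))
  epi <- paste0(c("K_PYR_01", "K_PYR_02"),
                "|g__Staphylococcus.s__Staphylococcus_epidermidis")
  hom <- paste0(c("K_PYR_01", "K_PYR_02"),
                "|g__Staphylococcus.s__Staphylococcus_hominis")
  expect_true(all(g_assoc$significant[g_assoc$feature %in% epi]))
  expect_true(all(g_assoc$significant[g_assoc$feature %in% hom]))
  expect_true(all(g_assoc$rho[g_assoc$feature %in% epi] > 0))
  expect_true(all(g_assoc$rho[g_assoc$feature %in% hom] < 0))
  pooled_rows <- p_assoc[p_assoc$feature %in% c("K_PYR_01", "K_PYR_02"), ]
  expect_false(any(pooled_rows$significant))
})
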