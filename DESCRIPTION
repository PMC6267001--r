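Package: skinmwas
Title: Metagenome-Wide Association of the Skin Microbiome with Body Odor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a metagenome-wide association
    workflow linking skin-microbiome taxonomic and taxon-stratified
    functional profiles to a continuous, perfumer-scored malodor-intensity
    phenotype across body sites (underarm, neck, head), age strata
    (children, teenagers, pooled youth), and paired pre/post-exercise
    timepoints. Includes a synthetic-cohort generator with planted,
    ground-truthed taxon and enzyme effects; parsers and abundance filters
    for merged taxonomic and stratified gene-family profile tables; a
    dual-mode (cross-sectional Spearman, longitudinal Wilcoxon
    signed-rank) association engine with Benjamini-Hochberg FDR control;
    pooled "bag of genes" versus taxon-stratified "bag of genomes"
    functional association with KEGG-orthology/pathway aggregation and a
    candidate-pathway decision rule; and Bray-Curtis ordination with
    canonical analysis of principal coordinates and permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
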