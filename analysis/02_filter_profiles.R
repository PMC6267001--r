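#!/usr/bin/env Rscript

## Stage 2 — parse the profile tables and apply the abundance gates.
##
## Mirrors the study's feature filters, per body site: species retained at
## mean relative abundance > 1% in either children or teenagers; gene
## families retained at mean community RPK > 10 in either group, then
## renormalized to per-sample relative abundances (strata scaled by the
## same factor); pathways retained at mean coverage > 0.3 across all the
## site's samples.

library(skinmwas)

indir <- "results/sim"
out <- "results/filtered"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read_metadata(file.path(indir, "metadata.tsv"))
taxa <- read_taxon_table(file.path(indir, "taxa_merged.tsv"))
genes <- read_stratified_gene_table(file.path(indir, "genefamilies_rpk.tsv"))
pathways <- read_pathway_table(file.path(indir, "pathway_abundance.tsv"),
                               file.path(indir, "pathway_coverage.tsv"))

for (s in unique(meta$site)) {
  m <- meta[meta$site == s, ]
  taxa_f <- filter_taxa_by_abundance(taxa, m, threshold = 1)
  genes_f <- filter_gene_families(genes, m, min_mean_rpk = 10)
  pwy_keep <- filter_pathways_by_coverage(pathways, m, min_mean_cov = 0.3)
  cat(sprintf(
    "%-9s taxa %2d -> %2d | gene families %3d -> %3d | pathways %d -> %d\n",
    s, nrow(taxa), nrow(taxa_f),
    length(unique(parse_strata(rownames(genes))$gene_family)),
    length(unique(parse_strata(rownames(genes_f))$gene_family)),
    nrow(pathways$coverage), length(pwy_keep)))
  write_taxon_table(taxa_f, file.path(out, paste0(s, "_taxa.tsv")))
  write_stratified_gene_table(genes_f,
                              file.path(out, paste0(s, "_genes.tsv")))
  writeLines(pwy_keep, file.path(out, paste0(s, "_pathways_kept.txt")))
}
cat("Filtered tables written to", out, "\n")
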