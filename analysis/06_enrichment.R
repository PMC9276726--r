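#!/usr/bin/env Rscript
# Stage 6 -- gene-set over-representation of the candidate region genes.
#
# Hypergeometric test of each comparison's region gene list against the
# simulated gene sets (which include one set enriched for sweep-interval
# genes as a positive control); universe = all genes in the gene models.

library(sweepscan)

genes <- load_gff("results/data/genes.gff3")
sets <- read_gmt("results/data/sets.gmt")
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

for (control in c("TT", "MS", "DU", "LW")) {
  comparison <- paste0("XP_vs_", control)
  f <- file.path("results/scan", comparison, "region_genes.tsv")
  if (!file.exists(f)) next
  selected <- read.table(f, header = TRUE)$gene_id
  if (!length(selected)) next
  res <- hypergeom_enrich(selected, sets, universe = names(genes))
  write.table(res, file.path("results/enrichment",
                             paste0(comparison, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- res[1, ]
  cat(sprintf(
    "%s: %d significant sets; top: %s (k=%d/%d, p=%.3g)\n",
    comparison, sum(res$significant), top$set_id, top$k, top$K, top$p_value
  ))
}
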