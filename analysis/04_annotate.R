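#!/usr/bin/env Rscript
# Stage 4 -- functional annotation of the filtered SNPs.
#
# ANNOVAR-style categories against the simulated gene models, a
# category-count summary with percentages, coding effects for exonic SNPs,
# and the Venn decomposition of per-comparison region gene lists.

library(sweepscan)

gm <- qc_filter(apply_hard_filters(parse_vcf("results/data/cohort.vcf")))
genes <- attach_cds_sequences(load_gff("results/data/genes.gff3"),
                              "results/data/cds.fasta")
dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)

cats <- classify_sites(gm$sites, genes)
summary <- summarize_annotation_counts(table(cats))
write.table(summary, "results/annotation/category_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("SNP functional categories:\n")
print(summary)

# coding effects for exonic SNPs
exonic <- which(cats == "exonic")
effects <- character(0)
for (i in exonic) {
  s <- gm$sites[i, ]
  for (g in genes) {
    if (g$chrom != s$chrom) next
    for (tx in g$transcripts) {
      if (is.null(tx$cds_seq)) next
      if (!any(tx$cds$start <= s$pos & s$pos <= tx$cds$end)) next
      effects <- c(effects, coding_effect(s$chrom, s$pos, s$ref, s$alt, tx))
    }
  }
}
if (length(effects)) {
  eff_summary <- summarize_annotation_counts(table(effects))
  write.table(eff_summary, "results/annotation/coding_effects.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\ncoding effects among exonic SNPs:\n")
  print(eff_summary)
}

# Venn cells of the four comparisons' region gene lists
lists <- list()
for (control in c("TT", "MS", "DU", "LW")) {
  f <- file.path("results/scan", paste0("XP_vs_", control),
                 "region_genes.tsv")
  if (file.exists(f)) {
    lists[[paste0("XP_vs_", control)]] <- read.table(f, header = TRUE)$gene_id
  }
}
if (length(lists) >= 2) {
  venn <- intersect_gene_lists(lists)
  cells <- data.frame(cell = names(venn$cells), genes = unname(venn$cells))
  write.table(cells, "results/annotation/region_gene_venn.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  all_cell <- paste(names(lists), collapse = "&")
  cat(sprintf("\ngenes shared by all four comparisons: %d\n",
              venn$cells[all_cell]))
}
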