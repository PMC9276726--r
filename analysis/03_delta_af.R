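#!/usr/bin/env Rscript
# Stage 3 -- per-SNP delta-AF screen for XP-specific near-fixed alleles.
#
# For each comparison, computes |AltAF_XP - AltAF_control| per SNP, flags
# SNPs with AF_XP > 0.8 and AF_control < 0.2, and maps the passing SNPs to
# genes (1 kb flanks). Also intersects the four passing sets.

library(sweepscan)

gm <- qc_filter(apply_hard_filters(parse_vcf("results/data/cohort.vcf")))
popmap <- read_popmap("results/data/popmap.tsv")
genes <- load_gff("results/data/genes.gff3")
af <- allele_frequencies(gm, popmap)

dir.create("results/delta_af", showWarnings = FALSE, recursive = TRUE)
pass_sets <- list()
for (control in c("TT", "MS", "DU", "LW")) {
  d <- population_specific_screen(compute_delta_af(af, "XP", control))
  gmap <- snps_to_genes(d[d$passes_screen, ], genes)
  comparison <- paste0("XP_vs_", control)
  write.table(d, file.path("results/delta_af", paste0(comparison, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pass_sets[[comparison]] <- paste(d$chrom[d$passes_screen],
                                   d$pos[d$passes_screen])
  cat(sprintf("XP vs %s: %d / %d SNPs pass the 0.8/0.2 screen (%d genes)\n",
              control, sum(d$passes_screen), nrow(d),
              length(unique(gmap$gene_id))))
}
shared <- Reduce(intersect, pass_sets)
cat(sprintf("SNPs passing in all four comparisons: %d\n", length(shared)))
writeLines(shared, "results/delta_af/shared_all_comparisons.txt")
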