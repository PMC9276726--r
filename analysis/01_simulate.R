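#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
#
# Five pig-breed-like populations (XP the target; TT, MS, DU, LW controls)
# of 25 diploids each, two 10 Mb autosomes at ~1 SNP / 2 kb, Balding-
# Nichols divergence F = 0.05, and four designated 340 kb sweep intervals
# in which XP allele frequencies are pushed toward fixation at s = 0.9.
# Writes the VCF, population map, truth files, and simulated gene models
# under results/data/.

library(sweepscan)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sweeps <- data.frame(
  chrom = rep(c("1", "2"), each = 2),
  start = rep(c(2000001L, 6000001L), 2),
  end   = rep(c(2340000L, 6340000L), 2),
  pop = "XP", s = 0.9
)
cfg <- sweep_sim_config(
  populations = c(XP = 25, TT = 25, MS = 25, DU = 25, LW = 25),
  chrom_lengths = c("1" = 10000000, "2" = 10000000),
  sweep_intervals = sweeps,
  seed = 2022
)

# gene models first, so SNP reference alleles can be made consistent with
# the coding sequences
genes <- simulate_gene_models(cfg$chrom_lengths, n_genes = 300,
                              seed = 2022, sweep_intervals = sweeps,
                              out_dir = out)
cat(sprintf("gene models: %d genes, %d gene sets (incl. sweep_set)\n",
            length(genes$models), length(genes$sets)))

sim <- simulate_cohort(cfg, out_dir = out, gene_models = genes$models)
cat(sprintf("cohort: %d SNPs x %d samples, %d sweep SNPs in %d intervals\n",
            nrow(sim$genotypes$sites), length(sim$genotypes$samples),
            nrow(sim$truth$snps), nrow(sim$truth$intervals)))
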