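# Independent oracles, each written as a direct transcription of the
# definition it checks -- deliberately separate from the package's code
# paths.

# Per-site pi by exhaustive pair enumeration: draw every unordered pair of
# alleles from a vector of k alt and n - k ref alleles and count differing
# pairs.
pi_pair_oracle <- function(alt_count, n_alleles) {
  alleles <- c(rep(1, alt_count), rep(0, n_alleles - alt_count))
  pairs <- utils::combn(n_alleles, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Weir & Cockerham (1984) two-population components, scalar loop form over
# populations (independent transcription of the estimator).
wc84_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  hbar <- sum(n * h) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# Windowed weighted Fst on raw dosage columns: per-site n, p, h from
# genotype counts, WC84 components via the oracle above, ratio of sums.
windowed_fst_oracle <- function(dos1, dos2) {
  sums <- c(a = 0, abc = 0)
  for (i in seq_len(nrow(dos1))) {
    g1 <- dos1[i, ][!is.na(dos1[i, ])]
    g2 <- dos2[i, ][!is.na(dos2[i, ])]
    if (!length(g1) || !length(g2)) next
    n <- c(length(g1), length(g2))
    p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
    h <- c(mean(g1 == 1), mean(g2 == 1))
    if (all(p == 0) && all(h == 0)) next
    if (all(p == 1) && all(h == 0)) next
    comp <- wc84_oracle(n, p, h)
    tot <- sum(comp)
    if (tot == 0) next
    sums["a"] <- sums["a"] + comp["a"]
    sums["abc"] <- sums["abc"] + tot
  }
  unname(sums["a"] / sums["abc"])
}

# Upper-tail hypergeometric probability by direct combinatorial enumeration.
hyper_tail_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Coding effect by whole-CDS translation diff (Biostrings translate).
translation_diff_oracle <- function(cds_seq, off, alt_base) {
  ref_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq), no.init.codon = TRUE))
  s <- strsplit(cds_seq, "")[[1]]
  s[off] <- alt_base
  alt_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(s, collapse = "")), no.init.codon = TRUE))
  ref_aa <- strsplit(ref_prot, "")[[1]]
  alt_aa <- strsplit(alt_prot, "")[[1]]
  i <- (off - 1) %/% 3 + 1
  if (ref_aa[i] == alt_aa[i]) return("synonymous")
  if (ref_aa[i] != "*" && alt_aa[i] == "*") return("stopgain")
  if (ref_aa[i] == "*" && alt_aa[i] != "*") return("stoploss")
  "nonsynonymous"
}

# Small genotype matrix builder for fixtures.
make_gm <- function(dosage, chrom = "1", pos = NULL, qual = 100,
                    samples = NULL, ...) {
  dosage <- as.matrix(dosage)
  if (is.null(pos)) pos <- seq_len(nrow(dosage)) * 100L
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(dosage)))
  extra <- list(...)
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "G", qual = qual,
                      stringsAsFactors = FALSE)
  for (nm in names(extra)) sites[[nm]] <- extra[[nm]]
  genotype_matrix(sites, dosage, samples)
}

# Two-population popmap over a matrix's samples (first n1 -> pop1).
make_popmap <- function(gm, n1, pop1 = "XP", pop2 = "TT") {
  n <- length(gm$samples)
  stats::setNames(c(rep(pop1, n1), rep(pop2, n - n1)), gm$samples)
}

# Standard sweep-recovery simulation design: two 10 Mb chromosomes, four
# 340 kb sweep intervals (100 fully-contained 100 kb/10 kb windows, ~5% of
# all windows), XP vs TT at F = 0.05.
recovery_sim_design <- function() {
  list(
    intervals = data.frame(
      chrom = rep(c("1", "2"), each = 2),
      start = rep(c(2000001L, 6000001L), 2),
      end = rep(c(2340000L, 6340000L), 2),
      pop = "XP", s = 0.9,
      stringsAsFactors = FALSE
    ),
    chrom_lengths = c("1" = 10000000, "2" = 10000000),
    populations = c(XP = 25, TT = 25)
  )
}
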