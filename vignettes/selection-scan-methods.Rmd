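---
title: "Methods: windowed sweep scans, the ΔAF screen, and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed sweep scans, the ΔAF screen, and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and the numerical choices behind
`sweepscan`: what each statistic assumes, which parameters matter and why
their defaults are what they are, what the simulator does and does not
emulate, and where the design was genuinely open.

## The scan model

The scan targets the classic signature of a recent selective sweep: in the
swept population an allele has risen to (near) fixation, so locally (i)
allele frequencies are strongly differentiated from related populations and
(ii) nucleotide diversity is depressed. Two windowed statistics capture
these, and a candidate region must be extreme in **both**.

**Differentiation.** Per biallelic site, the two-population Weir–Cockerham
(1984) variance components are computed from the per-site called sample
sizes $n_1, n_2$, alternate-allele frequencies $p_1, p_2$, and observed
heterozygote fractions $h_1, h_2$:
with $r = 2$, $\bar n = (n_1 + n_2)/2$,
$n_c = (r\bar n - (n_1^2 + n_2^2)/(r\bar n))/(r-1)$,
$\bar p$ and $\bar h$ the $n_i$-weighted means and
$s^2 = \sum_i n_i (p_i - \bar p)^2 / ((r-1)\bar n)$,

$$a = \frac{\bar n}{n_c}\Big(s^2 - \frac{1}{\bar n - 1}\big(\bar p(1-\bar p) - \tfrac{r-1}{r}s^2 - \tfrac{\bar h}{4}\big)\Big),$$
$$b = \frac{\bar n}{\bar n - 1}\Big(\bar p(1-\bar p) - \tfrac{r-1}{r}s^2 - \tfrac{2\bar n - 1}{4\bar n}\bar h\Big), \qquad c = \bar h / 2.$$

The windowed estimator is the "weighted" ratio of sums
$F_{ST} = \sum a / \sum(a+b+c)$ over polymorphic sites — the same windowed
form VCFtools reports. Sites where $a+b+c = 0$ (monomorphic in the pooled
sample, or degenerate single-individual sites) carry no information and are
excluded from both sums. Negative window values, a known property of the
estimator near zero differentiation, are reported as-is: clamping would
distort nothing but the ranking is what the scan uses, and the ranking is
unaffected.

**Diversity.** Per site, $\pi = 2k(n-k)/(n(n-1))$ for $k$ alternate alleles
among $n$ called alleles — the unbiased pairwise-difference estimator.
Windowed $\pi$ divides the site sum by the full window length in bp
(VCFtools' `--window-pi` convention). Because target and control share
windows, the ratio $\theta_\pi = \pi_{control}/\pi_{target}$ is insensitive
to that denominator choice. The orientation puts diversity **loss in the
target** above 1, matching the expectation that domestication and selection
reduce diversity in the swept population; the reciprocal orientation is a
single argument swap and inverts every ratio exactly (a tested invariant).
Windows where $\pi_{target} = 0$ get an infinite ratio: they are kept for
the Fst tail but excluded from the ratio quantile, since no finite
threshold can rank them. At the default sweep strengths this is rare; it
becomes common only at $s = 1$ with no missing data.

**Outliers and regions.** With $N$ windows carrying finite values of both
statistics, each statistic's outlier set is the $k = \lceil (1-q)N \rceil$
highest windows ($q = 0.95$ by default), with all windows tied at the
boundary value included. Top-$k$ with tie inclusion was chosen over
interpolated percentiles because it is exactly reproducible across
platforms and makes the realized thresholds (the minimum value in each
outlier set) directly reportable, mirroring how per-comparison cutoffs like
"Fst > 0.15 and θπ > 1.23" are quoted in practice. The candidate set is the
intersection; merging uses bedtools semantics (overlapping *or* book-ended
windows join), carrying window counts and per-region maxima.

**Window geometry.** Defaults are 100-kb windows, 10-kb step, and a minimum
of 10 SNPs per window; sparser windows are discarded as unstable. Starts
run $1, 1+\text{step}, \dots$ while the start is inside the chromosome, and
the final windows truncate at the chromosome end. Quantiles are taken over
all windows jointly, not per chromosome.

## The ΔAF screen

Per SNP, $\Delta AF = |AltAF_{target} - AltAF_{control}|$, with
frequencies computed from called genotypes only (missing calls drop out of
numerator and denominator; a population with no called genotypes at a site
makes the site undefined and skipped, with a count). The
population-specific screen passes a SNP iff $AF_{target} > 0.8$ **and**
$AF_{control} < 0.2$, strict inequalities as printed conventions state
them ("> 80%", "< 20%"); a passing SNP therefore always has
$\Delta AF > 0.6$. The screened allele is the VCF alternate allele — no
outgroup polarization into ancestral/derived is attempted, because none of
the downstream decisions depend on polarity. Screens are pairwise (one
control at a time); intersecting the per-comparison passing sets is left to
the caller (the analysis drivers show it).

## Filtering

Hard filters follow GATK SNP conventions with strict bounds: QUAL > 30,
QD > 5.0, FS < 60.0, MQ > 40.0, MQRankSum > −12.5, ReadPosRankSum > −8.0.
A metric absent from a record does not fail the site (GATK treats
un-annotated sites as passing), and the removal report counts failures per
criterion. Cohort QC removes sites with pooled MAF < 0.05 (a site at
exactly 0.05 is kept, the PLINK `--maf` convention), call rate < 0.90, or
missing fraction > 0.20. Call rate and missing rate are complementary and
one bound implies the other at these values, but both are applied
independently as stated so that changing one threshold alone behaves
predictably. MAF is pooled across the merged cohort, not per population,
matching a merged-cohort filtering step applied before any scan.

## Annotation

Gene models are per-transcript (exons, CDS, UTRs as 1-based inclusive
intervals). Classification uses ANNOVAR-style precedence — exonic >
splicing > UTR5/UTR3 > intronic > upstream/downstream > intergenic — with a
1-kb flank for upstream/downstream and a 2-bp intronic splice window, the
ANNOVAR defaults. A SNP hitting multiple transcripts takes the
highest-precedence category; conflicts at equal precedence produce the
combined labels `UTR5;UTR3` and `upstream/downstream`. Coding effects
translate only the affected codon (reverse-complemented for minus-strand
transcripts) under the standard nuclear code, classify
synonymous/nonsynonymous/stopgain/stoploss, and return `unknown` when the
supplied reference base conflicts with the CDS sequence or the codon is
incomplete — agreement with a whole-CDS translation-diff oracle is tested
across 1,000 random simulated transcripts.

## Structure and LD summaries

PCA standardizes dosages per site by $2\hat p$ and
$\sqrt{2\hat p(1-\hat p)}$ (Patterson scaling), after per-site mean
imputation of missing dosages — imputation is used *only* here; every other
statistic is complete-case per site. Coordinates are eigenvectors of the
sample covariance scaled by the square roots of their eigenvalues.
IBS distance is the per-site mean of $|d_i - d_j|/2$ over co-called sites.
The neighbor-joining tree uses the Saitou–Nei algorithm (via `ape::nj`,
which is exact on additive matrices); negative branch lengths, which only
arise on non-additive noise, are clamped to zero with the deficit moved to
the sister branch so parent-path lengths are preserved. LD is genotype
(composite) $r^2$ — the squared Pearson correlation of dosage vectors —
because inputs are unphased; pairs run within chromosomes up to 300 kb by
default and are averaged in 1-kb bins, with within-population monomorphic
sites skipped.

## The simulator

`simulate_cohort()` draws, per neutral SNP, an ancestral frequency
$p \sim U(0.05, 0.95)$ and per population a Balding–Nichols frequency
$p_i \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, then diploid genotypes
$\sim \mathrm{Binomial}(2, p_i)$. Two populations simulated this way have
expected pairwise Weir–Cockerham Fst ≈ F, which is what makes the
parameter-recovery test meaningful. Inside a sweep interval the target
population's frequency moves toward fixation,
$p_t \leftarrow (1-s)p_t + s\,\mathrm{round}(p_t)$, leaving controls
neutral — reduced target π, elevated Fst and ΔAF follow by construction.
Genotypes are masked missing uniformly at the configured rate, and the
whole simulation is deterministic given the seed (byte-identical VCF
output is a tested contract).

Frequency-level simulation was chosen over coalescent machinery because
every in-scope statistic is a function of frequencies and dosages; it runs
in seconds and needs no external dependency. The ancestral-frequency bounds
(0.05, 0.95) keep monomorphic draws from dominating at small sample sizes.
Sites are independent by default, which real genomes are not: an optional
block mode (`ld_block_bp`) shares frequencies within blocks and partially
copies genotypes with a probability decaying over distance, giving the LD
statistic a decaying curve to measure. What passing tests on simulated
cohorts do **not** show: robustness to haplotype structure, demographic
history (bottlenecks, admixture), allele-frequency spectra from real
mutation processes, or genotyping error that correlates with depth — the
simulator has none of these.

Simulated gene models pack non-overlapping multi-exon genes (2–4 exons,
CDS of 100–250 codons starting ATG and ending with a stop, no internal
stops, 50–200 bp UTRs, 200–1000 bp introns) with random intergenic gaps
spread over the genome, on either strand. When gene models are passed to
the cohort simulator, SNPs landing in a CDS take their reference allele
from the coding sequence so that coding-effect calls are internally
consistent. The GMT output contains random sets plus one set enriched for
genes inside sweep intervals, as a positive control for the enrichment
stage.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for overlap $k$ between a selected gene list (size $n$) and a
set (size $K$ after intersection with the universe) in a universe of $N$
genes. The universe defaults to all genes in the loaded gene models, not
all genes mentioned in the GMT — candidate lists are drawn from the
annotated genome, so that is the correct reference population. The
significance flag uses raw $p < 0.05$, mirroring the common reporting
practice the package emulates; Benjamini–Hochberg q-values are always
computed alongside so users can apply the stricter criterion.

## Problem sizes and determinism

The test suite exercises the estimators against independent oracles
(exhaustive pair counting for π at $n \le 12$; an independently transcribed
WC84 evaluator on 1,000 random sites; whole-CDS translation diffs on 1,000
transcripts; combinatorial enumeration for the hypergeometric tail) and
runs the scan end-to-end on simulated cohorts of 25 + 25 diploids with
50,000 SNPs for parameter recovery ($F \in \{0.05, 0.15, 0.3\}$, recovered
within ±0.02) and ~10,000 SNPs across ~2,000 windows for sweep recovery
(5% of windows swept at $s = 0.9$; ≥ 80% recovery with ≤ 1% neutral
contamination over 5 seeds). These sizes were chosen as the smallest at
which the quantile machinery and the recovery criteria are statistically
stable. All randomness flows through explicit seeds; identical inputs
produce byte-identical outputs.

## Known limitations

- Haplotype-based statistics (XP-EHH, iHS) and composite-likelihood sweep
  models are out of scope; the scan sees only frequencies and dosages.
- The annotation stage does not consult dbSNP (no known/novel split) and
  does no deleteriousness prediction.
- The simulator's sweeps act on frequencies, not haplotypes, so signatures
  that live in haplotype structure (e.g., EHH decay) cannot be emulated.
- With very strong sweeps ($s = 1$) and no missing data, fully swept
  windows have $\pi_{target} = 0$ and drop out of the ratio tail by the
  infinite-ratio rule; at the default $s = 0.9$ this does not occur.
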