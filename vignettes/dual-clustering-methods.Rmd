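---
title: "Dual-clustering association screening: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-clustering association screening: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualclust)
```

## The problem

Whole-genome sequencing yields a high density of rare variants (minor
allele frequency, MAF, below 5%), individually carried by few subjects,
while disease-relevant phenotypes such as blood pressure are often
measured repeatedly over time. Single-marker tests are underpowered for
rare variants, and cross-sectional analyses that test one exam at a time
can miss variants whose effect is on the *trajectory* of the trait — for
example a gene that changes how blood pressure rises with age rather than
its level at baseline.

`dualclust` screens genes for association with a longitudinal trait by
clustering the subjects twice and asking whether the two partitions agree:

1. **Genotype side (per gene).** Subjects are scored pairwise by an
   inverse-probability-weighted similarity over the gene's SNPs, converted
   to a distance, and partitioned by Ward hierarchical clustering into
   `k` groups (the studied range is 5–10, default 10).
2. **Phenotype side (once).** Covariate-adjusted trait trajectories are
   clustered by Ward linkage on Euclidean distances and cut into 2 groups,
   which in blood-pressure data separate into a "high" and a "low" cluster.

Association between the gene's partition and the 0/1 phenotype-cluster
indicator `Y` is then scored with ordinary single-variable machinery: the
partition-retention I statistic and one-way ANOVA, with permutation
p-values and Bonferroni or Benjamini–Hochberg control across genes. A
linear weighted-kernel variance-component score test on the same `Y`
serves as the comparator, and an ROC/AUC harness compares methods on
synthetic genomes with known causal genes.

## The genotype similarity

For genotypes $g_i, g_j \in \{0,1,2\}$ (minor-allele counts) at a SNP with
observed MAF $p$, the pair score is case-based on the unordered pair:

| pair | score |
|---|---|
| $(0,0)$ | $2p^2$ |
| $(1,1)$ | $\tfrac12\!\left(\tfrac1{p^2}+\tfrac1{(1-p)^2}\right)-\tfrac1{p(1-p)}$ |
| $(2,2)$ | $2(1-p)^2$ |
| $g_i+g_j=1$ | $\tfrac1{(1-p)^2}-\tfrac1{2p(1-p)}$ |
| $\{0,2\}$ | $-\tfrac1{p(1-p)}$ |
| $g_i+g_j=3$ | $\tfrac1{p^2}-\tfrac1{2p(1-p)}$ |

The reciprocals of genotype probabilities make a shared *minor* allele at
a rare SNP worth far more than a shared common allele: as $p \to 0$ the
$(1,1)$ score diverges while the $(0,0)$ score vanishes, and opposite
homozygotes always score negative. All six coefficients live in one
table-driven function (`ip_score_table`), and the test suite pins every
case against an independently coded symbolic oracle over
$p = 0.01, \dots, 0.49$, so a correction to any coefficient is a one-line
change re-verified by the whole suite.

Gene-level similarity is the sum of the per-SNP scores over the gene's
retained SNPs; the distance transform is
$d(i,j) = -\mathrm{sim}(i,j) + \max_{m \ne n}\mathrm{sim}(m,n)$, anchoring
the most similar pair at distance 0. An exponential transform
$d = e^{-\lambda\,\mathrm{sim}}$ is available behind a flag
(`similarity_to_distance(transform = "exponential")`) but the linear shift
is the default. Observed MAFs are computed from the analysis sample after
rounding dosages to called genotypes (ties at .5 round half-up) and
folding each SNP to its minor allele; monomorphic SNPs are excluded
because the score is undefined at $p = 0$. The default MAF window for
screening is the closed interval $[0.01, 0.05]$ — the rare-variant band
the method targets — with both bounds adjustable.

## Clustering conventions

Ward linkage is applied **directly to the supplied distance matrix** via
the squared-distance Lance–Williams update (`hclust`'s `ward.D2`), since
the genotype distances come from a transformed similarity, not a
Euclidean embedding. The suite verifies the merge sequence against an
exhaustive step-by-step Ward-cost oracle on random matrices. Cutting the
tree at `k` undoes the last `k − 1` merges; labels are canonicalized by
first appearance so partitions are comparable across subject orderings.
Partition sizes outside 5–10 are allowed but flagged. On the phenotype
side the same Ward criterion is used on Euclidean distances between
adjusted trajectory vectors, for consistency with the genotype side; the
2-group cut's mean trajectories are attached so callers can identify the
high and low groups.

## Phenotype preparation

Traits are residualized per time point by OLS on intercept, age, sex,
age×sex and (per-exam) medication; the residuals are the clustering
features. This is deliberately a cross-sectional adjustment, not a joint
longitudinal model: the clustering step that follows consumes the whole
residual trajectory, which is where the longitudinal structure is used.
Baseline age is used at every exam (a per-exam age column can be supplied
by editing the covariates). A subject missing some — not all — exams has
gaps filled by carrying the last observed adjusted value forward (leading
gaps back-filled), with the affected subjects flagged; this is the
package's rule for an situation the method itself does not address.

## Association scores

With partition element sizes $n_i$, element means $\bar Y_i$, overall
mean $\bar Y$ and population standard deviation $s$ (denominator $n$),

$$I = \sum_i \frac{n_i(\bar Y_i - \bar Y)^2}{s^2 / n_i}
    = \sum_i \frac{n_i^2(\bar Y_i - \bar Y)^2}{s^2}.$$

$I$ is affine-invariant in $Y$ and dimensionless. A `per_n` variant
dividing by $n$ is exposed; for fixed $n$ the two differ by a constant
factor, so rankings, permutation p-values and ROC curves are identical
either way. The ANOVA F uses the classical between/within decomposition
with the asymptotic $F(k-1, n-k)$ tail. $Y$ is the phenotype-cluster
indicator (coded 1 for the high-trajectory group) and the gene's genotype
partition is the grouping factor — the roles are fixed this way
throughout. Note the ANOVA's asymptotic p-value treats a binary response
as Gaussian; it is best read as a ranking score, which is how the ROC
harness uses it. The permutation p-value
$(1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$ is exact for any statistic
and is the recommended inferential quantity; the permutation null for
both I and F is computed from group sums of permuted $Y$ in one
vectorized pass, which is what makes genome-scale permutation screens
affordable (F is monotone in the between-group sum of squares at fixed
total, so both statistics need only the $k \times B$ group-sum matrix).

Perfect separation (zero within-group variance) is reported as a floored
p-value $1/(B_{\text{floor}}+1)$ with a degenerate flag rather than 0, so
downstream ranking and multiplicity code never sees an exact zero.

## The kernel-score comparator

The comparator forms $K = GWG^\top$ with $W = \mathrm{diag}(w_k)$,
$w_k = \mathrm{Beta}(p_k; 1, 25)^2$ — the standard rare-variant-boosting
weight, configurable — and tests $Q = r^\top K r$ with $r$ the OLS
residuals of $Y$ on the covariate design (intercept by default). $Y$ is
the same cluster indicator, treated as a continuous response (the linear,
Gaussian form of the test). The null of $Q$ is
$\sum_i \lambda_i \chi^2_1$ with $\lambda$ the eigenvalues of
$\hat\sigma^2 P_0 K P_0$, computed cheaply as an $m \times m$ problem from
the residualized weighted genotype columns; the p-value uses Liu-type
moment matching (matching skewness, and kurtosis where attainable, to a
noncentral chi-square), with a seeded permutation fallback whenever the
approximation fails. The suite cross-validates the moment-matched p
against B = 20,000 permutations. A gene on which the test fails yields an
NA p-value with a reason string, never a silently dropped row; the ROC
harness ranks NA scores last and reports their count.

## The synthetic genome

`sim_config()` fixes the study conditions; `simulate_genotypes()`,
`simulate_traits()` and `simulate_replicates()` realize them
reproducibly from one master seed (each replicate's derived seed is
recorded so it can be regenerated in isolation).

* **Genotypes.** Per SNP a true MAF is drawn from `maf_law` and genotypes
  are Binomial(2, p) — exact Hardy–Weinberg proportions, unrelated
  subjects. The default spectrum is rare-variant-rich: 80% of SNPs
  Uniform(0.005, 0.05), 20% Uniform(0.05, 0.5). Genes are contiguous SNP
  blocks (default 20 SNPs; the power studies use 30).
* **Traits.** `trait(i,t) = 120 + 0.5·age + 5·sex − 0.1·age·sex −
  8·med_t + effect(t)·burden(i) + N(0, 10²)`, in mmHg on an SBP-like
  scale: a 10 mmHg residual SD and covariate effects of a few mmHg are
  typical of blood-pressure regressions, and the defaults were fixed once
  on that reasoning. Burden is the subject's minor-allele count over the
  causal gene's rare SNPs (observed MAF < 0.05, fraction configurable).
  `effect(t)` encodes the genetics–time interaction: `level` (constant),
  `slope` (`effect_size · t`, absent at baseline), or `crossing`
  (`effect_size · (t − (T−1)/2)`, sign flips across the exams). The
  default `effect_size` of 5 mmHg per burden unit makes a 30-rare-SNP
  causal gene (burden SD ≈ 1.3) a strong, clearly detectable signal by
  the last exam — the regime the power studies are meant to probe.
  Covariates: age uniform on 30–80 years, sex Bernoulli(0.5), per-exam
  medication Bernoulli(0.3), independent.
* **What it does not emulate.** Pedigree/family structure (the source
  cohorts are family-based; relatedness inflates p-values for causal and
  noncausal genes alike, leaving ROC comparisons intact, and is out of
  scope), linkage disequilibrium between SNPs, imputation uncertainty,
  and irregular visit times. Passing tests on this generator therefore
  demonstrate correctness and calibration under idealized sampling, not
  performance on family data with LD.

## Numerical and design choices

* Dosage rounding half-up; MAF from rounded genotypes; missing dosages
  imputed to the modal called genotype (count logged; per-SNP exclusion
  available).
* MAF window closed on both ends; a flag switches to open bounds.
* Ward tie-breaks are `hclust`'s; on continuous distances ties have
  probability zero, and the duplicate-point case is covered by tests.
* Permutation comparisons use `>=` on identically computed statistics, so
  genuine ties count toward the p-value (the conservative convention).
* The exact signed-rank branch of `compare_auc` (n ≤ 25 nonzero pairs)
  enumerates the sign-assignment distribution by dynamic programming on
  doubled midranks, which stays exact under tied AUC differences; above
  25 the tie-corrected normal approximation is used.
* Genes whose SNPs all leave the MAF window are skipped with a warning
  and listed in the result attributes; a screen in which *no* gene
  survives is an error, not an empty table.
* Subjects present on only one side of the genotype/phenotype pair are
  dropped with a warning and counted; fully disjoint sets are fatal.

## Problem sizes used in the checks

The packaged checks run, among smaller oracle comparisons: a null
calibration with 500 subjects and 2,000 null genes at B = 2,000
permutations (type-I error at α = 0.05 and a Kolmogorov–Smirnov
uniformity check); a power study with one causal 30-rare-SNP gene among
50 genes, slope-type effect, 500 subjects and 20 phenotype replicates
(rank-1 recovery and replicate-averaged AUC); and a comparator
calibration of 20 instances at B = 20,000. `scripts/acceptance.R`
recomputes the same kinds of quantities at 600 null genes (B = 1,000)
and 10 replicates. These sizes were chosen as the package's own
desk-scale study design; the generator's defaults, not the assertions,
define the conditions.

## Known limitations

* The asymptotic ANOVA p on a binary indicator is approximate; use the
  permutation p for inference (the default ranking when `B > 0`).
* The I statistic's scale depends on the chosen normalization; only
  rankings and permutation p-values are comparable across choices.
* The phenotype 2-group summary discards within-cluster trait variation;
  with more time points, trajectory-aware distances could replace the
  Euclidean choice (the clustering entry points accept any matrix).
* Observed-MAF weighting is sample-dependent; an external frequency
  table can be substituted by overwriting `panel$maf` before screening.

## A worked miniature

```{r example}
cfg <- sim_config(n_subjects = 300, n_genes = 12, snps_per_gene = 25,
                  maf_law = function(m) runif(m, 0.011, 0.049),
                  causal_genes = 5L, effect_model = "slope", seed = 42)
panel <- simulate_genotypes(cfg)
traits <- simulate_traits(panel, cfg)
res <- screen(panel, traits, B = 500, seed = 9)
head(res[, c("gene", "n_snps", "i_score", "f_stat", "p_perm", "p_adj",
             "significant")])
```

The causal gene (`gene005`) should head the table with a permutation p at
or near the floor `1/(B+1)`, and survive Bonferroni adjustment across the
12 genes.
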