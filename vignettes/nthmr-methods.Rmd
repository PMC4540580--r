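---
title: "Non-transmitted haplotype scores as genetic instruments: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-transmitted haplotype scores as genetic instruments: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model the package implements, the
choices made where the design was genuinely open, and what the simulation
-based validation does and does not demonstrate. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The inferential problem

For a mother/child pair, let $G_i \in \{0,1,2\}$ be the mother's
effect-allele dosage at SNP $i$ and $b_i$ the published per-allele effect
on the exposure (here adult height, in cm/allele). The genotype score
$M = \sum_i b_i G_i$ is a strong proxy for maternal height but an invalid
instrument for causal claims about the child's outcomes: half of the
maternal alleles are transmitted, so $M$ is correlated with the child's
genotype, which may influence birth outcomes directly.

Writing $A_i$ and $B_i$ for the transmitted and non-transmitted maternal
alleles ($G_i = A_i + B_i$), the maternal score splits as $M = M1 + M2$
with $M1 = \sum_i b_i A_i$ and $M2 = \sum_i b_i B_i$; the fetal score
splits as $C = C1 + C2$ with $C1 \equiv M1$ and $C2$ the paternal
transmitted score. $M2$ indexes the maternal phenotype through alleles the
child never received, so under random mating it is unconfounded by
transmission: association of $M2$ with an outcome indicates a causal path
through the maternal phenotype, while association of $C2$ (paternal
alleles, which do not affect the maternal phenotype) indicates fetal
genetic effects. The package's estimand is the per-cm causal effect of
maternal height on gestational age (days), birth weight (g) and birth
length (cm), by two-stage least squares with four instrument choices
(Section 4).

## 2. Transmission inference

**Genotype rule.** If mother or child is homozygous the transmission is
forced; the full enumeration is in `call_by_genotype()`. Opposite
homozygotes are Mendelian errors: the site is flagged and excluded from
scoring, and pairs whose error rate across weight SNPs exceeds 1% (default)
are flagged as probable non-maternal relationships. The 1% default replaces
the genome-wide relatedness screen that a full study would run on IBD
sharing, which is out of scope here.

**Haplotype rule.** At double heterozygotes the phased local haplotypes
decide. A symmetric window is grown around the focal SNP in 100 kb steps up
to 1 Mb (only the upper bound is inherent to the method; incremental growth
resolves most sites with fewer comparisons). Within a window, only
assignments *consistent with the observed focal alleles* are considered:
the child haplotype carrying the same focal allele as maternal haplotype 1
is compared with it, the other child haplotype with maternal haplotype 2,
by identity fraction over non-missing flank sites (missing sites are
ignored, not imputed). The assignment with the higher identity wins; the
focal allele of the winning maternal haplotype is the transmitted allele.
If the margin is at or below `min_margin` (default 0, i.e. only exact ties)
at the maximum window, the call is unresolved. The consistency restriction
matters: an unrestricted best-over-all-four-pairings rule lets the paternal
haplotype spuriously tie against the wrong maternal haplotype and inflates
the unresolved rate without improving accuracy.

Phase is taken as given. A simulator switch-error option
(`phase_switch_rate`) exists to probe robustness; the homozygote rule is
immune to phase error by construction.

## 3. Scores and the unresolved-site policy

`haplotype_scores()` computes $M$, $M1$, $M2$, $C$, $C1 = M1$, $C2$ per
pair. At unresolved (or Mendelian-error) sites the contribution is split in
expectation — $b_i G_i / 2$ to each of $M1$ and $M2$, and
$b_i (C_i - G_i/2)$ to $C2$ — which preserves $M = M1 + M2$ and
$C = C1 + C2$ exactly and is unbiased for the score means. The alternative
(dropping the site for that pair) breaks comparability of scores across
pairs. The split is mildly attenuating for haplotype-score *contrasts*, and
it leaks a negative artifact into the $M2$–$C2$ correlation (the shared
$G_i/2$ enters the two with opposite signs), which is why correlation-based
checks in the test suite restrict to fully resolved pairs. With default
simulator settings unresolved calls are well below 1%, so the leakage is
negligible in estimation; pairs with more than 5% unresolved sites are
flagged, not dropped. Missing genotypes are mean-imputed from the mothers'
effect-allele frequencies (mothers are the unrelated stratum of a duo
cohort), and scores are reported in raw units (outcome change per unit of
weighted score) rather than standardized, so coefficients are directly
comparable across cohorts; standardization, where wanted, is a display
choice left to the caller.

## 4. Two-stage least squares

`iv_2sls()` is written in projection form: with instrument matrix $Z$
(excluded instruments, adjustments, covariates, intercept) and regressor
matrix $X$ (exposure, adjustments, covariates, intercept),
$\hat\beta = (X' P_Z X)^{-1} X' P_Z y$, standard errors from
$\hat\sigma^2 (X' P_Z X)^{-1}$ with residuals computed against the
*observed* exposure; a sandwich option exists but homoskedastic errors are
the default. The four configurations of `run_iv_methods()` are: (1)
instrument $M$; (2) instrument $M$, adjusting for $C$; (3) instrument $M2$;
(4) instrument $M2$, adjusting for $M1$ and $C2$. Adjustment terms enter
*both* stages — "controlling for" a covariate in only one stage of 2SLS is
inconsistent, so the standard both-stage formulation is used. The
first-stage partial $F$ of the excluded instrument is reported and a value
below 10 (conventional threshold) sets a warning flag rather than failing:
a weak instrument widens the confidence interval, it does not invalidate
the algebra. Covariate sets follow the outcome rule throughout: maternal
age and fetal sex for gestational age; those plus gestational age for birth
weight and birth length. Fetal sex is coded 0/1 (female/male) and
gestational age is in days.

Under the generative model, methods 1–2 are biased whenever the fetal score
affects the outcome (the instrument is correlated with $C$), method 3 is
consistent under random mating, and assortative mating re-introduces a
small bias into method 3 through the $M2$–$C2$ correlation that method 4
removes by adjustment. The acceptance suite measures exactly these
contrasts.

## 5. Association engine

`fit_linear()` reports the unstandardized coefficient and the *incremental*
$r^2$ of the predictor over the covariate-only model (for the score-on-
height regression, which carries no covariates, this is the plain model
$r^2$). `single_snp_scan()` uses Frisch–Waugh residualization — outcome and
genotype matrix residualized on the covariates once — which equals per-SNP
OLS exactly while scaling to thousands of SNPs; monomorphic SNPs are
skipped with a note. The inflation factor is
$\lambda = \mathrm{median}(\chi^2) / 0.4549$.

Three auxiliary analyses mirror standard robustness checks: (i)
gestation-adjusted birth-weight z-scores by residualizing birth weight on a
cubic in gestational age plus sex and standardizing — a percentile-free
construction chosen because no external reference population is bundled;
(ii) logistic regression of preterm status (gestational age < 37 weeks)
with a Firth-penalized fallback under separation; (iii) a rank-based check
— Spearman correlation between covariate-adjusted outcome residuals and the
score — chosen as the nonparametric method because it is invariant to the
two-segment outcome distributions produced by case/control ascertainment;
other rank tests would serve equally and the choice is labelled in the
output.

The haplotype-score associations fit $M1$, $M2$, $C2$ *jointly* in one
model by default: the three scores are mutually correlated under assortative
mating, and joint fitting keeps each coefficient interpretable as adjusted
for the other two. A separate-models option exists. The maternal-vs-paternal
transmitted contrast is a z-test on $\hat\beta_{M1} - \hat\beta_{C2}$ using
the coefficient covariance. p-values are two-sided throughout and no
multiple-testing correction is applied.

## 6. The generative model

`simulate_cohort()` draws, per locus: an effect-allele frequency
(Uniform(0.1, 0.9)), a weight $b_i \sim N(0, 0.1)$ cm, and
`flank_snps` phased flanking SNPs (default 25) within ±0.5 Mb. Parental
haplotypes are drawn per block; a flank copies its haplotype's focal allele
state with probability `ld_strength` = 0.3 and otherwise draws from its own
frequency. This keeps local LD strong while preserving haplotype
diversity: a near-deterministic copying scheme (copy probability ~0.98)
makes unrelated haplotypes sharing a focal allele almost identical across
flanks, so double-heterozygote assignments tie with high probability and
the matcher's accuracy targets become unreachable — diversity, not LD
strength, is what makes haplotype matching informative when transmission
is an exact copy. Blocks are transmitted without recombination and
independently of each other, which keeps the truth ledger exact; child
haplotype slots are randomized per block so inference cannot exploit
storage order.

Maternal height is
$\mu + \sigma\,(\sqrt{r^2}\,\tilde S + \sqrt{1-r^2}\,\tilde E)$ with the
score standardized by its theoretical moments, $r^2 = 0.20$ by default (the
fraction of height variance a modern height score explains in homogeneous
European-ancestry samples), $\mu = 166$ cm, $\sigma = 6$ cm. Assortative
mating rank-matches mothers and fathers through a Gaussian copula at
spousal correlation 0.2 by default — a typical published spousal height
correlation; the value is a modelling choice, not an estimate from any
specific cohort. Outcomes follow linear structural equations: gestational
age gains 0.4 days per cm of maternal height (the causal scale the IV
analysis targets), birth weight and length carry fetal-genetic effects per
SD of the child score (100 g and 0.45 cm defaults, matching the order of
magnitude of genotype-score associations in birth cohorts) plus growth per
gestational day (20 g/d, 0.075 cm/d); residual SDs are 12 d, 400 g, 1.8 cm.
Sex and confounder loadings default to zero (neutral); a shared
standard-normal confounder with configurable loadings implements the
nongenetic-confounding path. Two-segment ascertainment retains pairs with
gestational age in 154–258 d (cases) or 273–286 d (controls) at a
configured mix, emulating case/control sampling in pregnancy cohorts.

What the simulator does *not* emulate: genome-wide LD and recombination
maps, imputation uncertainty, genotyping error, population structure, and —
importantly — *multi-generation* assortative mating. One-generation rank
matching correlates the two parents (hence $M2$ with $C2$) but cannot
correlate a mother's own two haplotypes, so the simulator produces no
$M1$–$M2$ correlation; real cohorts with persistent assortment would. Tests
passing on these cohorts therefore validate the algebra and the estimators
under the stated model, not robustness to every failure mode of real data.

## 7. Numerical choices and problem sizes

Ties in haplotype matching are broken only by a strictly larger identity
fraction (tolerance $10^{-12}$); windows grow in 100 kb steps; identity
fractions ignore missing sites. The exact Hardy-Weinberg test (mothers
only, to avoid duo non-independence) uses the standard outward recursion
from the modal heterozygote count. QC defaults: call rate ≥ 0.98, MAF ≥
0.03, HWE $p \ge 10^{-4}$. Strand-ambiguous (A/T, C/G) weight SNPs are
dropped by default — without frequency information their orientation is
undecidable, and dropping is the conservative choice; a `keep_ambiguous`
switch exists. Weight SNPs absent from a panel are dropped and counted in
the harmonization report.

Validation problem sizes were chosen so that each Monte-Carlo band is
meaningful: transmission accuracy on 400 pairs × 25 SNPs (10,000 duo
loci); IV recovery on 200 replicates of n = 5,000 pairs with 12 loci × 8
flanks (the score's height-variance share, not the locus count, drives
instrument strength, so few loci suffice and keep replicates cheap); the
null inflation factor on 20,000 independent SNPs, because the MC standard
error of a median-based $\lambda$ is $\approx 2.34/\sqrt{S}$ — at a few
hundred SNPs a $1 \pm 0.05$ band would be dominated by noise. The
assortative-mating contrast (method 4 vs method 3) uses a strong fetal
birth-weight effect (400 g/SD, residual SD 300 g) so the bias being removed
is well above replicate noise.

## 8. Known limitations

Biological pleiotropy is outside the model: a weight SNP affecting the
outcome other than through the exposure violates exogeneity for every
method, including method 3; the scan's effect-size correlation diagnostic
indicates, but cannot prove, a common mediated path. The expected-value
split at unresolved sites slightly attenuates haplotype-score contrasts.
The 2SLS standard errors are homoskedastic by default. The generative
model's independence of loci overstates the effective number of
independent SNPs relative to clumped GWAS panels. Meta-analysis is
fixed-effect only, matching the analysis design it reproduces; between-study
heterogeneity is reported via Cochran's Q, not modelled.
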