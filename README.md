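# nthmr: Mendelian randomization with non-transmitted haplotype genetic scores

Observational studies consistently find that shorter mothers deliver
earlier, smaller babies. Whether that association reflects a causal effect
of the maternal phenotype on the intrauterine environment, shared
mother–child genetics, or nongenetic confounding cannot be decided from the
regression alone. `nthmr` implements a Mendelian-randomization design for
mother/child duo data that separates these explanations, for statistical
geneticists and perinatal epidemiologists working with phased genotype and
pregnancy-outcome data.

## The method

A weighted genetic score over trait-associated SNPs,
*S* = Σᵢ *bᵢGᵢ* with *Gᵢ* ∈ {0, 1, 2} the effect-allele dosage and *bᵢ* the
published per-allele effect (cm of adult height per allele), indexes
maternal height. The maternal score *M* is not a valid instrument on its
own: half of the mother's alleles are transmitted, so *M* is correlated
with the child's genotype, which may affect the outcome directly.

`nthmr` therefore infers, for every pair and SNP, which maternal allele was
transmitted — forced by the genotypes whenever mother or child is
homozygous, and decided by local haplotype sharing (windows grown up to
1 Mb around the focal SNP) when both are heterozygous. The scores then
decompose as

* *M* = *M1* + *M2*: maternal transmitted + non-transmitted haplotype scores,
* *C* = *C1* + *C2*: fetal score = maternal transmitted (*C1* ≡ *M1*) +
  paternal transmitted,

and *M2* — alleles the child never received — is a genetic instrument for
maternal height that is free of confounding by transmission. Causal effects
are estimated by two-stage least squares under four instrument
configurations (instrument *M*; *M* controlling for *C*; instrument *M2*;
*M2* controlling for *M1* and *C2* against assortative-mating leakage), and
cohorts are combined by inverse-variance fixed-effect meta-analysis with
Cochran's Q heterogeneity test. Single-SNP association scans with the
genomic inflation factor λ and the correlation of per-SNP effects with the
reference weights diagnose whether score–outcome associations are mediated
by the exposure or by SNP-specific (pleiotropic) pathways.

Because individual-level cohort data of this kind cannot be redistributed,
the package ships a generative model (`simulate_cohort()`) producing
phased mother/father/child cohorts with a truth ledger: score-explained
height variance, assortative mating, fetal-genetic vs maternal-causal
outcome paths, and two-segment case/control ascertainment on gestational
age are all configurable, so every inferential stage can be validated
end to end.

## Worked example

```r
library(nthmr)

cfg <- sim_config(n_pairs = 1000, n_snps = 200, flank_snps = 12, seed = 7)
sim <- simulate_cohort(cfg)
calls <- infer_transmission(sim$cohort)
print(calls)
#> transmission calls: 1000 pairs x 200 SNPs
#>   homozygote_rule  159836 (79.92%)
#>   haplotype_match  40090 (20.05%)
#>   unresolved       74 (0.04%)
#>   mendelian_error  0 (0.00%)
```

About 80% of pair/SNP combinations are settled by a homozygote, the rest by
haplotype matching; unresolved double-heterozygotes (no distinguishing
flank information) are rare and contribute an expected-value split.

```r
scores <- haplotype_scores(sim$cohort, calls)
df <- analysis_frame(sim$cohort, scores)
fit_linear(df, "maternal_height", "M", covariates = character(0))
#>   cohort         outcome predictor beta    se        p    r2    n
#> 1    SIM maternal_height         M 3.23 0.188 3.41e-58 0.228 1000

run_iv_methods(df, "gestational_age")
#>   cohort         outcome method  beta    se        p first_stage_F    n
#> 1    SIM gestational_age      1 0.345 0.129 0.007368           291 1000
#> 2    SIM gestational_age      2 0.498 0.148 0.000778           220 1000
#> 3    SIM gestational_age      3 0.383 0.168 0.022587           153 1000
#> 4    SIM gestational_age      4 0.369 0.167 0.027210           173 1000
```

The genotype score explains ~23% of maternal height variance in this draw
(`r2`), and all four instrument choices recover the simulated causal effect
of 0.4 gestational days per cm of maternal height within their standard
errors — Method 3 (instrument *M2*) is the transmission-proof estimate.
Combining published per-cohort estimates:

```r
fixed_effect_meta(c(0.293, 0.303, 0.400), c(0.142, 0.104, 0.102))
#> fixed-effect meta-analysis of 3 studies
#>   beta = 0.34  se = 0.0648  p = 1.54e-07
#>   heterogeneity: Q = 0.582 (df = 2), p_het = 0.747
```

`run_pipeline()` drives the whole analysis (QC → transmission → scores →
associations → IV → meta, plus scan diagnostics) from a YAML config or
in-memory cohorts and writes tidy TSV tables with a checksummed manifest.

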