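Package: nthmr
Title: Mendelian Randomization with Non-Transmitted Haplotype Genetic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates causal effects of a maternal phenotype (adult height)
    on pregnancy outcomes (gestational age, birth weight, birth length) from
    mother/child duo data using genetic scores built from trait-associated
    SNPs. Infers which maternal allele was transmitted to the child at each
    scored SNP (by genotype logic where a homozygote forces the answer, and
    by local haplotype matching at double heterozygotes), decomposes maternal
    and fetal weighted genetic scores into transmitted and non-transmitted
    haplotype components, and uses the non-transmitted haplotype score as a
    genetic instrument in two-stage least-squares analysis under four
    instrument configurations. Includes allele harmonization and SNP-level
    quality control for phased VCF input, inverse-variance fixed-effect
    meta-analysis with Cochran's Q heterogeneity test, single-SNP association
    scans with genomic-inflation diagnostics, and a synthetic mother/father/
    child cohort generator with a truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
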