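test_that("the generator is deterministic given a seed and varies across seeds", {
  cfg <- sim_config(n_pairs = 50, n_snps = 8, flank_snps = 3, seed = 301)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$panel, b$cohort$panel)
  expect_identical(a$cohort$pheno, b$cohort$pheno)
  expect_identical(a$truth$transmitted, b$truth$transmitted)
  # byte-identical files too
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- simulate_cohort_files(cfg, d1)
  p2 <- simulate_cohort_files(cfg, d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), info = f)

  c2 <- simulate_cohort(sim_config(n_pairs = 50, n_snps = 8, flank_snps = 3,
                                   seed = 302))
  expect_false(identical(a$cohort$panel$H1, c2$cohort$panel$H1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_pairs = 0), "n_pairs")
  expect_error(sim_config(target_r2_height = 0.99, n_snps = 5), "unattainable")
  expect_error(sim_config(target_r2_height = 1.2), "target_r2_height")
  expect_error(sim_config(maf_range = c(0.9, 0.1)), "maf_range")
  expect_error(sim_config(case_range = c(300, 200)), "case_range")
  expect_error(sim_config(confounder_effects = c(height = 10, ga = 0, bw = 0, bl = 0)),
               "confounder")
})

test_that("the truth ledger satisfies its identities and the score explains the target height variance", {
  sim <- small_sim(n_pairs = 10000, n_snps = 60, flank_snps = 0, seed = 303)
  tr <- sim$truth
  expect_true(all(tr$scores$M == tr$scores$M1 + tr$scores$M2))
  expect_true(all(tr$scores$C1 == tr$scores$M1))
  expect_true(all(tr$maternal_child_slot %in% 1:2))
  # regressing height on the true genotype score recovers target r2 +/- 0.02
  r2 <- summary(stats::lm(sim$cohort$pheno$maternal_height ~ tr$scores$M))$r.squared
  expect_lt(abs(r2 - 0.20), 0.02)
  # genotypes in the panel are consistent with the truth alleles
  co <- sim$cohort
  mi <- match(co$pairs$mother, co$panel$samples)
  gm <- co$panel$H1[mi, co$focal_idx] + co$panel$H2[mi, co$focal_idx]
  expect_true(all(gm == tr$transmitted + tr$nontransmitted))
  ci <- match(co$pairs$child, co$panel$samples)
  gc <- co$panel$H1[ci, co$focal_idx] + co$panel$H2[ci, co$focal_idx]
  expect_true(all(gc == tr$transmitted + tr$paternal))
})

test_that("assortative mating controls the spousal and haplotype-score correlations", {
  sim0 <- small_sim(n_pairs = 4000, n_snps = 40, flank_snps = 0, seed = 304,
                    assortative_r = 0)
  tr0 <- sim0$truth
  expect_lt(abs(cor(tr0$scores$M1, tr0$scores$M2)), 2 / sqrt(4000))
  expect_lt(abs(cor(sim0$cohort$pheno$maternal_height,
                    tr0$components$paternal_height)), 0.05)

  sim1 <- small_sim(n_pairs = 4000, n_snps = 40, flank_snps = 0, seed = 305,
                    assortative_r = 0.25)
  tr1 <- sim1$truth
  expect_lt(abs(cor(sim1$cohort$pheno$maternal_height,
                    tr1$components$paternal_height) - 0.25), 0.05)
  expect_gt(cor(tr1$scores$M2, tr1$scores$C2), 0)
})

test_that("two-segment ascertainment keeps gestational age inside the case/control windows", {
  sim <- small_sim(n_pairs = 600, n_snps = 10, flank_snps = 0, seed = 306,
                   ascertainment = "two_segment", case_fraction = 0.4)
  ga <- sim$cohort$pheno$gestational_age
  in_case <- ga >= 154 & ga <= 258
  in_ctrl <- ga >= 273 & ga <= 286
  expect_true(all(in_case | in_ctrl))
  expect_equal(sum(in_case), 240)
  expect_equal(nrow(sim$cohort$pheno), 600)
  expect_equal(sim$cohort$pheno$preterm, ga < 259)
})

test_that("phase switch errors degrade but do not break haplotype matching", {
  sim <- small_sim(n_pairs = 300, n_snps = 12, flank_snps = 12, seed = 307,
                   phase_switch_rate = 0.05)
  calls <- infer_transmission(sim$cohort)
  acc <- truth_vs_called(sim$truth, calls)
  # the homozygote rule is immune to phase error
  expect_equal(acc$by_resolution$homozygote_rule$concordance, 1)
  # haplotype matching stays informative despite 5% switch errors
  expect_gt(acc$by_resolution$haplotype_match$concordance, 0.9)
})
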