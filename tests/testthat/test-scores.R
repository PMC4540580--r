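test_that("genotype score is the weighted dosage sum", {
  w <- weight_df(2, beta = c(0.5, -0.2))
  expect_equal(genotype_score(w, matrix(c(0, 0), 1)), 0)
  expect_equal(genotype_score(w, matrix(c(2, 1), 1)), 0.8)

  # brute-force dot-product oracle on random draws
  set.seed(8)
  for (rep in 1:5) {
    k <- sample(5:50, 1)
    wt <- weight_df(k, beta = rnorm(k), pos = seq_len(k) * 1000L)
    G <- matrix(sample(0:2, 40 * k, replace = TRUE), nrow = 40)
    oracle <- apply(G, 1, function(g) sum(g * wt$beta))
    expect_equal(genotype_score(wt, G), oracle, tolerance = 1e-12)
  }

  # missing genotypes imputed at 2 * allele frequency
  G <- matrix(c(NA, 1), 1)
  expect_equal(genotype_score(w, G, impute_af = c(0.25, 0.5)), 0.5 * 0.5 - 0.2)
  expect_error(genotype_score(w, G), "no imputation frequencies")
  expect_error(genotype_score(w, matrix(NA_real_, 1, 2), impute_af = c(0.5, 0.5)),
               "all genotypes missing")
})

test_that("haplotype scores decompose the genotype scores exactly", {
  sim <- small_sim(n_pairs = 250, n_snps = 15, flank_snps = 10, seed = 13)
  calls <- infer_transmission(sim$cohort)
  sc <- haplotype_scores(sim$cohort, calls)

  expect_equal(sc$C1, sc$M1)
  expect_lt(max(abs(sc$M - (sc$M1 + sc$M2))), 1e-9)
  expect_lt(max(abs(sc$C - (sc$C1 + sc$C2))), 1e-9)

  # at fully resolved pairs the scores equal the truth ledger exactly
  full <- sc$n_unresolved == 0 & sc$n_missing == 0
  expect_gt(sum(full), 200)
  tr <- sim$truth$scores
  for (col in c("M", "M1", "M2", "C", "C2"))
    expect_lt(max(abs(sc[[col]][full] - tr[[col]][full])), 1e-9)
})

test_that("unresolved sites are split in expectation and flagged pairs reported", {
  # single-SNP cohort built by hand: mother 0/1, child 0/1, no flanks
  sim <- small_sim(n_pairs = 50, n_snps = 1, flank_snps = 0, seed = 17,
                   maf_range = c(0.5, 0.5))
  calls <- infer_transmission(sim$cohort)
  sc <- haplotype_scores(sim$cohort, calls)
  b <- sim$cohort$weights$beta
  mi <- match(sim$cohort$pairs$mother, sim$cohort$panel$samples)
  gm <- sim$cohort$panel$H1[mi, sim$cohort$focal_idx] +
    sim$cohort$panel$H2[mi, sim$cohort$focal_idx]
  unres <- calls$resolution[, 1] == "unresolved"
  expect_true(any(unres))  # double-hets cannot resolve without flanks
  expect_equal(sc$M1[unres], unname(b * gm[unres] / 2))
  expect_equal(sc$M2[unres], unname(b * gm[unres] / 2))
  expect_true(all(sc$flagged[unres]))  # 1 unresolved of 1 SNP > 5%
  expect_lt(max(abs(sc$M - (sc$M1 + sc$M2))), 1e-12)
})

test_that("scores are invariant to SNP permutation and linear in the weights", {
  sim <- small_sim(n_pairs = 60, n_snps = 10, flank_snps = 4, seed = 19)
  co <- sim$cohort
  calls <- infer_transmission(co)
  sc <- haplotype_scores(co, calls)

  perm <- sample(length(co$focal_idx))
  co2 <- co
  co2$weights <- co$weights[perm, ]
  co2$focal_idx <- co$focal_idx[perm]
  calls2 <- calls
  for (f in c("transmitted", "nontransmitted", "paternal", "resolution",
              "window_used"))
    calls2[[f]] <- calls2[[f]][, perm]
  calls2$snp_id <- calls2$snp_id[perm]
  sc2 <- haplotype_scores(co2, calls2)
  for (col in c("M", "M1", "M2", "C", "C2"))
    expect_equal(sc2[[col]], sc[[col]])

  co3 <- co
  co3$weights$beta <- 2 * co3$weights$beta
  sc3 <- haplotype_scores(co3, calls)
  for (col in c("M", "M1", "M2", "C", "C2"))
    expect_equal(sc3[[col]], 2 * sc[[col]])
})

test_that("score summary reports correlations, C1 identity and constant columns", {
  sim <- small_sim(n_pairs = 600, n_snps = 25, flank_snps = 8, seed = 23,
                   assortative_r = 0)
  calls <- infer_transmission(sim$cohort)
  sc <- haplotype_scores(sim$cohort, calls)
  sm <- score_summary(sc)
  expect_equal(stats::cor(sc$C1, sc$M1), 1)
  # random mating: maternal transmitted and nontransmitted scores independent
  expect_lt(abs(sm$cor["M1", "M2"]), 2 / sqrt(nrow(sc)) + 0.02)
  # parent-offspring sharing: M and C strongly correlated
  expect_gt(sm$cor["M", "C"], 0.3)

  const <- sc; const$M2 <- 0; const$M <- const$M1  # keep M = M1 + M2 plausible
  sm2 <- score_summary(const)
  expect_true(is.na(sm2$cor["M2", "C2"]))
  expect_match(attr(sm2$cor, "note"), "constant")
  expect_error(score_summary(sc[1:2, ]), "at least 3 pairs")
})

test_that("assortative mating induces the positive M2-C2 correlation", {
  # expected corr(M2, C2) ~ assortative_r * r2 / 2 ~ 0.025: a sign check
  # needs n large enough that the MC error (1/sqrt(n)) is well below it
  sim <- small_sim(n_pairs = 20000, n_snps = 40, flank_snps = 8, seed = 29,
                   assortative_r = 0.25)
  sm_true <- score_summary(structure(sim$truth$scores,
                                     class = c("score_set", "data.frame")))
  expect_gt(sm_true$cor["M2", "C2"], 0)
  expect_lt(sm_true$p["M2", "C2"], 0.01)
  # inferred scores: the sign survives on the fully resolved pairs (the
  # G/2 expectation-split at unresolved sites would otherwise leak an
  # artifactual negative M2-C2 component)
  sc <- haplotype_scores(sim$cohort, infer_transmission(sim$cohort))
  full <- sc$n_unresolved == 0
  expect_gt(mean(full), 0.8)
  sm_hat <- score_summary(sc[full, ])
  expect_gt(sm_hat$cor["M2", "C2"], 0)
})
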