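test_that("fit_linear matches identity, Frisch-Waugh and covariate-rule expectations", {
  set.seed(401)
  d <- data.frame(y = rnorm(80), x = rnorm(80), a = rnorm(80), cohort = "T")
  d$y2 <- d$y
  ident <- suppressWarnings(fit_linear(d, "y", "y2", covariates = character(0)))
  expect_equal(ident$beta, 1, tolerance = 1e-12)
  expect_equal(ident$r2, 1, tolerance = 1e-12)

  # Frisch-Waugh oracle: partial out the covariate from both sides
  fit <- fit_linear(d, "y", "x", covariates = "a")
  ry <- resid(lm(y ~ a, data = d)); rx <- resid(lm(x ~ a, data = d))
  expect_equal(fit$beta, unname(coef(lm(ry ~ rx))[2]), tolerance = 1e-10)

  # outcome rule picks the stated covariate sets
  expect_equal(default_covariates("birth_weight"),
               c("maternal_age", "fetal_sex", "gestational_age"))
  expect_equal(default_covariates("gestational_age"),
               c("maternal_age", "fetal_sex"))
  expect_equal(default_covariates("maternal_height"), character(0))

  d$b <- d$a  # exact collinearity
  expect_error(fit_linear(d, "y", "x", covariates = c("a", "b")),
               "rank-deficient.*b")

  # adding an orthogonalized irrelevant covariate leaves beta unchanged
  d$orth <- resid(lm(rnorm(80) ~ x + a, data = d))
  fit2 <- fit_linear(d, "y", "x", covariates = c("a", "orth"))
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-10)
})

test_that("an induced observational height-outcome association is recovered at the stated scale", {
  sim <- small_sim(n_pairs = 8000, n_snps = 30, flank_snps = 0, seed = 402,
                   causal_ga_per_cm = 0.34)
  df <- analysis_frame(sim$cohort)
  fit <- fit_linear(df, "gestational_age", "maternal_height")
  expect_lt(abs(fit$beta - 0.34), 2 * fit$se)
  expect_lt(fit$p, 0.01)
})

test_that("single-SNP scan is calibrated under the null and detects score-mediated signal", {
  sim <- small_sim(n_pairs = 1500, n_snps = 120, flank_snps = 0, seed = 403,
                   causal_ga_per_cm = 0, causal_bl_per_cm = 0,
                   fetal_effect_bw = 0, assortative_r = 0)
  scan0 <- single_snp_scan(sim$cohort, "gestational_age")
  expect_true(abs(scan0$lambda - 1) < 0.35)  # 120 SNPs: wide MC band
  expect_gt(min(scan0$results$p, na.rm = TRUE), 1e-6)

  # maternal height is score-built: the scan against height must correlate
  # with the generating weights
  scan1 <- single_snp_scan(sim$cohort, "maternal_height")
  expect_gt(scan1$rho_vs_weights, 0.3)
  expect_lt(scan1$rho_p, 1e-4)

  # causal height -> GA propagates a weight-correlated signal at scale
  sim2 <- small_sim(n_pairs = 6000, n_snps = 80, flank_snps = 0, seed = 404,
                    causal_ga_per_cm = 2)
  scan2 <- single_snp_scan(sim2$cohort, "gestational_age")
  expect_gt(scan2$rho_vs_weights, 0)
  expect_lt(scan2$rho_p, 0.05)
  expect_gt(scan2$lambda, 1)

  # monomorphic SNPs are skipped with a note
  co <- sim$cohort
  j <- co$focal_idx[1]
  co$panel$H1[, j] <- 0L; co$panel$H2[, j] <- 0L
  scan3 <- single_snp_scan(co, "gestational_age")
  expect_equal(scan3$n_skipped_monomorphic, 1)
  expect_true(is.na(scan3$results$beta[1]))
})

test_that("joint haplotype-score models separate maternal-causal from fetal-genetic patterns", {
  # fetal-only birth-weight effect: M1 and C2 significant, M2 null
  simf <- small_sim(n_pairs = 5000, n_snps = 25, flank_snps = 6, seed = 405,
                    causal_ga_per_cm = 0, causal_bl_per_cm = 0,
                    fetal_effect_bw = 120, assortative_r = 0)
  dff <- analysis_frame(simf$cohort,
                        haplotype_scores(simf$cohort, infer_transmission(simf$cohort)))
  hb <- haplotype_score_associations(dff, "birth_weight")
  expect_equal(hb$predictor, c("M1", "M2", "C2"))
  expect_lt(hb$p[hb$predictor == "M1"], 1e-4)
  expect_lt(hb$p[hb$predictor == "C2"], 1e-4)
  expect_gt(hb$p[hb$predictor == "M2"], 0.01)

  # maternal-causal-only GA effect: M2 significant, C2 null
  simm <- small_sim(n_pairs = 5000, n_snps = 25, flank_snps = 6, seed = 406,
                    causal_ga_per_cm = 1.5, fetal_effect_bw = 0,
                    causal_bl_per_cm = 0, assortative_r = 0)
  dfm <- analysis_frame(simm$cohort,
                        haplotype_scores(simm$cohort, infer_transmission(simm$cohort)))
  hg <- haplotype_score_associations(dfm, "gestational_age")
  expect_lt(hg$p[hg$predictor == "M2"], 0.01)
  expect_gt(hg$p[hg$predictor == "C2"], 0.05)

  # separate-model option returns the same predictors
  hs <- haplotype_score_associations(dfm, "gestational_age", joint = FALSE)
  expect_equal(hs$predictor, c("M1", "M2", "C2"))
})

test_that("the parent-of-origin contrast is near p = 1 at zero difference and powered when effects differ", {
  set.seed(407)
  n <- 3000
  d <- data.frame(M1 = rnorm(n), M2 = rnorm(n), C2 = rnorm(n),
                  maternal_age = runif(n, 20, 35), fetal_sex = rbinom(n, 1, 0.5),
                  gestational_age = rnorm(n, 280, 12))
  d$birth_weight <- 3500 + 50 * d$M1 + 50 * d$C2 + rnorm(n, 0, 300)
  td <- transmitted_effect_difference(d, "birth_weight")
  expect_gt(td$p, 0.05)  # equal effects: no difference detected

  d$birth_weight <- 3500 + 100 * d$M1 + 50 * d$C2 + rnorm(n, 0, 300)
  td2 <- transmitted_effect_difference(d, "birth_weight")
  expect_lt(td2$p, 0.01)
  expect_gt(td2$diff, 0)

  # exactly equal coefficients by column-exchange symmetry
  a <- rnorm(40); b <- rnorm(40); m <- rnorm(40)
  y <- a + b + rnorm(40)
  d0 <- data.frame(M1 = c(a, b), M2 = c(m, m), C2 = c(b, a), y = c(y, y))
  td0 <- transmitted_effect_difference(d0, "y", covariates = character(0))
  expect_lt(abs(td0$diff), 1e-10)
  expect_gt(td0$p, 0.999)
})

test_that("gestation-adjusted z-scores are standardized and free of GA signal", {
  sim <- small_sim(n_pairs = 6000, n_snps = 15, flank_snps = 0, seed = 408)
  df <- analysis_frame(sim$cohort)
  z <- ga_adjusted_zscore(df)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_lt(abs(cor(z, df$gestational_age)), 0.02)
  expect_error(ga_adjusted_zscore(df[1:5, ]), "too few")
})

test_that("preterm logistic regression recovers a 3%-per-cm protective height effect", {
  set.seed(409)
  n <- 20000
  h <- rnorm(n, 166, 6)
  age <- runif(n, 20, 35); sex <- rbinom(n, 1, 0.5)
  # log-odds slope log(0.97) per cm: taller mothers at lower preterm risk
  eta <- qlogis(0.2) + log(0.97) * (h - 166)
  d <- data.frame(preterm = rbinom(n, 1, plogis(eta)) == 1,
                  maternal_height = h, maternal_age = age, fetal_sex = sex)
  fit <- preterm_logistic(d, "maternal_height")
  expect_false(fit$separation)
  expect_lt(fit$ci[1], 0.97); expect_gt(fit$ci[2], 0.97)
  expect_lt(fit$p, 1e-4)

  # null predictor: CI covers 1
  d$noise <- rnorm(n)
  fit0 <- preterm_logistic(d, "noise")
  expect_lt(fit0$ci[1], 1); expect_gt(fit0$ci[2], 1)

  expect_error(preterm_logistic(transform(d, k = 1), "k"), "constant")
  expect_error(preterm_logistic(transform(d, preterm = TRUE), "maternal_height"),
               "both preterm and term")

  # complete separation falls back to the Firth fit
  ds <- data.frame(preterm = rep(c(TRUE, FALSE), each = 20),
                   maternal_height = c(rnorm(20, 150, 1), rnorm(20, 180, 1)),
                   maternal_age = runif(40, 20, 35),
                   fetal_sex = rbinom(40, 1, 0.5))
  fs <- preterm_logistic(ds, "maternal_height")
  expect_true(fs$separation)
  expect_true(is.finite(fs$beta) && is.finite(fs$se))
  expect_lt(fs$or, 1)
})

test_that("the rank-based association detects monotone signal and agrees with OLS under normality", {
  set.seed(410)
  n <- 2000
  d <- data.frame(M2 = rnorm(n), maternal_age = runif(n, 20, 35),
                  fetal_sex = rbinom(n, 1, 0.5))
  # monotone but heavy-tailed: rank test keeps power
  d$gestational_age <- 280 + exp(0.8 * d$M2) + rt(n, df = 2) * 5
  np <- nonparametric_association(d, "gestational_age", "M2")
  expect_lt(np$p, 1e-6); expect_gt(np$rho, 0)

  # exact normal linear case: parametric and rank p-values within 2x on the log scale
  d$ga2 <- 280 + 0.8 * d$M2 + rnorm(n, 0, 12)
  np2 <- nonparametric_association(d, "ga2", "M2",
                                   covariates = c("maternal_age", "fetal_sex"))
  par2 <- fit_linear(d, "ga2", "M2", covariates = c("maternal_age", "fetal_sex"))
  expect_lt(abs(log10(np2$p) - log10(par2$p)) / abs(log10(par2$p)), 1)
})
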