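#' Default covariate set for a pregnancy outcome
#'
#' Birth length and birth weight are adjusted for maternal age, fetal sex
#' and gestational age; gestational age for maternal age and fetal sex only;
#' other outcomes (e.g. maternal height regressed on a score) carry no
#' default covariates.
#'
#' @param outcome Outcome column name.
#' @return Character vector of covariate column names (possibly empty).
#' @export
default_covariates <- function(outcome) {
  switch(outcome,
         birth_length = ,
         birth_weight = c("maternal_age", "fetal_sex", "gestational_age"),
         gestational_age = c("maternal_age", "fetal_sex"),
         character(0))
}

# Build the analysis frame: phenotypes joined with scores (if given)
#' Merge phenotypes and scores into one analysis data.frame
#'
#' @param cohort A `cohort_data`.
#' @param scores Optional `score_set` from [haplotype_scores()].
#' @return A `data.frame` keyed by `pair_id`.
#' @export
analysis_frame <- function(cohort, scores = NULL) {
  df <- cohort$pheno
  if (!is.null(scores))
    df <- merge(df, as.data.frame(scores), by = "pair_id", sort = FALSE)
  df
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop_("rank-deficient design: collinear column(s) %s",
          paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Linear association between a predictor and an outcome
#'
#' Ordinary least squares of `outcome` on `predictor` plus covariates
#' (auto-selected by the outcome rule of [default_covariates()] unless
#' overridden), on complete cases. Reports the unstandardized coefficient of
#' the predictor, its standard error and two-sided p-value, and the
#' incremental r-squared of the predictor over the covariate-only model.
#'
#' @param data Analysis `data.frame` (see [analysis_frame()]).
#' @param outcome,predictor Column names.
#' @param covariates Character vector of covariate columns, or NULL for the
#'   outcome rule.
#' @param cohort Optional cohort label carried into the result.
#' @return One-row `data.frame`: `cohort`, `outcome`, `predictor`, `beta`,
#'   `se`, `p`, `r2`, `n`.
#' @export
fit_linear <- function(data, outcome, predictor, covariates = NULL,
                       cohort = data$cohort[1] %||% NA_character_) {
  if (is.null(covariates)) covariates <- default_covariates(outcome)
  covariates <- setdiff(covariates, c(outcome, predictor))
  vars <- unique(c(outcome, predictor, covariates))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(df) < length(vars) + 1)
    stop_("too few complete cases (%d) for model with %d terms", nrow(df), length(vars))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[c(predictor, covariates)]))
  check_full_rank(X)
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(predictor, covariates), collapse = " + ")))
  fit <- stats::lm(f, data = df)
  sm <- summary(fit)
  co <- sm$coefficients[predictor, ]
  r2_full <- sm$r.squared
  r2_cov <- if (length(covariates) > 0) {
    f0 <- stats::as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
    summary(stats::lm(f0, data = df))$r.squared
  } else 0
  data.frame(cohort = cohort, outcome = outcome, predictor = predictor,
             beta = unname(co["Estimate"]), se = unname(co["Std. Error"]),
             p = unname(co["Pr(>|t|)"]), r2 = r2_full - r2_cov, n = nrow(df),
             stringsAsFactors = FALSE)
}

#' Single-SNP association scan with inflation diagnostics
#'
#' Per-SNP OLS of the outcome on each weight-SNP genotype (effect-allele
#' dosage) with the outcome's covariates, in the chosen subjects. Computed
#' by Frisch-Waugh residualization: outcome and genotypes are residualized
#' on the covariates, and the per-SNP slope, its standard error (with the
#' correct residual degrees of freedom) and two-sided p-value follow from
#' the partialled regression. Reports the genomic inflation factor
#' `lambda = median(chi-square) / 0.4549` and the Pearson correlation of the
#' estimated per-SNP effects with the weight-table effects.
#'
#' @param cohort A `cohort_data`.
#' @param outcome Outcome column of the phenotype table (or
#'   `"maternal_height"`).
#' @param subjects `"mothers"` or `"children"`: whose genotypes are scanned.
#' @param covariates Covariates, or NULL for the outcome rule.
#' @return A `snp_scan` list: per-SNP results (`beta`, `se`, `p`,
#'   monomorphic SNPs skipped with a note), `lambda`, `rho_vs_weights` with
#'   its p-value, and Q-Q plot data (expected vs observed -log10 p).
#' @export
single_snp_scan <- function(cohort, outcome, subjects = c("mothers", "children"),
                            covariates = NULL) {
  subjects <- match.arg(subjects)
  if (is.null(covariates)) covariates <- default_covariates(outcome)
  if (length(cohort$focal_idx) < 50)
    warn_("only %d SNPs in scan; the inflation factor will be unstable",
          length(cohort$focal_idx))
  rows <- match(if (subjects == "mothers") cohort$pairs$mother else cohort$pairs$child,
                cohort$panel$samples)
  G <- cohort$panel$H1[rows, cohort$focal_idx, drop = FALSE] +
    cohort$panel$H2[rows, cohort$focal_idx, drop = FALSE]
  df <- cohort$pheno
  vars <- unique(c(outcome, covariates))
  cc <- stats::complete.cases(df[vars])
  df <- df[cc, , drop = FALSE]; G <- G[cc, , drop = FALSE]
  af <- colMeans(G, na.rm = TRUE) / 2
  if (anyNA(G)) {
    fill <- matrix(rep(2 * af, each = nrow(G)), nrow = nrow(G))
    G[is.na(G)] <- fill[is.na(G)]
  }
  mono <- apply(G, 2, stats::sd) == 0
  y <- df[[outcome]]
  Xc <- cbind(1, as.matrix(df[covariates]))
  # Frisch-Waugh: residualize outcome and genotypes on the covariates
  qc_ <- qr(Xc)
  ry <- stats::residuals(stats::lm.fit(Xc, y))
  RG <- G - Xc %*% qr.coef(qc_, G)
  gss <- colSums(RG^2)
  beta <- colSums(RG * ry) / gss
  dof <- nrow(df) - ncol(Xc) - 1
  rss <- sum(ry^2) - beta^2 * gss
  se <- sqrt(pmax(rss, 0) / dof / gss)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), dof)
  beta[mono] <- se[mono] <- p[mono] <- NA_real_

  chisq <- stats::qchisq(p[!mono], df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  ok <- !mono & !is.na(beta)
  ct <- stats::cor.test(beta[ok], cohort$weights$beta[ok])
  pv <- sort(p[!mono])
  qq <- data.frame(expected = -log10(stats::ppoints(length(pv))),
                   observed = -log10(pv))
  out <- list(results = data.frame(snp_id = cohort$weights$snp_id,
                                   af = af, beta = beta, se = se, p = p,
                                   monomorphic = mono, stringsAsFactors = FALSE),
              outcome = outcome, subjects = subjects, n = nrow(df),
              n_skipped_monomorphic = sum(mono),
              lambda = lambda, rho_vs_weights = unname(ct$estimate),
              rho_p = ct$p.value, qq = qq)
  class(out) <- "snp_scan"
  out
}

#' @export
print.snp_scan <- function(x, ...) {
  cat(sprintf("single-SNP scan: %s in %s (n = %d, %d SNPs, %d monomorphic skipped)\n",
              x$outcome, x$subjects, x$n, nrow(x$results), x$n_skipped_monomorphic))
  cat(sprintf("  lambda = %.3f; rho vs weights = %.3f (p = %.3g)\n",
              x$lambda, x$rho_vs_weights, x$rho_p))
  invisible(x)
}

#' Joint association of the haplotype scores with an outcome
#'
#' Fits the three haplotype scores (M1, M2, C2) jointly in one OLS model
#' with the outcome's covariates, so that each coefficient is adjusted for
#' the other two components (which are mutually correlated under assortative
#' mating). A `joint = FALSE` option fits the three separate single-score
#' models instead.
#'
#' @param data Analysis frame containing scores and phenotypes.
#' @param outcome Outcome column.
#' @param covariates Covariates, or NULL for the outcome rule.
#' @param joint Fit the three scores in one model (default) or separately.
#' @return Three-row `data.frame` (predictors M1, M2, C2) with `beta`, `se`,
#'   `p`, `n`.
#' @export
haplotype_score_associations <- function(data, outcome, covariates = NULL,
                                         joint = TRUE) {
  if (is.null(covariates)) covariates <- default_covariates(outcome)
  terms <- c("M1", "M2", "C2")
  if (!joint) {
    out <- do.call(rbind, lapply(terms, function(tm)
      fit_linear(data, outcome, tm, covariates)))
    out$r2 <- NULL
    return(out)
  }
  vars <- unique(c(outcome, terms, covariates))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(terms, covariates), collapse = " + ")))
  fit <- stats::lm(f, data = df)
  co <- summary(fit)$coefficients[terms, , drop = FALSE]
  out <- data.frame(cohort = data$cohort[1] %||% NA_character_,
                    outcome = outcome, predictor = terms,
                    beta = co[, "Estimate"], se = co[, "Std. Error"],
                    p = co[, "Pr(>|t|)"], n = nrow(df),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Test the difference between maternally and paternally transmitted effects
#'
#' From the joint haplotype-score model, tests `beta_M1 - beta_C2 = 0` by a
#' z-test using the coefficient covariance (a parent-of-origin contrast:
#' both scores index transmitted alleles in the child, differing only in the
#' transmitting parent).
#'
#' @param data Analysis frame with scores.
#' @param outcome Outcome column.
#' @param covariates Covariates, or NULL for the outcome rule.
#' @return List with `diff`, `se`, `z`, `p` (two-sided).
#' @export
transmitted_effect_difference <- function(data, outcome, covariates = NULL) {
  res <- haplotype_score_associations(data, outcome, covariates, joint = TRUE)
  fit <- attr(res, "fit")
  V <- stats::vcov(fit)
  d <- stats::coef(fit)[["M1"]] - stats::coef(fit)[["C2"]]
  se <- sqrt(V["M1", "M1"] + V["C2", "C2"] - 2 * V["M1", "C2"])
  z <- if (se > 0) d / se else 0
  list(diff = d, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Gestation-adjusted birth-weight z-scores
#'
#' Residual-based standardization: regresses birth weight on a cubic
#' polynomial in gestational age plus fetal sex within the cohort, then
#' standardizes the residuals to mean 0 and SD 1. The result is a
#' birth-weight measure free of gestational-age (and sex) signal, usable as
#' an outcome in the score analyses.
#'
#' @param data Analysis frame with `birth_weight`, `gestational_age`,
#'   `fetal_sex`.
#' @return Numeric vector of z-scores aligned with the rows of `data`
#'   (NA where inputs are missing).
#' @export
ga_adjusted_zscore <- function(data) {
  cc <- stats::complete.cases(data[c("birth_weight", "gestational_age", "fetal_sex")])
  if (sum(cc) < 10) stop_("too few complete cases for the cubic fit")
  fit <- stats::lm(birth_weight ~ poly(gestational_age, 3) + fetal_sex,
                   data = data[cc, ])
  z <- rep(NA_real_, nrow(data))
  r <- stats::residuals(fit)
  z[cc] <- (r - mean(r)) / stats::sd(r)
  z
}

#' Logistic regression of preterm birth on a predictor
#'
#' Odds ratio per unit predictor with Wald confidence interval and p-value.
#' If the fit separates (fitted probabilities collapse to 0/1), a Firth
#' penalized fit is used instead and the result flagged.
#'
#' @param data Analysis frame with a logical `preterm` column.
#' @param predictor Predictor column (e.g. `maternal_height` or `M2`).
#' @param covariates Covariates (default maternal age and fetal sex).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `beta`, `se`, `p`, `ci`, `n`, `separation`.
#' @export
preterm_logistic <- function(data, predictor,
                             covariates = c("maternal_age", "fetal_sex"),
                             conf_level = 0.95) {
  vars <- unique(c("preterm", predictor, covariates))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  y <- as.integer(df$preterm)
  if (length(unique(y)) < 2) stop_("both preterm and term births are required")
  if (stats::sd(df[[predictor]]) == 0) stop_("predictor is constant")
  X <- cbind(`(Intercept)` = 1, as.matrix(df[c(predictor, covariates)]))
  check_full_rank(X)
  f <- stats::as.formula(paste("preterm ~", paste(c(predictor, covariates),
                                                  collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = df))
  pr <- stats::fitted(fit)
  separated <- any(pr > 1 - 1e-8) || any(pr < 1e-8) ||
    any(abs(stats::coef(fit)) > 15)
  if (separated) {
    fl <- firth_logistic(X, y)
    beta <- fl$coef[[predictor]]; se <- fl$se[[predictor]]
  } else {
    sm <- summary(fit)$coefficients
    beta <- sm[predictor, "Estimate"]; se <- sm[predictor, "Std. Error"]
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(beta), beta = beta, se = se, p = z_p(beta, se),
       ci = exp(c(beta - zq * se, beta + zq * se)), n = nrow(df),
       separation = separated)
}

# Firth-penalized logistic regression (Jeffreys-prior score adjustment),
# used as the separation fallback. Plain Newton iteration on the modified
# score U*(b) = X'(y - p + h (1/2 - p)).
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * w
    I <- crossprod(X, XW)
    H <- XW %*% solve(I, t(X))
    h <- diag(H)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(I, U)
    b <- b + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(I)))
  names(b) <- names(se) <- colnames(X)
  list(coef = as.list(b), se = as.list(se), iter = it)
}

#' Rank-based (nonparametric) association between a score and an outcome
#'
#' Residualizes the outcome on the covariates, then tests the Spearman rank
#' correlation between the residuals and the score. Robust to the broken
#' (two-segment) outcome distributions produced by case/control
#' ascertainment on gestational age.
#'
#' @param data Analysis frame.
#' @param outcome,score Column names.
#' @param covariates Covariates, or NULL for the outcome rule.
#' @return List with `rho`, `p` (two-sided), `n`.
#' @export
nonparametric_association <- function(data, outcome, score, covariates = NULL) {
  if (is.null(covariates)) covariates <- default_covariates(outcome)
  vars <- unique(c(outcome, score, covariates))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  r <- if (length(covariates) > 0) {
    f <- stats::as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
    stats::residuals(stats::lm(f, data = df))
  } else df[[outcome]]
  ct <- suppressWarnings(stats::cor.test(r, df[[score]], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(df))
}
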