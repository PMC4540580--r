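#' Two-stage least-squares instrumental-variable estimation
#'
#' Standard 2SLS of `outcome` on `exposure`, instrumented by `instruments`,
#' with `adjust` terms and `covariates` entering both stages. Stage 1
#' regresses the exposure (and nothing else: adjustments and covariates are
#' exogenous regressors, included as their own instruments) on the full
#' instrument set; stage 2 regresses the outcome on the fitted exposure and
#' the exogenous regressors. Standard errors use the 2SLS variance formula
#' with residuals computed from the observed (not fitted) exposure;
#' `robust = TRUE` switches to heteroskedasticity-robust (sandwich)
#' standard errors. The first-stage partial F statistic of the excluded
#' instruments is reported, with a warning flag below `weak_f`.
#'
#' @param data Analysis `data.frame`.
#' @param outcome,exposure Column names.
#' @param instruments Character vector of excluded-instrument columns.
#' @param adjust Additional exogenous adjustment columns (enter both stages).
#' @param covariates Covariate columns (enter both stages); NULL applies the
#'   outcome rule of [default_covariates()].
#' @param robust Use sandwich standard errors? Default FALSE (homoskedastic).
#' @param weak_f Weak-instrument threshold on the first-stage F (default 10);
#'   crossing it sets a flag, it does not fail the fit.
#' @return An `iv2sls` object with `print`, `summary`, `coef`, `vcov` and
#'   `confint` methods; `$beta`, `$se`, `$p` refer to the exposure term.
#' @examples
#' d <- data.frame(z = rnorm(100))
#' d$x <- d$z + rnorm(100)
#' d$y <- 0.5 * d$x + rnorm(100)
#' iv_2sls(d, "y", "x", "z")
#' @export
iv_2sls <- function(data, outcome, exposure, instruments,
                    adjust = character(0), covariates = character(0),
                    robust = FALSE, weak_f = 10) {
  if (is.null(covariates)) covariates <- default_covariates(outcome)
  covariates <- setdiff(covariates, c(outcome, exposure, instruments, adjust))
  vars <- unique(c(outcome, exposure, instruments, adjust, covariates))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(df)
  if (n < length(vars) + 2) stop_("too few complete cases for 2SLS")
  if (any(vapply(df[instruments], stats::sd, numeric(1)) == 0))
    stop_("zero-variance instrument")
  y <- df[[outcome]]
  exog <- c(adjust, covariates)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[c(exposure, exog)]))
  Z <- cbind(`(Intercept)` = 1, as.matrix(df[c(instruments, exog)]))
  if (ncol(Z) < ncol(X)) stop_("under-identified: fewer instruments than endogenous terms")
  check_full_rank(X); check_full_rank(Z)

  qz <- qr(Z)
  PzX <- qr.fitted(qz, X)                       # projection of X on the instrument space
  A <- crossprod(PzX)                           # X' Pz X
  bhat <- solve(A, crossprod(PzX, y))
  resid <- y - as.vector(X %*% bhat)            # residuals from observed exposure
  k <- ncol(X)
  if (robust) {
    meat <- crossprod(PzX * resid)
    V <- solve(A, t(solve(A, meat)))
    V <- V * n / (n - k)
  } else {
    s2 <- sum(resid^2) / (n - k)
    V <- s2 * solve(A)
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  coefs <- stats::setNames(as.vector(bhat), colnames(X))

  # first-stage partial F of the excluded instruments
  x1 <- df[[exposure]]
  f1 <- stats::lm.fit(Z, x1)
  Z0 <- cbind(rep(1, n), if (length(exog) > 0) as.matrix(df[exog]))
  f0 <- stats::lm.fit(Z0, x1)
  rss1 <- sum(f1$residuals^2); rss0 <- sum(f0$residuals^2)
  q <- length(instruments)
  first_stage_F <- ((rss0 - rss1) / q) / (rss1 / (n - ncol(Z)))

  se <- sqrt(diag(V))
  out <- list(coefficients = coefs, vcov = V, n = n,
              outcome = outcome, exposure = exposure,
              instruments = instruments, adjust = adjust,
              covariates = covariates, robust = robust,
              beta = coefs[[exposure]], se = se[[exposure]],
              p = z_p(coefs[[exposure]], se[[exposure]]),
              first_stage_F = first_stage_F,
              weak_instrument = is.finite(first_stage_F) && first_stage_F < weak_f,
              residuals = resid)
  class(out) <- "iv2sls"
  if (out$weak_instrument)
    warn_("weak instrument: first-stage F = %.2f < %g", first_stage_F, weak_f)
  out
}

#' @export
print.iv2sls <- function(x, ...) {
  cat(sprintf("2SLS: %s ~ %s | %s%s (n = %d)\n", x$outcome, x$exposure,
              paste(x$instruments, collapse = " + "),
              if (length(x$adjust) > 0)
                paste0(", adjusting for ", paste(x$adjust, collapse = " + "))
              else "", x$n))
  cat(sprintf("  beta = %.4g  se = %.4g  p = %.3g  (first-stage F = %.1f%s)\n",
              x$beta, x$se, x$p, x$first_stage_F,
              if (x$weak_instrument) ", WEAK" else ""))
  invisible(x)
}

#' @export
coef.iv2sls <- function(object, ...) object$coefficients

#' @export
vcov.iv2sls <- function(object, ...) object$vcov

#' @export
residuals.iv2sls <- function(object, ...) object$residuals

#' @export
confint.iv2sls <- function(object, parm = NULL, level = 0.95, ...) {
  co <- object$coefficients
  se <- sqrt(diag(object$vcov))
  if (is.null(parm)) parm <- names(co)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(co[parm] - zq * se[parm], co[parm] + zq * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
summary.iv2sls <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = object$coefficients / se,
               `Pr(>|z|)` = z_p(object$coefficients, se))
  structure(list(coefficients = tab, call_info = object), class = "summary.iv2sls")
}

#' @export
print.summary.iv2sls <- function(x, ...) {
  print(x$call_info)
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Instrumental-variable analysis under the four instrument configurations
#'
#' Runs 2SLS of an outcome on maternal height under the four instrument
#' choices: Method 1 instruments with the maternal genotype score M;
#' Method 2 with M while controlling for the fetal genotype score C;
#' Method 3 with the maternal non-transmitted haplotype score M2 (a valid
#' instrument unconfounded by genetic transmission); Method 4 with M2 while
#' controlling for the transmitted scores M1 and C2 to guard against
#' assortative-mating correlation between haplotype scores. Adjustment
#' terms enter both stages; outcome-appropriate covariates are included
#' throughout.
#'
#' @param data Analysis frame with scores (see [analysis_frame()]).
#' @param outcome Outcome column.
#' @param exposure Exposure column (default `maternal_height`).
#' @param methods Subset of 1:4.
#' @param covariates Covariates, or NULL for the outcome rule.
#' @param ... Passed to [iv_2sls()].
#' @return A `data.frame` with one row per method (`beta`, `se`, `p`,
#'   `first_stage_F`, `n`); the fitted `iv2sls` objects are in
#'   `attr(, "fits")`.
#' @export
run_iv_methods <- function(data, outcome, exposure = "maternal_height",
                           methods = 1:4, covariates = NULL, ...) {
  stopifnot(all(methods %in% 1:4))
  spec <- list(`1` = list(inst = "M", adj = character(0)),
               `2` = list(inst = "M", adj = "C"),
               `3` = list(inst = "M2", adj = character(0)),
               `4` = list(inst = "M2", adj = c("M1", "C2")))
  fits <- lapply(methods, function(m) {
    s <- spec[[as.character(m)]]
    iv_2sls(data, outcome, exposure, instruments = s$inst, adjust = s$adj,
            covariates = covariates, ...)
  })
  out <- data.frame(cohort = data$cohort[1] %||% NA_character_,
                    outcome = outcome, method = methods,
                    beta = vapply(fits, `[[`, numeric(1), "beta"),
                    se = vapply(fits, `[[`, numeric(1), "se"),
                    p = vapply(fits, `[[`, numeric(1), "p"),
                    first_stage_F = vapply(fits, `[[`, numeric(1), "first_stage_F"),
                    n = vapply(fits, `[[`, numeric(1), "n"),
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}
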