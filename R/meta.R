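#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-study estimates with weights `w_i = 1 / se_i^2`:
#' `beta_meta = sum(w_i beta_i) / sum(w_i)`, `se_meta = sum(w_i)^(-1/2)`,
#' two-sided p from the normal distribution, and Cochran's
#' `Q = sum(w_i (beta_i - beta_meta)^2)` tested against chi-square with
#' `k - 1` degrees of freedom for between-study heterogeneity.
#'
#' @param beta Numeric vector of study estimates (or a 2-column matrix /
#'   data.frame of beta and se).
#' @param se Numeric vector of standard errors (all > 0).
#' @param labels Optional study labels.
#' @return An `fe_meta` object: `beta`, `se`, `p`, `Q`, `df`, `p_het`, `k`,
#'   and the per-study table.
#' @examples
#' fixed_effect_meta(c(0.293, 0.303, 0.400), c(0.142, 0.104, 0.102))
#' @export
fixed_effect_meta <- function(beta, se, labels = NULL) {
  if (is.matrix(beta) || is.data.frame(beta)) {
    se <- beta[[2]]; beta <- beta[[1]]
  }
  k <- length(beta)
  if (k == 0) stop_("no studies to combine")
  if (length(se) != k) stop_("beta and se lengths differ")
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop_("all estimates must be finite with positive standard errors")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  Q <- sum(w * (beta - b)^2)
  df <- k - 1L
  p_het <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  out <- list(beta = b, se = s, p = z_p(b, s), Q = Q, df = df, p_het = p_het,
              k = k,
              studies = data.frame(label = labels %||% paste0("study", seq_len(k)),
                                   beta = beta, se = se, weight = w / sum(w),
                                   stringsAsFactors = FALSE))
  class(out) <- "fe_meta"
  out
}

#' @export
print.fe_meta <- function(x, digits = 3, ...) {
  cat(sprintf("fixed-effect meta-analysis of %d studies\n", x$k))
  cat(sprintf("  beta = %s  se = %s  p = %.3g\n",
              signif(x$beta, digits), signif(x$se, digits), x$p))
  if (x$df > 0)
    cat(sprintf("  heterogeneity: Q = %.3f (df = %d), p_het = %.3g\n",
                x$Q, x$df, x$p_het))
  invisible(x)
}

#' Meta-analyze a table of per-cohort estimates by group
#'
#' Groups a tidy result table (e.g. rows from [fit_linear()] or
#' [run_iv_methods()] across cohorts) and applies [fixed_effect_meta()]
#' within each group. Groups with a single study are passed through
#' unchanged with a note (e.g. an outcome absent from all but one cohort).
#'
#' @param results `data.frame` with at least `cohort`, `beta`, `se` columns.
#' @param by Character vector of grouping columns (default
#'   `c("outcome", "predictor")` intersected with the available columns).
#' @return `data.frame` with one row per group: the grouping keys, `k`,
#'   `beta`, `se`, `p`, `Q`, `p_het`, `note`.
#' @export
meta_all <- function(results, by = NULL) {
  if (is.null(by))
    by <- intersect(c("outcome", "predictor", "method"), names(results))
  if (length(by) == 0) stop_("no grouping columns found")
  if (nrow(results) == 0) stop_("empty result table")
  key <- interaction(results[by], drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(results)), key), function(idx) {
    g <- results[idx, , drop = FALSE]
    m <- fixed_effect_meta(g$beta, g$se, labels = g$cohort)
    cbind(g[1, by, drop = FALSE],
          data.frame(k = m$k, beta = m$beta, se = m$se, p = m$p,
                     Q = m$Q, p_het = m$p_het,
                     note = if (m$k == 1)
                       sprintf("single cohort (%s): passed through", g$cohort[1])
                     else "", stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
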