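#' Weighted genotype score
#'
#' Weighted sum of effect-allele dosages, `S = sum(b_i * G_i)` with
#' `G_i` in 0/1/2. Missing genotypes are imputed as twice the effect-allele
#' frequency supplied in `impute_af` (by convention the frequency among the
#' cohort's mothers).
#'
#' @param weights Weight table (`beta` column, rows aligned with the columns
#'   of `genotypes`).
#' @param genotypes Numeric matrix (samples x SNPs) of effect-allele dosages.
#' @param impute_af Optional per-SNP effect-allele frequencies used for
#'   mean-imputation of missing genotypes; when NULL, any missing genotype
#'   is an error.
#' @return Numeric vector of scores, one per row of `genotypes`.
#' @export
genotype_score <- function(weights, genotypes, impute_af = NULL) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(weights))
    stop_("genotype matrix has %d columns but weight table has %d rows",
          ncol(genotypes), nrow(weights))
  if (any(rowSums(!is.na(genotypes)) == 0))
    stop_("all genotypes missing for sample(s): %s",
          paste(which(rowSums(!is.na(genotypes)) == 0), collapse = ", "))
  if (anyNA(genotypes)) {
    if (is.null(impute_af))
      stop_("missing genotypes present but no imputation frequencies supplied")
    fill <- matrix(rep(2 * impute_af, each = nrow(genotypes)),
                   nrow = nrow(genotypes))
    genotypes[is.na(genotypes)] <- fill[is.na(genotypes)]
  }
  as.vector(genotypes %*% weights$beta)
}

#' Haplotype-decomposed genetic scores per pair
#'
#' Builds the five weighted scores per mother/child pair: the maternal
#' genotype score M, its transmitted (M1) and non-transmitted (M2) haplotype
#' components, the fetal genotype score C, and the paternal transmitted
#' component C2 (with C1 = M1 by construction). At sites where the
#' transmission call is unresolved (or Mendelian-inconsistent), the
#' contribution is split in expectation: `b_i * G_i / 2` to each of M1 and
#' M2, and `b_i * (C_i - G_i / 2)` to C2, which preserves M = M1 + M2 and
#' C = C1 + C2 exactly. Missing genotypes are mean-imputed from the
#' mothers' effect-allele frequencies.
#'
#' @param cohort A `cohort_data`.
#' @param calls A `transmission_calls` covering the cohort's pairs and
#'   weight SNPs.
#' @param max_unresolved_frac Pairs with more than this fraction of
#'   unresolved weight SNPs are flagged (not dropped); default 0.05.
#' @return A `data.frame` (`score_set`) with columns `pair_id`, `M`, `M1`,
#'   `M2`, `C`, `C1`, `C2`, `n_unresolved`, `n_missing`, `flagged`.
#' @export
haplotype_scores <- function(cohort, calls, max_unresolved_frac = 0.05) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(calls, "transmission_calls"))
  if (!identical(calls$pair_id, cohort$pairs$pair_id) ||
      !identical(calls$snp_id, cohort$weights$snp_id))
    stop_("calls do not cover the cohort's pairs and weight SNPs")
  panel <- cohort$panel
  mi <- match(cohort$pairs$mother, panel$samples)
  ci <- match(cohort$pairs$child, panel$samples)
  fi <- cohort$focal_idx
  Gm <- panel$H1[mi, fi, drop = FALSE] + panel$H2[mi, fi, drop = FALSE]
  Gc <- panel$H1[ci, fi, drop = FALSE] + panel$H2[ci, fi, drop = FALSE]
  n_missing <- rowSums(is.na(Gm)) + rowSums(is.na(Gc))

  af <- colMeans(Gm, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0.5
  impute <- function(G) {
    if (!anyNA(G)) return(G)
    fill <- matrix(rep(2 * af, each = nrow(G)), nrow = nrow(G))
    G[is.na(G)] <- fill[is.na(G)]
    G
  }
  Gm <- impute(Gm); Gc <- impute(Gc)

  b <- cohort$weights$beta
  W <- matrix(rep(b, each = nrow(Gm)), nrow = nrow(Gm))
  resolved <- calls$resolution %in% c("homozygote_rule", "haplotype_match")
  resolved <- matrix(resolved, nrow = nrow(Gm))
  A <- ifelse(resolved, calls$transmitted, Gm / 2)
  M1 <- rowSums(W * A)
  M2 <- rowSums(W * (Gm - A))
  C2 <- rowSums(W * (Gc - A))
  M <- as.vector(Gm %*% b)
  C <- as.vector(Gc %*% b)
  n_unres <- rowSums(!resolved)
  out <- data.frame(pair_id = cohort$pairs$pair_id, M = M, M1 = M1, M2 = M2,
                    C = C, C1 = M1, C2 = C2, n_unresolved = n_unres,
                    n_missing = n_missing,
                    flagged = n_unres / length(b) > max_unresolved_frac,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}

#' Summaries and pairwise correlations of the genetic scores
#'
#' Means, SDs and the pairwise Pearson correlation matrix (with two-sided
#' p-values) among the M, M1, M2, C and C2 scores, mirroring how score
#' interdependence (e.g. the positive M2-C2 correlation induced by
#' assortative mating) is usually reported.
#'
#' @param scores A `score_set` from [haplotype_scores()].
#' @return List with `stats` (per-score mean/sd), `cor` and `p` (5 x 5
#'   matrices; entries are NA with a note when a score is constant).
#' @export
score_summary <- function(scores) {
  cols <- c("M", "M1", "M2", "C", "C2")
  if (nrow(scores) < 3) stop_("need at least 3 pairs to summarize scores")
  x <- as.matrix(scores[cols])
  stats_df <- data.frame(score = cols, mean = colMeans(x),
                         sd = apply(x, 2, stats::sd), row.names = NULL)
  k <- length(cols)
  cm <- pm <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { cm[i, j] <- 1; next }
    if (constant[i] || constant[j]) next
    ct <- stats::cor.test(x[, i], x[, j])
    cm[i, j] <- unname(ct$estimate); pm[i, j] <- ct$p.value
  }
  if (any(constant))
    attr(cm, "note") <- sprintf("constant score(s): %s (correlation undefined)",
                                paste(cols[constant], collapse = ", "))
  list(stats = stats_df, cor = cm, p = pm)
}
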