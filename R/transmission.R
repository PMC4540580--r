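#' Transmission call from genotypes alone
#'
#' When mother or child is homozygous at a biallelic SNP, the transmitted
#' maternal allele is forced by the genotypes. Full enumeration (mother,
#' child genotype as dosage 0/1/2): any homozygote resolves the call; the
#' double heterozygote (1,1) is ambiguous and needs haplotype information;
#' opposite homozygotes ((0,2) or (2,0)) are Mendelian errors.
#'
#' @param mother_gt,child_gt Integer genotype dosages in \{0, 1, 2\}
#'   (vectorized; recycled to common length).
#' @return A `data.frame` with columns `transmitted`, `nontransmitted`,
#'   `paternal` (0/1 or NA) and `resolution` (`homozygote_rule`,
#'   `needs_haplotype`, or `mendelian_error`).
#' @examples
#' call_by_genotype(0, 1)   # transmitted 0, paternal 1
#' call_by_genotype(1, 2)   # transmitted 1, nontransmitted 0
#' @export
call_by_genotype <- function(mother_gt, child_gt) {
  n <- max(length(mother_gt), length(child_gt))
  m <- rep_len(as.integer(mother_gt), n)
  c_ <- rep_len(as.integer(child_gt), n)
  if (anyNA(m) || anyNA(c_) || any(m < 0L | m > 2L | c_ < 0L | c_ > 2L))
    stop_("genotypes must be 0, 1 or 2")
  t <- nt <- pat <- rep(NA_integer_, n)
  res <- rep("needs_haplotype", n)
  me <- (m == 0L & c_ == 2L) | (m == 2L & c_ == 0L)
  res[me] <- "mendelian_error"
  solvable <- !me & !(m == 1L & c_ == 1L)
  t[solvable] <- ifelse(m[solvable] != 1L, m[solvable] %/% 2L,
                        c_[solvable] %/% 2L)
  nt[solvable] <- m[solvable] - t[solvable]
  pat[solvable] <- c_[solvable] - t[solvable]
  res[solvable] <- "homozygote_rule"
  data.frame(transmitted = t, nontransmitted = nt, paternal = pat,
             resolution = res, stringsAsFactors = FALSE)
}

# identity fraction between child and mother flank haplotypes over the
# non-missing sites of the current window (-Inf when nothing overlaps)
hap_identity <- function(C, M) {
  den <- rowSums(!is.na(C) & !is.na(M))
  agr <- rowSums(C == M, na.rm = TRUE)
  ifelse(den > 0, agr / den, -Inf)
}

# core of the haplotype-matching rule at a double-heterozygous focal SNP,
# vectorized over pairs. Only assignments consistent with the observed focal
# alleles are considered: the child haplotype carrying the same focal allele
# as maternal haplotype 1 is scored against it, and the other child
# haplotype against maternal haplotype 2. The assignment with the higher
# identity wins; margins at or below min_margin are unresolved. C1/C2 and
# M1/M2 are flank matrices (pairs x window sites); c1f and m1f/m2f are the
# focal alleles of child haplotype 1 and the mother's haplotypes.
match_window <- function(C1, C2, M1, M2, c1f, m1f, m2f, min_margin) {
  sel <- c1f == m1f                    # child slot carrying m1's focal allele
  Cx <- C1; Cx[!sel, ] <- C2[!sel, , drop = FALSE]
  Cy <- C2; Cy[!sel, ] <- C1[!sel, , drop = FALSE]
  d <- hap_identity(Cx, M1) - hap_identity(Cy, M2)
  out <- rep(NA_integer_, length(c1f))
  resolved <- !is.nan(d) & abs(d) > min_margin + 1e-12
  out[resolved] <- ifelse(d[resolved] > 0, m1f[resolved], m2f[resolved])
  out
}

#' Transmission call by local haplotype matching (single pair)
#'
#' For a double-heterozygous focal SNP, grows a symmetric window around the
#' focal site and compares each of the child's phased haplotypes against
#' each of the mother's over the non-missing flank sites in the window. The
#' child haplotype uniquely best-matching a maternal haplotype is declared
#' maternal-origin, and that maternal haplotype's focal allele is the
#' transmitted allele. If at the maximum window the best assignment is tied
#' (or the winning margin is below `min_margin`), the call is unresolved.
#'
#' @param mother_haps,child_haps 2 x L integer matrices (rows = the two
#'   phased haplotypes, columns = sites, values 0/1 or NA).
#' @param focal Column index of the focal SNP.
#' @param pos Optional base-pair positions of the L sites; when omitted, all
#'   flanking sites are used in a single full-window pass.
#' @param window_step,max_window Window growth schedule in bp (defaults
#'   100 kb steps up to 1 Mb); only used when `pos` is given.
#' @param min_margin Minimum identity-fraction margin between best and
#'   second-best assignment (default 0: only exact ties are unresolved).
#' @param require_double_het Error unless both mother and child are
#'   heterozygous at the focal SNP (the caller contract for double-het
#'   sites). Set FALSE to run the matcher as a cross-check on sites where
#'   the mother is heterozygous but the child is not.
#' @return A one-row `data.frame` as in [call_by_genotype()], plus
#'   `window_used` (bp, NA when `pos` is omitted or the call unresolved).
#' @export
call_by_haplotype <- function(mother_haps, child_haps, focal, pos = NULL,
                              window_step = 1e5, max_window = 1e6,
                              min_margin = 0, require_double_het = TRUE) {
  stopifnot(is.matrix(mother_haps), is.matrix(child_haps),
            nrow(mother_haps) == 2, nrow(child_haps) == 2,
            ncol(mother_haps) == ncol(child_haps))
  mf <- mother_haps[, focal]; cf <- child_haps[, focal]
  if (anyNA(mf) || anyNA(cf))
    stop_("focal genotypes must be non-missing")
  if (sum(mf) != 1L)
    stop_("mother must be heterozygous at the focal SNP for haplotype matching")
  if (require_double_het && sum(cf) != 1L)
    stop_("child must be heterozygous at the focal SNP (set require_double_het = FALSE to override)")
  flanks <- setdiff(seq_len(ncol(mother_haps)), focal)
  steps <- if (is.null(pos)) list(flanks) else {
    dist <- abs(pos[flanks] - pos[focal])
    lapply(seq(window_step, max_window, by = window_step),
           function(w) flanks[dist <= w])
  }
  # enumeration of (child haplotype -> maternal haplotype) assignments
  # consistent with the observed focal alleles
  combos <- expand.grid(ci = 1:2, mi = 1:2)
  combos <- combos[cf[combos$ci] == mf[combos$mi], , drop = FALSE]
  t <- NA_integer_; w_used <- NA_real_
  for (k in seq_along(steps)) {
    f <- steps[[k]]
    if (length(f) == 0 || nrow(combos) == 0) next
    sc <- mapply(function(ci, mi)
      hap_identity(child_haps[ci, f, drop = FALSE],
                   mother_haps[mi, f, drop = FALSE]),
      combos$ci, combos$mi)
    implied <- mf[combos$mi]
    best_by_allele <- tapply(sc, implied, max)
    if (length(best_by_allele) == 1) {
      if (is.finite(best_by_allele[[1]]) || length(f) == 0) {
        t <- as.integer(names(best_by_allele))
        w_used <- if (is.null(pos)) NA_real_ else k * window_step
        break
      }
    } else {
      d <- best_by_allele[[2]] - best_by_allele[[1]]
      if (!is.nan(d) && abs(d) > min_margin + 1e-12) {
        t <- as.integer(names(best_by_allele)[if (d > 0) 2 else 1])
        w_used <- if (is.null(pos)) NA_real_ else k * window_step
        break
      }
    }
  }
  if (is.na(t))
    return(data.frame(transmitted = NA_integer_, nontransmitted = NA_integer_,
                      paternal = NA_integer_, resolution = "unresolved",
                      window_used = NA_real_, stringsAsFactors = FALSE))
  data.frame(transmitted = t, nontransmitted = sum(mf) - t,
             paternal = sum(cf) - t, resolution = "haplotype_match",
             window_used = w_used, stringsAsFactors = FALSE)
}

#' Infer allele transmission for every pair and weight SNP
#'
#' Applies the genotype rule where a homozygote forces the call and local
#' haplotype matching (incrementally growing window up to `max_window`) at
#' double heterozygotes. Mendelian-inconsistent sites are flagged and
#' excluded from scoring; sites with missing focal genotypes are unresolved.
#'
#' @param cohort A `cohort_data` object (harmonized, QC-passed).
#' @param window_step,max_window,min_margin See [call_by_haplotype()].
#' @return A `transmission_calls` object: integer matrices `transmitted`,
#'   `nontransmitted`, `paternal` (pairs x SNPs; NA when not resolved),
#'   character matrix `resolution`, numeric matrix `window_used`, and the
#'   pair/SNP ids. `summary()` gives per-pair resolution counts.
#' @export
infer_transmission <- function(cohort, window_step = 1e5, max_window = 1e6,
                               min_margin = 0) {
  stopifnot(inherits(cohort, "cohort_data"))
  panel <- cohort$panel
  mi <- match(cohort$pairs$mother, panel$samples)
  ci <- match(cohort$pairs$child, panel$samples)
  n <- length(mi); S <- length(cohort$focal_idx)
  v <- panel$variants

  t_m <- nt_m <- pat_m <- matrix(NA_integer_, n, S)
  res_m <- matrix("unresolved", n, S)
  win_m <- matrix(NA_real_, n, S)
  steps <- seq(window_step, max_window, by = window_step)

  for (s in seq_len(S)) {
    j <- cohort$focal_idx[s]
    m1a <- panel$H1[mi, j]; m2a <- panel$H2[mi, j]
    c1a <- panel$H1[ci, j]; c2a <- panel$H2[ci, j]
    mgt <- m1a + m2a; cgt <- c1a + c2a
    obs <- !is.na(mgt) & !is.na(cgt)

    me <- obs & ((mgt == 0L & cgt == 2L) | (mgt == 2L & cgt == 0L))
    res_m[me, s] <- "mendelian_error"
    hom <- obs & !me & !(mgt == 1L & cgt == 1L)
    if (any(hom)) {
      t0 <- ifelse(mgt[hom] != 1L, mgt[hom] %/% 2L, cgt[hom] %/% 2L)
      t_m[hom, s] <- t0
      nt_m[hom, s] <- mgt[hom] - t0
      pat_m[hom, s] <- cgt[hom] - t0
      res_m[hom, s] <- "homozygote_rule"
    }
    dh <- which(obs & !me & mgt == 1L & cgt == 1L)
    if (length(dh) == 0) next

    fl <- which(v$chrom == v$chrom[j] & v$pos != v$pos[j] &
                  abs(v$pos - v$pos[j]) <= max_window)
    if (length(fl) == 0) next
    dist <- abs(v$pos[fl] - v$pos[j])
    pending <- dh
    for (w in steps) {
      f <- fl[dist <= w]
      if (length(f) == 0 || length(pending) == 0) next
      C1 <- panel$H1[ci[pending], f, drop = FALSE]
      C2 <- panel$H2[ci[pending], f, drop = FALSE]
      M1 <- panel$H1[mi[pending], f, drop = FALSE]
      M2 <- panel$H2[mi[pending], f, drop = FALSE]
      t_w <- match_window(C1, C2, M1, M2, c1a[pending],
                          m1a[pending], m2a[pending], min_margin)
      done <- which(!is.na(t_w))
      if (length(done) > 0) {
        p <- pending[done]
        t_m[p, s] <- t_w[done]
        nt_m[p, s] <- 1L - t_w[done]
        pat_m[p, s] <- 1L - t_w[done]
        res_m[p, s] <- "haplotype_match"
        win_m[p, s] <- w
        pending <- pending[-done]
      }
      if (length(pending) == 0) break
    }
  }

  snp_ids <- cohort$weights$snp_id
  dimnames(t_m) <- dimnames(nt_m) <- dimnames(pat_m) <- dimnames(res_m) <-
    dimnames(win_m) <- list(cohort$pairs$pair_id, snp_ids)
  out <- list(pair_id = cohort$pairs$pair_id, snp_id = snp_ids,
              transmitted = t_m, nontransmitted = nt_m, paternal = pat_m,
              resolution = res_m, window_used = win_m)
  class(out) <- "transmission_calls"
  out
}

#' @export
print.transmission_calls <- function(x, ...) {
  tab <- table(factor(x$resolution,
                      levels = c("homozygote_rule", "haplotype_match",
                                 "unresolved", "mendelian_error")))
  cat(sprintf("transmission calls: %d pairs x %d SNPs\n",
              length(x$pair_id), length(x$snp_id)))
  for (nm in names(tab))
    cat(sprintf("  %-16s %d (%.2f%%)\n", nm, tab[[nm]],
                100 * tab[[nm]] / length(x$resolution)))
  invisible(x)
}

#' @export
summary.transmission_calls <- function(object, ...) {
  lev <- c("homozygote_rule", "haplotype_match", "unresolved", "mendelian_error")
  counts <- sapply(lev, function(l) rowSums(object$resolution == l))
  out <- data.frame(pair_id = object$pair_id, counts,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$unresolved_frac <- out$unresolved / length(object$snp_id)
  out$mendel_frac <- out$mendelian_error / length(object$snp_id)
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.transmission_calls <- function(x, ...) {
  data.frame(pair_id = rep(x$pair_id, times = length(x$snp_id)),
             snp_id = rep(x$snp_id, each = length(x$pair_id)),
             transmitted = as.vector(x$transmitted),
             nontransmitted = as.vector(x$nontransmitted),
             paternal = as.vector(x$paternal),
             resolution = as.vector(x$resolution),
             window_used = as.vector(x$window_used),
             stringsAsFactors = FALSE)
}

#' Compare transmission calls against a simulation truth ledger
#'
#' @param truth A `cohort_truth` from [simulate_cohort()].
#' @param calls A `transmission_calls` from [infer_transmission()] on the
#'   same cohort.
#' @return List with overall and per-resolution concordance of the
#'   transmitted-allele calls, the unresolved and Mendelian-error rates, and
#'   a per-SNP concordance table.
#' @export
truth_vs_called <- function(truth, calls) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(calls, "transmission_calls"))
  if (!identical(sort(truth$pair_id), sort(calls$pair_id)))
    stop_("truth and calls cover different pair sets")
  if (!identical(sort(truth$snp_id), sort(calls$snp_id)))
    stop_("truth and calls cover different SNP sets")
  pi <- match(calls$pair_id, truth$pair_id)
  si <- match(calls$snp_id, truth$snp_id)
  tr_true <- truth$transmitted[pi, si, drop = FALSE]

  resolved <- matrix(calls$resolution %in% c("homozygote_rule", "haplotype_match"),
                     nrow = nrow(calls$resolution))
  correct <- calls$transmitted == tr_true
  by_res <- lapply(c(homozygote_rule = "homozygote_rule",
                     haplotype_match = "haplotype_match"), function(l) {
    idx <- calls$resolution == l
    n <- sum(idx)
    list(n = n, concordance = if (n > 0) mean(correct[idx]) else NA_real_)
  })
  per_snp <- vapply(seq_along(calls$snp_id), function(s) {
    idx <- resolved[, s]
    if (!any(idx)) return(NA_real_)
    mean(correct[idx, s])
  }, numeric(1))
  list(n_calls = length(calls$resolution),
       overall_concordance = mean(correct[resolved]),
       by_resolution = by_res,
       unresolved_rate = mean(calls$resolution == "unresolved"),
       mendelian_error_rate = mean(calls$resolution == "mendelian_error"),
       per_snp = data.frame(snp_id = calls$snp_id, concordance = per_snp,
                            stringsAsFactors = FALSE))
}
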