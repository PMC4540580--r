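#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided test for deviation from Hardy-Weinberg proportions at a
#' biallelic site, computed by summing the conditional probabilities (given
#' the allele counts) of all heterozygote counts no more probable than the
#' observed one. This is the standard exact recursion on the number of
#' heterozygotes; no pre-installed package exposes it, so it is implemented
#' here directly.
#'
#' @param n_het Observed number of heterozygous individuals.
#' @param n_hom1,n_hom2 Observed counts of the two homozygote classes.
#' @return Two-sided exact p-value (1 for degenerate sites with no minor
#'   allele).
#' @examples
#' hwe_exact_test(57, 14, 50)
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  stopifnot(length(n_het) == 1, n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L || n_rare == 0L) return(1)

  # probabilities of each possible heterozygote count, conditional on the
  # minor-allele count, built outward from the mode by the HW recursion
  het_values <- seq.int(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(het_values))
  mid <- round(n_rare * (2 * n - n_rare) / (2 * n))
  if ((mid %% 2) != (n_rare %% 2)) mid <- mid + 1
  i_mid <- match(mid, het_values)
  probs[i_mid] <- 1
  # downward: het -> het - 2
  if (i_mid > 1) {
    for (i in seq(i_mid, 2)) {
      het <- het_values[i]
      hom_r <- (n_rare - het) / 2
      hom_c <- n - het - hom_r
      probs[i - 1] <- probs[i] * het * (het - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  # upward: het -> het + 2
  if (i_mid < length(het_values)) {
    for (i in seq(i_mid, length(het_values) - 1)) {
      het <- het_values[i]
      hom_r <- (n_rare - het) / 2
      hom_c <- n - het - hom_r
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c /
        ((het + 1) * (het + 2))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, het_values)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}
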