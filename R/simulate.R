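#' Configuration for the synthetic duo-cohort generator
#'
#' Defines the generative model for a mother/father/child cohort with the
#' statistical structure the haplotype-score analysis assumes: a weighted
#' genetic score explaining a target fraction of maternal height variance,
#' direct (causal) maternal-height paths and fetal-genetic paths to the
#' pregnancy outcomes, optional assortative mating on height, an optional
#' shared nongenetic confounder, and optional two-segment case/control
#' ascertainment on gestational age.
#'
#' Defaults encode the study conditions the analysis targets: the score
#' explains ~20% of maternal height variance; maternal height causally adds
#' 0.4 gestational days per cm and 0.05 cm of birth length per cm; birth
#' weight and birth length carry direct fetal-genetic effects while
#' gestational age does not; spousal height correlation 0.2; ascertainment
#' off. Effect sizes for fetal sex and the confounder default to zero
#' (neutral), and fetal score effects are expressed per standard deviation
#' of the child genotype score so they do not depend on the SNP count.
#'
#' @param n_pairs Number of mother/child pairs emitted.
#' @param n_snps Number of weight (focal) SNPs; default 697.
#' @param flank_snps Phased flanking SNPs per focal locus (default 25).
#' @param flank_span Width in bp of the flank window around each focal SNP
#'   (flanks are placed within +/- `flank_span / 2`; default 1e6).
#' @param maf_range Range of effect-allele frequencies, drawn uniformly.
#' @param sigma_b SD of the normal distribution of per-allele weights (cm).
#' @param target_r2_height Fraction of maternal height variance explained by
#'   the genotype score (default 0.20).
#' @param height_mean,height_sd Maternal (and paternal) height distribution, cm.
#' @param causal_ga_per_cm,causal_bw_per_cm,causal_bl_per_cm Direct causal
#'   effect of maternal height on gestational age (days/cm), birth weight
#'   (g/cm) and birth length (cm/cm).
#' @param fetal_effect_ga,fetal_effect_bw,fetal_effect_bl Direct fetal-genetic
#'   effect per SD of the child genotype score (days, g, cm).
#' @param ga_mean,ga_sd Gestational-age intercept and residual SD (days).
#' @param bw_mean,bw_sd,bl_mean,bl_sd Birth weight (g) and length (cm)
#'   intercepts and residual SDs.
#' @param bw_per_ga_day,bl_per_ga_day Growth per gestational day.
#' @param sex_effect_ga,sex_effect_bw,sex_effect_bl Additive male effects.
#' @param confounder_effects Named numeric vector with loadings of a shared
#'   standard-normal nongenetic confounder on `height`, `ga`, `bw`, `bl`.
#' @param assortative_r Spousal (mother-father) height correlation, achieved
#'   by Gaussian-copula rank matching.
#' @param ld_strength Probability that a flanking allele copies its
#'   haplotype's focal-SNP allele state rather than being drawn from the
#'   flank's own frequency; controls local LD while preserving haplotype
#'   diversity.
#' @param phase_switch_rate Per-(child, locus) probability of a phase switch
#'   error within the flank window (default 0).
#' @param ascertainment `"none"` or `"two_segment"` (case/control sampling on
#'   gestational age).
#' @param case_range,control_range Gestational-age windows (days) retained
#'   under two-segment ascertainment; defaults 154-258 and 273-286.
#' @param case_fraction Fraction of emitted pairs drawn from `case_range`.
#' @param seed Integer seed; the generator is byte-deterministic given the
#'   full configuration including the seed.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_pairs = 1000, n_snps = 697, flank_snps = 25,
                       flank_span = 1e6, maf_range = c(0.1, 0.9),
                       sigma_b = 0.1, target_r2_height = 0.20,
                       height_mean = 166, height_sd = 6,
                       causal_ga_per_cm = 0.4, causal_bw_per_cm = 0,
                       causal_bl_per_cm = 0.05,
                       fetal_effect_ga = 0, fetal_effect_bw = 100,
                       fetal_effect_bl = 0.45,
                       ga_mean = 280, ga_sd = 12,
                       bw_mean = 3500, bw_sd = 400,
                       bl_mean = 50, bl_sd = 1.8,
                       bw_per_ga_day = 20, bl_per_ga_day = 0.075,
                       sex_effect_ga = 0, sex_effect_bw = 0, sex_effect_bl = 0,
                       confounder_effects = c(height = 0, ga = 0, bw = 0, bl = 0),
                       assortative_r = 0.2, ld_strength = 0.3,
                       phase_switch_rate = 0,
                       ascertainment = c("none", "two_segment"),
                       case_range = c(154, 258), control_range = c(273, 286),
                       case_fraction = 0.5, seed = NULL) {
  cfg <- list(n_pairs = n_pairs, n_snps = n_snps, flank_snps = flank_snps,
              flank_span = flank_span, maf_range = maf_range,
              sigma_b = sigma_b, target_r2_height = target_r2_height,
              height_mean = height_mean, height_sd = height_sd,
              causal_ga_per_cm = causal_ga_per_cm,
              causal_bw_per_cm = causal_bw_per_cm,
              causal_bl_per_cm = causal_bl_per_cm,
              fetal_effect_ga = fetal_effect_ga,
              fetal_effect_bw = fetal_effect_bw,
              fetal_effect_bl = fetal_effect_bl,
              ga_mean = ga_mean, ga_sd = ga_sd, bw_mean = bw_mean,
              bw_sd = bw_sd, bl_mean = bl_mean, bl_sd = bl_sd,
              bw_per_ga_day = bw_per_ga_day, bl_per_ga_day = bl_per_ga_day,
              sex_effect_ga = sex_effect_ga, sex_effect_bw = sex_effect_bw,
              sex_effect_bl = sex_effect_bl,
              confounder_effects = confounder_effects,
              assortative_r = assortative_r, ld_strength = ld_strength,
              phase_switch_rate = phase_switch_rate,
              ascertainment = match.arg(ascertainment),
              case_range = case_range, control_range = control_range,
              case_fraction = case_fraction, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_pairs < 1) stop_("n_pairs must be at least 1")
    if (n_snps < 1) stop_("n_snps must be at least 1")
    if (flank_snps < 0) stop_("flank_snps must be non-negative")
    if (target_r2_height <= 0 || target_r2_height >= 1)
      stop_("target_r2_height must lie in (0, 1)")
    if (target_r2_height > 0.95 || (n_snps < 10 && target_r2_height > 0.5))
      stop_("target_r2_height = %.2f unattainable with %d loci: a score on so few discrete genotypes cannot explain that much variance", target_r2_height, n_snps)
    if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2])
      stop_("maf_range must be an increasing interval inside (0, 1)")
    if (ld_strength < 0 || ld_strength > 1) stop_("ld_strength must lie in [0, 1]")
    if (abs(assortative_r) >= 1) stop_("assortative_r must lie in (-1, 1)")
    if (case_fraction < 0 || case_fraction > 1) stop_("case_fraction must lie in [0, 1]")
    if (case_range[1] >= case_range[2] || control_range[1] >= control_range[2])
      stop_("case_range and control_range must be valid intervals")
    if (phase_switch_rate < 0 || phase_switch_rate > 1)
      stop_("phase_switch_rate must lie in [0, 1]")
    ch <- confounder_effects[["height"]] %||% 0
    if (ch^2 > (1 - target_r2_height) * height_sd^2)
      stop_("confounder loading on height exceeds the nongenetic height variance")
  })
  invisible(cfg)
}

# eight unambiguous ordered allele pairs (never A/T or C/G)
.unambiguous_pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                            c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))

# draw one set of parental haplotypes: focal alleles n x S, flank alleles
# n x (S * Fk), flanks coupled to the focal state with probability ld
gen_hap <- function(n, p_focal, p_flank, ld, Fk) {
  S <- length(p_focal)
  focal <- matrix(stats::rbinom(n * S, 1L, rep(p_focal, each = n)), nrow = n)
  if (Fk == 0) return(list(focal = focal, flank = matrix(0L, n, 0)))
  SF <- S * Fk
  base <- matrix(stats::rbinom(n * SF, 1L, rep(p_flank, each = n)), nrow = n)
  mask <- matrix(stats::rbinom(n * SF, 1L, ld), nrow = n)
  focal_rep <- focal[, rep(seq_len(S), each = Fk), drop = FALSE]
  flank <- mask * focal_rep + (1L - mask) * base
  list(focal = focal, flank = flank)
}

# generate a raw (unascertained) population of N trios given locus-level draws
gen_population <- function(N, cfg, loci) {
  S <- cfg$n_snps; Fk <- cfg$flank_snps
  b <- loci$beta
  var_s <- sum(b^2 * 2 * loci$p_focal * (1 - loci$p_focal))
  if (var_s <= 0) stop_("degenerate weight/frequency draw: score variance is zero")
  mean_s <- sum(b * 2 * loci$p_focal)
  sd_hap <- sqrt(var_s)

  m1 <- gen_hap(N, loci$p_focal, loci$p_flank, cfg$ld_strength, Fk)
  m2 <- gen_hap(N, loci$p_focal, loci$p_flank, cfg$ld_strength, Fk)
  f1 <- gen_hap(N, loci$p_focal, loci$p_flank, cfg$ld_strength, Fk)
  f2 <- gen_hap(N, loci$p_focal, loci$p_flank, cfg$ld_strength, Fk)

  score_m <- as.vector((m1$focal + m2$focal) %*% b)
  score_f <- as.vector((f1$focal + f2$focal) %*% b)
  std_m <- (score_m - mean_s) / sd_hap
  std_f <- (score_f - mean_s) / sd_hap

  conf <- stats::rnorm(N)
  c_h <- cfg$confounder_effects[["height"]] %||% 0
  env_sd <- sqrt(max((1 - cfg$target_r2_height) * cfg$height_sd^2 - c_h^2, 0))
  env_m <- c_h * conf + stats::rnorm(N, 0, env_sd)
  env_f <- c_h * stats::rnorm(N) + stats::rnorm(N, 0, env_sd)
  gen_scale <- sqrt(cfg$target_r2_height) * cfg$height_sd
  height_m <- cfg$height_mean + gen_scale * std_m + env_m
  height_f <- cfg$height_mean + gen_scale * std_f + env_f

  # assortative mating: Gaussian-copula rank matching of spousal heights
  if (cfg$assortative_r != 0) {
    u <- stats::rnorm(N)
    v <- cfg$assortative_r * u + sqrt(1 - cfg$assortative_r^2) * stats::rnorm(N)
    perm_m <- order(height_m)[rank(u, ties.method = "first")]
    perm_f <- order(height_f)[rank(v, ties.method = "first")]
    for (nm in c("focal", "flank")) {
      m1[[nm]] <- m1[[nm]][perm_m, , drop = FALSE]
      m2[[nm]] <- m2[[nm]][perm_m, , drop = FALSE]
      f1[[nm]] <- f1[[nm]][perm_f, , drop = FALSE]
      f2[[nm]] <- f2[[nm]][perm_f, , drop = FALSE]
    }
    score_m <- score_m[perm_m]; std_m <- std_m[perm_m]
    env_m <- env_m[perm_m]; height_m <- height_m[perm_m]
    score_f <- score_f[perm_f]; std_f <- std_f[perm_f]
    env_f <- env_f[perm_f]; height_f <- height_f[perm_f]
    conf <- conf[perm_m]  # confounder travels with the mother
  }

  # meiosis: one maternal and one paternal haplotype per locus block,
  # no recombination within a block, independent across blocks
  expand_f <- function(x) x[, rep(seq_len(S), each = Fk), drop = FALSE]
  mat_slot <- matrix(stats::rbinom(N * S, 1L, 0.5), nrow = N) + 1L
  pat_slot <- matrix(stats::rbinom(N * S, 1L, 0.5), nrow = N) + 1L
  pick <- function(h1, h2, slot) ifelse(slot == 1L, h1, h2)
  cm_focal <- pick(m1$focal, m2$focal, mat_slot)
  cp_focal <- pick(f1$focal, f2$focal, pat_slot)
  if (Fk > 0) {
    ms_f <- expand_f(mat_slot); ps_f <- expand_f(pat_slot)
    cm_flank <- pick(m1$flank, m2$flank, ms_f)
    cp_flank <- pick(f1$flank, f2$flank, ps_f)
  } else {
    cm_flank <- cp_flank <- matrix(0L, N, 0)
  }
  # child phase slots are arbitrary: per block, which child haplotype is the
  # maternal one is randomized so inference cannot exploit slot order
  swap <- matrix(stats::rbinom(N * S, 1L, 0.5), nrow = N)
  c1_focal <- ifelse(swap == 0L, cm_focal, cp_focal)
  c2_focal <- ifelse(swap == 0L, cp_focal, cm_focal)
  if (Fk > 0) {
    sw_f <- expand_f(swap)
    c1_flank <- ifelse(sw_f == 0L, cm_flank, cp_flank)
    c2_flank <- ifelse(sw_f == 0L, cp_flank, cm_flank)
  } else {
    c1_flank <- c2_flank <- matrix(0L, N, 0)
  }

  # truth ledger components
  A <- ifelse(mat_slot == 1L, m1$focal, m2$focal)      # transmitted maternal
  B <- ifelse(mat_slot == 1L, m2$focal, m1$focal)      # nontransmitted
  P <- cp_focal                                        # paternal transmitted
  M1s <- as.vector(A %*% b); M2s <- as.vector(B %*% b); C2s <- as.vector(P %*% b)
  Cs <- as.vector((c1_focal + c2_focal) %*% b)
  std_c <- (Cs - mean_s) / sd_hap

  male <- stats::rbinom(N, 1L, 0.512)
  ce <- function(nm) cfg$confounder_effects[[nm]] %||% 0
  dh <- height_m - cfg$height_mean
  ga <- cfg$ga_mean + cfg$causal_ga_per_cm * dh + cfg$fetal_effect_ga * std_c +
    ce("ga") * conf + cfg$sex_effect_ga * male + stats::rnorm(N, 0, cfg$ga_sd)
  bw <- cfg$bw_mean + cfg$causal_bw_per_cm * dh + cfg$fetal_effect_bw * std_c +
    cfg$bw_per_ga_day * (ga - cfg$ga_mean) + ce("bw") * conf +
    cfg$sex_effect_bw * male + stats::rnorm(N, 0, cfg$bw_sd)
  bl <- cfg$bl_mean + cfg$causal_bl_per_cm * dh + cfg$fetal_effect_bl * std_c +
    cfg$bl_per_ga_day * (ga - cfg$ga_mean) + ce("bl") * conf +
    cfg$sex_effect_bl * male + stats::rnorm(N, 0, cfg$bl_sd)
  age <- round(stats::runif(N, 20, 35), 1)
  bmi <- round(stats::rnorm(N, 24, 3.5), 1)

  list(m1 = m1, m2 = m2,
       c1 = list(focal = c1_focal, flank = c1_flank),
       c2 = list(focal = c2_focal, flank = c2_flank),
       A = A, B = B, P = P, swap = swap,
       score_m = score_m, std_m = std_m, env_m = env_m, height_m = height_m,
       height_f = height_f, conf = conf, M1s = M1s, M2s = M2s, C2s = C2s,
       Cs = Cs, std_c = std_c, male = male, ga = ga, bw = bw, bl = bl,
       age = age, bmi = bmi)
}

subset_population <- function(pop, idx) {
  for (nm in c("m1", "m2", "c1", "c2"))
    pop[[nm]] <- lapply(pop[[nm]], function(x) x[idx, , drop = FALSE])
  for (nm in c("A", "B", "P", "swap"))
    pop[[nm]] <- pop[[nm]][idx, , drop = FALSE]
  for (nm in c("score_m", "std_m", "env_m", "height_m", "height_f", "conf",
               "M1s", "M2s", "C2s", "Cs", "std_c", "male", "ga", "bw", "bl",
               "age", "bmi"))
    pop[[nm]] <- pop[[nm]][idx]
  pop
}

#' Simulate a mother/father/child cohort with a truth ledger
#'
#' Draws locus frequencies and weights, parental haplotypes with local LD
#' blocks, rank-matched spouses (assortative mating), maternal height from
#' the genotype score plus a nongenetic term, child haplotypes by block-wise
#' transmission, and outcomes from the configured causal and fetal-genetic
#' paths; optionally applies two-segment case/control ascertainment on
#' gestational age. See [sim_config()] for the generative model.
#'
#' @param config A [sim_config()] object.
#' @return List with `cohort` (a `cohort_data` ready for analysis, already
#'   harmonized to effect-allele coding) and `truth` (a `cohort_truth`: true
#'   transmitted/nontransmitted/paternal alleles per pair and SNP, which
#'   child haplotype slot is maternal, true scores, and the latent
#'   components of height and the outcomes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  S <- cfg$n_snps; Fk <- cfg$flank_snps; n <- cfg$n_pairs

  # locus layout: loci cycle over chromosomes, centers spaced widely so no
  # haplotype window can reach a neighbouring locus; enough chromosomes are
  # used that positions stay within 32-bit integer range
  spacing <- 4e6 + cfg$flank_span
  n_chrom <- max(22L, ceiling(S / floor(2e9 / spacing)))
  chrom <- as.character(((seq_len(S) - 1L) %% n_chrom) + 1L)
  rank_on_chrom <- (seq_len(S) - 1L) %/% n_chrom
  center <- as.integer(2e6 + rank_on_chrom * spacing)
  p_focal <- stats::runif(S, cfg$maf_range[1], cfg$maf_range[2])
  beta <- stats::rnorm(S, 0, cfg$sigma_b)
  letters_focal <- .unambiguous_pairs[sample.int(8, S, replace = TRUE), , drop = FALSE]
  if (Fk > 0) {
    p_flank <- stats::runif(S * Fk, cfg$maf_range[1], cfg$maf_range[2])
    off <- sample(c(-1L, 1L), S * Fk, replace = TRUE) *
      as.integer(stats::runif(S * Fk, 1e3, cfg$flank_span / 2))
    flank_pos <- rep(center, each = Fk) + off
    letters_flank <- .unambiguous_pairs[sample.int(8, S * Fk, replace = TRUE), , drop = FALSE]
  } else {
    p_flank <- numeric(0); flank_pos <- integer(0)
    letters_flank <- matrix(character(0), 0, 2)
  }
  loci <- list(p_focal = p_focal, p_flank = p_flank, beta = beta)

  if (cfg$ascertainment == "none") {
    pop <- gen_population(n, cfg, loci)
  } else {
    n_case <- round(n * cfg$case_fraction); n_ctrl <- n - n_case
    sd_tot <- sqrt(cfg$ga_sd^2 + (cfg$causal_ga_per_cm * cfg$height_sd)^2 +
                     (cfg$confounder_effects[["ga"]] %||% 0)^2 +
                     cfg$fetal_effect_ga^2 + cfg$sex_effect_ga^2 / 4)
    p_win <- function(r) stats::pnorm(r[2], cfg$ga_mean, sd_tot) -
      stats::pnorm(r[1], cfg$ga_mean, sd_tot)
    N0 <- ceiling(1.4 * max(n_case / max(p_win(cfg$case_range), 1e-6),
                            n_ctrl / max(p_win(cfg$control_range), 1e-6))) + 100
    pop <- gen_population(N0, cfg, loci)
    in_case <- pop$ga >= cfg$case_range[1] & pop$ga <= cfg$case_range[2]
    in_ctrl <- pop$ga >= cfg$control_range[1] & pop$ga <= cfg$control_range[2]
    if (sum(in_case) < n_case || sum(in_ctrl) < n_ctrl)
      stop_("two-segment ascertainment could not fill %d cases / %d controls; the configured gestational-age model rarely visits the requested ranges", n_case, n_ctrl)
    idx <- sort(c(which(in_case)[seq_len(n_case)], which(in_ctrl)[seq_len(n_ctrl)]))
    pop <- subset_population(pop, idx)
  }

  # variant bookkeeping (pre-sort layout: S focal columns, then S*Fk flanks)
  focal_ids <- sprintf("snp%04d", seq_len(S))
  if (Fk > 0) {
    flank_ids <- sprintf("snp%04d_f%02d", rep(seq_len(S), each = Fk),
                         rep(seq_len(Fk), times = S))
  } else flank_ids <- character(0)
  variants <- data.frame(
    snp_id = c(focal_ids, flank_ids),
    chrom = c(chrom, rep(chrom, each = Fk)),
    pos = c(center, flank_pos),
    ref = c(letters_focal[, 2], letters_flank[, 2]),
    alt = c(letters_focal[, 1], letters_flank[, 1]),
    stringsAsFactors = FALSE)

  mother_ids <- sprintf("M%05d", seq_len(n))
  child_ids <- sprintf("C%05d", seq_len(n))
  pair_ids <- sprintf("P%05d", seq_len(n))
  H1 <- rbind(cbind(pop$m1$focal, pop$m1$flank), cbind(pop$c1$focal, pop$c1$flank))
  H2 <- rbind(cbind(pop$m2$focal, pop$m2$flank), cbind(pop$c2$focal, pop$c2$flank))
  rownames(H1) <- rownames(H2) <- c(mother_ids, child_ids)
  ord <- order(variants$chrom, variants$pos)
  panel <- list(samples = c(mother_ids, child_ids),
                variants = variants[ord, , drop = FALSE],
                H1 = H1[, ord, drop = FALSE], H2 = H2[, ord, drop = FALSE])
  rownames(panel$variants) <- NULL
  class(panel) <- "hap_panel"
  panel <- apply_phase_switches(panel, cfg, child_ids, chrom, center)

  weights <- data.frame(snp_id = focal_ids, chrom = chrom, pos = center,
                        effect_allele = letters_focal[, 1],
                        other_allele = letters_focal[, 2],
                        beta = beta, stringsAsFactors = FALSE)

  pheno <- data.frame(pair_id = pair_ids, cohort = "SIM",
                      maternal_height = pop$height_m, maternal_age = pop$age,
                      maternal_bmi = pop$bmi,
                      maternal_weight = round(pop$bmi * (pop$height_m / 100)^2, 1),
                      birth_length = pop$bl, birth_weight = pop$bw,
                      gestational_age = pop$ga,
                      fetal_sex = pop$male, preterm = pop$ga < 259,
                      stringsAsFactors = FALSE)
  pairs <- data.frame(pair_id = pair_ids, mother = mother_ids,
                      child = child_ids, stringsAsFactors = FALSE)

  cohort <- build_cohort(panel, weights, pheno, pairs)

  dimnames(pop$A) <- dimnames(pop$B) <- dimnames(pop$P) <-
    dimnames(pop$swap) <- list(pair_ids, focal_ids)
  truth <- list(pair_id = pair_ids, snp_id = focal_ids,
                transmitted = pop$A, nontransmitted = pop$B, paternal = pop$P,
                maternal_child_slot = pop$swap + 1L,
                scores = data.frame(pair_id = pair_ids,
                                    M = pop$M1s + pop$M2s, M1 = pop$M1s,
                                    M2 = pop$M2s, C = pop$Cs, C1 = pop$M1s,
                                    C2 = pop$C2s, stringsAsFactors = FALSE),
                components = data.frame(pair_id = pair_ids,
                                        std_score_m = pop$std_m,
                                        std_score_c = pop$std_c,
                                        height_env = pop$env_m,
                                        paternal_height = pop$height_f,
                                        confounder = pop$conf,
                                        stringsAsFactors = FALSE),
                config = cfg)
  class(truth) <- "cohort_truth"
  list(cohort = cohort, truth = truth)
}

# phase switch errors: for affected (child, locus) draws, swap the child's
# two haplotypes from a random breakpoint of the block onward
apply_phase_switches <- function(panel, cfg, child_ids, chrom, center) {
  if (cfg$phase_switch_rate <= 0) return(panel)
  S <- length(center)
  rows <- match(child_ids, panel$samples)
  hit <- which(matrix(stats::rbinom(length(child_ids) * S, 1L,
                                    cfg$phase_switch_rate),
                      nrow = length(child_ids)) == 1L, arr.ind = TRUE)
  if (nrow(hit) == 0) return(panel)
  for (k in seq_len(nrow(hit))) {
    s <- hit[k, 2]
    cols <- which(panel$variants$chrom == chrom[s] &
                    abs(panel$variants$pos - center[s]) <= cfg$flank_span / 2 + 1)
    cols <- cols[order(panel$variants$pos[cols])]
    if (length(cols) < 2) next
    brk <- sample.int(length(cols) - 1L, 1L)
    swap_cols <- cols[(brk + 1L):length(cols)]
    r <- rows[hit[k, 1]]
    tmp <- panel$H1[r, swap_cols]
    panel$H1[r, swap_cols] <- panel$H2[r, swap_cols]
    panel$H2[r, swap_cols] <- tmp
  }
  panel
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("truth ledger: %d pairs x %d weight SNPs\n",
              length(x$pair_id), length(x$snp_id)))
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Thin wrapper over [simulate_cohort()] + [write_cohort()] producing the
#' VCF/TSV file set the loaders consume, plus the truth ledger.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param flip_fraction Fraction of variants written with REF/ALT in the
#'   opposite orientation to the weight table (genotype codes inverted), to
#'   exercise allele harmonization on read-back. Uses the current RNG stream.
#' @return Named vector of file paths, invisibly.
#' @export
simulate_cohort_files <- function(config, dir, flip_fraction = 0) {
  sim <- simulate_cohort(config)
  cohort <- sim$cohort
  if (flip_fraction > 0) {
    nv <- nrow(cohort$panel$variants)
    fl <- which(stats::runif(nv) < flip_fraction)
    for (j in fl) {
      cohort$panel$H1[, j] <- 1L - cohort$panel$H1[, j]
      cohort$panel$H2[, j] <- 1L - cohort$panel$H2[, j]
      tmp <- cohort$panel$variants$ref[j]
      cohort$panel$variants$ref[j] <- cohort$panel$variants$alt[j]
      cohort$panel$variants$alt[j] <- tmp
    }
  }
  write_cohort(cohort, dir, truth = sim$truth)
}
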