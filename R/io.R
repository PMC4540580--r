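#' Read a SNP weight table
#'
#' Reads the per-SNP effect sizes used to build the weighted genetic score.
#' The table is tab-separated with header columns `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `beta`, where `beta` is the per-allele
#' effect on the exposure (cm of adult height per effect allele).
#'
#' @param path Path to the tab-separated weight file.
#' @return A `data.frame` with one row per SNP, invariants checked
#'   (unique `snp_id` and `(chrom, pos)`, finite numeric `beta`,
#'   single-base alleles, effect != other).
#' @export
read_weight_table <- function(path) {
  w <- read_tsv_(path)
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(required, names(w))
  if (length(missing_cols) > 0)
    stop_("weight table missing columns: %s", paste(missing_cols, collapse = ", "))
  if (nrow(w) == 0) stop_("empty weight table: %s", path)
  w <- w[required]
  w$chrom <- as.character(w$chrom)
  w$snp_id <- as.character(w$snp_id)
  if (anyDuplicated(w$snp_id))
    stop_("duplicate snp_id in weight table: %s",
          paste(unique(w$snp_id[duplicated(w$snp_id)]), collapse = ", "))
  key <- paste(w$chrom, w$pos)
  if (anyDuplicated(key))
    stop_("duplicate (chrom, pos) in weight table: %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  w$beta <- suppressWarnings(as.numeric(w$beta))
  if (any(is.na(w$beta) | !is.finite(w$beta)))
    stop_("non-numeric or non-finite beta in weight table (rows %s)",
          paste(which(is.na(w$beta) | !is.finite(w$beta)), collapse = ", "))
  w$pos <- as.integer(w$pos)
  w$effect_allele <- toupper(as.character(w$effect_allele))
  w$other_allele <- toupper(as.character(w$other_allele))
  bases <- c("A", "C", "G", "T")
  if (!all(w$effect_allele %in% bases) || !all(w$other_allele %in% bases))
    stop_("alleles must be single bases A/C/G/T")
  if (any(w$effect_allele == w$other_allele))
    stop_("effect_allele equals other_allele for snp(s): %s",
          paste(w$snp_id[w$effect_allele == w$other_allele], collapse = ", "))
  message(sprintf("read %d weight SNPs from %s", nrow(w), path))
  w
}

#' Read a mother-child pair map
#'
#' @param path TSV with columns `pair_id`, `mother`, `child` (sample ids).
#' @return A `data.frame`; errors if any sample id appears in two pairs.
#' @export
read_pair_map <- function(path) {
  p <- read_tsv_(path)
  req <- c("pair_id", "mother", "child")
  if (!all(req %in% names(p))) stop_("pair map must have columns pair_id, mother, child")
  p <- p[req]
  for (col in req) p[[col]] <- as.character(p[[col]])
  if (anyDuplicated(p$pair_id)) stop_("duplicate pair_id in pair map")
  samples <- c(p$mother, p$child)
  if (anyDuplicated(samples))
    stop_("sample(s) appear in more than one pair: %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  p
}

#' Read a phenotype table
#'
#' Expects columns `pair_id`, `cohort`, `maternal_height` (cm),
#' `maternal_age` (years), `birth_weight` (g), `gestational_age` (days) and
#' `fetal_sex` (`male`/`female` or 0/1); optional `maternal_weight`,
#' `maternal_bmi`, `birth_length`, `preterm`. `preterm` is derived as
#' gestational age < 37 completed weeks (259 days) when absent, and checked
#' for consistency when present.
#'
#' @param path TSV path.
#' @return A `data.frame` with `fetal_sex` coded 0 = female, 1 = male and a
#'   logical `preterm` column.
#' @export
read_phenotypes <- function(path) {
  ph <- read_tsv_(path)
  req <- c("pair_id", "cohort", "maternal_height", "maternal_age",
           "birth_weight", "gestational_age", "fetal_sex")
  missing_cols <- setdiff(req, names(ph))
  if (length(missing_cols) > 0)
    stop_("phenotype table missing columns: %s", paste(missing_cols, collapse = ", "))
  ph$pair_id <- as.character(ph$pair_id)
  if (anyDuplicated(ph$pair_id)) stop_("duplicate pair_id in phenotype table")
  if (is.character(ph$fetal_sex)) {
    sx <- tolower(ph$fetal_sex)
    if (!all(sx %in% c("male", "female", NA))) stop_("fetal_sex must be male/female or 0/1")
    ph$fetal_sex <- as.integer(sx == "male")
  }
  if (any(!is.na(ph$gestational_age) & ph$gestational_age <= 0))
    stop_("gestational_age must be positive")
  preterm_derived <- ph$gestational_age < 37 * 7
  if ("preterm" %in% names(ph)) {
    pt <- as.logical(ph$preterm)
    bad <- which(!is.na(pt) & !is.na(preterm_derived) & pt != preterm_derived)
    if (length(bad) > 0)
      stop_("preterm flag inconsistent with gestational_age (<37 wk) for pair(s): %s",
            paste(ph$pair_id[bad], collapse = ", "))
    ph$preterm <- pt
  } else {
    ph$preterm <- preterm_derived
  }
  ph
}

#' Read phased haplotypes from a VCF file
#'
#' Parses a VCF (v4.2) with phased `GT` fields into a haplotype panel:
#' per-sample, per-variant pairs of 0/1 alleles coded as ALT-allele dosage
#' (recoded to effect-allele dosage later by [harmonize_alleles()]).
#' Heterozygous genotypes must be phased (`0|1`); unphased homozygotes are
#' accepted since their phase is immaterial. A missing genotype masks both
#' haplotypes.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param samples Optional character vector restricting the panel.
#' @return A `hap_panel`: list with `samples`, `variants` (snp_id, chrom,
#'   pos, ref, alt), and integer matrices `H1`, `H2` (samples x variants).
#' @export
read_haplotype_panel <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-variant file
  variants <- data.frame(
    snp_id = as.character(fix[, "ID"]),
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = toupper(as.character(fix[, "REF"])),
    alt = toupper(as.character(fix[, "ALT"])),
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")  # variants x samples
  if (!is.null(samples)) {
    absent <- setdiff(samples, colnames(gt))
    if (length(absent) > 0)
      stop_("sample(s) not present in VCF: %s", paste(absent, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  miss <- is.na(gt) | a1 == "." | a2 == "."
  het_unphased <- !miss & sep == "/" & a1 != a2
  if (any(het_unphased)) {
    i <- which(het_unphased, arr.ind = TRUE)[1, ]
    stop_("unphased heterozygous genotype at %s:%d (%s), sample %s",
          variants$chrom[i[1]], variants$pos[i[1]], variants$snp_id[i[1]],
          colnames(gt)[i[2]])
  }
  h1 <- suppressWarnings(matrix(as.integer(a1), nrow = nrow(gt)))
  h2 <- suppressWarnings(matrix(as.integer(a2), nrow = nrow(gt)))
  h1[miss] <- NA_integer_
  h2[miss] <- NA_integer_
  if (any(!is.na(h1) & h1 > 1) || any(!is.na(h2) & h2 > 1))
    stop_("only biallelic sites with allele codes 0/1 are supported")
  # orient as samples x variants
  H1 <- t(h1); H2 <- t(h2)
  rownames(H1) <- rownames(H2) <- colnames(gt)
  ord <- order(variants$chrom, variants$pos)
  panel <- list(samples = colnames(gt), variants = variants[ord, , drop = FALSE],
                H1 = H1[, ord, drop = FALSE], H2 = H2[, ord, drop = FALSE])
  rownames(panel$variants) <- NULL
  class(panel) <- "hap_panel"
  panel
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("haplotype panel: %d samples x %d variants (%d missing genotypes)\n",
              length(x$samples), nrow(x$variants), sum(is.na(x$H1))))
  invisible(x)
}

#' Harmonize weight-table alleles with a genotype panel
#'
#' Matches weight SNPs to panel variants by `(chrom, pos)` and recodes panel
#' haplotypes to effect-allele dosage. If the weight effect/other alleles
#' match the panel REF/ALT directly, ALT dosage is kept (flipped to
#' `1 - dosage` when the effect allele is the panel REF). If they match only
#' after strand complement, the same logic applies on the complemented
#' alleles. Strand-ambiguous SNPs (A/T or C/G) are dropped by default since
#' their orientation cannot be resolved without frequency information;
#' `keep_ambiguous = TRUE` retains them, trusting the reported strand.
#' Unmatched or allele-incompatible SNPs are dropped.
#'
#' Harmonizing an already harmonized cohort is the identity: after
#' harmonization the panel ALT allele equals the effect allele at every kept
#' SNP, so a second pass keeps everything unflipped.
#'
#' @param weights Weight table from [read_weight_table()].
#' @param panel A `hap_panel`.
#' @param keep_ambiguous Keep strand-ambiguous (A/T, C/G) SNPs? Default FALSE.
#' @return List with `weights` (kept rows, in panel variant order), `panel`
#'   (recoded; weight positions carry effect-allele dosage and non-weight
#'   variants are untouched), and `report` (one row per weight SNP: status
#'   `kept`, `kept_flipped`, `kept_strand`, `kept_strand_flipped`,
#'   `dropped_ambiguous`, `dropped_mismatch`, or `dropped_absent`).
#' @export
harmonize_alleles <- function(weights, panel, keep_ambiguous = FALSE) {
  stopifnot(inherits(panel, "hap_panel"))
  v <- panel$variants
  key_w <- paste(weights$chrom, weights$pos)
  key_v <- paste(v$chrom, v$pos)
  idx <- match(key_w, key_v)

  status <- character(nrow(weights))
  flip <- logical(nrow(weights))
  for (i in seq_len(nrow(weights))) {
    j <- idx[i]
    if (is.na(j)) { status[i] <- "dropped_absent"; next }
    ea <- weights$effect_allele[i]; oa <- weights$other_allele[i]
    ref <- v$ref[j]; alt <- v$alt[j]
    ambiguous <- is_ambiguous_pair(ea, oa)
    if (ambiguous && !keep_ambiguous) { status[i] <- "dropped_ambiguous"; next }
    if (ea == alt && oa == ref) {
      status[i] <- "kept"; flip[i] <- FALSE
    } else if (ea == ref && oa == alt) {
      status[i] <- "kept_flipped"; flip[i] <- TRUE
    } else if (!ambiguous && comp_allele(ea) == alt && comp_allele(oa) == ref) {
      status[i] <- "kept_strand"; flip[i] <- FALSE
    } else if (!ambiguous && comp_allele(ea) == ref && comp_allele(oa) == alt) {
      status[i] <- "kept_strand_flipped"; flip[i] <- TRUE
    } else {
      status[i] <- "dropped_mismatch"
    }
  }
  kept <- grepl("^kept", status)
  if (!any(kept)) stop_("no weight SNPs could be matched to the panel")

  report <- data.frame(snp_id = weights$snp_id, chrom = weights$chrom,
                       pos = weights$pos, status = status,
                       stringsAsFactors = FALSE)

  # recode haplotypes and variant alleles so ALT == effect allele at kept SNPs
  for (i in which(kept)) {
    j <- idx[i]
    if (flip[i]) {
      panel$H1[, j] <- 1L - panel$H1[, j]
      panel$H2[, j] <- 1L - panel$H2[, j]
      panel$variants$ref[j] <- weights$other_allele[i]
      panel$variants$alt[j] <- weights$effect_allele[i]
    } else {
      panel$variants$ref[j] <- weights$other_allele[i]
      panel$variants$alt[j] <- weights$effect_allele[i]
    }
  }
  w_kept <- weights[kept, , drop = FALSE]
  ord <- order(idx[kept])
  w_kept <- w_kept[ord, , drop = FALSE]
  rownames(w_kept) <- NULL
  list(weights = w_kept, panel = panel, report = report)
}

#' SNP-level quality-control filter
#'
#' Removes SNPs with low call rate, low minor allele frequency, or
#' significant deviation from Hardy-Weinberg equilibrium. Call rate is
#' computed over all samples; MAF and the exact HWE test use mothers only
#' (the unrelated stratum of a duo cohort) when a pair map is supplied.
#'
#' @param panel A `hap_panel`.
#' @param pairs Optional pair map (`data.frame` with `mother` column);
#'   restricts MAF/HWE to mothers.
#' @param call_rate_min Minimum genotype call rate per SNP (default 0.98).
#' @param maf_min Minimum minor allele frequency (default 0.03).
#' @param hwe_p_min Minimum exact HWE p-value (default 1e-4).
#' @return List with the filtered `panel` and a `report` data.frame (per-SNP
#'   call rate, MAF, HWE p and which filters failed).
#' @export
qc_filter <- function(panel, pairs = NULL, call_rate_min = 0.98,
                      maf_min = 0.03, hwe_p_min = 1e-4) {
  stopifnot(inherits(panel, "hap_panel"))
  for (th in c(call_rate_min, maf_min, hwe_p_min))
    if (!is.finite(th) || th < 0 || th > 1)
      stop_("QC thresholds must lie in [0, 1]")
  mothers <- if (!is.null(pairs)) intersect(pairs$mother, panel$samples) else panel$samples
  if (length(mothers) == 0) stop_("no mother samples found in panel")
  mi <- match(mothers, panel$samples)

  call_rate <- colMeans(!is.na(panel$H1))
  gm <- panel$H1[mi, , drop = FALSE] + panel$H2[mi, , drop = FALSE]
  af <- colMeans(gm, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  maf <- pmin(af, 1 - af)
  n_het <- colSums(gm == 1L, na.rm = TRUE)
  n_hom0 <- colSums(gm == 0L, na.rm = TRUE)
  n_hom2 <- colSums(gm == 2L, na.rm = TRUE)
  hwe_p <- vapply(seq_along(n_het), function(j)
    hwe_exact_test(n_het[j], n_hom0[j], n_hom2[j]), numeric(1))

  fail_call <- call_rate < call_rate_min
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- hwe_p < hwe_p_min
  fail <- fail_call | fail_maf | fail_hwe

  report <- data.frame(snp_id = panel$variants$snp_id,
                       chrom = panel$variants$chrom, pos = panel$variants$pos,
                       call_rate = call_rate, maf = maf, hwe_p = hwe_p,
                       fail_call_rate = fail_call, fail_maf = fail_maf,
                       fail_hwe = fail_hwe, removed = fail,
                       stringsAsFactors = FALSE)
  keep <- which(!fail)
  panel$variants <- panel$variants[keep, , drop = FALSE]
  rownames(panel$variants) <- NULL
  panel$H1 <- panel$H1[, keep, drop = FALSE]
  panel$H2 <- panel$H2[, keep, drop = FALSE]
  list(panel = panel, report = report)
}

#' Load and assemble a cohort for analysis
#'
#' Reads phased genotypes, phenotypes and the mother-child pair map,
#' harmonizes panel alleles to the weight table, optionally applies SNP QC,
#' and screens each pair for Mendelian inconsistencies (mother and child
#' opposite homozygotes) at the weight SNPs. Pairs whose inconsistency rate
#' exceeds `mendel_threshold` are flagged as probable non-maternal
#' relationships (they are flagged, not dropped).
#'
#' @param vcf_path Phased VCF with mother and child samples.
#' @param phenotype_path Phenotype TSV (see [read_phenotypes()]).
#' @param pairs_path Pair-map TSV (see [read_pair_map()]).
#' @param weights Weight table (`data.frame`) or path to one.
#' @param qc Apply [qc_filter()]? Default TRUE.
#' @param mendel_threshold Pair flag threshold on the fraction of weight SNPs
#'   with a Mendelian inconsistency (default 0.01).
#' @param keep_ambiguous Passed to [harmonize_alleles()].
#' @param ... Further arguments to [qc_filter()].
#' @return A `cohort_data` object: list with `panel` (harmonized, QC-passed),
#'   `weights` (kept rows aligned with the focal SNPs), `pheno`, `pairs`,
#'   `focal_idx` (panel column indices of weight SNPs) and `reports`.
#' @export
read_cohort <- function(vcf_path, phenotype_path, pairs_path, weights,
                        qc = TRUE, mendel_threshold = 0.01,
                        keep_ambiguous = FALSE, ...) {
  if (is.character(weights)) weights <- read_weight_table(weights)
  pairs <- read_pair_map(pairs_path)
  pheno <- read_phenotypes(phenotype_path)
  absent <- setdiff(pairs$pair_id, pheno$pair_id)
  if (length(absent) > 0)
    stop_("missing phenotype record(s) for pair(s): %s", paste(absent, collapse = ", "))
  panel <- read_haplotype_panel(vcf_path, samples = c(pairs$mother, pairs$child))
  h <- harmonize_alleles(weights, panel, keep_ambiguous = keep_ambiguous)
  panel <- h$panel
  qc_report <- NULL
  if (qc) {
    q <- qc_filter(panel, pairs = pairs, ...)
    panel <- q$panel
    qc_report <- q$report
  }
  build_cohort(panel, h$weights, pheno, pairs,
               reports = list(harmonization = h$report, qc = qc_report),
               mendel_threshold = mendel_threshold)
}

# Assemble a cohort_data object from in-memory parts and run the Mendelian
# screen. Used by read_cohort() and by the simulator.
build_cohort <- function(panel, weights, pheno, pairs, reports = list(),
                         mendel_threshold = 0.01) {
  key_v <- paste(panel$variants$chrom, panel$variants$pos)
  focal_idx <- match(paste(weights$chrom, weights$pos), key_v)
  keep_w <- !is.na(focal_idx)
  weights <- weights[keep_w, , drop = FALSE]
  focal_idx <- focal_idx[keep_w]
  if (length(focal_idx) == 0) stop_("no weight SNPs remain after QC")
  rownames(weights) <- NULL

  mi <- match(pairs$mother, panel$samples)
  ci <- match(pairs$child, panel$samples)
  if (anyNA(mi) || anyNA(ci))
    stop_("pair map references sample(s) absent from the genotype panel: %s",
          paste(c(pairs$mother[is.na(mi)], pairs$child[is.na(ci)]), collapse = ", "))
  gm <- panel$H1[mi, focal_idx, drop = FALSE] + panel$H2[mi, focal_idx, drop = FALSE]
  gc <- panel$H1[ci, focal_idx, drop = FALSE] + panel$H2[ci, focal_idx, drop = FALSE]
  inconsistent <- (gm == 0L & gc == 2L) | (gm == 2L & gc == 0L)
  n_checked <- rowSums(!is.na(inconsistent))
  rate <- rowSums(inconsistent, na.rm = TRUE) / pmax(n_checked, 1L)
  mendel <- data.frame(pair_id = pairs$pair_id, n_checked = n_checked,
                       mendel_rate = rate, flagged = rate > mendel_threshold,
                       stringsAsFactors = FALSE)

  pheno <- pheno[match(pairs$pair_id, pheno$pair_id), , drop = FALSE]
  rownames(pheno) <- NULL
  reports$mendel <- mendel
  x <- list(panel = panel, weights = weights, pheno = pheno, pairs = pairs,
            focal_idx = focal_idx, reports = reports)
  class(x) <- "cohort_data"
  x
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort of %d mother/child pairs, %d weight SNPs (%d panel variants)\n",
              nrow(x$pairs), length(x$focal_idx), nrow(x$panel$variants)))
  if (!is.null(x$reports$mendel) && any(x$reports$mendel$flagged))
    cat(sprintf("  %d pair(s) flagged for Mendelian inconsistency\n",
                sum(x$reports$mendel$flagged)))
  invisible(x)
}

# ---- writers -----------------------------------------------------------

#' Write a haplotype panel as a phased VCF
#'
#' Minimal VCF v4.2 writer for the panel dialect this package reads back:
#' one GT FORMAT field, phased `a|b` genotypes, `.|.` for missing.
#'
#' @param panel A `hap_panel` (allele codes are ALT dosage).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "hap_panel"))
  v <- panel$variants
  n_var <- nrow(v)
  gt <- matrix("", nrow = n_var, ncol = length(panel$samples))
  a1 <- t(panel$H1); a2 <- t(panel$H2)
  gt[] <- paste0(a1, "|", a2)
  gt[is.na(a1)] <- ".|."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  fixed <- paste(v$chrom, v$pos, v$snp_id, v$ref, v$alt, ".", ".", ".", "GT",
                 sep = "\t")
  body <- do.call(paste, c(list(fixed), asplit(gt, 2), list(sep = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a cohort (and optional truth ledger) to disk
#'
#' Emits the file set [read_cohort()] consumes: `genotypes.vcf`,
#' `phenotypes.tsv`, `pairs.tsv`, `weights.tsv`, plus
#' `truth_transmission.tsv` and `truth_scores.tsv` when a truth ledger from
#' [simulate_cohort()] is given.
#'
#' @param cohort A `cohort_data` object.
#' @param dir Output directory (created if needed).
#' @param truth Optional `cohort_truth` object.
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             pheno = file.path(dir, "phenotypes.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             weights = file.path(dir, "weights.tsv"))
  write_panel_vcf(cohort$panel, paths["vcf"])
  pheno <- cohort$pheno
  pheno$fetal_sex <- ifelse(pheno$fetal_sex == 1, "male", "female")
  write_tsv_(pheno, paths["pheno"])
  write_tsv_(cohort$pairs, paths["pairs"])
  write_tsv_(cohort$weights, paths["weights"])
  if (!is.null(truth)) {
    paths["truth_transmission"] <- file.path(dir, "truth_transmission.tsv")
    paths["truth_scores"] <- file.path(dir, "truth_scores.tsv")
    tt <- data.frame(
      pair_id = rep(truth$pair_id, times = ncol(truth$transmitted)),
      snp_id = rep(colnames(truth$transmitted), each = length(truth$pair_id)),
      transmitted = as.vector(truth$transmitted),
      nontransmitted = as.vector(truth$nontransmitted),
      paternal = as.vector(truth$paternal),
      maternal_child_slot = as.vector(truth$maternal_child_slot),
      stringsAsFactors = FALSE)
    write_tsv_(tt, paths["truth_transmission"])
    write_tsv_(truth$scores, paths["truth_scores"])
  }
  invisible(paths)
}
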