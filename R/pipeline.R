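#' Run the full per-cohort and meta analysis from one configuration
#'
#' Orchestrates, per cohort: load (or accept in-memory) data, SNP QC and
#' allele harmonization, transmission inference, score construction, the
#' observational and score association tables, the single-SNP scan, and the
#' four-method IV analysis; then combines cohorts by fixed-effect
#' meta-analysis. Emits a bundle of tidy tables (observational associations;
#' score-exposure association with incremental r2; genotype-score and
#' haplotype-score outcome associations; score correlations; IV results;
#' scan diagnostics) plus a manifest recording the seed, per-stage record
#' counts and checksums of every written file.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `cohorts` (named list; each entry either paths `vcf`, `phenotypes`,
#'   `pairs`, or a `simulate` block of [sim_config()] arguments), `weights`
#'   (path, for file-based cohorts), `out_dir` (optional; tables are written
#'   as TSV when set), `seed`, `analyses` (subset of `observational`,
#'   `score_exposure`, `genotype_scores`, `haplotype_scores`,
#'   `correlations`, `iv`, `scan`), and threshold overrides (`call_rate_min`,
#'   `maf_min`, `hwe_p_min`, `mendel_threshold`, `max_unresolved_frac`,
#'   `max_window`, `weak_f`).
#' @param cohorts Optional named list of pre-built `cohort_data` objects
#'   (overrides `config$cohorts`).
#' @return Invisibly, a list of result tables and the manifest.
#' @export
run_pipeline <- function(config, cohorts = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  all_analyses <- c("observational", "score_exposure", "genotype_scores",
                    "haplotype_scores", "correlations", "iv", "scan")
  analyses <- config$analyses %||% all_analyses
  bad <- setdiff(analyses, all_analyses)
  if (length(bad) > 0) stop_("unknown analysis toggle(s): %s", paste(bad, collapse = ", "))
  seed <- config$seed %||% NA_integer_
  if (!is.na(seed)) set.seed(seed)
  out_dir <- config$out_dir
  log_msg <- function(...) message(sprintf(...))

  # ---- load cohorts ----
  if (is.null(cohorts)) {
    if (is.null(config$cohorts) || length(config$cohorts) == 0)
      stop_("no cohorts configured")
    cohorts <- lapply(names(config$cohorts), function(nm) {
      entry <- config$cohorts[[nm]]
      if (!is.null(entry$simulate)) {
        log_msg("[%s] simulating cohort", nm)
        args <- entry$simulate
        sim <- simulate_cohort(do.call(sim_config, args))
        co <- sim$cohort
      } else {
        for (f in c("vcf", "phenotypes", "pairs"))
          if (is.null(entry[[f]]) || !file.exists(entry[[f]]))
            stop_("[%s] missing or nonexistent path for '%s'", nm, f)
        log_msg("[%s] loading cohort", nm)
        co <- read_cohort(entry$vcf, entry$phenotypes, entry$pairs,
                          weights = config$weights,
                          mendel_threshold = config$mendel_threshold %||% 0.01,
                          call_rate_min = config$call_rate_min %||% 0.98,
                          maf_min = config$maf_min %||% 0.03,
                          hwe_p_min = config$hwe_p_min %||% 1e-4)
      }
      co$pheno$cohort <- nm
      co
    })
    names(cohorts) <- names(config$cohorts)
  }

  counts <- data.frame(cohort = names(cohorts),
                       n_pairs = vapply(cohorts, function(co) nrow(co$pairs), 1L),
                       n_weight_snps = vapply(cohorts, function(co)
                         length(co$focal_idx), 1L),
                       n_pairs_mendel_flagged = vapply(cohorts, function(co)
                         sum(co$reports$mendel$flagged), 1L))

  tables <- list()
  outcomes <- config$outcomes %||% c("birth_length", "birth_weight", "gestational_age")

  per_cohort <- lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    log_msg("[%s] transmission inference (%d pairs x %d SNPs)",
            nm, nrow(co$pairs), length(co$focal_idx))
    calls <- infer_transmission(co, max_window = config$max_window %||% 1e6)
    scores <- haplotype_scores(co, calls,
                               max_unresolved_frac = config$max_unresolved_frac %||% 0.05)
    df <- analysis_frame(co, scores)
    avail <- outcomes[vapply(outcomes, function(o)
      o %in% names(df) && sum(!is.na(df[[o]])) > 10, logical(1))]
    res <- list(cohort = nm, calls = calls, scores = scores, frame = df)

    if ("observational" %in% analyses)
      res$observational <- do.call(rbind, lapply(avail, function(o)
        fit_linear(df, o, "maternal_height", cohort = nm)))
    if ("score_exposure" %in% analyses)
      res$score_exposure <- fit_linear(df, "maternal_height", "M",
                                       covariates = character(0), cohort = nm)
    if ("genotype_scores" %in% analyses)
      res$genotype_scores <- do.call(rbind, lapply(avail, function(o) rbind(
        fit_linear(df, o, "M", cohort = nm),
        fit_linear(df, o, "C", cohort = nm),
        transform(fit_linear(df, o, "M", covariates =
                               c(default_covariates(o), "C"), cohort = nm),
                  predictor = "M_adjusted_C"))))
    if ("haplotype_scores" %in% analyses)
      res$haplotype_scores <- do.call(rbind, lapply(avail, function(o)
        haplotype_score_associations(df, o)))
    if ("correlations" %in% analyses)
      res$correlations <- score_summary(scores)
    if ("iv" %in% analyses)
      res$iv <- do.call(rbind, lapply(avail, function(o)
        run_iv_methods(df, o, weak_f = config$weak_f %||% 10)))
    if ("scan" %in% analyses) {
      res$scan <- lapply(avail, function(o)
        single_snp_scan(co, o, subjects = "mothers"))
      names(res$scan) <- avail
    }
    res
  })
  names(per_cohort) <- names(cohorts)

  gather <- function(field) {
    parts <- Filter(Negate(is.null), lapply(per_cohort, `[[`, field))
    if (length(parts) == 0) NULL else do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }
  tables$observational <- gather("observational")
  tables$score_exposure <- gather("score_exposure")
  tables$genotype_scores <- gather("genotype_scores")
  tables$haplotype_scores <- gather("haplotype_scores")
  tables$iv <- gather("iv")
  if (!is.null(tables$observational))
    tables$observational_meta <- meta_all(tables$observational)
  if (!is.null(tables$score_exposure))
    tables$score_exposure_meta <- meta_all(tables$score_exposure)
  if (!is.null(tables$genotype_scores))
    tables$genotype_scores_meta <- meta_all(tables$genotype_scores)
  if (!is.null(tables$haplotype_scores))
    tables$haplotype_scores_meta <- meta_all(tables$haplotype_scores)
  if (!is.null(tables$iv))
    tables$iv_meta <- meta_all(tables$iv, by = c("outcome", "method"))
  if ("scan" %in% analyses) {
    tables$scan <- do.call(rbind, unlist(lapply(per_cohort, function(r)
      lapply(names(r$scan), function(o)
        data.frame(cohort = r$cohort, outcome = o, lambda = r$scan[[o]]$lambda,
                   rho_vs_weights = r$scan[[o]]$rho_vs_weights,
                   rho_p = r$scan[[o]]$rho_p, n = r$scan[[o]]$n,
                   stringsAsFactors = FALSE))), recursive = FALSE))
    rownames(tables$scan) <- NULL
  }
  if ("correlations" %in% analyses)
    tables$correlations <- lapply(per_cohort, `[[`, "correlations")

  manifest <- list(package_version = as.character(utils::packageVersion("nthmr")),
                   seed = seed, analyses = analyses,
                   skipped_analyses = setdiff(all_analyses, analyses),
                   counts = counts, files = list())

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table <- function(x, name) {
      if (is.null(x) || !is.data.frame(x)) return(NULL)
      p <- file.path(out_dir, paste0(name, ".tsv"))
      num <- vapply(x, is.numeric, logical(1))
      x[num] <- lapply(x[num], function(v) signif(v, 10))
      write_tsv_(x, p)
      p
    }
    written <- c(
      write_table(tables$observational, "associations_observational"),
      write_table(tables$observational_meta, "associations_observational_meta"),
      write_table(tables$score_exposure, "score_exposure"),
      write_table(tables$score_exposure_meta, "score_exposure_meta"),
      write_table(tables$genotype_scores, "genotype_score_associations"),
      write_table(tables$genotype_scores_meta, "genotype_score_associations_meta"),
      write_table(tables$haplotype_scores, "haplotype_score_associations"),
      write_table(tables$haplotype_scores_meta, "haplotype_score_associations_meta"),
      write_table(tables$iv, "iv_results"),
      write_table(tables$iv_meta, "iv_results_meta"),
      write_table(tables$scan, "scan_summary"))
    for (nm in names(per_cohort)) {
      written <- c(written,
                   write_table(as.data.frame(per_cohort[[nm]]$calls),
                               paste0("transmission_calls_", nm)),
                   write_table(as.data.frame(per_cohort[[nm]]$scores),
                               paste0("scores_", nm)))
      for (o in names(per_cohort[[nm]]$scan))
        written <- c(written, write_table(per_cohort[[nm]]$scan[[o]]$qq,
                                          paste0("qq_", nm, "_", o)))
    }
    manifest$files <- lapply(written, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(tables = tables, per_cohort = per_cohort, manifest = manifest))
}
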