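# shared fixtures, built in code

small_sim <- function(n_pairs = 300, n_snps = 20, flank_snps = 8, seed = 1, ...) {
  simulate_cohort(sim_config(n_pairs = n_pairs, n_snps = n_snps,
                             flank_snps = flank_snps, seed = seed, ...))
}

# configuration with every genetic and causal path switched off
null_config <- function(...) {
  sim_config(causal_ga_per_cm = 0, causal_bw_per_cm = 0, causal_bl_per_cm = 0,
             fetal_effect_ga = 0, fetal_effect_bw = 0, fetal_effect_bl = 0,
             assortative_r = 0, ...)
}

# build a hap_panel in code from explicit haplotype matrices
make_panel <- function(H1, H2, chrom = "1", pos = NULL, ref = NULL, alt = NULL,
                       samples = NULL) {
  nv <- ncol(H1)
  samples <- samples %||% sprintf("S%02d", seq_len(nrow(H1)))
  rownames(H1) <- rownames(H2) <- samples
  v <- data.frame(snp_id = sprintf("v%03d", seq_len(nv)),
                  chrom = rep_len(chrom, nv),
                  pos = pos %||% (seq_len(nv) * 1000L),
                  ref = ref %||% rep("G", nv), alt = alt %||% rep("A", nv),
                  stringsAsFactors = FALSE)
  p <- list(samples = samples, variants = v,
            H1 = matrix(as.integer(H1), nrow = nrow(H1),
                        dimnames = list(samples, NULL)),
            H2 = matrix(as.integer(H2), nrow = nrow(H2),
                        dimnames = list(samples, NULL)))
  class(p) <- "hap_panel"
  p
}

write_weight_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

weight_df <- function(n = 3, beta = NULL, chrom = "1", pos = NULL) {
  data.frame(snp_id = sprintf("rs%d", seq_len(n)), chrom = rep_len(chrom, n),
             pos = pos %||% (seq_len(n) * 1000L),
             effect_allele = rep("A", n), other_allele = rep("G", n),
             beta = beta %||% round(stats::rnorm(n, 0, 0.1), 4),
             stringsAsFactors = FALSE)
}
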