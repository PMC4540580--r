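#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

#' Read a tab-separated table with a header
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used for
#' every tabular input of the package (TSV, header, no factors, `NA` for
#' missing).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame`.
#' @keywords internal
read_tsv_ <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

write_tsv_ <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

# two-sided normal p-value from an estimate and its standard error
z_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# DNA complement for strand checks
comp_allele <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
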