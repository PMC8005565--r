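#' Bundled example dataset: hypothyroidism instruments and NAFLD outcomes
#'
#' Nine independent genome-wide-significant hypothyroidism variants
#' (exposure, log-odds scale) with their associations in a histology-based
#' non-alcoholic fatty liver disease GWAS (outcome), already harmonized to
#' a shared effect allele. This published instrument set is the package's
#' worked example: a fixed-effects IVW analysis of it gives an odds ratio
#' of about 1.76 for NAFLD per unit log-odds of hypothyroidism.
#'
#' @param what `"pairs"` (default) returns the harmonized pairs used by the
#'   estimators; `"table"` returns the raw bundled table including
#'   chromosome and position.
#' @return `mr_harmonized` data frame of nine SNPs (with extra `chrom` and
#'   `pos` columns), or the raw data frame.
#' @export
#' @examples
#' pairs <- hypothyroidism_nafld()
#' nrow(pairs)
#' mr_ivw(pairs)
hypothyroidism_nafld <- function(what = c("pairs", "table")) {
  what <- match.arg(what)
  path <- system.file("extdata", "hypothyroidism_nafld.tsv",
                      package = "mrkit", mustWork = TRUE)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (what == "table") return(raw)
  out <- mr_pairs(
    snp_id = raw$SNP,
    beta_exposure = raw$beta.exposure, se_exposure = raw$se.exposure,
    beta_outcome = raw$beta.outcome, se_outcome = raw$se.outcome,
    pval_exposure = raw$pval.exposure, pval_outcome = raw$pval.outcome
  )
  out$chrom <- as.character(raw$CHR)
  out$pos <- as.integer(raw$Pos)
  out
}
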