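# Synthetic two-sample GWAS summary statistics with known causal effect
# and pleiotropy structure, for estimator validation.

#' Configuration for a synthetic two-sample MR study
#'
#' Validates and assembles the generator settings. The defaults mirror a
#' small, well-powered binary-trait study: nine instruments with absolute
#' exposure effects between 0.11 and 0.28 log-odds, exposure standard
#' errors around 0.025, outcome standard errors around 0.09, a true causal
#' effect of 0.564 log-odds per exposure unit, and no pleiotropy.
#'
#' Per-SNP direct (pleiotropic) effects `alpha_j` are defined on the
#' exposure-increasing allele: "directional" pleiotropy means the direct
#' effects share a sign relative to the allele that raises the exposure,
#' which is what biases IVW upward and what the MR-Egger intercept
#' estimates. `pleiotropy_prop` controls the fraction of instruments
#' carrying a direct effect (1 = all). With `inside_violation = TRUE` the
#' direct effects are correlated with instrument strength (correlation
#' 0.7), violating the InSIDE assumption that MR-Egger relies on.
#'
#' @param n_snps number of instruments (>= 3).
#' @param causal_effect true causal effect, log-odds of outcome per unit
#'   exposure.
#' @param exposure_effect_range interval for the absolute true exposure
#'   effects; signs are random.
#' @param se_exposure_scale,se_outcome_scale per-SNP standard errors of the
#'   exposure and outcome associations (> 0).
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct
#'   effects) or `"directional"` (non-zero mean).
#' @param pleiotropy_mean mean direct effect (directional mode).
#' @param pleiotropy_sd spread of the direct effects (>= 0).
#' @param pleiotropy_prop fraction of instruments with a direct effect.
#' @param inside_violation correlate direct effects with instrument
#'   strength.
#' @param seed RNG seed for [generate_study()]; `NULL` uses the current
#'   RNG state.
#' @return list of class `mr_synth_config`.
#' @export
synth_config <- function(n_snps = 9,
                         causal_effect = 0.564,
                         exposure_effect_range = c(0.11, 0.28),
                         se_exposure_scale = 0.025,
                         se_outcome_scale = 0.09,
                         pleiotropy_mode = c("none", "balanced",
                                             "directional"),
                         pleiotropy_mean = 0,
                         pleiotropy_sd = 0,
                         pleiotropy_prop = 1,
                         inside_violation = FALSE,
                         seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!is.numeric(n_snps) || n_snps < 3) {
    mr_config_error("n_snps must be at least 3")
  }
  if (length(exposure_effect_range) != 2 ||
      any(exposure_effect_range <= 0) || diff(exposure_effect_range) < 0) {
    mr_config_error(
      "exposure_effect_range must be an increasing positive interval")
  }
  if (se_exposure_scale <= 0 || se_outcome_scale <= 0) {
    mr_config_error("standard-error scales must be positive")
  }
  if (pleiotropy_sd < 0) mr_config_error("pleiotropy_sd must be >= 0")
  if (pleiotropy_prop < 0 || pleiotropy_prop > 1) {
    mr_config_error("pleiotropy_prop must lie in [0, 1]")
  }
  if (pleiotropy_mode == "none" &&
      (pleiotropy_mean != 0 || pleiotropy_sd != 0)) {
    mr_config_error(
      "pleiotropy_mode 'none' is incompatible with non-zero pleiotropy parameters")
  }
  if (pleiotropy_mode == "balanced" && pleiotropy_mean != 0) {
    mr_config_error("balanced pleiotropy requires pleiotropy_mean = 0")
  }
  out <- list(
    n_snps = as.integer(n_snps), causal_effect = causal_effect,
    exposure_effect_range = exposure_effect_range,
    se_exposure_scale = se_exposure_scale,
    se_outcome_scale = se_outcome_scale,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_prop = pleiotropy_prop,
    inside_violation = inside_violation, seed = seed
  )
  class(out) <- "mr_synth_config"
  out
}

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T")
)

#' Generate a synthetic two-sample MR study
#'
#' Realizes the summary-data generating model: true exposure effects
#' `bx_j` drawn uniformly from `exposure_effect_range` with random signs;
#' observed exposure effects `bx_j + N(0, se_exposure)`; outcome effects
#' `theta * bx_j + sign(bx_j) * alpha_j + N(0, se_outcome)`, where
#' `alpha_j` is the per-SNP direct effect coded on the exposure-increasing
#' allele (see [synth_config()]). Alleles are assigned avoiding
#' palindromic pairs, frequencies drawn uniformly on (0.05, 0.95) and
#' shared between the two studies, and p-values computed from the normal
#' approximation. Positions are spaced > 10 Mb apart along chromosomes
#' 1–22 so the instruments survive default clumping.
#'
#' @param config a [synth_config()] object.
#' @return list of class `mr_synthetic`: `exposure` and `outcome`
#'   (`mr_summary` tables sharing SNP ids and alleles) and `truth` (list
#'   with `causal_effect`, `alpha`, `beta_x_true`).
#' @export
#' @examples
#' study <- generate_study(synth_config(n_snps = 20, seed = 7))
#' head(study$exposure)
#' study$truth$causal_effect
generate_study <- function(config) {
  if (!inherits(config, "mr_synth_config")) {
    mr_config_error("config must come from synth_config()")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_snps

  bx_true <- runif(n, config$exposure_effect_range[1],
                   config$exposure_effect_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)

  alpha <- numeric(n)
  if (config$pleiotropy_mode != "none") {
    k <- round(config$pleiotropy_prop * n)
    idx <- if (k > 0) sample.int(n, k) else integer(0)
    base <- config$pleiotropy_mean +
      config$pleiotropy_sd * rnorm(length(idx))
    if (config$inside_violation && length(idx) > 1 &&
        config$pleiotropy_sd > 0) {
      # mix in standardized instrument strength at correlation 0.7
      strength <- abs(bx_true[idx])
      z <- (strength - mean(strength)) / max(sd(strength), 1e-12)
      base <- config$pleiotropy_mean + config$pleiotropy_sd *
        (0.7 * z + sqrt(1 - 0.7^2) * rnorm(length(idx)))
    }
    alpha[idx] <- base
  }

  se_x <- rep(config$se_exposure_scale, n)
  se_y <- rep(config$se_outcome_scale, n)
  bx_obs <- bx_true + rnorm(n, 0, se_x)
  by_obs <- config$causal_effect * bx_true + sign(bx_true) * alpha +
    rnorm(n, 0, se_y)

  pair_idx <- sample.int(nrow(NON_PALINDROMIC_PAIRS), n, replace = TRUE)
  ea <- NON_PALINDROMIC_PAIRS[pair_idx, 1]
  oa <- NON_PALINDROMIC_PAIRS[pair_idx, 2]
  eaf <- runif(n, 0.05, 0.95)
  chrom <- as.character(rep_len(1:22, n))
  pos <- 1000000L + (seq_len(n) - 1L) %/% 22L * 20000000L
  snp_id <- sprintf("snp%04d", seq_len(n))

  mk <- function(beta, se) {
    # floor the normal tail so extreme z-scores keep pval inside (0, 1]
    pval <- pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
    mr_summary(snp_id = snp_id, beta = beta, se = se, pval = pval,
               chrom = chrom, pos = pos,
               effect_allele = ea, other_allele = oa, eaf = eaf)
  }
  out <- list(
    exposure = mk(bx_obs, se_x),
    outcome = mk(by_obs, se_y),
    truth = list(causal_effect = config$causal_effect, alpha = alpha,
                 beta_x_true = bx_true)
  )
  class(out) <- "mr_synthetic"
  out
}

#' Harmonized pairs from a synthetic study
#'
#' Convenience shortcut: a synthetic study's exposure and outcome tables
#' already share effect alleles, so the harmonized pairs are a direct join.
#'
#' @param study a `mr_synthetic` object.
#' @return `mr_harmonized` data frame.
#' @export
synthetic_pairs <- function(study) {
  mr_pairs(
    snp_id = study$exposure$snp_id,
    beta_exposure = study$exposure$beta,
    se_exposure = study$exposure$se,
    beta_outcome = study$outcome$beta,
    se_outcome = study$outcome$se,
    pval_exposure = study$exposure$pval,
    pval_outcome = study$outcome$pval
  )
}
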