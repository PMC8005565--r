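# Causal-effect estimators for two-sample MR on harmonized summary data.
#
# All estimators consume a `mr_harmonized` data frame (see mr_pairs()) and
# return a one-row `mr_estimate` data frame on the log-odds scale, with the
# odds-ratio columns derived by exponentiation.

CI_Z <- 1.96  # normal-theory 95% interval multiplier used throughout

# Internal constructor: CI, p and OR columns from (beta, se).
# df = Inf -> normal reference; finite df -> t distribution (MR-Egger).
new_mr_estimate <- function(method, beta, se, n_snps, df = Inf) {
  if (!is.finite(se) || se <= 0) {
    mr_analysis_error(sprintf("%s: standard error is not positive", method))
  }
  crit <- if (is.finite(df)) stats::qt(0.975, df) else CI_Z
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  pval <- if (is.finite(df)) 2 * pt(-abs(beta / se), df)
          else 2 * pnorm(-abs(beta / se))
  out <- data.frame(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high, pval = pval,
    odds_ratio = exp(beta), ci_or_low = exp(ci_low),
    ci_or_high = exp(ci_high), n_snps = n_snps,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_estimate", "data.frame")
  out
}

check_pairs <- function(pairs, min_n, method) {
  if (!inherits(pairs, "data.frame") ||
      !all(c("beta_exposure", "se_exposure", "beta_outcome",
             "se_outcome") %in% names(pairs))) {
    mr_config_error("pairs must be a harmonized data frame (see mr_pairs())")
  }
  if (nrow(pairs) < min_n) {
    mr_analysis_error(sprintf(
      "%s requires at least %d instruments, got %d",
      method, min_n, nrow(pairs)))
  }
  if (min_n >= 2 && any(pairs$beta_exposure == 0)) {
    mr_analysis_error(sprintf("%s: zero exposure effect for %s", method,
      paste(pairs$snp_id[pairs$beta_exposure == 0], collapse = ", ")))
  }
  invisible(pairs)
}

wald_ratios <- function(pairs) pairs$beta_outcome / pairs$beta_exposure

# inverse variance of the first-order Wald ratio: bx^2 / sy^2
ratio_weights <- function(pairs) pairs$beta_exposure^2 / pairs$se_outcome^2

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate: outcome effect divided by exposure effect,
#' with the first-order standard error `se_outcome / |beta_exposure|`
#' (exposure-side uncertainty ignored, the usual strong-instrument
#' approximation).
#'
#' @param pair a one-row harmonized data frame ([mr_pairs()]).
#' @return one-row `mr_estimate` (method `"wald"`).
#' @export
mr_wald_ratio <- function(pair) {
  check_pairs(pair, 1, "wald_ratio")
  if (nrow(pair) != 1) {
    mr_config_error("mr_wald_ratio expects exactly one instrument")
  }
  if (pair$beta_exposure == 0) {
    mr_analysis_error(sprintf("wald_ratio undefined: beta_exposure = 0 (%s)",
                              pair$snp_id))
  }
  new_mr_estimate("wald", pair$beta_outcome / pair$beta_exposure,
                  pair$se_outcome / abs(pair$beta_exposure), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Combines the per-SNP Wald ratios with inverse-variance weights
#' `beta_exposure^2 / se_outcome^2`; algebraically this is the weighted
#' regression of the outcome effects on the exposure effects through the
#' origin. The fixed-effects standard error is
#' `sqrt(1 / sum(beta_exposure^2 / se_outcome^2))`; under
#' `effects_model = "random"` the standard error is inflated by
#' `max(1, sqrt(Q / (n - 2)))`, where Q is Cochran's Q at the fixed-effects
#' estimate — the point estimate is identical between the two models.
#'
#' @param pairs harmonized data frame with at least two instruments.
#' @param effects_model `"fixed"` (default) or `"random"`.
#' @return one-row `mr_estimate` (method `"ivw_fixed"` or `"ivw_random"`).
#' @export
#' @examples
#' mr_ivw(hypothyroidism_nafld())
mr_ivw <- function(pairs, effects_model = c("fixed", "random")) {
  effects_model <- match.arg(effects_model)
  check_pairs(pairs, 2, "ivw")
  w <- ratio_weights(pairs)
  r <- wald_ratios(pairs)
  beta <- sum(w * r) / sum(w)
  se <- sqrt(1 / sum(w))
  if (effects_model == "random") {
    q <- sum(w * (r - beta)^2)
    se <- se * max(1, sqrt(q / (nrow(pairs) - 2)))
  }
  new_mr_estimate(paste0("ivw_", effects_model), beta, se, nrow(pairs))
}

# Parametric bootstrap se for median-type estimators: resample both effect
# sizes from their sampling distributions and recompute the point estimate.
bootstrap_se <- function(pairs, point_fn, n_boot = 1000, seed = 42) {
  est <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      p2 <- pairs
      p2$beta_exposure <- rnorm(nrow(pairs), pairs$beta_exposure,
                                pairs$se_exposure)
      p2$beta_outcome <- rnorm(nrow(pairs), pairs$beta_outcome,
                               pairs$se_outcome)
      point_fn(p2)
    }, numeric(1))
  })
  sd(est)
}

#' Simple (unweighted) median estimate
#'
#' The median of the per-SNP Wald ratios; consistent when at least half the
#' instruments are valid. The standard error comes from a parametric
#' bootstrap (both effect sizes resampled from their sampling
#' distributions).
#'
#' @param pairs harmonized data frame with at least three instruments.
#' @param n_boot bootstrap replicates for the standard error (default 1000).
#' @param seed bootstrap seed (default 42); the caller's RNG stream is left
#'   untouched.
#' @return one-row `mr_estimate` (method `"simple_median"`).
#' @export
mr_simple_median <- function(pairs, n_boot = 1000, seed = 42) {
  check_pairs(pairs, 3, "simple_median")
  point <- function(p) median(wald_ratios(p))
  new_mr_estimate("simple_median", point(pairs),
                  bootstrap_se(pairs, point, n_boot, seed), nrow(pairs))
}

# Weighted median of x with weights w: interpolate x (sorted) against the
# standardized mid-cumulative weights s_j = (cum_j - w_j/2) / sum(w) at 0.5.
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  approx(s, x, xout = 0.5, ties = "ordered")$y
}

# Heterogeneity penalty factors min(1, 20 * p_j): p_j is the upper chi^2(1)
# tail of SNP j's Q contribution at the (unpenalized) IVW estimate. SNPs
# consistent with the pooled estimate keep their weight; outliers shrink.
penalty_factors <- function(pairs, k = 20) {
  w <- ratio_weights(pairs)
  r <- wald_ratios(pairs)
  theta <- sum(w * r) / sum(w)
  q_j <- w * (r - theta)^2
  pmin(1, k * pchisq(q_j, df = 1, lower.tail = FALSE))
}

#' Weighted median estimate (optionally penalized)
#'
#' The Wald ratio at the 50% point of the weight distribution over the
#' sorted per-SNP ratios, with inverse-variance weights
#' `beta_exposure^2 / se_outcome^2` by default; consistent when valid
#' instruments carry at least half the total weight. With
#' `penalized = TRUE` each weight is first multiplied by
#' `min(1, 20 p_j)`, where `p_j` is the upper chi-squared(1) tail
#' probability of that SNP's heterogeneity contribution at the IVW
#' estimate, down-weighting outlying instruments. Standard error by
#' parametric bootstrap (weights and penalties recomputed per replicate).
#'
#' @param pairs harmonized data frame with at least three instruments.
#' @param weights optional user weights (default inverse-variance).
#' @param penalized apply heterogeneity penalization (default `FALSE`).
#' @param penalty_k penalty multiplier (default 20).
#' @param n_boot,seed bootstrap controls as in [mr_simple_median()].
#' @return one-row `mr_estimate` (method `"weighted_median"` or
#'   `"penalized_weighted_median"`).
#' @export
mr_weighted_median <- function(pairs, weights = NULL, penalized = FALSE,
                               penalty_k = 20, n_boot = 1000, seed = 42) {
  check_pairs(pairs, 3, "weighted_median")
  point <- function(p) {
    w <- if (is.null(weights)) ratio_weights(p) else weights
    if (penalized) w <- w * penalty_factors(p, penalty_k)
    weighted_median_point(wald_ratios(p), w)
  }
  method <- if (penalized) "penalized_weighted_median" else "weighted_median"
  new_mr_estimate(method, point(pairs),
                  bootstrap_se(pairs, point, n_boot, seed), nrow(pairs))
}

#' Penalized IVW estimate
#'
#' IVW with each inverse-variance weight multiplied by the heterogeneity
#' penalty `min(1, 20 p_j)` (see [mr_weighted_median()]); identical to
#' plain IVW when no instrument is penalized.
#'
#' @param pairs harmonized data frame with at least two instruments.
#' @param penalty_k penalty multiplier (default 20).
#' @return one-row `mr_estimate` (method `"penalized_ivw"`).
#' @export
mr_penalized_ivw <- function(pairs, penalty_k = 20) {
  check_pairs(pairs, 2, "penalized_ivw")
  w <- ratio_weights(pairs) * penalty_factors(pairs, penalty_k)
  r <- wald_ratios(pairs)
  beta <- sum(w * r) / sum(w)
  new_mr_estimate("penalized_ivw", beta, sqrt(1 / sum(w)), nrow(pairs))
}

#' Robust IVW estimate (MM-estimation)
#'
#' Robust weighted regression of the outcome effects on the exposure
#' effects through the origin, weights `1 / se_outcome^2`, by MM-estimation
#' with Tukey's bisquare psi (tuning constant 4.685) started from a
#' high-breakdown S-estimate, as implemented by [MASS::rlm()]. With
#' `penalized = TRUE` the weights are heterogeneity-penalized first. The
#' stochastic S-estimate search runs under a fixed internal seed so the fit
#' is reproducible.
#'
#' @param pairs harmonized data frame with at least three instruments.
#' @param penalized apply heterogeneity penalization to the weights.
#' @param penalty_k penalty multiplier (default 20).
#' @param maxit,acc iteration cap and convergence tolerance of the IWLS
#'   refinement (defaults 500 and 1e-7).
#' @return one-row `mr_estimate` (method `"robust_ivw"` or
#'   `"penalized_robust_ivw"`).
#' @export
mr_robust_ivw <- function(pairs, penalized = FALSE, penalty_k = 20,
                          maxit = 500, acc = 1e-7) {
  check_pairs(pairs, 3, "robust_ivw")
  w <- 1 / pairs$se_outcome^2
  if (penalized) w <- w * penalty_factors(pairs, penalty_k)
  method <- if (penalized) "penalized_robust_ivw" else "robust_ivw"
  # an (almost) exact linear relation leaves the MM scale estimate
  # degenerate; the weighted LS fit is already the robust optimum there
  wls <- lm(pairs$beta_outcome ~ pairs$beta_exposure - 1, weights = w)
  if (max(abs(resid(wls))) <= 1e-8 * max(abs(pairs$beta_outcome), 1)) {
    se <- sqrt(1 / sum(w * pairs$beta_exposure^2))
    return(new_mr_estimate(method, unname(coef(wls)[1]), se, nrow(pairs)))
  }
  fit <- with_local_seed(1, MASS::rlm(
    pairs$beta_outcome ~ pairs$beta_exposure - 1, weights = w,
    method = "MM", psi = MASS::psi.bisquare, c = 4.685,
    maxit = maxit, acc = acc
  ))
  if (!fit$converged) {
    mr_analysis_error(sprintf(
      "%s: MM-estimation did not converge in %d iterations", method, maxit))
  }
  cf <- summary(fit)$coefficients
  new_mr_estimate(method, cf[1, "Value"], cf[1, "Std. Error"], nrow(pairs))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept, weights `1 / se_outcome^2`, after orienting every
#' instrument so its exposure effect is positive (both betas negated where
#' needed — the identifying convention for the intercept's sign). The slope
#' is the pleiotropy-adjusted causal estimate; the intercept estimates the
#' average direct (pleiotropic) effect per SNP. Standard errors use the
#' known-variance weighted fit inflated by `max(1, sqrt(RSS / (n - 2)))`
#' (multiplicative random effects); inference uses the t distribution with
#' n − 2 degrees of freedom.
#'
#' @param pairs harmonized data frame with at least three instruments.
#' @return object of class `mr_egger_result`: list with `slope` (a
#'   `mr_estimate`, method `"egger_slope"`), `intercept`, `intercept_se`,
#'   `intercept_ci_low`, `intercept_ci_high`, `intercept_pval`, `n_snps`.
#' @export
#' @examples
#' mr_egger(hypothyroidism_nafld())
mr_egger <- function(pairs) {
  check_pairs(pairs, 3, "egger")
  flip <- sign(pairs$beta_exposure)
  bx <- pairs$beta_exposure * flip
  by <- pairs$beta_outcome * flip
  w <- 1 / pairs$se_outcome^2
  n <- nrow(pairs)
  fit <- lm(by ~ bx, weights = w)
  # dispersion floored at 1: se cannot fall below the known-variance WLS se
  sigma2 <- sum(w * resid(fit)^2) / (n - 2)
  infl <- max(1, sqrt(sigma2))
  vc_unscaled <- vcov(fit) / summary(fit)$sigma^2
  ses <- sqrt(diag(vc_unscaled)) * infl
  est <- coef(fit)
  slope <- new_mr_estimate("egger_slope", est[["bx"]], ses[["bx"]], n,
                           df = n - 2)
  tcrit <- stats::qt(0.975, n - 2)
  out <- list(
    slope = slope,
    intercept = est[["(Intercept)"]],
    intercept_se = ses[["(Intercept)"]],
    intercept_ci_low = est[["(Intercept)"]] - tcrit * ses[["(Intercept)"]],
    intercept_ci_high = est[["(Intercept)"]] + tcrit * ses[["(Intercept)"]],
    intercept_pval = 2 * pt(-abs(est[["(Intercept)"]] / ses[["(Intercept)"]]),
                            n - 2),
    n_snps = n
  )
  class(out) <- "mr_egger_result"
  out
}

MR_METHODS <- c("ivw_fixed", "ivw_random", "simple_median", "weighted_median",
                "penalized_weighted_median", "penalized_ivw", "robust_ivw",
                "penalized_robust_ivw", "egger")

# Dispatch a method label to its estimator; egger contributes its slope row.
estimate_by_label <- function(pairs, method, n_boot = 1000, seed = 42) {
  switch(method,
    ivw_fixed = mr_ivw(pairs, "fixed"),
    ivw_random = mr_ivw(pairs, "random"),
    simple_median = mr_simple_median(pairs, n_boot = n_boot, seed = seed),
    weighted_median = mr_weighted_median(pairs, n_boot = n_boot, seed = seed),
    penalized_weighted_median = mr_weighted_median(
      pairs, penalized = TRUE, n_boot = n_boot, seed = seed),
    penalized_ivw = mr_penalized_ivw(pairs),
    robust_ivw = mr_robust_ivw(pairs),
    penalized_robust_ivw = mr_robust_ivw(pairs, penalized = TRUE),
    egger = mr_egger(pairs)$slope,
    mr_config_error(paste0("unknown estimator label: ", method))
  )
}

#' Run a set of MR estimators
#'
#' Applies each requested estimator to the same harmonized pairs and stacks
#' the results into one table (for MR-Egger, the slope; the intercept is
#' attached as attribute `"egger_intercept"`).
#'
#' @param pairs harmonized data frame.
#' @param methods estimator labels, a subset of
#'   `c("ivw_fixed", "ivw_random", "simple_median", "weighted_median",
#'   "penalized_weighted_median", "penalized_ivw", "robust_ivw",
#'   "penalized_robust_ivw", "egger")` (default: all).
#' @param n_boot,seed bootstrap controls for the median-type estimators.
#' @return `mr_estimate` data frame, one row per method.
#' @export
#' @examples
#' mr_all_methods(hypothyroidism_nafld(),
#'                methods = c("ivw_fixed", "simple_median"), n_boot = 200)
mr_all_methods <- function(pairs, methods = MR_METHODS, n_boot = 1000,
                           seed = 42) {
  if (!length(methods)) mr_config_error("methods must be non-empty")
  bad <- setdiff(methods, MR_METHODS)
  if (length(bad)) {
    mr_config_error(paste0("unknown estimator label(s): ",
                           paste(bad, collapse = ", ")))
  }
  rows <- lapply(methods, estimate_by_label, pairs = pairs,
                 n_boot = n_boot, seed = seed)
  out <- do.call(rbind, rows)
  class(out) <- c("mr_estimate", "data.frame")
  if ("egger" %in% methods) {
    attr(out, "egger_intercept") <- mr_egger(pairs)[
      c("intercept", "intercept_se", "intercept_pval")]
  }
  out
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat("Two-sample MR estimate(s) [log-odds scale]\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.mr_egger_result <- function(x, digits = 4, ...) {
  cat("MR-Egger regression (", x$n_snps, " instruments)\n", sep = "")
  cat("slope:\n")
  print(x$slope, digits = digits)
  cat(sprintf("intercept: %.*g (se %.*g, p = %.*g)\n", digits, x$intercept,
              digits, x$intercept_se, digits, x$intercept_pval))
  invisible(x)
}
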