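# Heterogeneity, sensitivity and plot-data diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios from the
#' pooled estimate, with weights `beta_exposure^2 / se_outcome^2`; under
#' instrument homogeneity Q follows a chi-squared distribution with
#' n − 1 degrees of freedom. By convention (overridable downstream)
#' p < 0.01 flags significant heterogeneity and motivates the
#' random-effects IVW model.
#'
#' @param pairs harmonized data frame with at least two instruments.
#' @param at_estimate optional pooled log-odds estimate at which to evaluate
#'   Q; defaults to the fixed-effects IVW estimate, which minimizes Q.
#' @return object of class `mr_heterogeneity`: list with `q_stat`, `df`,
#'   `pval` and the named per-SNP contributions `per_snp_q`.
#' @export
#' @examples
#' cochran_q(hypothyroidism_nafld())
cochran_q <- function(pairs, at_estimate = NULL) {
  check_pairs(pairs, 2, "cochran_q")
  w <- ratio_weights(pairs)
  r <- wald_ratios(pairs)
  theta <- if (is.null(at_estimate)) sum(w * r) / sum(w) else at_estimate
  per <- setNames(w * (r - theta)^2, pairs$snp_id)
  q <- sum(per)
  df <- nrow(pairs) - 1L
  out <- list(q_stat = q, df = df,
              pval = pchisq(q, df, lower.tail = FALSE),
              per_snp_q = per, at_estimate = theta)
  class(out) <- "mr_heterogeneity"
  out
}

#' @export
print.mr_heterogeneity <- function(x, digits = 4, ...) {
  cat(sprintf("Cochran's Q = %.*g on %d df, p = %.*g\n",
              digits, x$q_stat, x$df, digits, x$pval))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect with each instrument excluded in turn and
#' summarizes how much any single SNP drives the pooled result: whether any
#' reduced-set estimate changes sign, the largest absolute shift from the
#' full estimate, and whether every reduced-set estimate stays inside the
#' full-set confidence interval.
#'
#' @param pairs harmonized data frame with at least three instruments.
#' @param method estimator label (see [mr_all_methods()]); default
#'   `"ivw_fixed"`.
#' @param ... passed to the estimator (e.g. `n_boot`, `seed`).
#' @return object of class `mr_loo`: list with `rows` (data frame `snp_id`,
#'   `beta`, `se`, `ci_low`, `ci_high`, one row per excluded SNP),
#'   `full_estimate` (`mr_estimate`), `any_sign_change`, `max_abs_shift`,
#'   `all_within_full_ci`.
#' @export
#' @examples
#' leave_one_out(hypothyroidism_nafld())
leave_one_out <- function(pairs, method = "ivw_fixed", ...) {
  check_pairs(pairs, 3, "leave_one_out")
  full <- estimate_by_label(pairs, method, ...)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    est <- tryCatch(
      estimate_by_label(pairs[-i, , drop = FALSE], method, ...),
      error = function(e) {
        mr_analysis_error(sprintf("leave_one_out failed excluding %s: %s",
                                  pairs$snp_id[i], conditionMessage(e)))
      })
    data.frame(snp_id = pairs$snp_id[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  out <- list(
    rows = rows,
    full_estimate = full,
    any_sign_change = any(sign(rows$beta) != sign(full$beta)),
    max_abs_shift = max(abs(rows$beta - full$beta)),
    all_within_full_ci = all(rows$beta >= full$ci_low &
                               rows$beta <= full$ci_high)
  )
  class(out) <- "mr_loo"
  out
}

#' @export
print.mr_loo <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Leave-one-out (%s, %d instruments): full beta %.*g; max shift %.*g; %s\n",
    x$full_estimate$method, nrow(x$rows), digits, x$full_estimate$beta,
    digits, x$max_abs_shift,
    if (x$any_sign_change) "SIGN CHANGE" else "no sign change"))
  invisible(x)
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratio estimates and their precisions
#' (`|beta_exposure| / se_outcome`, the reciprocal of the ratio's standard
#' error). A symmetric funnel of estimates around the pooled value is
#' evidence against directional pleiotropy. SNPs with a zero exposure
#' effect have no defined ratio and are dropped with a warning.
#'
#' @param pairs harmonized data frame.
#' @return data frame with columns `snp_id`, `ratio_estimate`, `precision`.
#' @export
funnel_data <- function(pairs) {
  check_pairs(pairs, 1, "funnel_data")
  zero <- pairs$beta_exposure == 0
  if (any(zero)) {
    warning(sprintf("funnel_data: dropping %d SNP(s) with beta_exposure = 0",
                    sum(zero)))
    pairs <- pairs[!zero, , drop = FALSE]
  }
  data.frame(
    snp_id = pairs$snp_id,
    ratio_estimate = wald_ratios(pairs),
    precision = abs(pairs$beta_exposure) / pairs$se_outcome,
    stringsAsFactors = FALSE
  )
}

#' Scatter-plot data with fitted lines
#'
#' Exports the per-SNP effect-versus-effect scatter (exposure effect,
#' outcome effect, both standard errors) together with one fitted line per
#' supplied estimate: slope = the method's causal estimate, intercept 0 for
#' every method except MR-Egger, whose intercept is its average-pleiotropy
#' estimate.
#'
#' @param pairs harmonized data frame.
#' @param fits list of `mr_estimate` and/or `mr_egger_result` objects
#'   (possibly empty).
#' @return list with `points` (data frame `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`) and `lines` (data frame
#'   `method`, `slope`, `intercept`).
#' @export
scatter_data <- function(pairs, fits = list()) {
  check_pairs(pairs, 1, "scatter_data")
  points <- data.frame(
    snp_id = pairs$snp_id,
    beta_exposure = pairs$beta_exposure, se_exposure = pairs$se_exposure,
    beta_outcome = pairs$beta_outcome, se_outcome = pairs$se_outcome,
    stringsAsFactors = FALSE
  )
  if (inherits(fits, c("mr_estimate", "mr_egger_result"))) fits <- list(fits)
  lines <- lapply(fits, function(f) {
    if (inherits(f, "mr_egger_result")) {
      data.frame(method = "egger", slope = f$slope$beta,
                 intercept = f$intercept, stringsAsFactors = FALSE)
    } else if (inherits(f, "mr_estimate")) {
      data.frame(method = f$method, slope = f$beta, intercept = 0,
                 stringsAsFactors = FALSE)
    } else {
      mr_config_error(
        "fits must contain mr_estimate or mr_egger_result objects")
    }
  })
  lines <- if (length(lines)) do.call(rbind, lines) else
    data.frame(method = character(), slope = numeric(),
               intercept = numeric(), stringsAsFactors = FALSE)
  list(points = points, lines = lines)
}
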