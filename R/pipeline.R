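# End-to-end analysis pipeline: read -> select -> clump -> harmonize ->
# estimate -> diagnose -> report, with deterministic TSV outputs.

#' Assemble and validate an analysis configuration
#'
#' Either supply `exposure_path` and `outcome_path` (two per-study GWAS
#' summary tables; selection, clumping and harmonization are applied), or
#' `harmonized_path` (a pre-harmonized joined table with headers `SNP`,
#' `beta.exposure`, `se.exposure`, `pval.exposure`, `beta.outcome`,
#' `se.outcome`, `pval.outcome`; upstream steps are skipped).
#'
#' @param exposure_path,outcome_path paths to the two GWAS summary tables.
#' @param harmonized_path path to a pre-harmonized joined table.
#' @param output_dir directory for the report bundle (created if needed).
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @param clump_window_kb clumping window in kb (default 10000).
#' @param clump_r2 clumping r² threshold (default 0.001).
#' @param palindrome_policy `"drop"` or `"infer_by_eaf"`.
#' @param eaf_ambiguity_band palindrome frequency band (default 0.08).
#' @param heterogeneity_alpha significance level below which Cochran's Q
#'   switches the reported IVW model to random effects (default 0.01).
#' @param methods estimator labels to run (default: all).
#' @param bootstrap_reps bootstrap replicates for median-type standard
#'   errors (default 1000).
#' @param seed seed for the bootstrap (default 42).
#' @param exposure_map,outcome_map header mappings for the two per-study
#'   tables (see [default_column_map()]).
#' @return list of class `mr_analysis_config`.
#' @export
analysis_config <- function(exposure_path = NULL, outcome_path = NULL,
                            harmonized_path = NULL, output_dir = NULL,
                            p_threshold = 5e-8, clump_window_kb = 10000,
                            clump_r2 = 0.001,
                            palindrome_policy = "drop",
                            eaf_ambiguity_band = 0.08,
                            heterogeneity_alpha = 0.01,
                            methods = MR_METHODS,
                            bootstrap_reps = 1000, seed = 42,
                            exposure_map = default_column_map(),
                            outcome_map = default_column_map()) {
  if (!length(methods)) mr_config_error("methods must be non-empty")
  bad <- setdiff(methods, MR_METHODS)
  if (length(bad)) {
    mr_config_error(paste0("unknown estimator label(s): ",
                           paste(bad, collapse = ", ")))
  }
  pre <- !is.null(harmonized_path)
  if (!pre && (is.null(exposure_path) || is.null(outcome_path))) {
    mr_config_error(
      "supply exposure_path and outcome_path, or harmonized_path")
  }
  if (is.null(output_dir)) mr_config_error("output_dir is required")
  if (p_threshold <= 0 || p_threshold > 1) {
    mr_config_error("p_threshold must lie in (0, 1]")
  }
  if (heterogeneity_alpha <= 0 || heterogeneity_alpha >= 1) {
    mr_config_error("heterogeneity_alpha must lie in (0, 1)")
  }
  out <- list(
    exposure_path = exposure_path, outcome_path = outcome_path,
    harmonized_path = harmonized_path, output_dir = output_dir,
    p_threshold = p_threshold, clump_window_kb = clump_window_kb,
    clump_r2 = clump_r2, palindrome_policy = palindrome_policy,
    eaf_ambiguity_band = eaf_ambiguity_band,
    heterogeneity_alpha = heterogeneity_alpha, methods = methods,
    bootstrap_reps = bootstrap_reps, seed = seed,
    exposure_map = exposure_map, outcome_map = outcome_map
  )
  class(out) <- "mr_analysis_config"
  out
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [analysis_config()].
#' @return list of class `mr_analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) mr_io_error(paste0("cannot read config: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    mr_config_error(paste0("unknown config key(s): ",
                           paste(bad, collapse = ", ")))
  }
  for (f in c("exposure_map", "outcome_map")) {
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  }
  if (!is.null(vals$methods)) vals$methods <- unlist(vals$methods)
  do.call(analysis_config, vals)
}

fmt_num <- function(x, digits = 4) formatC(x, format = "f", digits = digits)
fmt_p <- function(x) signif(x, 4)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Joined pre-harmonized table (Table-1-style headers) -> mr_harmonized
read_harmonized_table <- function(path) {
  if (!file.exists(path)) mr_io_error(paste0("cannot read file: ", path))
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("SNP", "beta.exposure", "se.exposure", "beta.outcome",
            "se.outcome")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    mr_config_error(paste0("pre-harmonized table lacks column(s): ",
                           paste(missing, collapse = ", ")))
  }
  grab <- function(col) if (col %in% names(raw)) raw[[col]] else NA_real_
  mr_pairs(
    snp_id = raw$SNP,
    beta_exposure = raw$beta.exposure, se_exposure = raw$se.exposure,
    beta_outcome = raw$beta.outcome, se_outcome = raw$se.outcome,
    pval_exposure = grab("pval.exposure"), pval_outcome = grab("pval.outcome")
  )
}

#' Run the end-to-end two-sample MR analysis
#'
#' Executes the full pipeline described by the configuration and writes a
#' deterministic report bundle to `output_dir`:
#' `harmonized.tsv` and `exclusions.tsv`; `estimates.tsv` (one row per
#' requested method: beta, se, 95% CI, p, OR and its CI, instrument
#' count); `pleiotropy.tsv` (MR-Egger intercept) when Egger is requested;
#' `heterogeneity.tsv` (Cochran's Q, df, p and the resulting fixed/random
#' model choice); `leave_one_out.tsv`; `funnel.tsv`, `scatter_points.tsv`
#' and `scatter_lines.tsv`; and `run_log.txt` recording configuration,
#' seed and versions. Numeric columns are printed at fixed precision
#' (effects and ORs to 4 decimals, p-values to 4 significant figures) so
#' repeated runs with the same configuration are byte-identical.
#'
#' @param config a [analysis_config()] object (or a path to a YAML file).
#' @return invisibly, a list with the in-memory results: `pairs`,
#'   `exclusions`, `estimates`, `egger`, `heterogeneity`, `model_choice`,
#'   `loo`, `funnel`, `scatter`, `output_dir`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (!inherits(config, "mr_analysis_config")) {
    mr_config_error("config must come from analysis_config()")
  }
  log_lines <- c(
    sprintf("mrkit %s | R %s", as.character(packageVersion("mrkit")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %s", config$seed),
    sprintf("methods: %s", paste(config$methods, collapse = ", "))
  )
  info <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(config$harmonized_path)) {
    info("mode: pre-harmonized input %s", config$harmonized_path)
    pairs <- read_harmonized_table(config$harmonized_path)
    exclusions <- data.frame(snp_id = character(), reason = character())
  } else {
    info("mode: two-study input %s / %s", config$exposure_path,
         config$outcome_path)
    exposure <- read_summary_table(config$exposure_path, config$exposure_map)
    outcome <- read_summary_table(config$outcome_path, config$outcome_map)
    info("read %d exposure and %d outcome records", nrow(exposure),
         nrow(outcome))
    exposure <- select_instruments(exposure, config$p_threshold)
    info("instrument selection (p < %g): %d kept", config$p_threshold,
         nrow(exposure))
    exposure <- clump(exposure, config$clump_window_kb, config$clump_r2)
    info("clumping (window %g kb, r2 %g): %d kept", config$clump_window_kb,
         config$clump_r2, nrow(exposure))
    pairs <- harmonize(exposure, outcome,
                       palindrome_policy = config$palindrome_policy,
                       eaf_ambiguity_band = config$eaf_ambiguity_band)
    exclusions <- exclusion_report(pairs)
    for (i in seq_len(nrow(exclusions))) {
      info("excluded %s: %s", exclusions$snp_id[i], exclusions$reason[i])
    }
    info("harmonized pairs: %d", nrow(pairs))
  }

  estimates <- mr_all_methods(pairs, config$methods,
                              n_boot = config$bootstrap_reps,
                              seed = config$seed)
  egger <- if ("egger" %in% config$methods) mr_egger(pairs) else NULL
  het <- cochran_q(pairs)
  model_choice <- if (het$pval < config$heterogeneity_alpha) "random"
                  else "fixed"
  info("heterogeneity: Q = %.4f (df %d, p = %.4g) -> %s-effects model",
       het$q_stat, het$df, het$pval, model_choice)
  loo <- leave_one_out(pairs, "ivw_fixed")
  funnel <- funnel_data(pairs)
  fit_list <- list(mr_ivw(pairs))
  if (!is.null(egger)) fit_list <- c(fit_list, list(egger))
  scatter <- scatter_data(pairs, fit_list)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(config$output_dir, name)

  hp <- pairs
  for (col in c("beta_exposure", "se_exposure", "beta_outcome",
                "se_outcome")) hp[[col]] <- fmt_num(hp[[col]])
  for (col in c("pval_exposure", "pval_outcome"))
    hp[[col]] <- fmt_p(hp[[col]])
  write_tsv(hp, outfile("harmonized.tsv"))
  write_tsv(exclusions, outfile("exclusions.tsv"))

  est_out <- as.data.frame(estimates)
  for (col in c("beta", "se", "ci_low", "ci_high", "odds_ratio",
                "ci_or_low", "ci_or_high")) est_out[[col]] <-
    fmt_num(est_out[[col]])
  est_out$pval <- fmt_p(est_out$pval)
  write_tsv(est_out, outfile("estimates.tsv"))

  if (!is.null(egger)) {
    write_tsv(data.frame(
      intercept = fmt_num(egger$intercept),
      se = fmt_num(egger$intercept_se),
      pval = fmt_p(egger$intercept_pval)
    ), outfile("pleiotropy.tsv"))
  }

  write_tsv(data.frame(
    q_stat = fmt_num(het$q_stat), df = het$df, pval = fmt_p(het$pval),
    model_choice = model_choice
  ), outfile("heterogeneity.tsv"))

  loo_out <- loo$rows
  for (col in c("beta", "se", "ci_low", "ci_high"))
    loo_out[[col]] <- fmt_num(loo_out[[col]])
  write_tsv(loo_out, outfile("leave_one_out.tsv"))

  fun_out <- funnel
  fun_out$ratio_estimate <- fmt_num(fun_out$ratio_estimate)
  fun_out$precision <- fmt_num(fun_out$precision)
  write_tsv(fun_out, outfile("funnel.tsv"))

  sp <- scatter$points
  for (col in setdiff(names(sp), "snp_id")) sp[[col]] <- fmt_num(sp[[col]])
  write_tsv(sp, outfile("scatter_points.tsv"))
  sl <- scatter$lines
  sl$slope <- fmt_num(sl$slope)
  sl$intercept <- fmt_num(sl$intercept)
  write_tsv(sl, outfile("scatter_lines.tsv"))

  writeLines(log_lines, outfile("run_log.txt"))

  invisible(list(
    pairs = pairs, exclusions = exclusions, estimates = estimates,
    egger = egger, heterogeneity = het, model_choice = model_choice,
    loo = loo, funnel = funnel, scatter = scatter,
    output_dir = config$output_dir
  ))
}
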