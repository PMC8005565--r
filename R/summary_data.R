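#' Default header mapping for GWAS summary-statistic tables
#'
#' Maps the canonical `mrkit` field names to the column headers expected in
#' an input file. Any entry may be overridden or set to `NA` (column absent;
#' only `eaf`, `effect_allele`, `other_allele`, `chrom` and `pos` may be
#' missing).
#'
#' @param ... named overrides, e.g. `beta = "beta.exposure"`.
#' @return named character vector mapping field names to file headers.
#' @export
#' @examples
#' default_column_map(beta = "beta.exposure", se = "se.exposure")
default_column_map <- function(...) {
  map <- c(
    snp_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(map))
    if (length(bad)) {
      mr_config_error(paste0("unknown summary-statistic field(s): ",
                             paste(bad, collapse = ", ")))
    }
    map[names(dots)] <- dots
  }
  map
}

#' Construct a validated summary-statistics table
#'
#' Builds a `mr_summary` data frame (one row per SNP of one GWAS) from
#' vectors, enforcing the per-record invariants: positive standard errors,
#' p-values in (0, 1], allele frequencies in \[0, 1\] when present, and
#' distinct single-letter alleles when present.
#'
#' @param snp_id character variant identifiers.
#' @param beta per-allele effect estimates (log-odds scale for a binary
#'   trait).
#' @param se standard errors of `beta` (> 0).
#' @param pval association p-values in (0, 1].
#' @param chrom,pos chromosome labels and 1-based base-pair positions
#'   (optional, needed for clumping).
#' @param effect_allele,other_allele alleles (A/C/G/T; optional, needed for
#'   harmonization).
#' @param eaf effect-allele frequencies (optional).
#' @return data frame of class `mr_summary`.
#' @export
mr_summary <- function(snp_id, beta, se, pval,
                       chrom = NA, pos = NA,
                       effect_allele = NA, other_allele = NA, eaf = NA) {
  out <- data.frame(
    snp_id = as.character(snp_id), chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf), beta = as.numeric(beta),
    se = as.numeric(se), pval = as.numeric(pval),
    stringsAsFactors = FALSE
  )
  bad <- validate_summary_rows(out)
  if (any(nzchar(bad))) {
    first <- which(nzchar(bad))[1]
    mr_analysis_error(sprintf("invalid summary record %s (row %d): %s",
                              out$snp_id[first], first, bad[first]))
  }
  class(out) <- c("mr_summary", "data.frame")
  out
}

# Per-row invariant check; returns "" for valid rows, reason otherwise.
validate_summary_rows <- function(df) {
  n <- nrow(df)
  reason <- character(n)
  num_ok <- function(x) !is.na(x) & is.finite(x)
  for (i in seq_len(n)) {
    r <- df[i, ]
    if (!nzchar(r$snp_id) || is.na(r$snp_id)) reason[i] <- "missing snp_id"
    else if (!num_ok(r$beta)) reason[i] <- "unparseable or missing beta"
    else if (!num_ok(r$se) || r$se <= 0) reason[i] <- "se not positive"
    else if (!num_ok(r$pval) || r$pval <= 0 || r$pval > 1)
      reason[i] <- "pval outside (0,1]"
    else if (!is.na(r$eaf) && (r$eaf < 0 || r$eaf > 1))
      reason[i] <- "eaf outside [0,1]"
    else if (!is.na(r$effect_allele) || !is.na(r$other_allele)) {
      ok <- function(a) !is.na(a) && a %in% c("A", "C", "G", "T")
      if (!ok(r$effect_allele) || !ok(r$other_allele))
        reason[i] <- "allele not a single A/C/G/T base"
      else if (r$effect_allele == r$other_allele)
        reason[i] <- "effect and other allele identical"
    }
  }
  reason
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab- or comma-separated, header row
#' required), renames columns according to `column_map`, and validates each
#' row against the summary-record invariants. Invalid rows are dropped and
#' reported; valid rows are returned in file order.
#'
#' @param path path to the file.
#' @param column_map named mapping from field names to file headers; see
#'   [default_column_map()]. Optional fields mapped to `NA` are filled with
#'   missing values.
#' @param sep field separator; `NULL` (default) sniffs tab then comma from
#'   the header line.
#' @return `mr_summary` data frame with attribute `"rejected"`: a data frame
#'   (`row`, `snp_id`, `reason`) describing dropped rows.
#' @export
#' @examples
#' tsv <- system.file("extdata", "hypothyroidism_nafld.tsv", package = "mrkit")
#' exp <- read_summary_table(tsv, default_column_map(
#'   chrom = "CHR", pos = "Pos", beta = "beta.exposure",
#'   se = "se.exposure", pval = "pval.exposure",
#'   effect_allele = NA, other_allele = NA, eaf = NA))
#' nrow(exp)
read_summary_table <- function(path, column_map = default_column_map(),
                               sep = NULL) {
  if (!file.exists(path)) mr_io_error(paste0("cannot read file: ", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", strip.white = TRUE)
  optional <- c("chrom", "pos", "effect_allele", "other_allele", "eaf")
  mandatory <- setdiff(names(default_column_map()), optional)
  for (f in mandatory) {
    h <- column_map[[f]]
    if (is.na(h) || !h %in% names(raw)) {
      mr_config_error(sprintf(
        "mandatory column for field '%s' (header '%s') not found in %s",
        f, h, path))
    }
  }
  get_col <- function(f) {
    h <- column_map[[f]]
    if (is.null(h) || is.na(h) || !h %in% names(raw)) rep(NA, nrow(raw))
    else raw[[h]]
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    snp_id = as.character(get_col("snp_id")),
    chrom = as.character(get_col("chrom")),
    pos = suppressWarnings(as.integer(num(get_col("pos")))),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    eaf = num(get_col("eaf")), beta = num(get_col("beta")),
    se = num(get_col("se")), pval = num(get_col("pval")),
    stringsAsFactors = FALSE
  )
  reason <- validate_summary_rows(out)
  drop <- nzchar(reason)
  rejected <- data.frame(row = which(drop), snp_id = out$snp_id[drop],
                         reason = reason[drop], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message(sprintf("read_summary_table: dropped %d invalid row(s) of %d",
                    nrow(rejected), nrow(out)))
  }
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mr_summary", "data.frame")
  attr(out, "rejected") <- rejected
  out
}

#' Select genome-wide significant instruments
#'
#' Keeps records whose exposure association p-value is strictly below the
#' threshold (genome-wide significance, 5e-8, by default), preserving input
#' order.
#'
#' @param stats `mr_summary` data frame.
#' @param p_threshold significance threshold in (0, 1).
#' @return the filtered `mr_summary`.
#' @export
select_instruments <- function(stats, p_threshold = 5e-8) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold > 1) {
    mr_config_error("p_threshold must be a single number in (0, 1]")
  }
  out <- stats[stats$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy distance/LD clumping of instruments
#'
#' Retains one representative variant per region: candidates are visited in
#' ascending p-value order (ties broken by `snp_id`), and a candidate is
#' discarded when a previously kept SNP on the same chromosome lies within
#' `window_kb` kilobases (inclusive) unless a supplied pairwise r-squared
#' shows the pair to be in linkage equilibrium (r² < `r2_threshold`). With
#' no `ld` lookup, distance alone decides — the conservative choice when no
#' reference panel is available. Pairs absent from a supplied lookup are
#' treated as unknown and discarded on distance, for the same reason.
#'
#' @param stats `mr_summary` with non-missing `chrom` and `pos`.
#' @param window_kb clumping window in kilobases (default 10000).
#' @param r2_threshold LD threshold (default 0.001).
#' @param ld optional data frame (`snp_a`, `snp_b`, `r2`) of precomputed
#'   pairwise r² values (unordered pairs).
#' @return the clumped `mr_summary`, in the original row order of the kept
#'   records.
#' @export
clump <- function(stats, window_kb = 10000, r2_threshold = 0.001, ld = NULL) {
  if (!is.numeric(window_kb) || window_kb <= 0) {
    mr_config_error("window_kb must be a positive number")
  }
  if (nrow(stats) <= 1) return(stats)
  if (anyNA(stats$pos) || anyNA(stats$chrom)) {
    mr_analysis_error("clumping requires chrom and pos for every record")
  }
  lookup_r2 <- function(a, b) {
    if (is.null(ld)) return(NA_real_)
    hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
    if (!any(hit)) NA_real_ else ld$r2[which(hit)[1]]
  }
  ord <- order(stats$pval, stats$snp_id)
  kept <- integer(0)
  for (i in ord) {
    blocked <- FALSE
    for (k in kept) {
      if (stats$chrom[k] != stats$chrom[i]) next
      if (abs(stats$pos[k] - stats$pos[i]) > window_kb * 1000) next
      r2 <- lookup_r2(stats$snp_id[k], stats$snp_id[i])
      if (is.na(r2) || r2 >= r2_threshold) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) kept <- c(kept, i)
  }
  out <- stats[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) ALLELE_COMPLEMENT[ea] == oa

#' Construct harmonized exposure–outcome pairs
#'
#' Low-level constructor for a `mr_harmonized` data frame, the container all
#' estimators operate on: one row per SNP with exposure and outcome effects
#' aligned to one shared effect allele.
#'
#' @param snp_id character identifiers (must be unique).
#' @param beta_exposure,se_exposure exposure effect and its standard error.
#' @param beta_outcome,se_outcome outcome effect (same effect allele) and
#'   its standard error.
#' @param pval_exposure,pval_outcome association p-values (optional).
#' @param flipped logical; whether the outcome record's alleles were swapped
#'   during harmonization.
#' @return data frame of class `mr_harmonized`.
#' @export
mr_pairs <- function(snp_id, beta_exposure, se_exposure,
                     beta_outcome, se_outcome,
                     pval_exposure = NA_real_, pval_outcome = NA_real_,
                     flipped = FALSE) {
  out <- data.frame(
    snp_id = as.character(snp_id),
    beta_exposure = as.numeric(beta_exposure),
    se_exposure = as.numeric(se_exposure),
    beta_outcome = as.numeric(beta_outcome),
    se_outcome = as.numeric(se_outcome),
    pval_exposure = as.numeric(pval_exposure),
    pval_outcome = as.numeric(pval_outcome),
    flipped = as.logical(flipped),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$snp_id)) {
    mr_analysis_error("duplicated snp_id in harmonized pairs")
  }
  if (any(!is.finite(out$se_exposure) | out$se_exposure <= 0) ||
      any(!is.finite(out$se_outcome) | out$se_outcome <= 0)) {
    mr_analysis_error("harmonized pairs require positive standard errors")
  }
  class(out) <- c("mr_harmonized", "data.frame")
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared SNP to the exposure
#' study's effect allele. For each SNP present in both tables:
#' matching alleles are kept as-is; swapped alleles flip the outcome beta
#' (and complement its frequency); strand-complement (or swapped-complement)
#' alleles are complemented first; palindromic SNPs (A/T or C/G) are dropped
#' under the `"drop"` policy, or kept under `"infer_by_eaf"` when both
#' allele frequencies are informative (outside `0.5 ± eaf_ambiguity_band`),
#' using frequency agreement to resolve the strand; irreconcilable allele
#' sets are dropped as incompatible. Duplicate ids keep the first occurrence
#' only.
#'
#' @param exposure,outcome `mr_summary` tables with allele columns.
#' @param palindrome_policy `"drop"` (default) or `"infer_by_eaf"`.
#' @param eaf_ambiguity_band half-width of the frequency band around 0.5
#'   within which a palindromic SNP is considered unresolvable (default
#'   0.08, i.e. 0.42–0.58).
#' @return `mr_harmonized` data frame (exposure row order) with attribute
#'   `"exclusions"`: data frame (`snp_id`, `reason`) with reason codes
#'   `palindromic`, `incompatible_alleles`, `duplicate`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer_by_eaf"),
                      eaf_ambiguity_band = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) {
    mr_analysis_error("no shared SNPs between exposure and outcome")
  }
  excl <- list()
  note <- function(id, why) excl[[length(excl) + 1]] <<- c(id, why)

  # first occurrence wins for duplicated ids in either table
  dup_e <- exposure$snp_id[duplicated(exposure$snp_id)]
  dup_o <- outcome$snp_id[duplicated(outcome$snp_id)]
  for (id in unique(c(dup_e, dup_o))) note(id, "duplicate")
  exposure <- exposure[!duplicated(exposure$snp_id), , drop = FALSE]
  outcome <- outcome[!duplicated(outcome$snp_id), , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    if (!ex$snp_id %in% outcome$snp_id) next
    ou <- outcome[outcome$snp_id == ex$snp_id, ][1, ]
    if (is.na(ex$effect_allele) || is.na(ou$effect_allele)) {
      mr_analysis_error(sprintf("harmonize requires alleles for %s",
                                ex$snp_id))
    }
    if (is_palindromic(ex$effect_allele, ex$other_allele)) {
      amb <- function(f) is.na(f) || abs(f - 0.5) <= eaf_ambiguity_band
      if (palindrome_policy == "drop" || amb(ex$eaf) || amb(ou$eaf)) {
        note(ex$snp_id, "palindromic")
        next
      }
      # resolvable palindrome: strand fixed by frequency agreement
      same_strand <- (ou$eaf > 0.5) == (ex$eaf > 0.5)
      flipped <- !same_strand
      beta_o <- if (flipped) -ou$beta else ou$beta
    } else {
      ea <- ou$effect_allele
      oa <- ou$other_allele
      comp <- unname(ALLELE_COMPLEMENT[c(ea, oa)])
      if (ea == ex$effect_allele && oa == ex$other_allele) {
        flipped <- FALSE
      } else if (ea == ex$other_allele && oa == ex$effect_allele) {
        flipped <- TRUE
      } else if (comp[1] == ex$effect_allele && comp[2] == ex$other_allele) {
        flipped <- FALSE
      } else if (comp[1] == ex$other_allele && comp[2] == ex$effect_allele) {
        flipped <- TRUE
      } else {
        note(ex$snp_id, "incompatible_alleles")
        next
      }
      beta_o <- if (flipped) -ou$beta else ou$beta
    }
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = ex$snp_id, beta_exposure = ex$beta, se_exposure = ex$se,
      beta_outcome = beta_o, se_outcome = ou$se,
      pval_exposure = ex$pval, pval_outcome = ou$pval,
      flipped = flipped, stringsAsFactors = FALSE
    )
  }
  exclusions <- if (length(excl)) {
    data.frame(snp_id = vapply(excl, `[`, "", 1),
               reason = vapply(excl, `[`, "", 2), stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    mr_analysis_error("all shared SNPs were excluded during harmonization")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mr_harmonized", "data.frame")
  attr(out, "exclusions") <- exclusions
  out
}

#' Exclusion report from a harmonization result
#'
#' @param pairs a `mr_harmonized` object returned by [harmonize()].
#' @return data frame with columns `snp_id` and `reason`.
#' @export
exclusion_report <- function(pairs) {
  rep <- attr(pairs, "exclusions")
  if (is.null(rep)) {
    rep <- data.frame(snp_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  }
  rep
}
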