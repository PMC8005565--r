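pairs9 <- nine_snp_pairs()

test_that("Wald ratio divides outcome by exposure effect", {
  est <- mr_wald_ratio(pairs9[pairs9$snp_id == "rs17020127", ])
  expect_equal(est$beta, -0.2438 / -0.2289, tolerance = 1e-12)
  expect_equal(est$se, 0.1347 / 0.2289, tolerance = 1e-12)

  est2 <- mr_wald_ratio(pairs9[pairs9$snp_id == "rs229536", ])
  expect_equal(est2$beta, 0.0347 / -0.1172, tolerance = 1e-12)
  expect_lt(est2$beta, 0)

  null_pair <- mr_pairs("z", 0.2, 0.02, 0, 0.05)
  expect_equal(mr_wald_ratio(null_pair)$beta, 0)

  bad <- mr_pairs("z", 0, 0.02, 0.1, 0.05)
  expect_error(mr_wald_ratio(bad), class = "mrkit_analysis_error")
})

test_that("fixed-effects IVW reproduces the published pooled estimate", {
  est <- mr_ivw(pairs9)
  expect_equal(est$odds_ratio, 1.7578, tolerance = 1e-4)
  expect_equal(est$ci_or_low, 1.1897, tolerance = 1e-4)
  expect_equal(est$ci_or_high, 2.5970, tolerance = 1e-4)
  expect_lt(abs(est$pval - 0.0046), 0.001)
  expect_equal(est$n_snps, 9)
})

test_that("random-effects IVW shares the point estimate, never shrinks the se", {
  fixed <- mr_ivw(pairs9, "fixed")
  random <- mr_ivw(pairs9, "random")
  expect_equal(random$beta, fixed$beta)
  expect_gte(random$se, fixed$se)
  # under strong heterogeneity the random-effects se must inflate
  set.seed(11)
  het <- random_pairs(10)
  het$beta_outcome <- het$beta_exposure * rnorm(10, 0.5, 2)
  expect_gt(mr_ivw(het, "random")$se, mr_ivw(het, "fixed")$se)
})

test_that("IVW equals the inverse-variance-weighted mean of Wald ratios", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_pairs(sample(3:20, 1))
    expect_equal(mr_ivw(p)$beta, oracle_ivw_mean(p), tolerance = 1e-12)
  }
})

test_that("two identical instruments pool to the single Wald ratio", {
  p <- mr_pairs(c("a", "b"), c(0.2, 0.2), 0.02, c(0.1, 0.1), 0.05)
  expect_equal(mr_ivw(p)$beta, 0.5, tolerance = 1e-12)
  expect_error(mr_ivw(p[1, ]), class = "mrkit_analysis_error")
})

test_that("estimators are scale-equivariant in the outcome", {
  set.seed(7)
  p <- random_pairs(8)
  c_ <- 3.7
  p2 <- p
  p2$beta_outcome <- p$beta_outcome * c_
  p2$se_outcome <- p$se_outcome * c_
  for (f in list(function(q) mr_ivw(q),
                 function(q) mr_penalized_ivw(q),
                 function(q) mr_simple_median(q, n_boot = 100),
                 function(q) mr_weighted_median(q, n_boot = 100))) {
    a <- f(p)
    b <- f(p2)
    expect_equal(b$beta, c_ * a$beta, tolerance = 1e-8)
    expect_equal(b$se, c_ * a$se, tolerance = 1e-8)
  }
})

test_that("simple median matches the published order statistic", {
  est <- mr_simple_median(pairs9, n_boot = 300)
  expect_equal(round(est$beta, 3), 0.583)
  # published OR is the exponential of the 3-decimal point estimate
  expect_equal(round(exp(round(est$beta, 3)), 4), 1.7914)
  expect_equal(est$odds_ratio, exp(est$beta))
})

test_that("median estimators honour order statistics and reductions", {
  p <- mr_pairs(c("a", "b", "c"), c(0.1, 0.1, 0.1), 0.02,
                c(0.1, 0.2, 3.0), 0.05)
  expect_equal(mr_simple_median(p, n_boot = 50)$beta, 2, tolerance = 1e-12)
  pc <- mr_pairs(c("a", "b", "c"), c(0.1, 0.2, 0.3), 0.02,
                 c(0.07, 0.14, 0.21), 0.05)
  expect_equal(mr_simple_median(pc, n_boot = 50)$beta, 0.7,
               tolerance = 1e-12)
  # equal weights reduce the weighted median to the interpolated median
  wm <- mr_weighted_median(p, weights = rep(1, 3), n_boot = 50)
  expect_equal(wm$beta, 2, tolerance = 1e-12)
})

test_that("weighted median reproduces the published penalized estimate", {
  unpen <- mr_weighted_median(pairs9, n_boot = 300)
  pen <- mr_weighted_median(pairs9, penalized = TRUE, n_boot = 300)
  expect_equal(round(unpen$beta, 3), 0.548)
  expect_equal(round(pen$beta, 3), 0.548)
  expect_equal(pen$odds_ratio, 1.7298, tolerance = 5e-4)
  # no SNP is penalized on this homogeneous data
  expect_equal(pen$beta, unpen$beta, tolerance = 1e-12)
})

test_that("weighted median stays within the uncontaminated convex hull", {
  set.seed(42)
  for (i in 1:20) {
    n <- 11
    p <- mr_pairs(sprintf("s%d", 1:n),
                  beta_exposure = runif(n, 0.18, 0.22),
                  se_exposure = 0.01,
                  beta_outcome = NA, se_outcome = 0.05)
    clean_ratio <- rnorm(n, 0.5, 0.05)
    dirty <- sample.int(n, 4)  # < half the (near-equal) weight
    clean_ratio[dirty] <- clean_ratio[dirty] + 5
    p$beta_outcome <- clean_ratio * p$beta_exposure
    est <- mr_weighted_median(p, n_boot = 20)
    expect_gte(est$beta, min(clean_ratio[-dirty]))
    expect_lte(est$beta, max(clean_ratio[-dirty]))
  }
})

test_that("penalized IVW reproduces the published value and shrinks outliers", {
  est <- mr_penalized_ivw(pairs9)
  expect_equal(round(est$beta, 3), 0.564)
  expect_equal(est$odds_ratio, 1.7577, tolerance = 2e-4)
  expect_lt(abs(est$pval - 0.005), 0.001)
  # homogeneous data: penalization is inert
  expect_equal(est$beta, mr_ivw(pairs9)$beta, tolerance = 1e-12)

  # one gross outlier: penalization pulls the estimate back towards the
  # IVW of the clean subset
  clean <- mr_pairs(sprintf("c%d", 1:4), c(0.2, 0.25, 0.3, 0.22), 0.02,
                    c(0.10, 0.13, 0.15, 0.11), c(0.01, 0.012, 0.01, 0.011))
  outlier <- mr_pairs("out", 0.24, 0.02, 0.50, 0.012)
  all5 <- rbind(clean, outlier)
  class(all5) <- class(clean)
  target <- mr_ivw(clean)$beta
  expect_lt(abs(mr_penalized_ivw(all5)$beta - target),
            abs(mr_ivw(all5)$beta - target))
})

test_that("robust IVW reproduces the published MM-estimate", {
  est <- mr_robust_ivw(pairs9)
  expect_equal(est$beta, 0.562, tolerance = 0.01)
  expect_equal(est$odds_ratio, 1.7542, tolerance = 0.02)
  pen <- mr_robust_ivw(pairs9, penalized = TRUE)
  expect_equal(pen$beta, est$beta, tolerance = 1e-6)  # nothing penalized
  # repeated calls are deterministic despite the stochastic S-start
  expect_identical(mr_robust_ivw(pairs9)$beta, est$beta)
})

test_that("robust IVW agrees with plain IVW on homogeneous data", {
  p <- mr_pairs(sprintf("s%d", 1:5), c(0.1, 0.15, 0.2, 0.25, 0.3), 0.02,
                NA, 0.05)
  p$beta_outcome <- 0.6 * p$beta_exposure
  expect_equal(mr_robust_ivw(p)$beta, mr_ivw(p)$beta, tolerance = 1e-6)
  expect_equal(mr_robust_ivw(p)$beta, 0.6, tolerance = 1e-6)
})

test_that("MR-Egger recovers the published intercept and slope", {
  e <- mr_egger(pairs9)
  expect_lt(abs(e$intercept - (-0.095)), 5e-4)
  expect_lt(abs(e$slope$beta - 1.12), 0.005)
  expect_equal(e$slope$method, "egger_slope")
  expect_equal(e$n_snps, 9)
  expect_true(e$intercept_pval > 0 && e$intercept_pval <= 1)
})

test_that("MR-Egger is exact on perfectly collinear data", {
  p <- mr_pairs(sprintf("s%d", 1:6),
                beta_exposure = c(-0.3, -0.1, 0.12, 0.2, 0.25, 0.31),
                se_exposure = 0.02, beta_outcome = NA, se_outcome = 0.05)
  p$beta_outcome <- 0.8 * p$beta_exposure
  e <- mr_egger(p)
  expect_equal(e$intercept, 0, tolerance = 1e-10)
  expect_equal(e$slope$beta, 0.8, tolerance = 1e-10)
})

test_that("insufficient instruments raise analysis errors", {
  expect_error(mr_simple_median(pairs9[1:2, ], n_boot = 10),
               class = "mrkit_analysis_error")
  expect_error(mr_weighted_median(pairs9[1:2, ], n_boot = 10),
               class = "mrkit_analysis_error")
  expect_error(mr_egger(pairs9[1:2, ]), class = "mrkit_analysis_error")
  expect_error(mr_robust_ivw(pairs9[1:2, ]),
               class = "mrkit_analysis_error")
})

test_that("odds-ratio columns are exact exponentials of the log-scale CI", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_pairs(6)
    est <- mr_ivw(p)
    expect_equal(est$ci_or_low, exp(est$ci_low), tolerance = 1e-15)
    expect_equal(est$ci_or_high, exp(est$ci_high), tolerance = 1e-15)
    expect_equal(est$odds_ratio, exp(est$beta), tolerance = 1e-15)
    expect_true(est$ci_low <= est$beta && est$beta <= est$ci_high)
  }
})

test_that("mr_all_methods stacks every requested estimator", {
  est <- mr_all_methods(pairs9, n_boot = 100)
  expect_equal(nrow(est), 9)
  expect_setequal(
    est$method,
    c("ivw_fixed", "ivw_random", "simple_median", "weighted_median",
      "penalized_weighted_median", "penalized_ivw", "robust_ivw",
      "penalized_robust_ivw", "egger_slope"))
  ic <- attr(est, "egger_intercept")
  expect_lt(abs(ic$intercept - (-0.095)), 5e-4)
  expect_error(mr_all_methods(pairs9, methods = character(0)),
               class = "mrkit_config_error")
  expect_error(mr_all_methods(pairs9, methods = "no_such_method"),
               class = "mrkit_config_error")
})

test_that("bootstrap standard errors are reproducible for a fixed seed", {
  a <- mr_simple_median(pairs9, n_boot = 200, seed = 9)
  b <- mr_simple_median(pairs9, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
  c_ <- mr_simple_median(pairs9, n_boot = 200, seed = 10)
  expect_false(identical(a$se, c_$se))
})
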