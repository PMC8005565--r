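# Shared fixtures built in code.

# The nine-SNP hypothyroidism -> NAFLD instrument set, spelled out here
# independently of the bundled TSV so tests of the reader/fixture have an
# in-code reference.
nine_snp_pairs <- function() {
  mr_pairs(
    snp_id = c("rs17020127", "rs181871363", "rs11571293", "rs9860547",
               "rs1993945", "rs9272245", "rs9273400", "rs925489",
               "rs229536"),
    beta_exposure = c(-0.2289, -0.276, 0.1259, -0.1121, 0.1468, 0.1458,
                      -0.2252, -0.1887, -0.1172),
    se_exposure = c(0.0306, 0.0456, 0.0215, 0.0205, 0.0201, 0.025, 0.022,
                    0.0211, 0.0202),
    pval_exposure = c(7.95e-14, 1.37e-09, 5.11e-09, 4.26e-08, 2.72e-13,
                      5.75e-09, 1.41e-24, 3.31e-19, 6.70e-09),
    beta_outcome = c(-0.2438, -0.2917, 0.0757, -0.0386, 0.0558, 0.2047,
                     -0.1314, -0.0102, 0.0347),
    se_outcome = c(0.1347, 0.2025, 0.0928, 0.0888, 0.0876, 0.0927, 0.095,
                   0.0904, 0.0879),
    pval_outcome = c(0.070361, 0.1499, 0.4147, 0.663599, 0.5244, 0.7014,
                     0.1667, 0.9098, 0.6933)
  )
}

fixture_tsv <- function() {
  system.file("extdata", "hypothyroidism_nafld.tsv", package = "mrkit",
              mustWork = TRUE)
}

# Column map for reading the exposure side of the joined fixture table.
exposure_map <- function() {
  default_column_map(chrom = "CHR", pos = "Pos", beta = "beta.exposure",
                     se = "se.exposure", pval = "pval.exposure",
                     effect_allele = NA, other_allele = NA, eaf = NA)
}

# Random harmonized pairs for property-style tests.
random_pairs <- function(n) {
  mr_pairs(
    snp_id = sprintf("s%03d", seq_len(n)),
    beta_exposure = runif(n, 0.05, 0.4) * sample(c(-1, 1), n, TRUE),
    se_exposure = runif(n, 0.01, 0.05),
    beta_outcome = rnorm(n, 0, 0.2),
    se_outcome = runif(n, 0.05, 0.2)
  )
}

# Independent closed-form oracle for the inverse-variance weighted mean of
# Wald ratios (the identity the IVW implementation must satisfy).
oracle_ivw_mean <- function(pairs) {
  r <- pairs$beta_outcome / pairs$beta_exposure
  w <- pairs$beta_exposure^2 / pairs$se_outcome^2
  sum(w * r) / sum(w)
}
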