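---
title: "Two-sample Mendelian randomization with mrkit: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The causal model

Mendelian randomization (MR) uses genetic variants as natural instruments
to estimate the causal effect of an exposure on an outcome from
observational data. Because alleles are assigned at conception, an
instrument's association with the outcome cannot be driven by reverse
causation or by classical confounders — provided three assumptions hold:
the variant is associated with the exposure (relevance), it affects the
outcome only through the exposure (exclusion restriction), and it is
independent of confounders of the exposure–outcome relation.

In the two-sample summary-data setting, instrument $j$ contributes an
estimated exposure effect $\hat\beta_{Xj}$ (s.e. $\sigma_{Xj}$) from one
GWAS and an outcome effect $\hat\beta_{Yj}$ (s.e. $\sigma_{Yj}$) from a
second, non-overlapping GWAS, both on a log-odds scale for binary traits.
Under the assumptions, each instrument yields a Wald ratio
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ with first-order standard
error $\sigma_{Yj} / |\hat\beta_{Xj}|$; the exposure-side uncertainty is
ignored, the usual strong-instrument (NOME) approximation, which is
accurate when $\sigma_{Xj} \ll |\hat\beta_{Xj}|$.

## Data preparation

`read_summary_table()` validates each record (positive standard error,
p-value in $(0,1]$, frequency in $[0,1]$, distinct A/C/G/T alleles) and
reports rejected rows rather than failing wholesale.
`select_instruments()` keeps associations below a significance threshold
(default $5\times 10^{-8}$, the conventional genome-wide level).

`clump()` enforces instrument independence greedily: candidates are
visited by ascending p-value (ties broken lexicographically by variant id,
for determinism) and dropped when a kept variant on the same chromosome
lies within the window (default 10,000 kb, inclusive) — unless a
user-supplied pairwise $r^2$ below the threshold (default 0.001)
certifies linkage equilibrium. The package deliberately does not compute
LD from genotypes: shipping or requiring a reference panel is out of
scope, so with no $r^2$ supplied, and likewise for pairs missing from a
supplied table, physical distance alone decides, which is conservative
(it can only remove more variants than LD-aware clumping would).

`harmonize()` aligns the outcome record of each shared SNP to the
exposure study's effect allele: matching alleles pass through, swapped
alleles negate the outcome beta, strand-complement codings are
complemented first, and irreconcilable allele sets are excluded as
incompatible. Palindromic variants (A/T, C/G) cannot be strand-resolved
from alleles alone; the default policy drops them, reproducing common
practice. The optional `infer_by_eaf` policy keeps a palindrome when both
allele frequencies fall outside $0.5 \pm$ `eaf_ambiguity_band` (default
band 0.08, i.e. 0.42–0.58) and uses frequency agreement to fix the
strand; palindromes with a missing frequency are always dropped under
either policy. Duplicated ids keep the first occurrence. Every exclusion
is reported with a reason code.

## The estimator family

All estimators operate on the harmonized pairs and report the causal
estimate on the log-odds scale together with a normal-theory 95%
confidence interval ($\hat\theta \pm 1.96\,\mathrm{se}$), a two-sided
p-value, and the exponentiated odds-ratio columns. MR-Egger is the one
exception: its inference uses the $t$ distribution with $n-2$ degrees of
freedom, reflecting the estimated intercept.

**IVW.** The inverse-variance weighted estimate pools the Wald ratios
with weights $w_j = \hat\beta_{Xj}^2 / \sigma_{Yj}^2$:
$$\hat\theta_{IVW} = \frac{\sum_j \hat\beta_{Xj}\hat\beta_{Yj}\sigma_{Yj}^{-2}}
{\sum_j \hat\beta_{Xj}^2 \sigma_{Yj}^{-2}},$$
algebraically the weighted regression of outcome on exposure effects
through the origin. The fixed-effects standard error is
$(\sum_j w_j)^{-1/2}$. The random-effects variant multiplies it by
$\max\{1, \sqrt{Q/(n-2)}\}$, where $Q$ is Cochran's Q at the fixed
estimate — the floor guarantees the random-effects interval never
undercuts the fixed-effects one, and the point estimate is identical
between the two models.

**Medians.** The simple median is the interpolated median of the Wald
ratios; the weighted median interpolates the ratio at standardized
mid-cumulative weight $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k = 0.5$
over the sorted ratios. Both are consistent as long as valid instruments
carry at least half the (total) weight — the 50% breakdown property that
motivates their use alongside IVW. Their sampling distributions have no
convenient closed form, so standard errors come from a parametric
bootstrap: both betas are resampled from
$N(\hat\beta, \sigma^2)$ per SNP and the estimator recomputed (weights
and penalties included), 1000 replicates by default under a dedicated
seed (default 42) that leaves the caller's RNG stream untouched.

**Penalization.** Outlying instruments can be down-weighted instead of
excluded: each weight is multiplied by $\min(1, 20\,p_j)$, where $p_j$ is
the upper $\chi^2_1$ tail probability of SNP $j$'s heterogeneity
contribution $w_j(\hat\theta_j - \hat\theta_{IVW})^2$ at the unpenalized
IVW estimate. The constant 20 (configurable via `penalty_k`) leaves any
instrument with $p_j \ge 0.05$ untouched, so on homogeneous data the
penalized estimators coincide exactly with their plain counterparts.

**Robust IVW.** A robust alternative fits the origin-constrained weighted
regression by MM-estimation with Tukey's bisquare $\psi$ (tuning constant
4.685, i.e. 95% Gaussian efficiency) started from a high-breakdown
S-estimate, via `MASS::rlm` (IWLS tolerance $10^{-7}$, at most 500
iterations). The S-estimate search is a resampling algorithm; it runs
under a fixed internal seed so repeated fits are identical. Exactly
collinear data leave the MM scale degenerate, so that case falls back to
the weighted least-squares fit, which is already the robust optimum.

**MR-Egger.** Allowing a free intercept in the weighted regression turns
it into a test for directional pleiotropy: the intercept estimates the
average direct effect of the instruments on the outcome, and the slope is
a pleiotropy-adjusted causal estimate (valid under the InSIDE assumption
that pleiotropic effects are independent of instrument strength). The
intercept is only identified once every instrument is oriented to its
exposure-increasing allele, so the fit first negates both betas of any
pair with $\hat\beta_{Xj} < 0$. Standard errors take the known-variance
WLS standard errors inflated by $\max\{1, \sqrt{RSS_w/(n-2)}\}$
(multiplicative random effects, floored so overdispersion can widen but
underdispersion cannot narrow them), with $t_{n-2}$ inference. A
published analysis of the bundled dataset quotes an intercept p-value of
0.431, which corresponds to the same standard error with a normal
reference; with the $t_7$ reference used here the value is 0.457 — the
intercept and its standard error are identical, only the reference
distribution differs.

## Diagnostics

`cochran_q()` reports $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ with
$n-1$ degrees of freedom and the per-SNP contributions; evaluated at the
fixed-effects IVW estimate, $Q$ is at its minimum over $\theta$. The
pipeline treats $p < 0.01$ (configurable `heterogeneity_alpha`) as
significant heterogeneity and switches its reported IVW model to random
effects.

`leave_one_out()` refits the chosen estimator on every $n-1$ subset. The
published leave-one-out criterion for the bundled dataset is descriptive
("no variant drives the result"), so the summary is deliberately
descriptive too: a sign-change flag, the maximum absolute shift, and
whether every reduced-set estimate stays inside the full-set confidence
interval — no formal influence test is constructed.

`funnel_data()` exports per-SNP ratio estimates against precision, defined
as $1/\sigma_{MR,j} = |\hat\beta_{Xj}|/\sigma_{Yj}$ (invariant to the
allele orientation); symmetry of the funnel is informal evidence against
directional pleiotropy. `scatter_data()` exports the effect-versus-effect
points plus one fitted line per estimate (intercept zero for all but
MR-Egger). Rendering is left to the user; the pipeline writes the plot
data as TSV.

## The synthetic-study generator

`generate_study()` realizes the summary-data model directly: true
exposure effects are drawn uniformly from `exposure_effect_range` with
random signs; observed effects add $N(0, \sigma_X^2)$ noise; outcome
effects are
$\theta\,\beta_{Xj}^{true} + \mathrm{sign}(\beta_{Xj}^{true})\,\alpha_j +
N(0, \sigma_Y^2)$. The direct (pleiotropic) effects $\alpha_j$ are coded
on the exposure-increasing allele: allele coding is arbitrary, so
"directional" pleiotropy is only meaningful relative to a fixed
orientation, and this is the orientation both IVW bias and the MR-Egger
intercept respond to. Balanced pleiotropy draws $\alpha_j$ with mean
zero; directional adds a non-zero mean; `pleiotropy_prop` restricts the
direct effects to a fraction of instruments; `inside_violation`
correlates them with instrument strength (correlation 0.7), breaking
InSIDE. Alleles avoid palindromic pairs (unless you construct them
yourself), frequencies are shared between the two studies, and positions
are spaced 20 Mb apart so default clumping keeps every instrument.

The defaults emulate the bundled study: nine instruments,
$\theta = 0.564$, $|\beta_X| \in [0.11, 0.28]$, $\sigma_X = 0.025$,
$\sigma_Y = 0.09$, no pleiotropy. What the generator does **not** emulate:
linkage disequilibrium between instruments, sample overlap between the
two GWAS, winner's-curse selection of instruments, allele-frequency–
dependent power, and non-normal sampling error. Passing the validation
suite therefore demonstrates correctness of the estimators under the
standard two-sample sampling model, not robustness to those
complications.

### Validation scenarios and problem sizes

The test suite exercises the estimators against the generator at sizes
chosen to keep Monte-Carlo error well below the asserted margins while
remaining quick to run:

* **Null coverage.** 1000 studies at the default nine-instrument
  configuration with $\theta = 0$; the fixed-effects IVW 95% CI must
  cover zero with frequency in [0.93, 0.97].
* **Recovery.** 200 studies at $n = 50$, $\theta = 0.56$; mean IVW bias
  below 0.02.
* **Contamination.** 200 studies at $n = 50$ with 40% of instruments
  carrying a large directional direct effect ($\alpha = 0.3$) and small
  sampling noise ($\sigma_X = 0.002$, $\sigma_Y = 0.005$). The median's
  50%-breakdown consistency is an asymptotic property in per-instrument
  precision, not in the number of instruments: with noisy ratios the
  weighted median of a contaminated mixture sits at a shifted quantile of
  the clean distribution and inherits bias proportional to the clean
  ratio spread. The strong-instrument regime is therefore the setting in
  which the property is well defined; there the weighted median stays
  within 0.05 of the truth while IVW is biased by an order of magnitude
  more.
* **Egger recovery.** 200 studies at $n = 50$ with directional
  pleiotropy of mean 0.05 and small exposure noise
  ($\sigma_X = 0.005$); the mean intercept estimate must land within
  0.01 of 0.05. Exposure-side noise attenuates the Egger slope and leaks
  into the intercept, so this check, too, belongs to the
  strong-instrument regime.

## Numerical conventions and edge cases

* Confidence intervals use the conventional 1.96 multiplier (not
  `qnorm(0.975)`); at four printed decimals the two are
  indistinguishable for this class of problem.
* Weighted-median interpolation uses the standardized mid-cumulative
  weights; at or beyond the extreme order statistics the boundary ratio
  is returned.
* A zero exposure effect makes the Wald ratio undefined: `mr_wald_ratio`
  raises an error, `funnel_data` drops the SNP with a warning, and the
  multi-SNP estimators refuse the input.
* Clumping tie-breaks (equal p-values) are lexicographic in the variant
  id, making the output independent of row order.
* Duplicate variant ids: first occurrence wins; no published rule exists
  for which copy to prefer, and the first-wins convention is at least
  deterministic.
* The generator floors p-values at the smallest positive double so that
  near-zero sampling noise cannot produce an invalid p-value of exactly
  zero.
* `run_analysis()` writes effects and odds ratios to four decimals and
  p-values to four significant figures, so identical configurations
  produce byte-identical reports.

## Worked example

```{r}
pairs <- hypothyroidism_nafld()
mr_ivw(pairs)
cochran_q(pairs)
mr_egger(pairs)$intercept
leave_one_out(pairs)
```

## Known limitations

Beyond the generator's simplifications listed above: no mode-based
estimators, no outlier-removal schemes beyond penalization, no
multivariable MR, and no LD-aware clumping from genotypes. The bundled
nine-SNP dataset is small enough that bootstrap standard errors for the
median estimators carry visible Monte-Carlo variability below the third
decimal; increase `n_boot` if that matters for your use.
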