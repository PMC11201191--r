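---
title: "Crossover regression for gene-environment interaction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover regression for gene-environment interaction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxecross)
```

## The model family

The package analyses how a SNP's risk-allele dosage (or a cumulative
genetic score, CGS) moderates the effect of an environment on a
quantitative outcome. The running application is a reading cohort: the
outcome is a character-recognition score (a count of correctly read
characters, 0-150), the environment is parental education (PE, the mean of
two integer 1-8 levels, so it lives on a half-step grid), and the
covariates are age in months and sex.

Exploratory stage. The standard moderated regression is

$$Y = A_0 + A_1 X_1 + A_2 G + A_3 (X_1 \times G) + A_4\,\mathrm{Age} + A_5\,\mathrm{Sex} + E,$$

with $G$ the 0/1/2 dosage coded linearly (a single slope and a single
interaction coefficient, not two dummies — the re-parameterized stage is
where group-specific slopes enter). The interaction evidence is the nested
F test on the increase in $R^2$ when the product term is added; across a
panel it is Bonferroni-controlled with $m$ equal to the number of SNPs
surviving the gene-environment correlation screen.

Confirmatory stage. The interaction is re-expressed around a crossover
point $C$ on the environment scale,

$$Y = A_0 + A_g\,(X_1 - C) + A_4\,\mathrm{Age} + A_5\,\mathrm{Sex} + E,$$

with one slope $A_g$ per dosage group (Models 3a-3d) or the
linear-by-linear structure $A_1 + A_2 X_2$ for the CGS (Models 3e-3f).
The six models differ on two axes:

* crossover free (3a, 3b, 3e) versus pinned at the top of the environment
  scale (3c, 3d, 3f) — a pinned crossover makes the interaction ordinal by
  construction, the diathesis-stress hypothesis;
* reference-group slope constrained to zero ("strong", 3a/3c) versus free
  ("weak", 3b/3d).

The decision procedure mirrors the confirmatory logic of the
differential-susceptibility literature: (i) proceed only if the
exploratory interaction F ratio exceeds 1.0; (ii) within each family keep
the strong model unless freeing the reference slope adds significant
variance (nested F at 0.05); (iii) compare the two finalists by AIC and
BIC jointly — finalists often have equal parameter counts, so an F test is
unavailable; if AIC and BIC disagree the verdict is reported as
indeterminate rather than silently preferring one; (iv) classify the shape:
disordinal (differential susceptibility) requires the crossover estimate
*and its whole 95% interval* inside the observed environment range; a
free-crossover winner whose interval reaches the range boundary is
reclassified as diathesis-stress, since a disordinal crossover is what the
theory asserts.

## Estimating the crossover

Given $C$ every model is linear, so $C$ is profiled: the residual sum of
squares $RSS(C)$ is evaluated on a 201-point grid spanning
$[\min(X_1) - 2\,\mathrm{SD}, \max(X_1) + 2\,\mathrm{SD}]$, the bracketing
interval around the grid minimum is refined by Brent search, and one
quadratic-interpolation step polishes the result (Brent's precision floor
is about $\sqrt{\varepsilon}\,|C|$, visible when checking the exact
re-parameterization identity below). Two non-obvious cases are handled
explicitly:

* Runaway optima. When the interaction slope is weak, the best-fitting
  crossover can lie far outside the data window ($RSS(C)$ approaches the
  same no-interaction asymptote as $C \to \pm\infty$, and the finite
  minimum may sit in either tail). If the grid minimum lands on a window
  edge, the window is extended on *both* sides (the boundary minimum can be
  on the wrong tail) until the minimum is interior, up to 12 doublings.
* Flat profiles. If the relative variation of $RSS(C)$ across the grid is
  below $10^{-10}$, or the fit is perfect at every $C$, the crossover is
  unidentified (the interaction slope is zero); the fit is flagged
  (`identified = FALSE`) and no SE is reported.

Standard error of $C$: the reported `c_se` is the standard
nonlinear-least-squares Wald SE from the Gauss-Newton information,
$\widehat{\sigma}^2 (J'J)^{-1}$, where the Jacobian column for $C$ is the
negative per-observation environment slope. This is what `nls` and the
NLS software behind published crossover tables report, and the test suite
checks agreement with `nls` on the joint fit. The curvature of the
profiled RSS (the observed information) is an asymptotically equivalent
alternative that differs in finite samples; because Wald intervals are
fragile when the profile flattens, a profile-likelihood interval
(`c_ci_profile`, inverting the F test on $RSS(C) - RSS_{\min}$) is emitted
alongside the Wald one.

Degrees of freedom count $C$ as a mean parameter wherever it is estimated:
the strong free-crossover model spends 6 mean parameters at $n = 1477$
(residual df 1471), its fixed-$C$ counterpart 5. Information criteria use
the least-squares forms $AIC = n\log(RSS/n) + 2k$ and
$BIC = n\log(RSS/n) + k\log n$ with $k$ = mean parameters + 1 for the
residual variance. Absolute AIC/BIC values are therefore comparable only
within this package; all decisions rest on differences, and same-df models
rank identically to RSS under both criteria (a tested invariant).

A useful exact identity ties the two stages together: the exploratory
model with linear dosage coding *is* a common-crossover model with equally
spaced slopes, with $C = -\hat A_2/\hat A_3$. The test suite verifies on
simulated cohorts that the profiled linear-moderator fit reproduces the
exploratory fit's fitted values to $10^{-8}$, and that fixed-$C$ fits
match ordinary least squares on the transformed columns to $10^{-10}$.

## Quality control and screening choices

* HWE test: the three-genotype goodness-of-fit statistic with the allele
  frequency estimated from the counts. The statistically standard
  reference distribution has df = 1; df = 2 (charging nothing for the
  estimated frequency) is available because published panel tables are
  sometimes computed that way — the bundled worked example (genotype
  counts 545/687/245, $\chi^2 = 1.30$, $p = 0.52$) reproduces its source
  table only at df = 2.
* QC thresholds default to call rate $\ge 0.95$, MAF $\ge 0.02$, HWE
  $p \ge 10^{-5}$; flags are non-destructive and a helper drops failures.
* The CGS is the unweighted sum of risk-allele dosages. Source-study betas
  are carried as metadata only; the one panel SNP with a negative source
  beta is coded by its declared risk allele as-is, following the unweighted
  coding rule (a weighted or flipped coding is a deliberate non-goal).
* The rGE screen excludes any SNP whose Pearson correlation with the
  environment is significant at 0.05 (two-sided), and recomputes the CGS
  on the retained panel. Exclusion is a hard rule at the chosen level;
  the level is configurable.

## What the synthetic cohorts emulate

The generator reproduces the statistical structure the analysis assumes,
under any of four generative models (strong/weak differential
susceptibility, strong/weak diathesis-stress) plus a no-interaction null:

* genotypes i.i.d. Binomial(2, MAF) — exact HWE; the focal SNP defaults to
  MAF 0.398;
* parental education as the mean of two independent integer 1-8 draws from
  a discretized-normal level distribution moment-matched to PE mean 3.21
  and SD 1.21. The SD is derived from the two published crossover anchors
  (the fixed diathesis-stress crossover 6.85 equals mean + 3 SD); the
  shape of the level distribution is otherwise unreported, so moment
  matching is the only constraint honoured;
* age Normal(116.34, 12.14) months truncated to [84, 156] (plausible for
  grades 3-6); sex Bernoulli(0.5) coded 0 = male (only the slope's sign
  depends on the coding);
* outcome $Y = A_0 + \mathrm{slope}(G)(X_1 - C) + 0.91\,\mathrm{Age} -
  2.53\,\mathrm{Sex} + \varepsilon$ with group slopes (0, 2.49, 3.27) and
  $C = 3.21$ under the strong differential-susceptibility default;
  diathesis-stress truths move $C$ to mean + 3 SD;
* the residual SD is not a published quantity; `calibrate_sigma()` finds it
  by root-finding on the fitted confirmatory $R^2$ (default target 0.2567),
  holding one latent cohort fixed so the objective is smooth and strictly
  decreasing. The calibrated value is near 19 score points;
* optional gene-environment correlation is injected by a Gaussian rank
  coupling that reorders PE against one SNP's dosage ranks; this preserves
  both marginals exactly (genotypes stay in HWE) and hits the target
  Pearson correlation by root-finding on the realized value.

What the generator does *not* emulate: genotyping error, missingness
mechanisms, imputation uncertainty, floor/ceiling effects in the reading
score, any skew in the PE distribution beyond its first two moments, and
real linkage disequilibrium between panel SNPs (dosages are independent
across SNPs). Passing simulation tests therefore validate the estimator
and decision procedure under the assumed structure, not robustness to
those real-data features.

## Validation problem sizes

The test suite exercises the pipeline at the study scale it targets:
crossover recovery and 95% CI coverage over 500 cohorts of n = 1477;
type-I error of the exploratory interaction test over 2000 null cohorts;
model-selection consistency over 200 cohorts per generative truth; the
re-parameterization identity over 100 cohorts of n = 400 and the
grid-search oracle over 20 cohorts of n = 300 — sizes chosen so each
property is measured with useful Monte-Carlo precision while the whole
suite stays quick. The coverage of the Wald interval for $C$ is mildly
conservative under these conditions (the SE inflates in low-slope
replicates, which also carry the large errors), a known property of Wald
intervals for crossover-type parameters.

## Known limitations

* No exact-test HWE (the chi-square approximation is poor at very small
  counts), no sample-level QC (relatedness, sex checks), no imputation.
* Wald and profile intervals for $C$ are both reported, but neither is
  trustworthy when the interaction slope is near zero; the flat-profile
  flag should be checked before interpreting $C$ at all.
* The decision procedure's AIC/BIC arbitration has no finite-sample error
  control; under a true diathesis-stress generative model the procedure
  picks the right family in a clear majority of replicates but not
  near-certainty, because the free-crossover competitor can imitate a
  top-of-scale crossover at the cost of one parameter.
* Robust/clustered standard errors, Bayesian fits, bootstrap intervals and
  quadratic-in-environment variants are out of scope.
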