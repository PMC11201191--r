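# gxecross

Gene–environment (G×E) interaction analysis for quantitative traits with a
small SNP panel, centred on the re-parameterized crossover regression that
arbitrates between the **differential-susceptibility** and
**diathesis–stress** models of G×E.

## The scientific problem

When a genotype moderates the effect of an environment on an outcome (say,
risk-allele dosage at a dyslexia-associated SNP moderating the effect of
parental education on a child's reading score), two competing theories
predict different interaction shapes:

* *Diathesis–stress*: risk-allele carriers are harmed by poor environments
  but never surpass non-carriers — the genotype-specific regression lines
  cross at or beyond the top of the observed environment range (an
  **ordinal** interaction).
* *Differential susceptibility*: carriers of a "plasticity" allele do worse
  in poor environments **and better in rich ones** — the lines cross inside
  the observed range (a **disordinal** interaction).

The standard product-term regression

> Y = A₀ + A₁X₁ + A₂T + A₃(X₁×T) + A₄·Age + A₅·Sex + E

(X₁ the environment, T the risk-allele dosage 0/1/2) detects an interaction
but cannot distinguish the two theories. Re-parameterizing around the
crossover point C,

> Y = A₀ + A_g·(X₁ − C) + A₄·Age + A₅·Sex + E,  slope A_g per dosage group g,

turns the question into a model-comparison problem: with C free the lines
cross where the data put them (differential susceptibility); with C pinned
at the top of the environment scale (mean + 3 SD) the interaction is
ordinal by construction (diathesis–stress). "Strong" variants constrain the
zero-risk-allele group's slope to zero; "weak" variants leave it free.
Given C the model is linear, so C is estimated by profiled least squares
(coarse grid, bracketed refinement, quadratic polish), with the standard
nonlinear-least-squares Wald SE from σ²(J′J)⁻¹ and a profile-likelihood
interval alongside. Nested F tests pick within families, AIC/BIC arbitrate
across them, and the crossover CI against the observed environment range
gives the ordinal/disordinal verdict.

The package implements the full pipeline around that core: variant QC
(Hardy–Weinberg χ², MAF, call rate), risk-allele dosage coding and the
unweighted cumulative genetic score (CGS), a gene–environment correlation
screen, the exploratory per-SNP scan with Bonferroni control, the CGS
interaction with its confirmatory gate (interaction F ratio > 1), and a
synthetic-cohort generator so that every stage is testable without access
to restricted cohort data.

## Worked example

```r
library(gxecross)

# a study-scale cohort under the strong differential-susceptibility model
cfg <- sim_config(n = 1477, model_id = "strong_ds", seed = 1)
cohort <- gen_cohort(cfg)

# confirmatory crossover regression for the focal SNP
fit <- fit_crossover_groups(cohort, "snp1", c_mode = "free", strong = TRUE)
print(fit)
#> Re-parameterized crossover regression (Model 3a, groups)
#>   C = 3.4416 (SE 0.3867), 95% CI [2.6838, 4.1995]
#>   A0 = 4.9582 (5.0438)
#>   A2 = 2.2468 (0.6105)
#>   A3 = 3.4144 (0.9641)
#>   R2 = 0.2336, F(5, 1471) = 89.67, AIC = 8696.43, BIC = 8733.51

# arbitrate among the four competing interaction models
cls <- compare_models(fit_crossover_family(cohort, "snp1"),
                      gate_passed = TRUE,
                      pe_range = range(cohort$pheno$pe))
print(cls)
#> G x E model classification
#>   gate passed: TRUE
#>   selected model: 3a
#>   family: differential_susceptibility   strength: strong   shape: disordinal
```

The crossover estimate (3.44, CI [2.68, 4.20]) sits near the generative
truth of 3.21 and well inside the observed parental-education range, the
dosage-group slopes (0 fixed / 2.25 / 3.41) bracket the generative
2.49/3.27, and the arbitration keeps the strong differential-susceptibility
model: freeing the reference slope adds nothing (p = 0.44), while the
fixed-crossover finalist loses on both AIC and BIC.

The `analysis/` directory holds the same workflow as numbered stage
scripts (simulate → QC → rGE screen → exploratory scan → confirmatory
models → operating characteristics), each writing its tables under
`results/`.

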