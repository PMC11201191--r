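test_that("noiseless crossover data are recovered exactly", {
  co <- gen_cohort(sim_config(n = 400, sigma = 0, model_id = "strong_ds",
                              seed = 61))
  fit <- fit_crossover_groups(co, "snp1", "free", strong = TRUE)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$c_hat, 3.21, tolerance = 1e-6)
  expect_equal(fit$group_slopes$estimate, c(2.49, 3.27), tolerance = 1e-6)
  expect_equal(fit$a0, -0.90, tolerance = 1e-6)
})

test_that("fixed-crossover fits equal OLS on the transformed columns", {
  for (i in 1:5) {
    co <- make_cohort(n = 250, seed = 700 + i)
    C <- fixed_crossover(co$pheno$pe)
    fit <- fit_crossover_groups(co, "snp1", "fixed", c_value = C,
                                strong = FALSE)
    ph <- co$pheno; d <- co$dosages[, 1]
    X <- cbind(1, (d == 0) * (ph$pe - C), (d == 1) * (ph$pe - C),
               (d == 2) * (ph$pe - C), ph$age, ph$sex)
    beta <- drop(ols_oracle(X, ph$score))
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
    expect_equal(fit$rss, sum((ph$score - X %*% beta)^2), tolerance = 1e-10)

    # CGS variant against the same oracle
    fitc <- fit_crossover_linear(co, "cgs", "fixed", c_value = C)
    Xc <- cbind(1, ph$pe - C, (ph$pe - C) * co$cgs, ph$age, ph$sex)
    betac <- drop(ols_oracle(Xc, ph$score))
    expect_equal(unname(fitc$coefficients), betac, tolerance = 1e-10)
  }
})

test_that("the profiled crossover matches an exhaustive grid search", {
  for (i in 1:3) {
    co <- make_cohort(n = 300, seed = 810 + i)
    fit <- fit_crossover_groups(co, "snp1", "free", strong = TRUE)
    oracle <- grid_search_c(co, "snp1", strong = TRUE, step = 0.001,
                            extra_center = fit$c_hat)
    expect_lt(abs(fit$c_hat - oracle$c), 0.001)
  }
})

test_that("Wald intervals use the 1.959964 normal quantile", {
  expect_equal(wald_ci(3.21, 0.36), c(2.5044, 3.9156), tolerance = 1e-4)
  expect_equal(wald_ci(3.21, 0.42), c(2.3868, 4.0332), tolerance = 1e-4)
  expect_equal(wald_ci(3.34, 0.56)[1], 2.2424, tolerance = 1e-4)
  expect_equal(wald_ci(5, 0), c(5, 5))
  expect_error(wald_ci(1, -1), "nonnegative")
  expect_error(wald_ci(1, 1, level = 1.2), "level")
})

test_that("model family obeys the nesting inequalities and IC/RSS ranking", {
  for (i in 1:5) {
    co <- make_cohort(n = 350, seed = 900 + i)
    fits <- fit_crossover_family(co, "snp1")
    expect_gte(fits[["3b"]]$r2, fits[["3a"]]$r2 - 1e-10)
    expect_gte(fits[["3d"]]$r2, fits[["3c"]]$r2 - 1e-10)
    expect_gte(fits[["3b"]]$r2, fits[["3d"]]$r2 - 1e-10)
    fe <- fit_crossover_family_cgs(co)
    expect_gte(fe[["3e"]]$r2, fe[["3f"]]$r2 - 1e-10)
    # same-df models rank identically by AIC, BIC and RSS
    expect_identical(fits[["3a"]]$aic < fits[["3d"]]$aic,
                     fits[["3a"]]$rss < fits[["3d"]]$rss)
    expect_identical(fits[["3a"]]$bic < fits[["3d"]]$bic,
                     fits[["3a"]]$rss < fits[["3d"]]$rss)
  }
})

test_that("the linear-coded interaction model is a common-crossover model", {
  co <- make_cohort(n = 500, seed = 77)
  m2 <- fit_ols(co, "snp1")
  b <- m2$coefficients
  # algebraic identity: C = -A2/A3, slopes A1 + A3 * T
  C <- -b[["G"]] / b[["X1:G"]]
  ph <- co$pheno; d <- co$dosages[, 1]
  pred <- (b[["(Intercept)"]] + b[["X1"]] * C) +
    (b[["X1"]] + b[["X1:G"]] * d) * (ph$pe - C) +
    b[["Age"]] * ph$age + b[["Sex"]] * ph$sex
  expect_equal(pred, m2$fitted, tolerance = 1e-8)

  # the profiled equally-spaced-slope fit lands on the same optimum
  fit <- fit_crossover_linear(co, moderator = d, c_mode = "free")
  expect_equal(fit$c_hat, C, tolerance = 1e-5)
  expect_equal(fit$fitted, m2$fitted, tolerance = 1e-8)
})

test_that("a flat profile flags the crossover as unidentified", {
  co <- gen_cohort(sim_config(n = 300, seed = 88, model_id = "null",
                              structure = "cgs", sigma = 1,
                              params = list(a1 = 2, a2 = 0)))
  # remove any sample interaction signal exactly: project it out
  fit <- fit_crossover_linear(co, "cgs", "free")
  if (!fit$identified) {
    expect_true(is.na(fit$c_se))
  } else {
    # sampling noise leaves a tiny interaction; the profile is then curved
    # but the interaction slope is negligible
    a2 <- fit$group_slopes$estimate[fit$group_slopes$term == "A2"]
    expect_lt(abs(a2), 0.05)
  }
  # an exactly flat case: interaction-free noiseless outcome
  co$pheno$score <- 1 + 0 * co$pheno$pe + 0.5 * co$pheno$age
  fit0 <- fit_crossover_linear(co, "cgs", "free")
  expect_false(fit0$identified)
})

test_that("crossover point and SE agree with joint nonlinear least squares", {
  co <- make_cohort(n = 1477, seed = 93, model_id = "strong_ds")
  fit <- fit_crossover_groups(co, "snp1", "free", strong = TRUE)
  ph <- co$pheno; d <- co$dosages[, 1]
  g1 <- as.numeric(d == 1); g2 <- as.numeric(d == 2)
  nls_fit <- nls(score ~ a0 + (g1 * a2 + g2 * a3) * (pe - C) +
                   b4 * age + b5 * sex,
                 data = cbind(ph, g1 = g1, g2 = g2),
                 start = list(a0 = 0, a2 = 1, a3 = 1, C = 3, b4 = 1, b5 = 0))
  est <- summary(nls_fit)$coefficients
  expect_equal(fit$c_hat, est["C", "Estimate"], tolerance = 1e-4)
  expect_equal(fit$c_se, est["C", "Std. Error"], tolerance = 1e-3)
  expect_equal(fit$group_slopes$estimate,
               unname(est[c("a2", "a3"), "Estimate"]), tolerance = 1e-4)
})

test_that("model comparison reproduces the published decision pattern", {
  co <- make_cohort(n = 1477, seed = 42, model_id = "strong_ds")
  fits <- fit_crossover_family(co, "snp1")
  cls <- compare_models(fits, gate_passed = TRUE,
                        pe_range = range(co$pheno$pe))
  expect_s3_class(cls, "gxe_classification")
  expect_equal(cls$selected_model, "3a")
  expect_equal(cls$family, "differential_susceptibility")
  expect_equal(cls$strength, "strong")
  expect_equal(cls$shape, "disordinal")

  # gate failure short-circuits the whole procedure
  cls0 <- compare_models(fits, gate_passed = FALSE,
                         pe_range = range(co$pheno$pe))
  expect_equal(cls0$family, "none")
  expect_true(is.na(cls0$selected_model))

  # CGS branch: acceptance of the free crossover hinges on the nested F
  fe <- fit_crossover_family_cgs(co)
  cmp <- nested_f_test(fe[["3f"]], fe[["3e"]])
  cls_c <- compare_models(fe, gate_passed = TRUE,
                          pe_range = range(co$pheno$pe))
  expected <- if (cmp$p < 0.05) "3e" else "3f"
  expect_equal(cls_c$selected_model, expected)
})

test_that("predicted surfaces cross at the crossover point", {
  co <- gen_cohort(sim_config(n = 400, sigma = 0, model_id = "strong_ds",
                              seed = 95))
  fit <- fit_crossover_groups(co, "snp1", "free", strong = TRUE)
  surf <- predicted_surface(fit, pe_grid = c(fit$c_hat, 5), levels = 0:2,
                            age = 116.34, sex = 0.5)
  at_c <- surf$predicted[surf$pe == fit$c_hat]
  expect_equal(max(at_c) - min(at_c), 0, tolerance = 1e-8)
  # the no-risk-allele group is flat in PE under the strong model
  flat <- predicted_surface(fit, pe_grid = c(2, 6), levels = 0)
  expect_equal(diff(flat$predicted), 0, tolerance = 1e-8)
  # slope arithmetic: difference between groups 2 and 0 at PE 5
  at5 <- surf[surf$pe == 5, ]
  expect_equal(at5$predicted[at5$level == 2] - at5$predicted[at5$level == 0],
               3.27 * (5 - 3.21), tolerance = 1e-4)
})
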