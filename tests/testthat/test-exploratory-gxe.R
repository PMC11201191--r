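test_that("OLS recovers exact fits on noiseless toy data", {
  pheno <- data.frame(id = paste0("i", 1:4), score = 2 * (1:4) + 1,
                      pe = 1:4, age = 0, sex = 0)
  co <- gxe_cohort(pheno, cbind(g = c(0, 1, 2, 1)))
  fit <- fit_ols(co, "g", interaction = FALSE, covariates = FALSE)
  expect_equal(unname(fit$coefficients[c("(Intercept)", "X1", "G")]),
               c(1, 2, 0), tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_equal(fit$r2, 1)
})

test_that("OLS agrees with a normal-equations oracle on random designs", {
  set.seed(14)
  for (i in 1:20) {
    n <- 60
    co <- make_cohort(n = n, seed = 1000 + i, n_snps = 2)
    fit <- fit_ols(co, "snp1")
    X <- cbind(1, co$pheno$pe, co$dosages[, 1],
               co$pheno$pe * co$dosages[, 1], co$pheno$age, co$pheno$sex)
    beta <- drop(ols_oracle(X, co$pheno$score))
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
    # SEs from the unbiased residual-variance estimator
    s2 <- sum((co$pheno$score - X %*% beta)^2) / (n - 6)
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))
    expect_equal(unname(fit$se), se, tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are reported with the offending column", {
  co <- make_cohort(n = 50, seed = 3)
  co$pheno$age <- 5 # constant, collinear with intercept
  expect_error(fit_ols(co, "snp1"), "Age")
})

test_that("the nested F statistic follows the delta-R-squared formula", {
  fake <- function(r2, df_resid, n) {
    structure(list(r2 = r2, df = c(model = n - 1 - df_resid,
                                   resid = df_resid), n = n),
              class = "gxe_lm")
  }
  cmp <- nested_f_test(fake(0.10, 51, 55), fake(0.20, 50, 55))
  expect_equal(cmp$f, 6.25, tolerance = 1e-12)
  expect_equal(cmp$df, c(1, 50), ignore_attr = TRUE)

  co <- make_cohort(n = 200, seed = 8)
  m2 <- fit_ols(co, "snp1")
  ident <- nested_f_test(fit_ols(co, "snp1"), m2)
  expect_equal(ident$f, 0)
  expect_equal(ident$p, 1)
  expect_error(nested_f_test(m2, fit_ols(co, "snp1", interaction = FALSE)),
               "nested")
})

test_that("adding a term never decreases R-squared", {
  for (i in 1:10) {
    co <- make_cohort(n = 150, seed = 2000 + i)
    m1 <- fit_ols(co, "snp1", interaction = FALSE)
    m2 <- fit_ols(co, "snp1", interaction = TRUE)
    expect_gte(m2$r2, m1$r2 - 1e-12)
    cmp <- nested_f_test(m1, m2)
    expect_gte(cmp$delta_r2, 0)
    expect_true(cmp$p >= 0 && cmp$p <= 1)
  }
})

test_that("interaction F-test p-values are uniform under the null", {
  set.seed(22)
  pvals <- replicate(400, {
    co <- gen_cohort(sim_config(n = 150, n_snps = 1, model_id = "null",
                                sigma = 19.44))
    nested_f_test(fit_ols(co, "snp1", interaction = FALSE),
                  fit_ols(co, "snp1"))$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the Bonferroni scan controls the per-test threshold", {
  co <- make_cohort(n = 600, seed = 44, n_snps = 8)
  scan <- run_snp_scan(co, alpha = 0.05)
  expect_equal(nrow(scan), 8)
  expect_equal(unique(scan$threshold), 0.05 / 8)
  expect_equal(scan$significant, scan$p < 0.05 / 8)
  # 0.005 clears the 8-SNP threshold, 0.01 does not
  expect_true(0.005 < unique(scan$threshold))
  expect_false(0.01 < unique(scan$threshold))
  # single-SNP scan keeps the raw level
  scan1 <- run_snp_scan(co, snps = "snp1", alpha = 0.05)
  expect_equal(scan1$threshold, 0.05)
  # verdicts invariant to SNP order
  scan_rev <- run_snp_scan(co, snps = rev(colnames(co$dosages)))
  expect_equal(scan_rev[match(scan$snp_id, scan_rev$snp_id), "p"], scan$p)
})

test_that("monomorphic SNPs are skipped with a warning", {
  co <- make_cohort(n = 80, seed = 5, n_snps = 2)
  co$dosages[, 2] <- 0
  expect_warning(scan <- run_snp_scan(co), "monomorphic")
  expect_equal(scan$snp_id, "snp1")
})

test_that("the CGS interaction recovers its generative slope and gates on F > 1", {
  co <- make_cohort(n = 1477, seed = 51, model_id = "strong_ds",
                    structure = "cgs")
  st <- fit_cgs_interaction(co)
  a3 <- st$inter$coefficients[["X1:G"]]
  expect_lt(abs(a3 - 0.52), 2 * st$inter$se[["X1:G"]])
  expect_identical(st$gate_passed, st$comparison$f > 1.0)

  co0 <- make_cohort(n = 300, seed = 52)
  co0$dosages[] <- 1L
  co0$cgs <- rowSums(co0$dosages)
  expect_error(fit_cgs_interaction(co0), "variance")
})

test_that("simple slopes combine main and product coefficients", {
  fake <- structure(list(
    coefficients = c("(Intercept)" = 0, X1 = 0.63, G = -5.08, `X1:G` = 1.56),
    vcov = diag(1e-4, 4, 4) |>
      `dimnames<-`(list(c("(Intercept)", "X1", "G", "X1:G"),
                        c("(Intercept)", "X1", "G", "X1:G"))),
    df = c(model = 5, resid = 1471), interaction = TRUE),
    class = "gxe_lm")
  ss <- simple_slopes(fake, 0:2)
  expect_equal(ss$slope, c(0.63, 2.19, 3.75))

  # zero product term: every level has the main-effect slope
  fake$coefficients[["X1:G"]] <- 0
  expect_equal(unique(simple_slopes(fake, 0:2)$slope), 0.63)

  # on strong differential-susceptibility data the reference-group slope is 0
  co <- make_cohort(n = 1477, seed = 53, model_id = "strong_ds")
  fit <- fit_ols(co, "snp1")
  s0 <- simple_slopes(fit, 0)
  expect_lt(abs(s0$slope), 2 * s0$se)
})
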