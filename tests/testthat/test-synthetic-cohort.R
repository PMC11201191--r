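test_that("genotype generation follows Hardy-Weinberg proportions", {
  expect_equal(gen_genotypes(50, 0, seed = 1), rep(0L, 50))
  expect_equal(gen_genotypes(50, 1, seed = 1), rep(2L, 50))
  expect_error(gen_genotypes(10, 1.2), "maf")

  d <- gen_genotypes(100000, 0.398, seed = 7)
  expect_lt(abs(mean(d) - 2 * 0.398), 0.01)

  d <- gen_genotypes(40000, 0.5, seed = 11)
  props <- genotype_counts(d) / 40000
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.01))
})

test_that("parental education lies on the half-step grid and matches its moments", {
  point <- c(0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(gen_environment(20, point, seed = 1), rep(3, 20),
               ignore_attr = TRUE)
  expect_error(gen_environment(10, c(0.5, 0.5)), "probabilities")

  pe <- gen_environment(10000, calibrate_pe_probs(), seed = 3)
  expect_lt(abs(mean(pe) - 3.21), 0.05)
  expect_lt(abs(sd(pe) - 1.21), 0.05)
  expect_gte(min(pe), 1)
  expect_lte(max(pe), 8)
  expect_true(all(pe * 2 == round(pe * 2)))
})

test_that("noiseless strong models leave the reference group flat in PE", {
  cfg <- sim_config(n = 300, sigma = 0, model_id = "strong_ds", seed = 5)
  co <- gen_cohort(cfg)
  ref <- co$dosages[, 1] == 0
  resid <- co$pheno$score - 0.91 * co$pheno$age + 2.53 * co$pheno$sex
  expect_true(sum(ref) > 10)
  expect_lt(var(resid[ref]), 1e-20)
})

test_that("generative parameters are recovered at cohort scale", {
  co <- make_cohort(n = 1477, seed = 21, model_id = "strong_ds")
  fit <- fit_crossover_groups(co, "snp1", "free", strong = TRUE)
  truth <- c(A2 = 2.49, A3 = 3.27)
  for (term in names(truth)) {
    row <- fit$group_slopes[fit$group_slopes$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 2 * row$se)
  }
  expect_lt(abs(fit$a0 - (-0.90)), 2 * fit$a0_se)
  expect_lt(abs(fit$c_hat - 3.21), 2 * fit$c_se)
})

test_that("cohort generation is deterministic under a fixed seed", {
  d1 <- file.path(tempdir(), "cohortA"); d2 <- file.path(tempdir(), "cohortB")
  co1 <- gen_cohort(sim_config(n = 10, seed = 99), out_dir = d1)
  co2 <- gen_cohort(sim_config(n = 10, seed = 99), out_dir = d2)
  expect_identical(co1$pheno, co2$pheno)
  expect_identical(co1$dosages, co2$dosages)
  expect_identical(readLines(file.path(d1, "phenotypes.csv")),
                   readLines(file.path(d2, "phenotypes.csv")))
  expect_identical(readLines(file.path(d1, "dosages.raw")),
                   readLines(file.path(d2, "dosages.raw")))
})

test_that("gene-environment correlation injection hits its target", {
  co0 <- gen_cohort(sim_config(n = 50000, n_snps = 2, seed = 13, rge_r = 0))
  expect_lt(abs(cor(co0$dosages[, 1], co0$pheno$pe)), 0.02)

  co <- gen_cohort(sim_config(n = 50000, n_snps = 2, seed = 13, rge_r = 0.3))
  expect_lt(abs(cor(co$dosages[, 1], co$pheno$pe) - 0.3), 0.03)
  # marginals preserved exactly
  expect_equal(sort(co$pheno$pe), sort(co0$pheno$pe))
  # parent levels stay consistent with the reordered PE
  expect_equal(co$pheno$pe, (co$pheno$pe_father + co$pheno$pe_mother) / 2)
})

test_that("the CGS is the dosage row sum and simulated SNPs pass an HWE screen", {
  co <- make_cohort(n = 800, seed = 31)
  expect_equal(co$cgs, rowSums(co$dosages))
  expect_true(all(co$cgs >= 0 & co$cgs <= 2 * ncol(co$dosages)))

  # across replicates, the HWE chi-square screen is non-significant at
  # about the nominal 5% rate
  set.seed(41)
  pvals <- replicate(300, {
    d <- gen_genotypes(500, 0.4)
    hwe_test(genotype_counts(d))$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
})

test_that("sigma calibration reaches the target model R-squared", {
  cfg <- sim_config(model_id = "strong_ds")
  sg <- calibrate_sigma(cfg, target_r2 = 0.2567, n_calib = 8000, seed = 2)
  expect_lt(abs(attr(sg, "achieved_r2") - 0.2567), 1e-3)
  expect_gt(sg, 10); expect_lt(sg, 40)
})
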