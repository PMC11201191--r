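test_that("HWE goodness-of-fit matches hand-computed statistics", {
  # pooled genotype counts for the focal SNP panel entry
  h <- hwe_test(c(545, 687, 245), df = 2)
  expect_equal(h$allele_freq, (2 * 245 + 687) / (2 * 1477))
  expect_equal(h$chi2, 1.3034, tolerance = 1e-4)
  expect_equal(h$p, 0.5212, tolerance = 1e-4)
  expect_equal(hwe_test(c(545, 687, 245), df = 1)$p, 0.2536, tolerance = 1e-4)

  # exact HWE proportions give a zero statistic at any df
  h0 <- hwe_test(c(25, 50, 25))
  expect_equal(h0$chi2, 0)
  expect_equal(h0$p, 1)

  # uniform counts: freq 0.5, expected (7.5, 15, 7.5), chi2 = 10/3
  h1 <- hwe_test(c(10, 10, 10), df = 2)
  expect_equal(h1$chi2, 10 / 3, tolerance = 1e-12)
  expect_equal(h1$p, pchisq(10 / 3, 2, lower.tail = FALSE))

  expect_error(hwe_test(c(0, 0, 0)), "zero")
  expect_error(hwe_test(c(-1, 5, 5)), "nonnegative")
})

test_that("HWE statistic is invariant to swapping the allele labels", {
  set.seed(8)
  for (i in 1:25) {
    cnt <- as.numeric(rmultinom(1, 200, c(0.3, 0.5, 0.2)))
    expect_equal(hwe_test(cnt)$chi2, hwe_test(rev(cnt))$chi2,
                 tolerance = 1e-12)
  }
})

test_that("variant QC flags call rate, MAF and HWE failures", {
  set.seed(3)
  n <- 400
  good <- gen_genotypes(n, 0.4, seed = 1)
  rare <- rbinom(n, 2, 0.01)
  gappy <- good; gappy[1:40] <- NA            # 10% missing
  off_hwe <- c(rep(0, 200), rep(2, 200))      # no heterozygotes at freq 0.5
  dos <- cbind(good = good, rare = rare, gappy = gappy, off_hwe = off_hwe)
  qc <- variant_qc(dos)
  v <- qc$variants
  expect_true(v$pass[v$snp_id == "good"])
  expect_false(v$pass_maf[v$snp_id == "rare"])
  expect_false(v$pass_call_rate[v$snp_id == "gappy"])
  expect_equal(v$call_rate[v$snp_id == "gappy"], 0.9)
  expect_false(v$pass_hwe[v$snp_id == "off_hwe"])
  expect_equal(colnames(drop_failed_variants(dos, qc)), "good")
  expect_error(variant_qc(dos[, 0, drop = FALSE]), "empty")
})

test_that("risk-allele dosage coding counts risk alleles", {
  expect_equal(code_risk_dosage(c("CC", "CT", "TT"), "T", "C", "rs281238"),
               c(0, 1, 2))
  expect_equal(code_risk_dosage(c("C/T", "T|T", NA, "CC"), "T", "C"),
               c(1, 2, NA, 0))
  expect_equal(code_risk_dosage("GG", "A", "G"), 0)
  err <- tryCatch(code_risk_dosage(c("CC", "CG"), "T", "C", "rs281238",
                                   ids = c("s1", "s2")),
                  error = conditionMessage)
  expect_match(err, "rs281238")
  expect_match(err, "s2")
})

test_that("the CGS is an unweighted dosage sum with the expected algebra", {
  expect_equal(compute_cgs(matrix(0, 5, 9)), rep(0, 5))
  expect_equal(compute_cgs(matrix(2, 1, 9)), 18)
  expect_equal(compute_cgs(matrix(c(2, 1, 0, 1, 0, 0, 2, 1, 1), 1, 9)), 8)
  expect_error(compute_cgs(matrix(c(1, NA), 1, 2)), "complete")

  # permutation equivariance in SNP order and additivity over partitions
  set.seed(5)
  dos <- matrix(rbinom(60, 2, 0.4), 10, 6)
  perm <- sample(6)
  expect_equal(compute_cgs(dos), compute_cgs(dos[, perm]))
  expect_equal(compute_cgs(dos),
               compute_cgs(dos[, 1:3]) + compute_cgs(dos[, 4:6]))
})

test_that("dosage tables round-trip through the PLINK-.raw-style format", {
  co <- make_cohort(n = 12, seed = 2, n_snps = 3)
  path <- tempfile(fileext = ".raw")
  alleles <- c(snp1 = "T", snp2 = "G", snp3 = "A")
  write_dosage_raw(co$dosages, co$pheno$id, path, counted_alleles = alleles)
  back <- read_dosage_raw(path)
  expect_equal(back$ids, co$pheno$id)
  expect_equal(unname(back$dosages), unname(co$dosages))
  expect_equal(back$counted_alleles[["snp1"]], "T")
})

test_that("VCF genotypes map onto declared risk alleles", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "15\t47432075\trs281238\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t100\trs000001\tG\tA\t.\tPASS\t.\tGT\t1|1\t0|0\t./."), vcf)
  info <- data.frame(snp_id = c("rs281238", "rs000001"),
                     risk_allele = c("T", "A"), other_allele = c("C", "G"))
  got <- read_genotypes_vcf(vcf, info)
  expect_equal(got$dosages[, "rs281238"], c(s1 = 0, s2 = 1, s3 = 2))
  expect_equal(got$dosages[, "rs000001"], c(s1 = 2, s2 = 0, s3 = NA))
})

test_that("fraction of HWE failures at the QC threshold vanishes on clean data", {
  set.seed(17)
  fails <- replicate(60, {
    d <- gen_genotypes(2000, 0.35)
    hwe_test(genotype_counts(d))$p < 1e-5
  })
  expect_equal(mean(fails), 0)
})
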