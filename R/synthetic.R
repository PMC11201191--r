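#' Simulation configuration for synthetic cohorts
#'
#' Bundles the generative settings for [gen_cohort()]. Defaults reproduce
#' the structure of a school-age reading cohort: a nine-SNP panel in
#' Hardy-Weinberg equilibrium at MAF 0.398 for the focal SNP, parental
#' education (PE) as the mean of two integer 1-8 levels calibrated to mean
#' 3.21 and SD 1.21, age 116.34 +/- 12.14 months truncated to 84-156,
#' balanced sex, and a phenotype generated from one of four competing
#' G\eqn{\times}E models around a crossover point on the environment scale.
#'
#' @param n individuals (default 1477).
#' @param maf risk-allele frequency per SNP; recycled to `n_snps`. The first
#'   (focal) SNP defaults to 0.398.
#' @param n_snps panel size (default 9).
#' @param pe_parent_probs probability vector over parent education levels
#'   1-8; default calibrated by [calibrate_pe_probs()] so PE has mean 3.21
#'   and SD 1.21.
#' @param age_mean_months,age_sd_months,age_range age distribution:
#'   Normal(116.34, 12.14) truncated to \[84, 156\] months.
#' @param sex_balance fraction with sex code 1 (0 = male, 1 = female).
#' @param model_id generative interaction model: `"strong_ds"` (strong
#'   differential susceptibility: zero slope in the no-risk-allele group,
#'   crossover near the PE mean), `"weak_ds"`, `"strong_dis"` /
#'   `"weak_dis"` (diathesis-stress: crossover at mean(PE) + 3 SD), or
#'   `"null"` (all genotype groups share one slope; no interaction).
#' @param params generative coefficients; missing entries are filled with
#'   defaults. For the genotype-group structure: `a0` (intercept at the
#'   crossover), `slopes` (length-3 PE slopes for dosage 0/1/2),
#'   `c` (crossover point), `age_slope`, `sex_slope`. For
#'   `structure = "cgs"`: `a1` (PE slope at CGS 0) and `a2`
#'   (linear-by-linear interaction slope) replace `slopes`.
#' @param sigma residual SD of the phenotype; the default (19.44) is
#'   produced by [calibrate_sigma()] so the fitted confirmatory model has
#'   R-squared near 0.257 at the default effects.
#' @param structure `"groups"` (slope per focal-SNP dosage group) or
#'   `"cgs"` (linear-by-linear in the cumulative genetic score).
#' @param focal_snp index of the SNP whose dosage moderates the phenotype.
#' @param rge_r target Pearson correlation between PE and the dosage of
#'   `rge_snp` (gene-environment correlation), injected by rank reordering;
#'   default 0 (independence).
#' @param rge_snp index of the SNP receiving the rGE injection.
#' @param snp_ids optional character vector of SNP names for the simulated
#'   panel (default `snp1`, `snp2`, ...).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 1477,
                       maf = c(0.398, rep(0.35, 8)),
                       n_snps = 9,
                       pe_parent_probs = NULL,
                       age_mean_months = 116.34,
                       age_sd_months = 12.14,
                       age_range = c(84, 156),
                       sex_balance = 0.5,
                       model_id = c("strong_ds", "weak_ds", "strong_dis",
                                    "weak_dis", "null"),
                       params = list(),
                       sigma = 19.44,
                       structure = c("groups", "cgs"),
                       focal_snp = 1L,
                       rge_r = 0,
                       rge_snp = 1L,
                       snp_ids = NULL,
                       seed = NULL) {
  model_id <- match.arg(model_id)
  structure_ <- match.arg(structure)
  if (n < 1) stop_input("n must be >= 1")
  maf <- rep_len(maf, n_snps)
  if (any(maf < 0 | maf > 1)) stop_input("each maf must lie in [0, 1]")
  if (sigma < 0) stop_input("sigma must be >= 0")
  if (sex_balance < 0 || sex_balance > 1) stop_input("sex_balance in [0, 1]")
  if (is.null(pe_parent_probs)) pe_parent_probs <- calibrate_pe_probs()
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(n_snps))
  if (length(snp_ids) != n_snps || anyDuplicated(snp_ids))
    stop_input("snp_ids must be ", n_snps, " unique names")
  if (length(pe_parent_probs) != 8 || any(pe_parent_probs < 0) ||
      abs(sum(pe_parent_probs) - 1) > 1e-8)
    stop_input("pe_parent_probs must be 8 nonnegative probabilities summing to 1")
  params <- utils::modifyList(default_params(model_id, structure_), params)
  if (model_id %in% c("strong_ds", "strong_dis") && structure_ == "groups")
    params$slopes[1] <- 0
  structure(
    list(n = as.integer(n), maf = maf, n_snps = as.integer(n_snps),
         pe_parent_probs = pe_parent_probs,
         age_mean_months = age_mean_months, age_sd_months = age_sd_months,
         age_range = age_range, sex_balance = sex_balance,
         model_id = model_id, params = params, sigma = sigma,
         structure = structure_, focal_snp = as.integer(focal_snp),
         rge_r = rge_r, rge_snp = as.integer(rge_snp),
         snp_ids = snp_ids, seed = seed),
    class = "sim_config")
}

# Generative defaults: strong differential susceptibility uses the focal-SNP
# group slopes (0, 2.49, 3.27) with crossover 3.21; diathesis-stress moves
# the crossover to mean(PE) + 3 SD = 6.85 with attenuated slopes; the CGS
# structure uses the linear-by-linear pair (a1 = -2.09 at CGS 0 plus
# a2 = 0.52 per risk allele, crossover 3.34).
default_params <- function(model_id, structure) {
  base <- list(a0 = -0.90, age_slope = 0.91, sex_slope = -2.53)
  if (structure == "cgs") {
    p <- c(base, list(a1 = -2.09, a2 = 0.52, c = 3.34))
    if (model_id %in% c("strong_dis", "weak_dis")) p$c <- 6.85
    if (model_id == "null") p$a2 <- 0
    return(p)
  }
  p <- switch(model_id,
    strong_ds  = c(base, list(slopes = c(0, 2.49, 3.27), c = 3.21)),
    weak_ds    = c(base, list(slopes = c(0.43, 2.52, 3.30), c = 3.21)),
    strong_dis = c(base, list(slopes = c(0, 1.89, 2.09), c = 6.85)),
    weak_dis   = c(base, list(slopes = c(1.77, 1.89, 2.09), c = 6.84)),
    null       = c(base, list(slopes = c(1.88, 1.88, 1.88), c = 3.21)))
  p
}

#' Calibrate parent education level probabilities
#'
#' Finds a discretized-normal probability vector over integer levels 1-8
#' such that the mean of two independent parent draws (the PE variable)
#' matches a target mean and SD by moment matching.
#'
#' @param target_mean,target_sd target PE mean (3.21) and SD (1.21). With
#'   independent parents the parent-level SD is `target_sd * sqrt(2)`.
#' @return probability vector of length 8.
#' @export
calibrate_pe_probs <- function(target_mean = 3.21, target_sd = 1.21) {
  lv <- 1:8
  sd_level <- target_sd * sqrt(2)
  moments <- function(par) {
    p <- stats::dnorm(lv, par[1], exp(par[2])); p <- p / sum(p)
    m <- sum(p * lv)
    c(m, sqrt(sum(p * lv^2) - m^2))
  }
  obj <- function(par) {
    mo <- moments(par)
    (mo[1] - target_mean)^2 + (mo[2] - sd_level)^2
  }
  fit <- stats::optim(c(target_mean, log(sd_level)), obj,
                      control = list(reltol = 1e-14))
  p <- stats::dnorm(lv, fit$par[1], exp(fit$par[2]))
  p / sum(p)
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws i.i.d. risk-allele dosages with P(2) = maf^2,
#' P(1) = 2 maf (1 - maf), P(0) = (1 - maf)^2, i.e. Binomial(2, maf).
#'
#' @param n individuals.
#' @param maf risk-allele frequency in \[0, 1\].
#' @param seed optional integer seed.
#' @return integer dosage vector in \{0,1,2\}.
#' @export
gen_genotypes <- function(n, maf, seed = NULL) {
  if (maf < 0 || maf > 1) stop_input("maf must lie in [0, 1]")
  with_seed(seed, stats::rbinom(n, 2L, maf))
}

#' Simulate parental education (PE)
#'
#' PE is the mean of two independent integer draws (father, mother) from
#' the 1-8 education scale, so PE lies on the 0.5-step grid in \[1, 8\].
#'
#' @param n individuals.
#' @param probs probability vector over levels 1-8.
#' @param seed optional integer seed.
#' @return numeric PE vector with attributes `father` and `mother` holding
#'   the integer parent levels.
#' @export
gen_environment <- function(n, probs = calibrate_pe_probs(), seed = NULL) {
  if (length(probs) != 8 || any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop_input("probs must be 8 nonnegative probabilities summing to 1")
  with_seed(seed, {
    father <- sample(1:8, n, replace = TRUE, prob = probs)
    mother <- sample(1:8, n, replace = TRUE, prob = probs)
    pe <- (father + mother) / 2
    attr(pe, "father") <- father
    attr(pe, "mother") <- mother
    pe
  })
}

#' Simulate the phenotype under a generative interaction model
#'
#' Generates `Y = A0 + slope(G) * (X1 - C) + b_age * Age + b_sex * Sex + e`
#' with `e ~ Normal(0, sigma^2)`, where the environment slope depends on
#' the genetic moderator: per focal-SNP dosage group
#' (`structure = "groups"`) or linearly in the CGS
#' (`structure = "cgs"`, slope `a1 + a2 * CGS`).
#'
#' @param frame data.frame with columns `pe`, `age`, `sex` and either
#'   `dosage` (focal-SNP dosage) or `cgs`.
#' @param config a [sim_config()].
#' @param seed optional integer seed for the residuals.
#' @return numeric phenotype vector.
#' @export
gen_phenotype <- function(frame, config, seed = NULL) {
  p <- config$params
  slope <- if (config$structure == "cgs") {
    if (is.null(frame$cgs)) stop_input("frame needs a cgs column")
    p$a1 + p$a2 * frame$cgs
  } else {
    if (is.null(frame$dosage)) stop_input("frame needs a dosage column")
    p$slopes[frame$dosage + 1L]
  }
  mu <- p$a0 + slope * (frame$pe - p$c) +
    p$age_slope * frame$age + p$sex_slope * frame$sex
  with_seed(seed, mu + stats::rnorm(length(mu), 0, config$sigma))
}

# Permutation of individuals such that cor(dosage, pe[perm]) ~= target_r
# while pe's marginal distribution is untouched: a Gaussian rank coupling
# generates a latent score correlated with the dosage ranks, sorted pe
# values are assigned by that score's ranks, and the latent correlation is
# tuned by root finding on the realized Pearson r.
rge_perm <- function(pe, dosage, target_r, seed = NULL) {
  with_seed(seed, {
    n <- length(pe)
    z_g <- stats::qnorm((rank(dosage, ties.method = "random") - 0.5) / n)
    noise <- stats::rnorm(n)
    ord_pe <- order(pe)
    perm_at <- function(rho) {
      lat <- rho * z_g + sqrt(1 - rho^2) * noise
      ord_pe[rank(lat, ties.method = "first")]
    }
    f <- function(rho) stats::cor(dosage, pe[perm_at(rho)]) - target_r
    rho <- stats::uniroot(f, interval = c(-0.999, 0.999), tol = 1e-4)$root
    perm_at(rho)
  })
}

#' Generate a synthetic cohort
#'
#' Assembles genotypes, environment, covariates, CGS and phenotype into a
#' [gxe_cohort()] according to a [sim_config()]. Optionally writes the
#' phenotype CSV and an additive dosage table so the file-reading path of
#' the analysis can be exercised.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes
#'   `phenotypes.csv` and `dosages.raw` there.
#' @return a `gxe_cohort`; deterministic given `config$seed`.
#' @export
gen_cohort <- function(config, out_dir = NULL) {
  sd_seed <- function(off) derive_seed(config$seed, off)
  n <- config$n
  dos <- sapply(seq_len(config$n_snps), function(j)
    gen_genotypes(n, config$maf[j], seed = sd_seed(j)))
  dos <- matrix(dos, nrow = n)
  colnames(dos) <- config$snp_ids %||% paste0("snp", seq_len(config$n_snps))
  pe <- gen_environment(n, config$pe_parent_probs, seed = sd_seed(100))
  father <- attr(pe, "father"); mother <- attr(pe, "mother")
  if (config$rge_r != 0) {
    idx <- rge_perm(as.numeric(pe), dos[, config$rge_snp],
                    config$rge_r, seed = sd_seed(101))
    pe <- as.numeric(pe)[idx]; father <- father[idx]; mother <- mother[idx]
  }
  age <- with_seed(sd_seed(102), {
    a <- stats::rnorm(n, config$age_mean_months, config$age_sd_months)
    while (any(bad <- a < config$age_range[1] | a > config$age_range[2]))
      a[bad] <- stats::rnorm(sum(bad), config$age_mean_months,
                             config$age_sd_months)
    a
  })
  sex <- with_seed(sd_seed(103), stats::rbinom(n, 1L, config$sex_balance))
  cgs <- rowSums(dos)
  frame <- data.frame(pe = as.numeric(pe), age = age, sex = sex,
                      dosage = dos[, config$focal_snp], cgs = cgs)
  y <- gen_phenotype(frame, config, seed = sd_seed(104))
  pheno <- data.frame(id = sprintf("S%05d", seq_len(n)), score = y,
                      pe = as.numeric(pe), age = age, sex = sex,
                      pe_father = father, pe_mother = mother,
                      stringsAsFactors = FALSE)
  cohort <- gxe_cohort(pheno, dos)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_phenotypes(pheno, file.path(out_dir, "phenotypes.csv"))
    write_dosage_raw(dos, pheno$id, file.path(out_dir, "dosages.raw"))
  }
  cohort
}

#' Calibrate the residual SD to a target model R-squared
#'
#' Finds `sigma` such that the confirmatory crossover model fitted to a
#' large simulated cohort attains a target coefficient of determination.
#' A single latent cohort is drawn once (unit-variance residuals) and the
#' phenotype is rebuilt as `mu + sigma * e` inside a bisection on the
#' fitted R-squared, which is continuous and strictly decreasing in
#' `sigma`.
#'
#' @param config a [sim_config()]; its `sigma` is ignored.
#' @param target_r2 target R-squared (default 0.2567).
#' @param n_calib cohort size used for calibration.
#' @param seed integer seed for the latent cohort.
#' @param interval search interval for sigma.
#' @param tol bisection tolerance on R-squared.
#' @return calibrated sigma (scalar), with attribute `achieved_r2`.
#' @export
calibrate_sigma <- function(config, target_r2 = 0.2567, n_calib = 20000,
                            seed = 1L, interval = c(0.1, 200), tol = 1e-4) {
  cfg0 <- config
  cfg0$n <- as.integer(n_calib)
  cfg0$sigma <- 0
  cfg0$seed <- seed
  cohort <- gen_cohort(cfg0)
  mu <- cohort$pheno$score
  e <- with_seed(derive_seed(seed, 999), stats::rnorm(n_calib))
  strong <- cfg0$model_id %in% c("strong_ds", "strong_dis")
  r2_at <- function(sigma) {
    cohort$pheno$score <- mu + sigma * e
    fit <- if (cfg0$structure == "cgs")
      fit_crossover_linear(cohort, c_mode = "free")
    else
      fit_crossover_groups(cohort, snp = colnames(cohort$dosages)[cfg0$focal_snp],
                           c_mode = "free", strong = strong)
    fit$r2
  }
  f <- function(sigma) r2_at(sigma) - target_r2
  if (f(interval[1]) < 0)
    stop_input("target_r2 unattainable: R2 below target even at sigma = ",
               interval[1])
  sigma <- stats::uniroot(f, interval = interval, tol = tol)$root
  structure(sigma, achieved_r2 = r2_at(sigma) )
}
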