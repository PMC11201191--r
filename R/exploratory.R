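# Exploratory moderated-regression stage: per-SNP and CGS interaction
# models with nested-F comparisons and Bonferroni control.

# Core least-squares engine used by every linear fit in the package.
# X must include an intercept column; names(X) label the coefficients.
ols_engine <- function(X, y, k_extra = 0) {
  n <- length(y)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_input("rank-deficient design; offending column(s): ",
               paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qr_x, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  rss <- sum(resid^2)
  k_mean <- ncol(X) + k_extra          # mean parameters (profiled ones via k_extra)
  df_resid <- n - k_mean
  sigma2 <- rss / df_resid
  xtx_inv <- chol2inv(qr.R(qr_x))[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE]
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  df_model <- k_mean - 1
  f_overall <- (r2 / df_model) / ((1 - r2) / df_resid)
  list(coefficients = coef, se = se, vcov = vcov, fitted = fitted,
       residuals = resid, rss = rss, tss = tss, r2 = r2,
       f_overall = f_overall, df = c(model = df_model, resid = df_resid),
       n = n, sigma2 = sigma2,
       aic = ls_aic(rss, n, k_mean), bic = ls_bic(rss, n, k_mean),
       loglik = ls_loglik(rss, n))
}

# Resolve a gene term: a SNP id, "cgs", or a numeric vector.
resolve_gene <- function(cohort, gene) {
  if (is.numeric(gene)) {
    if (length(gene) != n_individuals(cohort))
      stop_input("gene vector length does not match cohort size")
    return(list(g = gene, label = "G"))
  }
  if (identical(gene, "cgs")) return(list(g = cohort$cgs, label = "CGS"))
  if (!gene %in% colnames(cohort$dosages))
    stop_input("unknown SNP: ", gene)
  list(g = cohort$dosages[, gene], label = gene)
}

#' Fit the standard exploratory G\eqn{\times}E regression
#'
#' Ordinary least squares for
#' `Y = A0 + A1 X1 + A2 G + A3 (X1 x G) + A4 Age + A5 Sex + E`, where `X1`
#' is the environment (PE) and `G` is a SNP dosage (linear 0/1/2 coding) or
#' the CGS. The main-effects model omits the product term; comparing the
#' two with [nested_f_test()] is the exploratory interaction test.
#'
#' @param cohort a [gxe_cohort()] with complete cases.
#' @param gene SNP id, `"cgs"`, or a numeric moderator vector.
#' @param interaction include the `X1 x G` product term?
#' @param covariates include age and sex?
#' @return An object of class `gxe_lm`: coefficient estimates and standard
#'   errors, `vcov`, `r2`, `f_overall`, `df` (model, residual), `rss`,
#'   `n`, `aic`, `bic`, `loglik`, `fitted`, `residuals` and the term names.
#' @export
fit_ols <- function(cohort, gene, interaction = TRUE, covariates = TRUE) {
  ph <- cohort$pheno
  if (anyNA(ph$score) || anyNA(ph$pe))
    stop_input("cohort has missing values; call complete_cases() first")
  gg <- resolve_gene(cohort, gene)
  X <- cbind(`(Intercept)` = 1, X1 = ph$pe)
  X <- cbind(X, G = gg$g)
  if (interaction) X <- cbind(X, `X1:G` = ph$pe * gg$g)
  if (covariates) X <- cbind(X, Age = ph$age, Sex = ph$sex)
  fit <- ols_engine(X, ph$score)
  fit$gene <- gg$label
  fit$interaction <- interaction
  fit$terms <- colnames(X)
  class(fit) <- "gxe_lm"
  fit
}

#' @export
print.gxe_lm <- function(x, ...) {
  cat("Exploratory G x E regression (gene term: ", x$gene,
      if (x$interaction) ", with product term" else ", main effects only",
      ")\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  cat(sprintf("R2 = %.4f, F(%d, %d) = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$r2, x$df[1], x$df[2], x$f_overall, x$aic, x$bic))
  invisible(x)
}

#' Nested-model F test on the increase in R-squared
#'
#' `F = (dR2 / dk) / ((1 - R2_full) / df_resid_full)`, the hierarchical
#' regression test for the variance added by the extra term(s).
#'
#' @param reduced,full fitted models (`gxe_lm` or `reparam_fit`) on the same
#'   data, with the reduced model's terms a subset of the full model's.
#' @return list with `delta_r2`, `f`, `df` (numerator, denominator) and `p`.
#' @export
nested_f_test <- function(reduced, full) {
  if (reduced$n != full$n)
    stop_input("models were fitted to different numbers of observations")
  dk <- reduced$df[["resid"]] - full$df[["resid"]]
  if (dk == 0 && abs(full$r2 - reduced$r2) < 1e-12)
    return(list(delta_r2 = 0, f = 0, df = c(0, full$df[["resid"]]), p = 1))
  if (dk <= 0)
    stop_input("models are not nested: the full model must spend more df")
  if (full$r2 < reduced$r2 - 1e-10)
    stop_input("full model has lower R2 than reduced; fits are not nested")
  delta_r2 <- max(full$r2 - reduced$r2, 0)
  f <- (delta_r2 / dk) / ((1 - full$r2) / full$df[["resid"]])
  list(delta_r2 = delta_r2, f = f,
       df = c(dk, full$df[["resid"]]),
       p = stats::pf(f, dk, full$df[["resid"]], lower.tail = FALSE))
}

#' Exploratory interaction scan across a SNP panel
#'
#' Fits the main-effects and interaction models for each retained SNP,
#' tests the product term by nested F, and applies Bonferroni control at
#' `alpha / m` over the `m` retained SNPs. Monomorphic SNPs are skipped
#' with a warning.
#'
#' @param cohort a [gxe_cohort()].
#' @param snps SNP ids to scan (default: all columns of the dosage matrix).
#' @param alpha familywise level (default 0.05).
#' @return data.frame with one row per SNP: interaction estimate and SE,
#'   `delta_r2`, `f`, `p`, the Bonferroni `threshold` and `significant`
#'   flag; attribute `m` records the number tested.
#' @export
run_snp_scan <- function(cohort, snps = colnames(cohort$dosages), alpha = 0.05) {
  rows <- list()
  for (s in snps) {
    d <- cohort$dosages[, s]
    if (stats::var(d) == 0) {
      warning("skipping monomorphic SNP ", s)
      next
    }
    m1 <- fit_ols(cohort, s, interaction = FALSE)
    m2 <- fit_ols(cohort, s, interaction = TRUE)
    cmp <- nested_f_test(m1, m2)
    rows[[s]] <- data.frame(
      snp_id = s, a3 = m2$coefficients[["X1:G"]], se = m2$se[["X1:G"]],
      delta_r2 = cmp$delta_r2, f = cmp$f, p = cmp$p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_input("no polymorphic SNPs to scan")
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$threshold <- alpha / m
  out$significant <- out$p < out$threshold
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}

#' Exploratory CGS interaction with the confirmatory gate
#'
#' Fits the CGS main-effects and interaction models, their nested
#' comparison, and the gate used to decide whether confirmatory crossover
#' modelling is warranted: an interaction F ratio above 1.0.
#'
#' @param cohort a [gxe_cohort()] with a non-degenerate CGS.
#' @return list with `main` and `inter` (`gxe_lm` fits), `comparison`
#'   (nested F) and `gate_passed` (logical, `f > 1`).
#' @export
fit_cgs_interaction <- function(cohort) {
  if (stats::var(cohort$cgs) == 0)
    stop_input("CGS has zero variance; interaction model is unidentified")
  main <- fit_ols(cohort, "cgs", interaction = FALSE)
  inter <- fit_ols(cohort, "cgs", interaction = TRUE)
  cmp <- nested_f_test(main, inter)
  list(main = main, inter = inter, comparison = cmp,
       gate_passed = cmp$f > 1.0)
}

#' Simple slopes of the environment at fixed moderator levels
#'
#' For an interaction fit, the slope of the outcome on the environment at
#' moderator level `t` is `A1 + A3 t`, with a delta-method standard error
#' from the coefficient covariance.
#'
#' @param fit a `gxe_lm` with the product term.
#' @param levels moderator levels (e.g. dosages 0:2, or CGS at mean +/- SD).
#' @return data.frame with `level`, `slope`, `se`, `t`, `p`.
#' @export
simple_slopes <- function(fit, levels) {
  if (!isTRUE(fit$interaction))
    stop_input("simple slopes require a fit with the product term")
  v <- fit$vcov
  slope <- fit$coefficients[["X1"]] + fit$coefficients[["X1:G"]] * levels
  se <- sqrt(v["X1", "X1"] + levels^2 * v["X1:G", "X1:G"] +
               2 * levels * v["X1", "X1:G"])
  tval <- slope / se
  data.frame(level = levels, slope = slope, se = se, t = tval,
             p = 2 * stats::pt(abs(tval), fit$df[["resid"]], lower.tail = FALSE))
}
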