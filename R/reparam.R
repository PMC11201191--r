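# Confirmatory re-parameterized crossover regression.
#
# The interaction is re-expressed around a crossover point C on the
# environment scale: Y = A0 + slope(G) * (X1 - C) + b_age Age + b_sex Sex.
# Given C the model is linear, so C is estimated by profiling: the residual
# sum of squares is minimized over a coarse grid and refined by bracketed
# 1-D optimization. SE(C) is the standard nonlinear-least-squares Wald
# standard error from the Gauss-Newton information sigma^2 (J'J)^{-1}; a
# profile-likelihood interval is reported alongside because Wald intervals
# are fragile near flat profiles.

#' Wald confidence interval
#'
#' `estimate +/- z * se` with `z = qnorm((1 + level) / 2)`
#' (1.959964 at level 0.95).
#'
#' @param estimate point estimate.
#' @param se nonnegative standard error.
#' @param level confidence level in (0, 1).
#' @return numeric length-2 vector (lower, upper).
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (is.na(se) || se < 0) stop_input("se must be nonnegative")
  if (level <= 0 || level >= 1) stop_input("level must lie in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  c(estimate - z * se, estimate + z * se)
}

#' Fixed crossover value for diathesis-stress models
#'
#' The diathesis-stress variants pin the crossover at the top of the
#' environment scale: `mean(PE) + 3 SD(PE)` by default, or the observed
#' maximum.
#'
#' @param pe environment vector.
#' @param rule `"mean_plus_3sd"` (default) or `"observed_max"`.
#' @return scalar crossover value.
#' @export
fixed_crossover <- function(pe, rule = c("mean_plus_3sd", "observed_max")) {
  rule <- match.arg(rule)
  if (rule == "mean_plus_3sd") mean(pe) + 3 * stats::sd(pe) else max(pe)
}

# Shared profiling core. design_fun(C) must return the full design matrix
# (with intercept and covariates); slope_fun(coef) the per-observation
# environment slope implied by the linear coefficients (the negative of the
# mean function's derivative in C). Returns a reparam_fit.
profile_crossover <- function(design_fun, y, pe, c_mode, c_value,
                              model_id, structure, slope_names, slope_fun,
                              grid_n = 201, level = 0.95,
                              flat_tol = 1e-10) {
  rss_at <- function(C) {
    X <- design_fun(C)
    sum(.lm.fit(X, y)$residuals^2)
  }
  if (c_mode == "fixed") {
    if (is.null(c_value)) stop_input("c_value required when c_mode = 'fixed'")
    c_hat <- c_value
    eng <- ols_engine(design_fun(c_hat), y, k_extra = 0)
    c_se <- NA_real_; c_ci <- NULL; c_ci_profile <- NULL
    identified <- TRUE
    profile <- NULL
  } else {
    sd_pe <- stats::sd(pe)
    lo <- min(pe) - 2 * sd_pe
    hi <- max(pe) + 2 * sd_pe
    # when a weak interaction pushes the optimum past the initial window,
    # extend the window until the minimum is interior (the profile has a
    # finite asymptote as |C| grows, so a bounded number of extensions
    # suffices for any finite optimum)
    for (iter in 1:12) {
      grid <- seq(lo, hi, length.out = grid_n)
      prof <- vapply(grid, rss_at, numeric(1))
      i <- which.min(prof)
      if (i > 1 && i < grid_n) break
      # extend both tails: the profile approaches the same asymptote on
      # either side, so a boundary minimum may sit on the wrong tail
      span <- hi - lo
      lo <- lo - span
      hi <- hi + span
    }
    tss <- sum((y - mean(y))^2)
    # flat in relative terms, or a perfect fit at every C (both leave the
    # crossover unidentified)
    if ((max(prof) - min(prof)) < flat_tol * max(max(prof), 1e-300) ||
        max(prof) <= 1e-12 * tss) {
      # no curvature in C: the interaction slope is (numerically) zero and
      # the crossover is unidentified
      eng <- ols_engine(design_fun(mean(pe)), y, k_extra = 1)
      fit <- build_reparam(eng, mean(pe), NA_real_, NULL, NULL, FALSE,
                           model_id, structure, slope_names,
                           c_mode, identified = FALSE)
      fit$profile <- list(grid = grid, rss = prof)
      return(fit)
    }
    bracket <- c(grid[max(i - 1, 1)], grid[min(i + 1, grid_n)])
    opt <- stats::optimize(rss_at, interval = bracket, tol = 1e-10)
    c_hat <- opt$minimum
    # quadratic polish: Brent's precision floor is ~sqrt(eps)*|C|; one
    # interpolation step on the (locally quadratic) profile removes it
    h <- max(1e-4 * sd_pe, 1e-8)
    r_m <- rss_at(c_hat - h); r_0 <- rss_at(c_hat); r_p <- rss_at(c_hat + h)
    denom <- r_p - 2 * r_0 + r_m
    if (is.finite(denom) && denom > 0) {
      c_new <- c_hat - 0.5 * h * (r_p - r_m) / denom
      if (abs(c_new - c_hat) < 2 * h && rss_at(c_new) <= r_0) c_hat <- c_new
    }
    X_hat <- design_fun(c_hat)
    eng <- ols_engine(X_hat, y, k_extra = 1)
    # Wald SE from the Gauss-Newton information sigma^2 (J'J)^{-1}: the
    # Jacobian column for C is -slope_i, so
    # SE(C) = sigma / || (I - P_X) slope ||, the standard NLS standard error
    j_c <- slope_fun(eng$coefficients)
    r_j <- .lm.fit(X_hat, j_c)$residuals
    c_se <- if (sum(r_j^2) > 0) sqrt(eng$sigma2 / sum(r_j^2)) else NA_real_
    c_ci <- if (!is.na(c_se)) wald_ci(c_hat, c_se, level) else NULL
    # Profile CI: { C : RSS(C) - RSS_min <= sigma^2 qf(level, 1, df) },
    # more robust than Wald when the profile is asymmetric
    cut <- eng$rss + eng$sigma2 * stats::qf(level, 1, eng$df[["resid"]])
    g <- function(C) rss_at(C) - cut
    lo_ci <- if (g(lo) > 0 && g(c_hat) < 0)
      stats::uniroot(g, c(lo, c_hat), tol = 1e-6)$root else -Inf
    hi_ci <- if (g(hi) > 0 && g(c_hat) < 0)
      stats::uniroot(g, c(c_hat, hi), tol = 1e-6)$root else Inf
    c_ci_profile <- c(lo_ci, hi_ci)
    identified <- TRUE
    profile <- list(grid = grid, rss = prof)
  }
  fit <- build_reparam(eng, c_hat, c_se, c_ci, c_ci_profile,
                       c_mode == "fixed", model_id, structure, slope_names,
                       c_mode, identified = identified)
  fit$profile <- profile
  fit
}

build_reparam <- function(eng, c_hat, c_se, c_ci, c_ci_profile, c_fixed,
                          model_id, structure, slope_names, c_mode,
                          identified = TRUE) {
  coefs <- eng$coefficients
  se <- eng$se
  slopes <- data.frame(term = slope_names,
                       estimate = unname(coefs[slope_names]),
                       se = unname(se[slope_names]),
                       stringsAsFactors = FALSE)
  structure(
    list(model_id = model_id, structure = structure,
         c_hat = c_hat, c_se = c_se, c_ci = c_ci,
         c_ci_profile = c_ci_profile, c_fixed = c_fixed,
         identified = identified,
         a0 = unname(coefs["(Intercept)"]),
         a0_se = unname(se["(Intercept)"]),
         group_slopes = slopes,
         age_slope = unname(coefs["Age"]), age_se = unname(se["Age"]),
         sex_slope = unname(coefs["Sex"]), sex_se = unname(se["Sex"]),
         coefficients = coefs, se = se, vcov = eng$vcov,
         fitted = eng$fitted, residuals = eng$residuals,
         r2 = eng$r2, rss = eng$rss, f_overall = eng$f_overall,
         df = eng$df, n = eng$n, sigma2 = eng$sigma2,
         aic = eng$aic, bic = eng$bic, loglik = eng$loglik),
    class = "reparam_fit")
}

#' @export
print.reparam_fit <- function(x, ...) {
  cat("Re-parameterized crossover regression (Model ", x$model_id, ", ",
      x$structure, ")\n", sep = "")
  if (!x$identified) {
    cat("  crossover unidentified: flat RSS profile (no interaction slope)\n")
  } else if (x$c_fixed) {
    cat(sprintf("  C = %.4f (fixed)\n", x$c_hat))
  } else {
    cat(sprintf("  C = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
                x$c_hat, x$c_se, x$c_ci[1], x$c_ci[2]))
  }
  cat(sprintf("  A0 = %.4f (%.4f)\n", x$a0, x$a0_se))
  for (i in seq_len(nrow(x$group_slopes)))
    cat(sprintf("  %s = %.4f (%.4f)\n", x$group_slopes$term[i],
                x$group_slopes$estimate[i], x$group_slopes$se[i]))
  cat(sprintf("  R2 = %.4f, F(%d, %d) = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$r2, x$df[1], x$df[2], x$f_overall, x$aic, x$bic))
  invisible(x)
}

#' Crossover regression with genotype-group slopes
#'
#' Fits `Y = A0 + A_g (X1 - C) + b_age Age + b_sex Sex` with a separate
#' environment slope `A_g` for each dosage group of the focal SNP
#' (g = 0, 1, 2 risk alleles). `strong = TRUE` constrains the
#' no-risk-allele group's slope to zero (strong differential-susceptibility
#' or diathesis-stress form). With `c_mode = "free"` the crossover C is
#' profiled; with `c_mode = "fixed"` it is pinned (diathesis-stress models
#' fix it at the top of the environment scale, see [fixed_crossover()]).
#'
#' Model ids follow the four-model taxonomy: 3a = strong/free,
#' 3b = weak/free (differential susceptibility); 3c = strong/fixed,
#' 3d = weak/fixed (diathesis-stress).
#'
#' @param cohort a [gxe_cohort()].
#' @param snp SNP id (column of the dosage matrix) or a dosage vector.
#' @param c_mode `"free"` (profile C) or `"fixed"`.
#' @param c_value crossover value when `c_mode = "fixed"`.
#' @param strong constrain the dosage-0 slope to zero?
#' @param grid_n coarse-grid size for profiling.
#' @param level confidence level for the crossover interval.
#' @return a `reparam_fit` (see [print.reparam_fit()]); `group_slopes`
#'   holds A1-A3 (A1 omitted under `strong`).
#' @export
fit_crossover_groups <- function(cohort, snp, c_mode = c("free", "fixed"),
                                 c_value = NULL, strong = TRUE,
                                 grid_n = 201, level = 0.95) {
  c_mode <- match.arg(c_mode)
  d <- if (is.numeric(snp)) snp else {
    if (!snp %in% colnames(cohort$dosages)) stop_input("unknown SNP: ", snp)
    cohort$dosages[, snp]
  }
  sizes <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  if (any(sizes == 0))
    stop_input("empty genotype group; sizes (0/1/2 risk alleles): ",
               paste(sizes, collapse = "/"))
  ph <- cohort$pheno
  g0 <- as.numeric(d == 0); g1 <- as.numeric(d == 1); g2 <- as.numeric(d == 2)
  design_fun <- function(C) {
    dev <- ph$pe - C
    if (strong)
      cbind(`(Intercept)` = 1, A2 = g1 * dev, A3 = g2 * dev,
            Age = ph$age, Sex = ph$sex)
    else
      cbind(`(Intercept)` = 1, A1 = g0 * dev, A2 = g1 * dev, A3 = g2 * dev,
            Age = ph$age, Sex = ph$sex)
  }
  model_id <- if (c_mode == "free") {
    if (strong) "3a" else "3b"
  } else {
    if (strong) "3c" else "3d"
  }
  slope_names <- if (strong) c("A2", "A3") else c("A1", "A2", "A3")
  slope_fun <- function(coef) {
    s <- coef[["A2"]] * g1 + coef[["A3"]] * g2
    if (!strong) s <- s + coef[["A1"]] * g0
    s
  }
  profile_crossover(design_fun, ph$score, ph$pe, c_mode, c_value,
                    model_id, "groups", slope_names, slope_fun, grid_n, level)
}

#' Crossover regression with a linear-by-linear slope (CGS)
#'
#' Fits `Y = A0 + (A1 + A2 X2)(X1 - C) + b_age Age + b_sex Sex`, where the
#' environment slope varies linearly with the moderator `X2` (the CGS).
#' Model 3e profiles C; Model 3f fixes it at the top of the environment
#' scale. When the interaction slope `A2` is zero the profile is flat and
#' C is unidentified; the fit is then flagged (`identified = FALSE`).
#'
#' @param cohort a [gxe_cohort()].
#' @param moderator `"cgs"` (default) or a numeric moderator vector.
#' @inheritParams fit_crossover_groups
#' @return a `reparam_fit` with `group_slopes` rows A1 (slope at moderator
#'   0) and A2 (slope change per moderator unit).
#' @export
fit_crossover_linear <- function(cohort, moderator = "cgs",
                                 c_mode = c("free", "fixed"),
                                 c_value = NULL, grid_n = 201, level = 0.95) {
  c_mode <- match.arg(c_mode)
  x2 <- if (is.numeric(moderator)) moderator else {
    if (identical(moderator, "cgs")) cohort$cgs
    else cohort$dosages[, moderator]
  }
  if (stats::var(x2) == 0) stop_input("moderator has zero variance")
  ph <- cohort$pheno
  design_fun <- function(C) {
    dev <- ph$pe - C
    cbind(`(Intercept)` = 1, A1 = dev, A2 = dev * x2,
          Age = ph$age, Sex = ph$sex)
  }
  model_id <- if (c_mode == "free") "3e" else "3f"
  slope_fun <- function(coef) coef[["A1"]] + coef[["A2"]] * x2
  profile_crossover(design_fun, ph$score, ph$pe, c_mode, c_value,
                    model_id, "cgs", c("A1", "A2"), slope_fun, grid_n, level)
}

#' Fit the four genotype-group crossover models
#'
#' Convenience wrapper fitting Models 3a-3d for one SNP: strong and weak
#' differential susceptibility (free C) and strong and weak
#' diathesis-stress (C fixed by `fixed_c_rule`).
#'
#' @inheritParams fit_crossover_groups
#' @param fixed_c_rule rule for the diathesis-stress crossover
#'   (see [fixed_crossover()]).
#' @return named list of `reparam_fit`s: `3a`, `3b`, `3c`, `3d`.
#' @export
fit_crossover_family <- function(cohort, snp, fixed_c_rule = "mean_plus_3sd",
                                 grid_n = 201) {
  c_fix <- fixed_crossover(cohort$pheno$pe, fixed_c_rule)
  list(
    "3a" = fit_crossover_groups(cohort, snp, "free", strong = TRUE,
                                grid_n = grid_n),
    "3b" = fit_crossover_groups(cohort, snp, "free", strong = FALSE,
                                grid_n = grid_n),
    "3c" = fit_crossover_groups(cohort, snp, "fixed", c_value = c_fix,
                                strong = TRUE),
    "3d" = fit_crossover_groups(cohort, snp, "fixed", c_value = c_fix,
                                strong = FALSE))
}

#' Fit the two CGS crossover models
#'
#' @inheritParams fit_crossover_linear
#' @param fixed_c_rule rule for the fixed crossover of Model 3f.
#' @return named list of `reparam_fit`s: `3e`, `3f`.
#' @export
fit_crossover_family_cgs <- function(cohort, moderator = "cgs",
                                     fixed_c_rule = "mean_plus_3sd",
                                     grid_n = 201) {
  c_fix <- fixed_crossover(cohort$pheno$pe, fixed_c_rule)
  list(
    "3e" = fit_crossover_linear(cohort, moderator, "free", grid_n = grid_n),
    "3f" = fit_crossover_linear(cohort, moderator, "fixed", c_value = c_fix))
}
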