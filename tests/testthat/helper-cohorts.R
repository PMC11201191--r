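# Shared fixture builders: everything is generated in code.

# A small-to-medium synthetic cohort under a chosen generative model.
make_cohort <- function(n = 400, seed = 1, model_id = "strong_ds",
                        sigma = 19.44, ...) {
  gen_cohort(sim_config(n = n, seed = seed, model_id = model_id,
                        sigma = sigma, ...))
}

# A deterministic miniature cohort with hand-set columns, for exact
# algebraic checks.
toy_cohort <- function() {
  pheno <- data.frame(
    id = paste0("I", 1:8),
    score = c(10, 20, 30, 40, 15, 25, 35, 45),
    pe = c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5),
    age = c(100, 110, 120, 130, 105, 115, 125, 135),
    sex = c(0, 1, 0, 1, 0, 1, 0, 1))
  dos <- cbind(snpA = c(0, 1, 2, 1, 0, 2, 1, 0),
               snpB = c(2, 2, 0, 1, 1, 0, 0, 1))
  gxe_cohort(pheno, dos)
}

# Brute-force OLS oracle via the normal equations.
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Exhaustive grid search oracle for the profiled crossover. The search
# covers the standard profiling window plus (optionally) a fine band around
# a candidate optimum, so runaway crossovers from weak interactions are
# still checked exhaustively near the claimed argmin.
grid_search_c <- function(cohort, snp, strong = TRUE, step = 0.001,
                          extra_center = NULL) {
  ph <- cohort$pheno
  d <- cohort$dosages[, snp]
  g0 <- as.numeric(d == 0); g1 <- as.numeric(d == 1); g2 <- as.numeric(d == 2)
  lo <- min(ph$pe) - 2 * sd(ph$pe)
  hi <- max(ph$pe) + 2 * sd(ph$pe)
  grid <- seq(lo, hi, by = step)
  if (!is.null(extra_center) && (extra_center < lo || extra_center > hi))
    grid <- c(grid, seq(extra_center - 1, extra_center + 1, by = step))
  rss <- vapply(grid, function(C) {
    dev <- ph$pe - C
    X <- if (strong) cbind(1, g1 * dev, g2 * dev, ph$age, ph$sex)
    else cbind(1, g0 * dev, g1 * dev, g2 * dev, ph$age, ph$sex)
    sum(.lm.fit(X, ph$score)$residuals^2)
  }, numeric(1))
  list(c = grid[which.min(rss)], rss = min(rss), window = c(lo, hi))
}
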