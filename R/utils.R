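# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so simulation helpers do not perturb
# the global stream when given an explicit seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a substream seed from a base seed; keeps derived seeds inside the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

# Least-squares information criteria on the error-variance scale:
#   AIC = n log(RSS/n) + 2k,  BIC = n log(RSS/n) + k log(n)
# with k = number of mean parameters + 1 for the residual variance.
# Absolute values are comparable only within this package; differences and
# rankings are what model comparison uses.
ls_aic <- function(rss, n, k_mean) n * log(rss / n) + 2 * (k_mean + 1)
ls_bic <- function(rss, n, k_mean) n * log(rss / n) + (k_mean + 1) * log(n)

ls_loglik <- function(rss, n) -n / 2 * (log(2 * pi) + log(rss / n) + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
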