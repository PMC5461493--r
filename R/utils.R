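#' @importFrom rlang .data
#' @importFrom stats pf qlogis plogis rpois rnorm runif sd quantile t.test
#'   wilcox.test cor dnorm ks.test
NULL

# Derive a child seed from a master seed; keeps results < 2^31 so the value is
# always a valid R integer seed.
pm_child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(as.numeric(seed)) * 1009 + 97 * offset) %% 2147483629L)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
# A NULL seed means "use the current RNG stream".
with_pm_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# Add-one permutation p-value: never exactly zero.
perm_pvalue <- function(n_geq, n_total) (1 + n_geq) / (1 + n_total)

`%||%` <- function(a, b) if (is.null(a)) b else a
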