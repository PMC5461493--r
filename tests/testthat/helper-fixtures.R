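# Fixtures are generated once per test run and cached; decoding fixtures use
# 50 trials/condition so that >= 30 correct trials remain per condition after
# behavioural errors (the decoder uses correct trials only).
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, seed = 101L, ...) {
  key <- paste(c(name, seed, unlist(list(...))), collapse = "_")
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- make_fixture(name, seed = seed, ...)
  }
  .fx_cache[[key]]
}

fx_decode <- function(name, seed = 101L, n_neurons = 60L) {
  fx(name, seed = seed, n_neurons = n_neurons, n_trials_per_condition = 50L)
}

# Brute-force auROC oracle: enumerate all ordered pairs, ties count one half.
auroc_oracle <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (y > x) + 0.5 * (y == x)
  tot / (length(a) * length(b))
}

# Independent diagonal-covariance Gaussian classifier oracle: per-class
# means, pooled within-class per-feature variance, log-likelihood sums via
# dnorm, computed with plain loops (no shared code with the implementation).
diag_gauss_oracle <- function(Xtr, ytr, Xte) {
  classes <- sort(unique(ytr))
  f <- ncol(Xtr)
  mu <- sapply(classes, function(c) colMeans(Xtr[ytr == c, , drop = FALSE]))
  ssw <- rep(0, f)
  for (c in classes) {
    Z <- Xtr[ytr == c, , drop = FALSE]
    ssw <- ssw + colSums((Z - rep(colMeans(Z), each = nrow(Z)))^2)
  }
  v <- ssw / (nrow(Xtr) - length(classes))
  v[v <= 0] <- 1e-12
  apply(Xte, 1, function(x) {
    ll <- vapply(seq_along(classes), function(ci) {
      sum(dnorm(x, mu[, ci], sqrt(v), log = TRUE))
    }, numeric(1))
    classes[which.max(ll)]
  })
}

# Hand-built deterministic dataset: 2 tasks x 4 directions x n_per trials,
# constant 10 sp/s unless rate_fun overrides it.
make_tiny_dataset <- function(n_per = 5L, bin_ms = 40L, rate_fun = NULL) {
  dirs <- c(0, 90, 180, 270)
  cond <- expand.grid(direction_deg = dirs,
                      task = c("perceptual", "memory"),
                      rep = seq_len(n_per), stringsAsFactors = FALSE)
  n <- nrow(cond)
  trials <- tibble::tibble(
    trial_id = seq_len(n), task = cond$task, direction_deg = cond$direction_deg,
    outcome = rep(c("correct", "error"), length.out = n),
    delay_ms = 1500L, session_id = "s01", subject_id = "S1")
  nb <- (1000L + 1200L) %/% bin_ms
  if (is.null(rate_fun)) rate_fun <- function(i) matrix(10, n, nb)
  rates <- lapply(1:3, rate_fun)
  names(rates) <- c("n001", "n002", "n003")
  neurons <- tibble::tibble(neuron_id = names(rates), x_mm = 1:3, y_mm = 0,
                            subject_id = "S1")
  pm_dataset(trials, neurons, rates, dirs, bin_ms = bin_ms)
}
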