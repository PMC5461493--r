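#' Area under the ROC curve between two rate distributions
#'
#' Computed through the Mann-Whitney identity: the probability that a random
#' draw from `rates_b` exceeds a random draw from `rates_a`, counting ties as
#' one half.
#'
#' @param rates_a,rates_b Non-empty numeric vectors of firing rates.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(rates_a, rates_b) {
  if (length(rates_a) == 0 || length(rates_b) == 0) {
    stop("auroc needs non-empty rate vectors")
  }
  .auroc(rates_a, rates_b)
}

.auroc <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  (sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2) / (na * nb)
}

#' Rectify an auROC value to the 0.5-1 range
#'
#' Discriminability is direction-of-effect agnostic, so values below 0.5 are
#' mirrored: an auROC of 0.1 rectifies to 0.9.
#'
#' @param v auROC value(s) in `[0, 1]`.
#' @return `pmax(v, 1 - v)`.
#' @export
rectify_auroc <- function(v) {
  if (any(v < 0 | v > 1)) stop("auROC values must lie in [0, 1]")
  pmax(v, 1 - v)
}

# Highest rectified auROC over the 6 unordered direction pairs, plus the
# preferred direction (highest mean rate; exact ties go to the lowest angle).
# `g` is an integer direction index 1..4 aligned with sorted `direction_set`.
max_pair_auroc <- function(x, g, n_dirs = 4L) {
  best <- 0.5
  xs <- split(x, g)
  for (i in seq_len(n_dirs - 1L)) {
    for (j in seq.int(i + 1L, n_dirs)) {
      v <- .auroc(xs[[i]], xs[[j]])
      v <- max(v, 1 - v)
      if (v > best) best <- v
    }
  }
  best
}

#' Direction discriminability of one neuron in one task
#'
#' Rectified auROC between delay-window mean rates for all 6 unordered pairs
#' of sample directions; the highest value is the neuron's discriminability
#' and the direction with the highest mean rate is its preferred direction
#' (lowest angle wins exact ties).
#'
#' @param dataset A `pm_dataset`.
#' @param neuron_id Neuron identifier.
#' @param task `"perceptual"` or `"memory"`.
#' @param window Analysis window, default [delay_window()].
#' @return Tibble with `auroc` (rectified) and `pref_deg`.
#' @export
direction_discriminability <- function(dataset, neuron_id, task,
                                       window = delay_window()) {
  x <- delay_mean_matrix(dataset, window)[, as.character(neuron_id)]
  sel <- dataset$trials$task == task
  dirs <- sort(dataset$direction_set)
  g <- match(dataset$trials$direction_deg[sel], dirs)
  if (length(unique(g)) < 4) stop("missing direction condition in task ", task)
  if (min(table(g)) < 2) stop("need at least 2 trials per direction")
  xx <- x[sel]
  mu <- vapply(split(xx, g), mean, numeric(1))
  tibble::tibble(
    neuron_id = as.character(neuron_id), task = task,
    auroc = max_pair_auroc(xx, g),
    pref_deg = dirs[which.max(mu)]
  )
}

# Permutation engine shared by the exported wrapper and classify_neurons().
# Shuffling direction labels is equivalent to permuting the rate vector with
# the group structure held fixed, which is what we do.
perm_test_core <- function(x, g, n_shuffles, percentile) {
  real <- max_pair_auroc(x, g)
  n <- length(x)
  surr <- vapply(seq_len(n_shuffles), function(s) {
    max_pair_auroc(x[sample.int(n)], g)
  }, numeric(1))
  crit <- quantile(surr, percentile / 100, names = FALSE)
  list(auroc = real,
       p = perm_pvalue(sum(surr >= real), n_shuffles),
       significant = real >= crit)
}

#' Permutation significance of direction discriminability
#'
#' The discriminability computation is repeated after shuffling the direction
#' labels of all the task's trials, 500 times by default; the real value is
#' significant if it reaches or exceeds the 99th percentile of the surrogate
#' distribution. The p-value uses the add-one estimator
#' `(1 + k) / (1 + n_shuffles)`.
#'
#' @inheritParams direction_discriminability
#' @param n_shuffles Number of label shuffles (default 500; fewer than 100
#'   warns, fewer than 1 errors).
#' @param percentile Significance percentile (default 99).
#' @param seed Integer seed.
#' @return Tibble with `auroc`, `p`, `significant`.
#' @export
permutation_significance <- function(dataset, neuron_id, task,
                                     n_shuffles = 500L, percentile = 99,
                                     window = delay_window(), seed = NULL) {
  if (n_shuffles < 1) stop("n_shuffles must be at least 1")
  if (n_shuffles < 100) warning("n_shuffles < 100 gives a coarse p-value")
  x <- delay_mean_matrix(dataset, window)[, as.character(neuron_id)]
  sel <- dataset$trials$task == task
  g <- match(dataset$trials$direction_deg[sel], sort(dataset$direction_set))
  res <- with_pm_seed(seed, perm_test_core(x[sel], g, n_shuffles, percentile))
  tibble::tibble(neuron_id = as.character(neuron_id), task = task,
                 auroc = res$auroc, p = res$p, significant = res$significant)
}

# One-way ANOVA explained variance: SS_between / SS_total.
eta_squared <- function(x, g) {
  mu <- mean(x)
  sst <- sum((x - mu)^2)
  if (sst == 0) return(0)
  mg <- tapply(x, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng[ng > 0] * (mg - mu)^2)
  ssb / sst
}

#' Explained variance of direction in one neuron's delay rates
#'
#' Eta-squared from a one-way ANOVA of delay-window mean rates over the four
#' sample-direction conditions: the between-conditions sum of squares divided
#' by the total sum of squares.
#'
#' @inheritParams direction_discriminability
#' @return Eta-squared in `[0, 1]`.
#' @export
explained_variance <- function(dataset, neuron_id, task,
                               window = delay_window()) {
  x <- delay_mean_matrix(dataset, window)[, as.character(neuron_id)]
  sel <- dataset$trials$task == task
  g <- match(dataset$trials$direction_deg[sel], sort(dataset$direction_set))
  eta_squared(x[sel], g)
}

#' Classify neurons by perceptual and mnemonic discriminability
#'
#' Runs the discriminability permutation test independently in the two tasks
#' (which use disjoint trials) and labels each neuron `P` (perceptual only),
#' `M` (mnemonic only), `PM` (both) or `X` (neither). Also reports rectified
#' auROC, preferred direction, permutation p-value and ANOVA explained
#' variance per task.
#'
#' @param dataset A `pm_dataset`.
#' @param window Analysis window, default [delay_window()].
#' @param n_shuffles Label shuffles per neuron and task (default 500).
#' @param percentile Significance percentile (default 99).
#' @param seed Integer seed.
#' @param fdr If `TRUE`, significance is instead Benjamini-Hochberg FDR on
#'   the permutation p-values at level `fdr_level` (an optional stricter
#'   criterion; the default is the per-neuron percentile rule).
#' @param fdr_level FDR level when `fdr = TRUE` (default 0.05).
#' @return Tibble, one row per neuron: `neuron_id`, `auroc_perceptual`,
#'   `auroc_mnemonic`, `pref_perceptual`, `pref_mnemonic`, `p_perceptual`,
#'   `p_mnemonic`, `sig_perceptual`, `sig_mnemonic`, `eta2_perceptual`,
#'   `eta2_mnemonic`, `class`.
#' @export
classify_neurons <- function(dataset, window = delay_window(),
                             n_shuffles = 500L, percentile = 99,
                             seed = NULL, fdr = FALSE, fdr_level = 0.05) {
  if (n_shuffles < 1) stop("n_shuffles must be at least 1")
  M <- delay_mean_matrix(dataset, window)
  dirs <- sort(dataset$direction_set)
  tasks <- c("perceptual", "memory")
  per_task <- with_pm_seed(seed, lapply(tasks, function(tk) {
    sel <- dataset$trials$task == tk
    g <- match(dataset$trials$direction_deg[sel], dirs)
    rows <- lapply(seq_len(ncol(M)), function(j) {
      x <- M[sel, j]
      res <- perm_test_core(x, g, n_shuffles, percentile)
      mu <- vapply(split(x, g), mean, numeric(1))
      c(auroc = res$auroc, p = res$p, sig = res$significant,
        pref = dirs[which.max(mu)], eta2 = eta_squared(x, g))
    })
    do.call(rbind, rows)
  }))
  P <- per_task[[1]]
  Mm <- per_task[[2]]
  sig_p <- P[, "sig"] == 1
  sig_m <- Mm[, "sig"] == 1
  if (fdr) {
    sig_p <- stats::p.adjust(P[, "p"], "BH") <= fdr_level
    sig_m <- stats::p.adjust(Mm[, "p"], "BH") <= fdr_level
  }
  tibble::tibble(
    neuron_id = dataset$neurons$neuron_id,
    auroc_perceptual = P[, "auroc"], auroc_mnemonic = Mm[, "auroc"],
    pref_perceptual = P[, "pref"], pref_mnemonic = Mm[, "pref"],
    p_perceptual = P[, "p"], p_mnemonic = Mm[, "p"],
    sig_perceptual = sig_p, sig_mnemonic = sig_m,
    eta2_perceptual = P[, "eta2"], eta2_mnemonic = Mm[, "eta2"],
    class = dplyr::case_when(
      sig_p & sig_m ~ "PM",
      sig_p ~ "P",
      sig_m ~ "M",
      TRUE ~ "X"
    )
  )
}

#' Excess of perceptual-mnemonic neurons over independence
#'
#' Tests whether neurons significant in both tasks (PM) are more frequent
#' than expected if perceptual and mnemonic significance were independent
#' across neurons: the perceptual-significance flags and the
#' mnemonic-significance flags are independently reshuffled across the
#' recorded neurons, each shuffle yielding a surrogate percentage of doubly
#' significant neurons, and the p-value is the rank of the real percentage
#' among the surrogates (add-one estimator). The surrogate pool is the whole
#' classified population: restricting it to the significant neurons alone
#' would force the surrogate overlap to match or exceed the real one
#' whenever most significant neurons are PM, making an excess undetectable.
#'
#' @param classifications Output of [classify_neurons()].
#' @param n_shuffles Number of reshuffles (default 10000).
#' @param seed Integer seed.
#' @return Tibble with `pct_pm` (real percentage of doubly significant
#'   neurons), `p`, `n_neurons`.
#' @export
pm_excess_test <- function(classifications, n_shuffles = 10000L, seed = NULL) {
  cl <- classifications
  n <- nrow(cl)
  if (!any(cl$class %in% c("P", "M", "PM"))) {
    stop("no neurons in classes P, M or PM")
  }
  sp <- cl$sig_perceptual
  sm <- cl$sig_mnemonic
  real <- 100 * mean(sp & sm)
  surr <- with_pm_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    100 * mean(sp[sample.int(n)] & sm[sample.int(n)])
  }, numeric(1)))
  tibble::tibble(pct_pm = real,
                 p = perm_pvalue(sum(surr >= real), n_shuffles),
                 n_neurons = n)
}

#' Correlation between perceptual and mnemonic discriminability
#'
#' Pearson correlation of the per-neuron rectified auROC pair, with a
#' one-sided p-value from a shuffle null obtained by permuting the mnemonic
#' values across neurons.
#'
#' @param classifications Output of [classify_neurons()].
#' @param subset `"all"` neurons or `"PM"` neurons only.
#' @param n_shuffles Shuffles for the null (default 1000).
#' @param seed Integer seed.
#' @return Tibble with `r`, `p`, `n_neurons`.
#' @export
discriminability_correlation <- function(classifications,
                                         subset = c("all", "PM"),
                                         n_shuffles = 1000L, seed = NULL) {
  subset <- match.arg(subset)
  cl <- classifications
  if (subset == "PM") cl <- cl[cl$class == "PM", ]
  if (nrow(cl) < 3) stop("need at least 3 neurons in subset '", subset, "'")
  a <- cl$auroc_perceptual
  b <- cl$auroc_mnemonic
  r <- cor(a, b)
  surr <- with_pm_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    cor(a, b[sample.int(length(b))])
  }, numeric(1)))
  tibble::tibble(r = r, p = perm_pvalue(sum(surr >= r), n_shuffles),
                 n_neurons = nrow(cl))
}

#' Task differences in direction preference and overall rate
#'
#' For neurons significantly selective in both tasks, the circular difference
#' between the task-wise preferred directions is folded to 0, 90 or 180
#' degrees. For every neuron, overall delay rates are compared between the
#' two tasks with a two-sample t-test, with Benjamini-Hochberg adjustment
#' across neurons.
#'
#' @param classifications Output of [classify_neurons()].
#' @param dataset The `pm_dataset` the classifications came from.
#' @param window Analysis window, default [delay_window()].
#' @return Tibble with `neuron_id`, `pref_shift` (0/90/180, `NA` unless the
#'   neuron is selective in both tasks), `rate_diff_p`, `rate_diff_p_adj`,
#'   `rate_diff_sig`.
#' @export
compare_task_tuning <- function(classifications, dataset,
                                window = delay_window()) {
  M <- delay_mean_matrix(dataset, window)
  is_mem <- dataset$trials$task == "memory"
  shift <- abs(((classifications$pref_mnemonic -
                   classifications$pref_perceptual + 180) %% 360) - 180)
  shift[!(classifications$sig_perceptual & classifications$sig_mnemonic)] <- NA
  p <- vapply(seq_len(ncol(M)), function(j) {
    t.test(M[is_mem, j], M[!is_mem, j])$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, "BH")
  tibble::tibble(neuron_id = classifications$neuron_id,
                 pref_shift = shift,
                 rate_diff_p = p, rate_diff_p_adj = padj,
                 rate_diff_sig = padj <= 0.05)
}
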