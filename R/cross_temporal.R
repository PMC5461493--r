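#' Time-resolved window grid over sample and delay periods
#'
#' Non-overlapping windows of `window_ms` (a multiple of the bin width)
#' covering the stored epoch: the 1,000-ms sample plus the first 1,200 ms of
#' the delay.
#'
#' @param dataset A `pm_dataset`.
#' @param window_ms Window width in ms (default 40, the native bin width).
#' @return Tibble with `window`, `start_ms`, `end_ms` (relative to sample
#'   onset) and `is_delay` (window fully inside the analysed 240-1,200 ms
#'   delay epoch).
#' @export
time_window_grid <- function(dataset, window_ms = 40L) {
  total <- dataset$sample_ms + 1200L
  if (window_ms %% dataset$bin_ms != 0 || total %% window_ms != 0) {
    stop("window_ms must be a multiple of bin_ms (", dataset$bin_ms,
         ") and divide the stored epoch (", total, " ms)")
  }
  start <- seq(0L, total - window_ms, by = window_ms)
  tibble::tibble(window = seq_along(start), start_ms = start,
                 end_ms = start + window_ms,
                 is_delay = start >= dataset$sample_ms + 240L &
                   start + window_ms <= dataset$sample_ms + 1200L)
}

# Per-window rate features for one task's pseudotrials: list over windows of
# [trials x neurons] matrices sharing the pseudopopulation trial mapping.
xt_features <- function(pseudopop, task, grid) {
  ds <- pseudopop$dataset
  sel <- pseudopop$labels$task == task
  map <- pseudopop$map[sel, , drop = FALSE]
  ids <- pseudopop$neuron_ids
  lapply(seq_len(nrow(grid)), function(w) {
    win <- pm_window(grid$start_ms[w], grid$end_ms[w], "sample_onset")
    M <- delay_mean_matrix(ds, win)
    X <- vapply(seq_along(ids), function(j) M[map[, j], ids[j]],
                numeric(nrow(map)))
    matrix(X, nrow = nrow(map))
  })
}

# Cross-temporal LOO engine. For each training window the fold-wise model
# (z-scoring, ANOVA gate, diagonal LDA) is fitted on the remaining trials at
# that window; the held-out trial is then tested at every window, z-scored
# with the *test* window's training-fold statistics so train and test
# features live on a common scale. Returns a W x W accuracy matrix (%).
xt_engine <- function(Xw, y, alpha = 0.01, var_floor_frac = 1e-6) {
  W <- length(Xw)
  n <- nrow(Xw[[1]])
  k <- max(y)
  ng <- tabulate(y, k)
  S <- lapply(Xw, colSums)
  Q <- lapply(Xw, function(X) colSums(X^2))
  hits <- matrix(0L, W, W)
  for (a in seq_len(W)) {
    Xa <- Xw[[a]]
    Sg <- rowsum(Xa, y)
    for (i in seq_len(n)) {
      xi <- Xa[i, ]
      gi <- y[i]
      n1 <- n - 1L
      ng1 <- ng
      ng1[gi] <- ng1[gi] - 1L
      S1 <- S[[a]] - xi
      Q1 <- Q[[a]] - xi * xi
      Sg1 <- Sg
      Sg1[gi, ] <- Sg1[gi, ] - xi
      cs <- colSums(Sg1^2 / ng1)
      ssb <- cs - S1^2 / n1
      ssw <- pmax(Q1 - cs, 0)
      Fv <- (ssb / (k - 1)) / (ssw / (n1 - k))
      pv <- pf(Fv, k - 1, n1 - k, lower.tail = FALSE)
      sel <- which(is.finite(pv) & pv < alpha)
      if (length(sel) == 0) sel <- seq_along(S1)
      mu <- S1[sel] / n1
      v <- (Q1[sel] - S1[sel]^2 / n1) / (n1 - 1)
      sdv <- sqrt(pmax(v, 0))
      sdv[sdv == 0] <- 1
      zm <- (Sg1[, sel, drop = FALSE] / ng1 -
               rep(mu, each = k)) / rep(sdv, each = k)
      pooled <- (ssw[sel] / (n1 - k)) / sdv^2
      floor_ <- var_floor_frac * mean(pooled)
      if (!is.finite(floor_) || floor_ <= 0) floor_ <- 1e-12
      pooled <- pmax(pooled, floor_)
      ipool <- 1 / pooled
      for (b in seq_len(W)) {
        xb <- Xw[[b]][i, sel]
        Sb <- S[[b]][sel] - xb
        Qb <- Q[[b]][sel] - xb * xb
        vb <- (Qb - Sb^2 / n1) / (n1 - 1)
        sdb <- sqrt(pmax(vb, 0))
        sdb[sdb == 0] <- 1
        zb <- (xb - Sb / n1) / sdb
        dif <- sweep(zm, 2, zb)
        d2 <- as.numeric((dif * dif) %*% ipool)
        if (which.min(d2) == gi) hits[a, b] <- hits[a, b] + 1L
      }
    }
  }
  100 * hits / n
}

#' Cross-temporal direction decoding map
#'
#' Trains the direction classifier on the average firing rates in one time
#' window and tests on the same or a different window (leave-one-out over
#' pseudotrials, the same trial mapping at every window), for all pairs of
#' windows spanning the sample and delay periods of one task.
#'
#' @param dataset A `pm_dataset`.
#' @param task `"perceptual"` or `"memory"`.
#' @param window_ms Decoding window width in ms (default 40).
#' @param seed Integer seed for the pseudopopulation.
#' @param n_per_condition Pseudotrials per condition (default 30).
#' @param alpha ANOVA pre-selection level.
#' @param neuron_ids Optional neuron subset (duplicates allowed).
#' @return A `pm_xtmap`: list with `accuracy` (train x test matrix, %),
#'   `grid` (window metadata) and `task`.
#' @export
cross_temporal_decode <- function(dataset, task, window_ms = 40L,
                                  seed = NULL, n_per_condition = 30L,
                                  alpha = 0.01, neuron_ids = NULL) {
  grid <- time_window_grid(dataset, window_ms)
  pp <- build_pseudopopulation(dataset, n_per_condition = n_per_condition,
                               seed = seed, neuron_ids = neuron_ids)
  sel <- pp$labels$task == task
  dirs <- sort(unique(pp$labels$direction_deg))
  y <- match(pp$labels$direction_deg[sel], dirs)
  Xw <- xt_features(pp, task, grid)
  acc <- xt_engine(Xw, y, alpha = alpha)
  structure(list(accuracy = acc, grid = grid, task = task,
                 n_trials = sum(sel)), class = "pm_xtmap")
}

#' @export
print.pm_xtmap <- function(x, ...) {
  cat("<pm_xtmap> ", x$task, " task, ", nrow(x$grid), " x ", nrow(x$grid),
      " windows of ", x$grid$end_ms[1] - x$grid$start_ms[1], " ms\n", sep = "")
  invisible(x)
}

#' Cross-temporal decoding with bootstrap and chance distributions
#'
#' Produces the point-estimate map plus `n_boot` maps from neuron bootstraps
#' (sampling neurons with replacement) and `n_null` maps with direction
#' labels shuffled across the task's pseudotrials, which together support
#' the stability statistics of [stability_stats()]. Bootstrap and null
#' counts are deliberately configurable: the full-scale protocol (100
#' bootstraps, 1,000 shuffles) is preserved at reduced counts for desk-scale
#' runs.
#'
#' @inheritParams cross_temporal_decode
#' @param n_boot Bootstrap maps (default 20).
#' @param n_null Label-shuffle maps (default 100; the add-one p-value floor
#'   is `1/(n_null+1)`, so the default is the smallest count that can reach
#'   the 0.01 cell-level significance).
#' @return A `pm_xtmap` with extra elements `boot` (list of matrices) and
#'   `null` (list of matrices).
#' @export
cross_temporal_analysis <- function(dataset, task, window_ms = 40L,
                                    seed = NULL, n_per_condition = 30L,
                                    alpha = 0.01, n_boot = 20L, n_null = 100L) {
  grid <- time_window_grid(dataset, window_ms)
  pp <- build_pseudopopulation(dataset, n_per_condition = n_per_condition,
                               seed = seed)
  sel <- pp$labels$task == task
  dirs <- sort(unique(pp$labels$direction_deg))
  y <- match(pp$labels$direction_deg[sel], dirs)
  Xw <- xt_features(pp, task, grid)
  point <- xt_engine(Xw, y, alpha = alpha)

  ids <- dataset$neurons$neuron_id
  boot <- lapply(seq_len(n_boot), function(b) {
    sd_b <- if (is.null(seed)) NULL else pm_child_seed(seed, 100 + b)
    bids <- with_pm_seed(sd_b, sample(ids, length(ids), replace = TRUE))
    ppb <- build_pseudopopulation(dataset, n_per_condition = n_per_condition,
                                  seed = sd_b, neuron_ids = bids)
    xt_engine(xt_features(ppb, task, grid), y, alpha = alpha)
  })
  null <- with_pm_seed(if (is.null(seed)) NULL else pm_child_seed(seed, 7L), {
    lapply(seq_len(n_null), function(s) {
      xt_engine(Xw, y[sample.int(length(y))], alpha = alpha)
    })
  })
  structure(list(accuracy = point, grid = grid, task = task,
                 n_trials = sum(sel), boot = boot, null = null),
            class = "pm_xtmap")
}

#' Temporal stability of the population code
#'
#' For each training window, a delay testing window is counted as stable
#' when its cross-temporal accuracy is (a) above chance (add-one p-value
#' against the label-shuffle null of that cell below `alpha`) and (b) not
#' significantly below the same-window accuracy (one-sided
#' [accuracy_difference_test()] on the bootstrap maps at or above `alpha`).
#' The stability percentage is the fraction of delay testing windows that
#' are stable, and `ms_stable` converts it to milliseconds of the analysed
#' delay span.
#'
#' @param xt A `pm_xtmap` from [cross_temporal_analysis()].
#' @param alpha Cell-level significance (default 0.01).
#' @param n_perm Permutations per bootstrap comparison (default 1000).
#' @param seed Integer seed for the comparison permutations.
#' @return List with `per_train` (tibble: one row per delay training window
#'   with `pct_stable`, `ms_stable`) and `summary` (tibble: delay-averaged
#'   `pct_stable`, `ms_stable`, and the analysed span).
#' @export
stability_stats <- function(xt, alpha = 0.01, n_perm = 1000L, seed = NULL) {
  if (is.null(xt$boot) || is.null(xt$null)) {
    stop("stability_stats needs the bootstrap and null maps from cross_temporal_analysis()")
  }
  grid <- xt$grid
  delay_idx <- which(grid$is_delay)
  span_ms <- length(delay_idx) * (grid$end_ms[1] - grid$start_ms[1])
  nb <- length(xt$boot)
  per_train <- lapply(delay_idx, function(a) {
    stable <- logical(length(delay_idx))
    for (jj in seq_along(delay_idx)) {
      b <- delay_idx[jj]
      nullv <- vapply(xt$null, function(m) m[a, b], numeric(1))
      above <- null_pvalue(xt$accuracy[a, b], nullv) < alpha
      if (!above) next
      diag_b <- vapply(xt$boot, function(m) m[a, a], numeric(1))
      cell_b <- vapply(xt$boot, function(m) m[a, b], numeric(1))
      drop_test <- accuracy_difference_test(
        diag_b, cell_b, n_perm = n_perm,
        seed = if (is.null(seed)) NULL else pm_child_seed(seed, a * 101 + b))
      stable[jj] <- drop_test$p >= alpha
    }
    tibble::tibble(train_window = a, train_start_ms = grid$start_ms[a],
                   pct_stable = 100 * mean(stable),
                   ms_stable = mean(stable) * span_ms)
  })
  per_train <- dplyr::bind_rows(per_train)
  list(per_train = per_train,
       summary = tibble::tibble(task = xt$task,
                                pct_stable = mean(per_train$pct_stable),
                                ms_stable = mean(per_train$ms_stable),
                                delay_span_ms = span_ms))
}
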