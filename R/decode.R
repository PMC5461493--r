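#' Rotate session direction labels to the canonical frame
#'
#' Decoding pools sessions irrespective of which four (90-degree-spaced)
#' directions a session used, so direction labels are rigidly rotated to
#' 0/90/180/270: e.g. a 30/120/210/300 set relabels as 0/90/180/270, the
#' same rotation applying to both tasks.
#'
#' @param dataset A `pm_dataset`.
#' @return The dataset with canonical `direction_set` and trial labels.
#' @export
rotate_direction_labels <- function(dataset) {
  rot <- min(dataset$direction_set %% 360)
  map <- function(d) (d - rot) %% 360
  dataset$trials$direction_deg <- map(dataset$trials$direction_deg)
  dataset$direction_set <- sort(map(dataset$direction_set))
  validate_pm_dataset(dataset)
}

condition_levels <- function(direction_set) {
  dirs <- sort(direction_set %% 360)
  tibble::tibble(task = rep(c("perceptual", "memory"), each = 4),
                 direction_deg = rep(dirs, 2),
                 condition = paste(rep(c("perceptual", "memory"), each = 4),
                                   rep(dirs, 2), sep = "|"))
}

#' Assemble a pseudopopulation from non-simultaneously recorded neurons
#'
#' For each eligible neuron (at least `n_per_condition` usable trials in
#' every one of the eight task-by-direction conditions), `n_per_condition`
#' trials per condition are sampled and their within-condition order is
#' shuffled independently per neuron, randomly assigning trial simultaneity
#' among neurons. Only correctly performed trials are used by default.
#' Duplicate neuron ids are allowed (for neuron bootstraps): each copy draws
#' its own trials.
#'
#' @param dataset A `pm_dataset` (direction labels are rotated to the
#'   canonical frame internally).
#' @param n_per_condition Pseudotrials per condition (default 30).
#' @param seed Integer seed.
#' @param window Analysis window for the rate features, default
#'   [delay_window()].
#' @param neuron_ids Neurons to include (default: all); duplicates allowed.
#' @param correct_only Use correct trials only (default `TRUE`).
#' @return A `pm_pseudopop`: rate matrix `X` `[pseudotrials x neurons]`,
#'   `labels` tibble (`task`, `direction_deg`, `condition`), `map` of source
#'   trial rows, `neuron_ids`, and the source `dataset`.
#' @export
build_pseudopopulation <- function(dataset, n_per_condition = 30L, seed = NULL,
                                   window = delay_window(), neuron_ids = NULL,
                                   correct_only = TRUE) {
  dataset <- rotate_direction_labels(dataset)
  neuron_ids <- neuron_ids %||% dataset$neurons$neuron_id
  tr <- dataset$trials
  usable <- if (correct_only) tr$outcome == "correct" else rep(TRUE, nrow(tr))
  lv <- condition_levels(dataset$direction_set)
  cond_rows <- lapply(seq_len(8), function(c) {
    which(usable & tr$task == lv$task[c] & tr$direction_deg == lv$direction_deg[c])
  })
  counts <- lengths(cond_rows)
  # synthetic datasets record every neuron on every trial, so eligibility is
  # a property of the trial table; recorded datasets with per-neuron trial
  # subsets would mask rates as NA, which this format does not model
  eligible <- all(counts >= n_per_condition)
  if (!eligible) {
    stop("no eligible neurons: conditions have ",
         paste(counts, collapse = ", "), " usable trials; need ",
         n_per_condition, " per condition")
  }
  labels <- lv[rep(seq_len(8), each = n_per_condition), ]
  n_pt <- nrow(labels)
  with_pm_seed(seed, {
    map <- vapply(seq_along(neuron_ids), function(j) {
      unlist(lapply(cond_rows, function(rows) {
        sample(rows, n_per_condition, replace = FALSE)
      }))
    }, integer(n_pt))
    M <- delay_mean_matrix(dataset, window)
    X <- vapply(seq_along(neuron_ids), function(j) {
      M[map[, j], neuron_ids[j]]
    }, numeric(n_pt))
    structure(list(X = matrix(X, nrow = n_pt), labels = labels,
                   map = matrix(map, nrow = n_pt), neuron_ids = neuron_ids,
                   dataset = dataset, window = window),
              class = "pm_pseudopop")
  })
}

#' @export
print.pm_pseudopop <- function(x, ...) {
  cat("<pm_pseudopop> ", nrow(x$X), " pseudotrials x ", ncol(x$X),
      " neurons (", nrow(x$labels) / 8, " per condition)\n", sep = "")
  invisible(x)
}

#' Fit a diagonal linear discriminant classifier
#'
#' Gaussian classes with class-specific means and a single pooled diagonal
#' covariance (independent per-feature variances, pooled within-class across
#' classes), uniform priors. Degenerate features get their variance floored
#' at `var_floor_frac` times the mean pooled variance.
#'
#' @param X Numeric matrix `[rows x features]`.
#' @param y Class labels (coerced to factor; prediction ties go to the
#'   lowest level index).
#' @param var_floor_frac Relative variance floor (default `1e-6`).
#' @return A `pm_diaglda` model.
#' @export
diaglda_train <- function(X, y, var_floor_frac = 1e-6) {
  y <- as.factor(y)
  k <- nlevels(y)
  if (k < 2) stop("need at least 2 classes")
  ng <- tabulate(as.integer(y), k)
  if (any(ng < 2)) stop("every class needs at least 2 training rows")
  X <- as.matrix(X)
  Sg <- rowsum(X, y)                       # k x f class sums
  means <- Sg / ng
  ssw <- colSums(X^2) - colSums(Sg^2 / ng)
  pooled <- pmax(ssw, 0) / (nrow(X) - k)
  floor_ <- var_floor_frac * mean(pooled)
  if (!is.finite(floor_) || floor_ <= 0) floor_ <- 1e-12
  pooled <- pmax(pooled, floor_)
  structure(list(classes = levels(y), means = means, var = pooled),
            class = "pm_diaglda")
}

#' Predict class labels from a diagonal LDA model
#'
#' Assigns each row to the class maximizing
#' \eqn{-\sum_f (x_f - \mu_{c,f})^2 / (2\sigma^2_f)} (uniform priors); exact
#' ties go to the lowest class index.
#'
#' @param model A `pm_diaglda` from [diaglda_train()].
#' @param X Matrix (or vector) of test rows.
#' @return Character vector of predicted class labels.
#' @export
diaglda_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  iv <- 1 / model$var
  Mv <- model$means * rep(iv, each = nrow(model$means))
  lin <- X %*% t(Mv)
  const <- 0.5 * rowSums(model$means * Mv)
  scores <- sweep(lin, 2, const)
  model$classes[max.col(scores, ties.method = "first")]
}

#' Fit the fold-wise preprocessing transform
#'
#' Per-neuron z-scoring parameters estimated from the training rows only,
#' plus feature selection by a one-way ANOVA over the training-set condition
#' labels: neurons without a significant main effect (p below `alpha`) are
#' excluded from training and testing. If no neuron passes the gate, all are
#' retained so the classifier remains defined.
#'
#' @param X Training rate matrix `[rows x neurons]`.
#' @param y Training condition labels.
#' @param alpha ANOVA selection level (default 0.01).
#' @return A `pm_preprocess` transform.
#' @export
preprocess_fit <- function(X, y, alpha = 0.01) {
  X <- as.matrix(X)
  y <- as.factor(y)
  k <- nlevels(y)
  n <- nrow(X)
  ng <- tabulate(as.integer(y), k)
  S <- colSums(X)
  Sg <- rowsum(X, y)
  ssb <- colSums(Sg^2 / ng) - S^2 / n
  ssw <- pmax(colSums(X^2) - colSums(Sg^2 / ng), 0)
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  pv <- pf(Fv, k - 1, n - k, lower.tail = FALSE)
  sel <- which(is.finite(pv) & pv < alpha)
  if (length(sel) == 0) sel <- seq_len(ncol(X))
  mu <- S / n
  v <- (colSums(X^2) - S^2 / n) / (n - 1)
  sdv <- sqrt(pmax(v, 0))
  sdv[sdv == 0] <- 1
  structure(list(mean = mu, sd = sdv, selected = sel, p = pv),
            class = "pm_preprocess")
}

#' Apply a fitted preprocessing transform
#'
#' @param transform A `pm_preprocess` from [preprocess_fit()].
#' @param X Rate matrix to transform (training or test rows).
#' @return Z-scored matrix restricted to the selected neurons.
#' @export
preprocess_apply <- function(transform, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Z <- sweep(sweep(as.matrix(X), 2, transform$mean), 2, transform$sd, "/")
  Z[, transform$selected, drop = FALSE]
}

# Fast leave-one-out decoding: per fold, z-scoring + ANOVA gate + diagonal
# LDA are re-fitted on the remaining rows via rank-one downdates of the
# class/total sums, which makes the full protocol O(n_trials x n_neurons).
# Returns integer predictions in 1..k.
loo_diaglda <- function(X, y, alpha = 0.01, var_floor_frac = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- max(y)
  ng <- tabulate(y, k)
  if (any(ng < 2)) stop("every class needs at least 2 trials for LOO")
  S <- colSums(X)
  Q <- colSums(X^2)
  Sg <- rowsum(X, y)
  pred <- integer(n)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    gi <- y[i]
    n1 <- n - 1L
    ng1 <- ng
    ng1[gi] <- ng1[gi] - 1L
    S1 <- S - xi
    Q1 <- Q - xi * xi
    Sg1 <- Sg
    Sg1[gi, ] <- Sg1[gi, ] - xi
    cs <- colSums(Sg1^2 / ng1)
    ssb <- cs - S1^2 / n1
    ssw <- pmax(Q1 - cs, 0)
    Fv <- (ssb / (k - 1)) / (ssw / (n1 - k))
    pv <- pf(Fv, k - 1, n1 - k, lower.tail = FALSE)
    sel <- which(is.finite(pv) & pv < alpha)
    if (length(sel) == 0) sel <- seq_along(S)
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
    zi <- (xi[sel] - mu) / sdv
    dif <- sweep(zm, 2, zi)
    d2 <- as.numeric((dif * dif) %*% (1 / pooled))
    pred[i] <- which.min(d2)
  }
  pred
}

#' Leave-one-out condition decoding of a pseudopopulation
#'
#' Decodes the eight task-by-direction conditions with diagonal LDA under
#' leave-one-out cross-validation: each of the 240 pseudotrials is tested
#' once with the remaining 239 used for training, and z-scoring plus the
#' ANOVA feature gate are re-fitted inside every fold on its training rows
#' (no leakage).
#'
#' @param pseudopop A [build_pseudopopulation()] result.
#' @param alpha ANOVA pre-selection level (default 0.01).
#' @param scheme `"loo"` (default) for leave-one-out, or `"balanced"` for
#'   the condition-balanced alternative with `n_test` testing trials per
#'   condition per fold (25 training / 5 testing at the default sizes).
#' @param n_test Testing trials per condition per fold for the balanced
#'   scheme.
#' @return A `pm_confusion`: 8x8 incidence-count matrix, rows = true
#'   condition, columns = decoded condition.
#' @export
loo_decode <- function(pseudopop, alpha = 0.01,
                       scheme = c("loo", "balanced"), n_test = 5L) {
  scheme <- match.arg(scheme)
  lv <- unique(pseudopop$labels$condition)
  y <- match(pseudopop$labels$condition, lv)
  pred <- if (scheme == "loo") {
    loo_diaglda(pseudopop$X, y, alpha = alpha)
  } else {
    balanced_diaglda(pseudopop$X, y, alpha = alpha, n_test = n_test)
  }
  cm <- table(factor(y, levels = seq_along(lv)),
              factor(pred, levels = seq_along(lv)))
  cm <- matrix(as.integer(cm), nrow = length(lv),
               dimnames = list(true = lv, decoded = lv))
  structure(cm, class = c("pm_confusion", class(cm)))
}

# Condition-balanced cross-validation: each fold holds out n_test trials
# per condition (the pseudopopulation's within-condition order is already
# random, so contiguous chunks are a random partition), trains on the rest
# with the same fold-wise preprocessing, and every trial is tested exactly
# once.
balanced_diaglda <- function(X, y, alpha = 0.01, n_test = 5L) {
  ng <- tabulate(y)
  if (length(unique(ng)) != 1 || ng[1] %% n_test != 0) {
    stop("balanced scheme needs equal condition counts divisible by n_test")
  }
  n_folds <- ng[1] %/% n_test
  within_idx <- stats::ave(seq_along(y), y, FUN = seq_along)
  fold <- (within_idx - 1L) %/% n_test + 1L
  pred <- integer(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    pre <- preprocess_fit(X[tr, , drop = FALSE], y[tr], alpha = alpha)
    mdl <- diaglda_train(preprocess_apply(pre, X[tr, , drop = FALSE]), y[tr])
    pred[!tr] <- as.integer(diaglda_predict(
      mdl, preprocess_apply(pre, X[!tr, , drop = FALSE])))
  }
  pred
}

#' Leave-one-out direction decoding within one task
#'
#' Four-class direction decoding restricted to one task's pseudotrials, with
#' the same fold-wise preprocessing as [loo_decode()].
#'
#' @inheritParams loo_decode
#' @param task `"perceptual"` or `"memory"`.
#' @return A `pm_confusion` (4x4), dimnames are the canonical directions.
#' @export
loo_direction_decode <- function(pseudopop, task, alpha = 0.01) {
  sel <- pseudopop$labels$task == task
  dirs <- sort(unique(pseudopop$labels$direction_deg))
  y <- match(pseudopop$labels$direction_deg[sel], dirs)
  pred <- loo_diaglda(pseudopop$X[sel, , drop = FALSE], y, alpha = alpha)
  cm <- table(factor(y, levels = seq_along(dirs)),
              factor(pred, levels = seq_along(dirs)))
  cm <- matrix(as.integer(cm), nrow = length(dirs),
               dimnames = list(true = dirs, decoded = dirs))
  structure(cm, class = c("pm_confusion", class(cm)))
}

parse_condition <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  tibble::tibble(task = vapply(parts, `[`, "", 1),
                 direction_deg = as.numeric(vapply(parts, `[`, "", 2)))
}

#' Summarise a condition confusion matrix
#'
#' Task decoding accuracy is the percentage of trials decoded into a
#' condition of the same task; direction accuracy is computed separately
#' within trials with correct and with incorrect task decoding, per true
#' task. Undefined entries (empty denominators) are `NA`.
#'
#' @param conf An 8x8 `pm_confusion` from [loo_decode()].
#' @return One-row tibble: `task_accuracy`, `dir_perceptual_taskcorrect`,
#'   `dir_memory_taskcorrect`, `dir_perceptual_taskerror`,
#'   `dir_memory_taskerror`, `accuracy_8way` (all percentages).
#' @export
decode_summary <- function(conf) {
  stopifnot(nrow(conf) == 8)
  info_t <- parse_condition(rownames(conf))
  info_d <- parse_condition(colnames(conf))
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  same_task <- outer(info_t$task, info_d$task, "==")
  same_dir <- outer(info_t$direction_deg, info_d$direction_deg, "==")
  out <- list(task_accuracy = pct(sum(conf[same_task]), sum(conf)))
  for (tk in c("perceptual", "memory")) {
    rows <- info_t$task == tk
    tc <- same_task & rows
    te <- !same_task & rows
    out[[paste0("dir_", tk, "_taskcorrect")]] <-
      pct(sum(conf[tc & same_dir]), sum(conf[tc]))
    out[[paste0("dir_", tk, "_taskerror")]] <-
      pct(sum(conf[te & same_dir]), sum(conf[te]))
  }
  out$accuracy_8way <- pct(sum(diag(conf)), sum(conf))
  tibble::as_tibble(out[c("task_accuracy",
                          "dir_perceptual_taskcorrect", "dir_memory_taskcorrect",
                          "dir_perceptual_taskerror", "dir_memory_taskerror",
                          "accuracy_8way")])
}

#' Bootstrap decoding accuracy over neurons
#'
#' Samples neurons with replacement (`n_boot` samples of the original
#' population size), rebuilds the pseudopopulation for each sample (so
#' duplicate neurons carry independently shuffled trials), runs the
#' leave-one-out decoder and summarises each run.
#'
#' @param dataset A `pm_dataset`.
#' @param n_boot Number of bootstrap samples (default 100).
#' @param seed Integer seed.
#' @param neuron_ids Population to resample from (default: all neurons).
#' @param resample If `FALSE`, the original population is used in every run
#'   (only the trial assignment varies).
#' @param n_per_condition,window,alpha,correct_only Passed to
#'   [build_pseudopopulation()] / [loo_decode()].
#' @return Tibble with one row per bootstrap: `boot` plus the
#'   [decode_summary()] columns; the confusion matrices are in
#'   `attr(, "confusions")`.
#' @export
bootstrap_decode <- function(dataset, n_boot = 100L, seed = NULL,
                             neuron_ids = NULL, resample = TRUE,
                             n_per_condition = 30L, window = delay_window(),
                             alpha = 0.01, correct_only = TRUE) {
  neuron_ids <- neuron_ids %||% dataset$neurons$neuron_id
  res <- lapply(seq_len(n_boot), function(b) {
    sd_b <- if (is.null(seed)) NULL else pm_child_seed(seed, b)
    ids <- if (resample) {
      with_pm_seed(if (is.null(sd_b)) NULL else sd_b + 1L,
                   sample(neuron_ids, length(neuron_ids), replace = TRUE))
    } else neuron_ids
    pp <- build_pseudopopulation(dataset, n_per_condition = n_per_condition,
                                 seed = sd_b, window = window,
                                 neuron_ids = ids,
                                 correct_only = correct_only)
    conf <- loo_decode(pp, alpha = alpha)
    list(conf = conf, summary = decode_summary(conf))
  })
  out <- dplyr::bind_rows(lapply(res, `[[`, "summary"))
  out <- dplyr::mutate(out, boot = dplyr::row_number(), .before = 1)
  attr(out, "confusions") <- lapply(res, `[[`, "conf")
  out
}

#' Permutation test for a difference between two bootstrap distributions
#'
#' The real value is `mean(boot_a) - mean(boot_b)`; surrogates reassign the
#' pooled bootstrap values to the two groups at random. One-sided add-one
#' p-value for the real difference being positive.
#'
#' @param boot_a,boot_b Numeric vectors of bootstrap accuracies.
#' @param n_perm Number of reassignments (default 1000).
#' @param seed Integer seed.
#' @return Tibble with `difference` and `p`.
#' @export
accuracy_difference_test <- function(boot_a, boot_b, n_perm = 1000L,
                                     seed = NULL) {
  real <- mean(boot_a) - mean(boot_b)
  pool <- c(boot_a, boot_b)
  na <- length(boot_a)
  surr <- with_pm_seed(seed, vapply(seq_len(n_perm), function(s) {
    idx <- sample.int(length(pool), na)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1)))
  tibble::tibble(difference = real,
                 p = perm_pvalue(sum(surr >= real), n_perm))
}

#' Randomized-trial-labels chance distribution for decoding
#'
#' Reruns the full leave-one-out decoding protocol (including fold-wise
#' preprocessing) after shuffling the condition labels across pseudotrials,
#' `n` times, yielding the empirical chance distribution of every accuracy
#' measure.
#'
#' @param pseudopop A [build_pseudopopulation()] result.
#' @param n Number of label shuffles (default 1000).
#' @param seed Integer seed.
#' @param alpha ANOVA pre-selection level.
#' @return Tibble with one row per shuffle: `shuffle` plus the
#'   [decode_summary()] columns.
#' @export
randomized_label_null <- function(pseudopop, n = 1000L, seed = NULL,
                                  alpha = 0.01) {
  pp <- pseudopop
  nt <- nrow(pp$labels)
  with_pm_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n), function(s) {
      pp$labels <- pp$labels[sample.int(nt), ]
      cbind(tibble::tibble(shuffle = s), decode_summary(loo_decode(pp, alpha)))
    }))
  })
}

#' P-value of a real accuracy against a chance distribution
#'
#' Add-one proportion of surrogate accuracies at or above the real value.
#'
#' @param real Observed accuracy.
#' @param null_values Vector of surrogate accuracies.
#' @return p-value.
#' @export
null_pvalue <- function(real, null_values) {
  perm_pvalue(sum(null_values >= real), length(null_values))
}

#' Within- and cross-task direction decoding (2-fold)
#'
#' The 120 trials of each task's four direction conditions are split into
#' two balanced folds of 60. For every train-task/test-task combination the
#' classifier is trained on one fold of the training task and tested on the
#' complementary fold of the testing task (so train and test rows never
#' overlap even within task), averaging accuracy over the two folds.
#' Preprocessing (z-scoring + 4-level ANOVA gate) is fitted on each training
#' fold.
#'
#' @inheritParams loo_decode
#' @param seed Integer seed for the fold split.
#' @return Tibble with `train_task`, `test_task`, `accuracy` (%) for the
#'   four combinations.
#' @export
cross_task_decode <- function(pseudopop, seed = NULL, alpha = 0.01) {
  lb <- pseudopop$labels
  dirs <- sort(unique(lb$direction_deg))
  fold <- with_pm_seed(seed, {
    f <- integer(nrow(lb))
    for (tk in c("perceptual", "memory")) {
      for (d in dirs) {
        idx <- which(lb$task == tk & lb$direction_deg == d)
        half <- sample(idx, length(idx) %/% 2)
        f[idx] <- 2L
        f[half] <- 1L
      }
    }
    f
  })
  combos <- expand.grid(train_task = c("perceptual", "memory"),
                        test_task = c("perceptual", "memory"),
                        stringsAsFactors = FALSE)
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    hits <- 0L
    tot <- 0L
    for (f in 1:2) {
      tr <- lb$task == combos$train_task[i] & fold == f
      te <- lb$task == combos$test_task[i] & fold == (3L - f)
      ytr <- factor(lb$direction_deg[tr], levels = dirs)
      pre <- preprocess_fit(pseudopop$X[tr, , drop = FALSE], ytr, alpha)
      mdl <- diaglda_train(preprocess_apply(pre, pseudopop$X[tr, , drop = FALSE]),
                           ytr)
      pred <- diaglda_predict(mdl,
                              preprocess_apply(pre, pseudopop$X[te, , drop = FALSE]))
      hits <- hits + sum(pred == as.character(lb$direction_deg[te]))
      tot <- tot + sum(te)
    }
    100 * hits / tot
  }, numeric(1))
  tibble::tibble(combos, accuracy = acc)
}

#' Contribution of each functional class to population decoding
#'
#' Repeats the bootstrap decoding after removing all neurons of one
#' functional class (P, PM or M) and compares each accuracy measure with a
#' control population of matched size drawn from the full population without
#' replacement (via [accuracy_difference_test()] on the bootstrap
#' distributions).
#'
#' @param dataset A `pm_dataset`.
#' @param classifications Output of [classify_neurons()].
#' @param seed Integer seed.
#' @param n_boot Bootstraps per population (default 100).
#' @param n_perm Permutations per comparison (default 1000).
#' @param ... Passed to [bootstrap_decode()].
#' @return Tibble: `removed_class`, `measure`, `removed_mean`,
#'   `control_mean`, `delta` (control minus removed), `p`, `n_neurons`.
#' @export
class_removal_analysis <- function(dataset, classifications, seed = NULL,
                                   n_boot = 100L, n_perm = 1000L, ...) {
  measures <- c("task_accuracy", "dir_perceptual_taskcorrect",
                "dir_memory_taskcorrect")
  all_ids <- classifications$neuron_id
  out <- list()
  for (cls in c("P", "PM", "M")) {
    keep <- all_ids[classifications$class != cls]
    ctrl <- with_pm_seed(if (is.null(seed)) NULL else pm_child_seed(seed, 900 + match(cls, c("P", "PM", "M"))),
                         sample(all_ids, length(keep), replace = FALSE))
    b_rm <- bootstrap_decode(dataset, n_boot = n_boot,
                             seed = if (is.null(seed)) NULL else pm_child_seed(seed, 10 + match(cls, c("P", "PM", "M"))),
                             neuron_ids = keep, ...)
    b_ct <- bootstrap_decode(dataset, n_boot = n_boot,
                             seed = if (is.null(seed)) NULL else pm_child_seed(seed, 20 + match(cls, c("P", "PM", "M"))),
                             neuron_ids = ctrl, ...)
    for (m in measures) {
      tst <- accuracy_difference_test(b_ct[[m]], b_rm[[m]], n_perm = n_perm,
                                      seed = if (is.null(seed)) NULL else pm_child_seed(seed, 30 + match(cls, c("P", "PM", "M"))))
      out[[length(out) + 1]] <- tibble::tibble(
        removed_class = cls, measure = m,
        removed_mean = mean(b_rm[[m]]), control_mean = mean(b_ct[[m]]),
        delta = tst$difference, p = tst$p, n_neurons = length(keep))
    }
  }
  dplyr::bind_rows(out)
}

#' Decoding from neurons inside versus outside an anatomical region
#'
#' Runs the decoding pipeline on the inside-only subset, the outside-only
#' subset, and the outside subset downsampled (without replacement) to the
#' inside neuron count.
#'
#' @param dataset A `pm_dataset`.
#' @param inside Logical vector over `dataset$neurons` rows, or a predicate
#'   `function(neurons_tibble)` returning one.
#' @param seed Integer seed.
#' @param n_boot Bootstraps per subset (default 100).
#' @param ... Passed to [bootstrap_decode()].
#' @return Tibble: `subset`, `n_neurons`, mean of each accuracy measure; the
#'   per-bootstrap tibbles are in `attr(, "bootstraps")`.
#' @export
region_subset_decode <- function(dataset, inside, seed = NULL,
                                 n_boot = 100L, ...) {
  if (is.function(inside)) inside <- inside(dataset$neurons)
  stopifnot(is.logical(inside), length(inside) == nrow(dataset$neurons))
  ids_in <- dataset$neurons$neuron_id[inside]
  ids_out <- dataset$neurons$neuron_id[!inside]
  if (length(ids_in) == 0) stop("the region contains no neurons")
  subsets <- list(inside = ids_in, outside = ids_out)
  if (length(ids_out) > length(ids_in)) {
    subsets$outside_downsampled <- with_pm_seed(
      if (is.null(seed)) NULL else pm_child_seed(seed, 3L),
      sample(ids_out, length(ids_in), replace = FALSE))
  }
  boots <- lapply(seq_along(subsets), function(i) {
    if (length(subsets[[i]]) == 0) return(NULL)
    bootstrap_decode(dataset, n_boot = n_boot,
                     seed = if (is.null(seed)) NULL else pm_child_seed(seed, i),
                     neuron_ids = subsets[[i]], ...)
  })
  names(boots) <- names(subsets)
  out <- dplyr::bind_rows(lapply(names(subsets), function(nm) {
    b <- boots[[nm]]
    if (is.null(b)) return(NULL)
    dplyr::summarise(b, dplyr::across(-"boot", ~ mean(.x, na.rm = TRUE))) |>
      dplyr::mutate(subset = nm, n_neurons = length(subsets[[nm]]),
                    .before = 1)
  }))
  attr(out, "bootstraps") <- boots
  out
}
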