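circ_offset <- function(decoded, true) {
  d <- ((decoded - true + 180) %% 360) - 180
  d[d == -180] <- 180
  d
}

#' Incidence of direction decoding at each circular offset
#'
#' From a direction confusion, measures how often trials were decoded as a
#' direction 0, +90, -90 or 180 degrees away from the true one. Incidences
#' are obtained separately for each true direction condition before being
#' averaged, and sum to 100% at every stage. For an 8-condition confusion
#' the rows of the requested task are used and the decoded direction is
#' taken regardless of decoded task.
#'
#' @param conf A `pm_confusion` (8x8 conditions or 4x4 directions).
#' @param task Task whose trials to profile (required for 8x8 input).
#' @return Tibble with `offset_deg` (0, 90, -90, 180) and `incidence` (%).
#' @export
error_incidence_profile <- function(conf, task = NULL) {
  if (nrow(conf) == 8) {
    if (is.null(task)) stop("task is required for an 8-condition confusion")
    it <- parse_condition(rownames(conf))
    id <- parse_condition(colnames(conf))
    rows <- which(it$task == task)
    true_dir <- it$direction_deg[rows]
    dec_dir <- id$direction_deg
    conf <- conf[rows, , drop = FALSE]
  } else {
    true_dir <- as.numeric(rownames(conf))
    dec_dir <- as.numeric(colnames(conf))
  }
  offsets <- c(0, 90, -90, 180)
  per_cond <- vapply(seq_along(true_dir), function(r) {
    off <- circ_offset(dec_dir, true_dir[r])
    tot <- sum(conf[r, ])
    vapply(offsets, function(o) 100 * sum(conf[r, off == o]) / tot,
           numeric(1))
  }, numeric(4))
  tibble::tibble(offset_deg = offsets, incidence = rowMeans(per_cond))
}

#' Paired test for feature proximity in decoding errors
#'
#' Across repetitions of the decoding analysis, the mean incidence of +90
#' and -90 degree errors is compared with the incidence of 180 degree errors
#' by a one-sided paired t-test. Degenerate (zero-variance) differences are
#' guarded: the p-value is 0 or 1 by the sign of the constant difference.
#'
#' @param profiles Tibble with columns `rep`, `offset_deg`, `incidence`
#'   (one [error_incidence_profile()] per repetition).
#' @return Tibble: `mean_90`, `mean_180`, `excess_pct` (percentage excess of
#'   90 over 180 incidence), `t`, `df`, `p`.
#' @export
proximity_test <- function(profiles) {
  wide <- profiles |>
    dplyr::group_by(.data$rep) |>
    dplyr::summarise(
      inc90 = mean(.data$incidence[.data$offset_deg %in% c(90, -90)]),
      inc180 = mean(.data$incidence[.data$offset_deg == 180]),
      .groups = "drop")
  d <- wide$inc90 - wide$inc180
  if (length(d) < 2 || sd(d) <= 1e-9 * max(1, abs(mean(d)))) {
    p <- if (mean(d) > 0) 0 else 1
    tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = p)
  } else {
    tt <- t.test(wide$inc90, wide$inc180, paired = TRUE,
                 alternative = "greater")
  }
  tibble::tibble(mean_90 = mean(wide$inc90), mean_180 = mean(wide$inc180),
                 excess_pct = 100 * (mean(wide$inc90) - mean(wide$inc180)) /
                   mean(wide$inc180),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

#' Shuffle direction labels between whole conditions
#'
#' Control manipulation for the feature-proximity analysis: within each
#' task, the four direction labels are randomly permuted between the four
#' direction conditions while trials stay grouped within condition. Overall
#' decoding accuracy is preserved; the circular relationships between
#' directions are destroyed.
#'
#' @param dataset A `pm_dataset`.
#' @param seed Integer seed.
#' @return The dataset with swapped direction labels.
#' @export
swap_direction_labels <- function(dataset, seed = NULL) {
  dirs <- sort(dataset$direction_set)
  with_pm_seed(seed, {
    for (tk in c("perceptual", "memory")) {
      perm <- sample(dirs)
      sel <- dataset$trials$task == tk
      dataset$trials$direction_deg[sel] <-
        perm[match(dataset$trials$direction_deg[sel], dirs)]
    }
  })
  dataset
}

#' Repeated direction-decoding error profiles, optionally label-swapped
#'
#' Runs `n_rep` bootstrap repetitions of within-task direction decoding and
#' collects the [error_incidence_profile()] of each repetition, feeding
#' [proximity_test()]. With `label_swap = TRUE` each repetition first
#' permutes the direction labels between whole conditions (the control that
#' abolishes proximity structure without changing accuracy).
#'
#' @param dataset A `pm_dataset`.
#' @param task Task to decode.
#' @param n_rep Repetitions (default 50).
#' @param seed Integer seed.
#' @param label_swap Apply the condition-label swap control.
#' @param n_per_condition,alpha Decoding parameters.
#' @return Tibble with `rep`, `offset_deg`, `incidence`.
#' @export
error_profile_repetitions <- function(dataset, task, n_rep = 50L,
                                      seed = NULL, label_swap = FALSE,
                                      n_per_condition = 30L, alpha = 0.01) {
  ids <- dataset$neurons$neuron_id
  dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
    sd_r <- if (is.null(seed)) NULL else pm_child_seed(seed, r)
    ds <- dataset
    if (label_swap) {
      ds <- swap_direction_labels(ds, seed = if (is.null(sd_r)) NULL else sd_r + 13L)
    }
    bids <- with_pm_seed(if (is.null(sd_r)) NULL else sd_r + 29L,
                         sample(ids, length(ids), replace = TRUE))
    pp <- build_pseudopopulation(ds, n_per_condition = n_per_condition,
                                 seed = sd_r, neuron_ids = bids)
    conf <- loo_direction_decode(pp, task, alpha = alpha)
    dplyr::mutate(error_incidence_profile(conf), rep = r, .before = 1)
  }))
}

#' Delay-rate tuning profile around the preferred direction
#'
#' For neurons selective in a task, trial-mean delay rates are re-indexed by
#' the circular offset from each neuron's preferred direction (0, 90, -90,
#' 180) and normalized to the preferred-direction rate. Neurons with a zero
#' preferred rate are excluded from normalization with a warning. Also
#' reports a one-sided paired t-test of 90- versus 180-degree rates and the
#' mean ratio of the preferred-minus-anti-preferred rate difference to the
#' absolute 90-versus-minus-90 difference.
#'
#' @param dataset A `pm_dataset`.
#' @param classifications Output of [classify_neurons()].
#' @param task Task to profile.
#' @param window Analysis window, default [delay_window()].
#' @return List with `profile` (tibble: `neuron_id`, `offset_deg`,
#'   `mean_rate`, `norm_rate`) and `tests` (tibble: `t`, `df`, `p` for 90 vs
#'   180, `ratio_pref_anti_vs_orth`, `n_neurons`).
#' @export
tuning_profile <- function(dataset, classifications, task,
                           window = delay_window()) {
  sig_col <- if (task == "perceptual") "sig_perceptual" else "sig_mnemonic"
  pref_col <- if (task == "perceptual") "pref_perceptual" else "pref_mnemonic"
  cl <- classifications[classifications[[sig_col]], ]
  if (nrow(cl) == 0) stop("no selective neurons in task ", task)
  M <- delay_mean_matrix(dataset, window)
  sel <- dataset$trials$task == task
  dirv <- dataset$trials$direction_deg[sel]
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    x <- M[sel, cl$neuron_id[i]]
    off <- circ_offset(dirv, cl[[pref_col]][i])
    mu <- vapply(c(0, 90, -90, 180), function(o) mean(x[off == o]), numeric(1))
    tibble::tibble(neuron_id = cl$neuron_id[i], offset_deg = c(0, 90, -90, 180),
                   mean_rate = mu, norm_rate = mu / mu[1])
  })
  prof <- dplyr::bind_rows(rows)
  zero_pref <- prof$neuron_id[prof$offset_deg == 0 & prof$mean_rate == 0]
  if (length(zero_pref) > 0) {
    warning("excluding ", length(zero_pref),
            " neuron(s) with zero preferred-direction rate from normalization")
    prof$norm_rate[prof$neuron_id %in% zero_pref] <- NA_real_
  }
  wide <- prof |>
    dplyr::select("neuron_id", "offset_deg", "mean_rate") |>
    tidyr::pivot_wider(names_from = "offset_deg", values_from = "mean_rate",
                       names_prefix = "d")
  r90 <- (wide$d90 + wide$`d-90`) / 2
  tt <- t.test(r90, wide$d180, paired = TRUE, alternative = "greater")
  ratio <- (wide$d0 - wide$d180) / abs(wide$d90 - wide$`d-90`)
  ratio <- ratio[is.finite(ratio)]
  list(profile = prof,
       tests = tibble::tibble(t = unname(tt$statistic),
                              df = unname(tt$parameter), p = tt$p.value,
                              ratio_pref_anti_vs_orth = mean(ratio),
                              n_neurons = nrow(cl)))
}

#' Anatomical clustering of strongly discriminating neurons
#'
#' Tests, independently per subject, whether neurons with high
#' discriminability (auROC above `threshold`) sit closer together on the
#' cortical surface than chance: the observed mean pairwise Euclidean
#' distance among the high-discriminability neurons is compared with 1,000
#' surrogates obtained by shuffling the position values among all the
#' subject's neurons. The p-value is the fraction of surrogate mean
#' distances below the observed one (small p = clustering). Subjects with
#' fewer than two qualifying neurons are skipped with a message.
#'
#' @param neurons Tibble with `x_mm`, `y_mm`, `subject_id` and the
#'   discriminability column (e.g. [classify_neurons()] joined to the
#'   dataset's neuron table).
#' @param metric Name of the discriminability column (default
#'   `"auroc_perceptual"`).
#' @param threshold High-discriminability cutoff (default 0.75, exclusive).
#' @param n_shuffles Position shuffles (default 1000).
#' @param seed Integer seed.
#' @return Tibble per subject: `subject_id`, `n_high`, `observed_mm`,
#'   `p` (`NA` when skipped).
#' @export
topography_cluster_test <- function(neurons, metric = "auroc_perceptual",
                                    threshold = 0.75, n_shuffles = 1000L,
                                    seed = NULL) {
  stopifnot(all(c("x_mm", "y_mm", "subject_id", metric) %in% names(neurons)))
  out <- lapply(unique(neurons$subject_id), function(sj) {
    nb <- neurons[neurons$subject_id == sj, ]
    high <- which(nb[[metric]] > threshold)
    if (length(high) < 2) {
      message("subject ", sj, ": fewer than 2 neurons above ", threshold,
              "; clustering test skipped")
      return(tibble::tibble(subject_id = sj, n_high = length(high),
                            observed_mm = NA_real_, p = NA_real_))
    }
    pos <- cbind(nb$x_mm, nb$y_mm)
    mean_pd <- function(p) mean(stats::dist(p))
    obs <- mean_pd(pos[high, , drop = FALSE])
    surr <- with_pm_seed(seed, vapply(seq_len(n_shuffles), function(s) {
      mean_pd(pos[sample.int(nrow(pos), length(high)), , drop = FALSE])
    }, numeric(1)))
    tibble::tibble(subject_id = sj, n_high = length(high), observed_mm = obs,
                   p = mean(surr < obs))
  })
  dplyr::bind_rows(out)
}
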