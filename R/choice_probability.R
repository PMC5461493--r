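#' Choice probability of direction-selective neurons
#'
#' For each neuron that is direction-selective in a task (per
#' [classify_neurons()]), the choice probability (CP) is the auROC between
#' delay-window mean rates on correct versus error trials whose sample moved
#' in the neuron's preferred direction, oriented so CP above 0.5 means higher
#' rates on correct trials. Neurons with fewer than five correct or five
#' error preferred-direction trials in a task get `NA` for that task (an
#' exclusion, not an error).
#'
#' @param dataset A `pm_dataset`.
#' @param classifications Output of [classify_neurons()]; provides the
#'   selectivity gate and the preferred directions.
#' @param window Analysis window, default [delay_window()].
#' @param min_trials Minimum correct and error trial counts (default 5).
#' @return Tibble with one row per neuron: `neuron_id`, `cp_perceptual`,
#'   `cp_mnemonic` (each `NA` when the neuron is not selective in that task
#'   or fails the trial-count filter).
#' @export
choice_probability <- function(dataset, classifications,
                               window = delay_window(), min_trials = 5L) {
  M <- delay_mean_matrix(dataset, window)
  tr <- dataset$trials
  one <- function(j, task, sig, pref) {
    if (!sig) return(NA_real_)
    sel <- tr$task == task & tr$direction_deg == pref
    ok <- sel & tr$outcome == "correct"
    bad <- sel & tr$outcome == "error"
    if (sum(ok) < min_trials || sum(bad) < min_trials) return(NA_real_)
    .auroc(M[bad, j], M[ok, j])
  }
  cl <- classifications
  tibble::tibble(
    neuron_id = cl$neuron_id,
    cp_perceptual = vapply(seq_len(nrow(cl)), function(i) {
      one(match(cl$neuron_id[i], colnames(M)), "perceptual",
          cl$sig_perceptual[i], cl$pref_perceptual[i])
    }, numeric(1)),
    cp_mnemonic = vapply(seq_len(nrow(cl)), function(i) {
      one(match(cl$neuron_id[i], colnames(M)), "memory",
          cl$sig_mnemonic[i], cl$pref_mnemonic[i])
    }, numeric(1))
  )
}

#' Group-level choice probability statistics
#'
#' One-tailed one-sample Wilcoxon signed-rank tests of CP against 0.5 within
#' each task, and a one-tailed signed-rank test of the within-neuron
#' difference (memory CP minus perceptual CP) against 0.
#'
#' @param cp_results Output of [choice_probability()].
#' @param min_neurons Minimum neurons with CP required per test (default 5).
#' @return Tibble with one row per test (`perceptual_vs_0.5`,
#'   `memory_vs_0.5`, `memory_minus_perceptual`): `mean_cp` (or mean
#'   difference), `p`, `n_neurons`.
#' @export
cp_group_tests <- function(cp_results, min_neurons = 5L) {
  one_sided <- function(x, mu) {
    if (length(x) < min_neurons) {
      stop("need at least ", min_neurons, " neurons with CP for the test")
    }
    # signed-rank against mu, one-tailed for "greater"
    wilcox.test(x, mu = mu, alternative = "greater", exact = FALSE)$p.value
  }
  cp_p <- cp_results$cp_perceptual[!is.na(cp_results$cp_perceptual)]
  cp_m <- cp_results$cp_mnemonic[!is.na(cp_results$cp_mnemonic)]
  d <- cp_results$cp_mnemonic - cp_results$cp_perceptual
  d <- d[!is.na(d)]
  tibble::tibble(
    test = c("perceptual_vs_0.5", "memory_vs_0.5", "memory_minus_perceptual"),
    mean_cp = c(mean(cp_p), mean(cp_m), mean(d)),
    p = c(one_sided(cp_p, 0.5), one_sided(cp_m, 0.5), one_sided(d, 0)),
    n_neurons = c(length(cp_p), length(cp_m), length(d))
  )
}
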