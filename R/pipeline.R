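#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one dataset: neuron classification
#' (discriminability), choice probability, population decoding with
#' bootstraps and randomized-label nulls, cross-task decoding,
#' cross-temporal stability for both tasks, feature-proximity error
#' structure with its label-swap control, tuning profiles, and the
#' anatomical clustering test. All randomness derives from the single
#' `seed`, each stage drawing its own child stream, so two runs with the
#' same configuration and seed produce identical reports.
#'
#' @param config A named list (or path to a YAML file) with optional
#'   sections overriding the defaults below:
#'   \describe{
#'     \item{data}{`list(dir=)` to read a dataset directory, or
#'       `list(fixture=, n_neurons=, n_trials_per_condition=, ...)` to
#'       generate one with [make_fixture()].}
#'     \item{seed}{Master seed (default 1).}
#'     \item{discrim}{`n_shuffles` (500).}
#'     \item{decode}{`n_per_condition` (30), `n_boot` (100), `n_null`
#'       (1000), `alpha` (0.01).}
#'     \item{xtemporal}{`window_ms` (40), `n_boot` (20), `n_null` (100).}
#'     \item{structure}{`n_rep` (50).}
#'     \item{topography}{`threshold` (0.75), `n_shuffles` (1000).}
#'   }
#' @param out Optional directory; when given, `report.json`, `discrim.csv`
#'   and `cp.csv` are written there.
#' @return The report as a nested list (invisibly when `out` is given).
#' @export
pm_run_all <- function(config = list(), out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  dcf <- config$decode %||% list()
  n_per <- dcf$n_per_condition %||% 30L
  alpha <- dcf$alpha %||% 0.01

  log_msg <- function(...) message("[pmdecode] ", ...)
  t_start <- Sys.time()

  dataset <- if (!is.null(config$data$dir)) {
    read_pm_dataset(config$data$dir)
  } else {
    args <- config$data %||% list(fixture = "shared_code")
    fx <- args$fixture %||% "shared_code"
    args <- args[setdiff(names(args), "fixture")]
    do.call(make_fixture, c(list(name = fx, seed = pm_child_seed(seed, 1L)),
                            args))
  }
  log_msg(nrow(dataset$neurons), " neurons, ", nrow(dataset$trials), " trials")

  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_msg(name, " done in ",
            sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            " s")
    r
  }

  cl <- stage("discriminability", classify_neurons(
    dataset, n_shuffles = config$discrim$n_shuffles %||% 500L,
    seed = pm_child_seed(seed, 2L)))
  pmx <- stage("pm_excess", pm_excess_test(cl, seed = pm_child_seed(seed, 3L)))
  corr_all <- stage("correlation", discriminability_correlation(
    cl, "all", seed = pm_child_seed(seed, 4L)))
  cp <- stage("choice_probability", choice_probability(dataset, cl))
  cp_tests <- tryCatch(cp_group_tests(cp), error = function(e) NULL)

  pp <- stage("pseudopopulation", build_pseudopopulation(
    dataset, n_per_condition = n_per, seed = pm_child_seed(seed, 5L)))
  conf <- stage("loo_decode", loo_decode(pp, alpha = alpha))
  boot <- stage("bootstrap", bootstrap_decode(
    dataset, n_boot = dcf$n_boot %||% 100L, seed = pm_child_seed(seed, 6L),
    n_per_condition = n_per, alpha = alpha))
  nulld <- stage("null", randomized_label_null(
    pp, n = dcf$n_null %||% 1000L, seed = pm_child_seed(seed, 7L),
    alpha = alpha))
  xtask <- stage("cross_task", cross_task_decode(
    pp, seed = pm_child_seed(seed, 8L), alpha = alpha))

  xcf <- config$xtemporal %||% list()
  xt <- lapply(c(perceptual = "perceptual", memory = "memory"), function(tk) {
    m <- stage(paste0("xtemporal_", tk), cross_temporal_analysis(
      dataset, tk, window_ms = xcf$window_ms %||% 40L,
      seed = pm_child_seed(seed, 9L), n_per_condition = n_per, alpha = alpha,
      n_boot = xcf$n_boot %||% 20L, n_null = xcf$n_null %||% 100L))
    stability_stats(m, seed = pm_child_seed(seed, 10L))
  })

  scf <- config$structure %||% list()
  prox <- lapply(c(perceptual = "perceptual", memory = "memory"), function(tk) {
    reps <- stage(paste0("proximity_", tk), error_profile_repetitions(
      dataset, tk, n_rep = scf$n_rep %||% 50L,
      seed = pm_child_seed(seed, 11L), n_per_condition = n_per, alpha = alpha))
    list(profile = reps |> dplyr::group_by(.data$offset_deg) |>
           dplyr::summarise(incidence = mean(.data$incidence), .groups = "drop"),
         test = proximity_test(reps))
  })

  tcf <- config$topography %||% list()
  nb <- dplyr::left_join(dataset$neurons, cl, by = "neuron_id")
  topo <- stage("topography", dplyr::bind_rows(lapply(
    c("auroc_perceptual", "auroc_mnemonic"), function(m) {
      dplyr::mutate(topography_cluster_test(
        nb, metric = m, threshold = tcf$threshold %||% 0.75,
        n_shuffles = tcf$n_shuffles %||% 1000L,
        seed = pm_child_seed(seed, 12L)), metric = m, .before = 1)
    })))

  report <- list(
    schema_version = "1.0",
    seed = seed,
    dataset = list(n_neurons = nrow(dataset$neurons),
                   n_trials = nrow(dataset$trials),
                   direction_set = dataset$direction_set,
                   bin_ms = dataset$bin_ms),
    discriminability = list(
      class_counts = as.list(table(cl$class)),
      pm_excess = as.list(pmx),
      correlation_all = as.list(corr_all)),
    choice_probability = if (!is.null(cp_tests)) {
      lapply(split(cp_tests, cp_tests$test), as.list)
    } else list(note = "too few neurons with CP"),
    decoding = list(
      point = as.list(decode_summary(conf)),
      bootstrap_mean = as.list(dplyr::summarise(
        boot, dplyr::across(-"boot", ~ mean(.x, na.rm = TRUE)))),
      null_mean = as.list(dplyr::summarise(
        nulld, dplyr::across(-"shuffle", ~ mean(.x, na.rm = TRUE)))),
      p_task = null_pvalue(decode_summary(conf)$task_accuracy,
                           nulld$task_accuracy),
      cross_task = lapply(seq_len(nrow(xtask)), function(i) as.list(xtask[i, ]))),
    cross_temporal = lapply(xt, function(s) as.list(s$summary)),
    structure = lapply(prox, function(p) list(
      profile = as.list(tidyr::pivot_wider(p$profile,
                                           names_from = "offset_deg",
                                           values_from = "incidence")),
      test = as.list(p$test))),
    topography = lapply(seq_len(nrow(topo)), function(i) as.list(topo[i, ])),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(cl, file.path(out, "discrim.csv"), row.names = FALSE)
    utils::write.csv(cp, file.path(out, "cp.csv"), row.names = FALSE)
    return(invisible(report))
  }
  report
}
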