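dir_conf <- function(m) {
  dimnames(m) <- list(true = c(0, 90, 180, 270), decoded = c(0, 90, 180, 270))
  class(m) <- c("pm_confusion", class(m))
  m
}

test_that("error incidence profiles sum to 100 and match known confusions", {
  ident <- dir_conf(diag(30, 4))
  p <- error_incidence_profile(ident)
  expect_equal(p$incidence[p$offset_deg == 0], 100)
  expect_equal(sum(p$incidence), 100)

  unif <- dir_conf(matrix(10, 4, 4))
  pu <- error_incidence_profile(unif)
  expect_equal(pu$incidence, rep(25, 4))

  # asymmetric: 90-degree neighbours get all the errors
  m <- diag(20, 4)
  for (r in 1:4) {
    m[r, (r %% 4) + 1] <- 5
    m[r, ((r - 2) %% 4) + 1] <- 5
  }
  pa <- error_incidence_profile(dir_conf(m))
  expect_equal(pa$incidence[pa$offset_deg == 90], 100 * 5 / 30)
  expect_equal(pa$incidence[pa$offset_deg == 180], 0)
  expect_equal(sum(pa$incidence), 100)
})

test_that("proximity test guards degenerate inputs and detects excess", {
  reps <- tidyr::crossing(rep = 1:10, offset_deg = c(0, 90, -90, 180)) |>
    dplyr::mutate(incidence = dplyr::case_when(
      offset_deg == 0 ~ 50, offset_deg == 180 ~ 10, TRUE ~ 20))
  r <- proximity_test(reps)
  expect_equal(r$p, 0)  # identical repetitions with 90 > 180
  expect_equal(r$excess_pct, 100)

  # per-offset jitter so the paired differences genuinely vary
  noisy <- reps |>
    dplyr::mutate(incidence = incidence +
                    rep(seq(-1, 1, length.out = 10), each = 4) *
                      rep(c(0.3, -0.5, 0.4, 0.9), times = 10))
  rn <- proximity_test(noisy)
  expect_lt(rn$p, 0.001)
})

test_that("condition label swapping permutes whole conditions", {
  ds <- fx("shared_code", n_neurons = 6L, n_trials_per_condition = 10L)
  sw <- swap_direction_labels(ds, seed = 19)
  for (tk in c("perceptual", "memory")) {
    a <- table(ds$trials$direction_deg[ds$trials$task == tk])
    b <- table(sw$trials$direction_deg[sw$trials$task == tk])
    expect_equal(sort(as.integer(a)), sort(as.integer(b)))
  }
  # trials keep their grouping: the swap is a relabelling, rates untouched
  expect_identical(sw$rates, ds$rates)
})

test_that("tuning profiles recover the cosine pattern around the preferred direction", {
  cfg <- pm_gen_config(n_neurons = 20L, n_trials_per_condition = 60L,
                       mix = c(perceptual = 0, mnemonic = 0, both = 1,
                               untuned = 0), baseline = 10, gain = 4)
  ds <- pm_generate_dataset(cfg, seed = 23)
  cl <- classify_neurons(ds, n_shuffles = 100, seed = 29)
  tp <- tuning_profile(ds, cl, "memory")
  prof <- tp$profile |>
    dplyr::group_by(.data$offset_deg) |>
    dplyr::summarise(norm = mean(.data$norm_rate), .groups = "drop")
  b <- 10; g <- 4
  # closed-form generator pattern: (b + g cos(offset)) / (b + g)
  expect_equal(prof$norm[prof$offset_deg == 0], 1)
  expect_lt(abs(prof$norm[prof$offset_deg == 90] - b / (b + g)), 0.06)
  expect_lt(abs(prof$norm[prof$offset_deg == -90] - b / (b + g)), 0.06)
  expect_lt(abs(prof$norm[prof$offset_deg == 180] - (b - g) / (b + g)), 0.06)
  # orthogonal directions sit between preferred and anti-preferred
  expect_lt(tp$tests$p, 0.01)
  expect_gt(tp$tests$ratio_pref_anti_vs_orth, 2)
})

test_that("topography clustering test finds planted clusters and stays calibrated", {
  ds <- fx("clustered_topography", n_neurons = 50L)
  cl <- classify_neurons(ds, n_shuffles = 150, seed = 31)
  nb <- dplyr::left_join(ds$neurons, cl, by = "neuron_id")
  res <- topography_cluster_test(nb, "auroc_perceptual", seed = 37)
  expect_gte(res$n_high, 2)
  expect_lt(res$p, 0.05)

  # invariance under rigid motion of all coordinates
  th <- 0.7
  rot <- nb |>
    dplyr::mutate(x2 = cos(th) * x_mm - sin(th) * y_mm + 5,
                  y2 = sin(th) * x_mm + cos(th) * y_mm - 2) |>
    dplyr::mutate(x_mm = x2, y_mm = y2)
  res2 <- topography_cluster_test(rot, "auroc_perceptual", seed = 37)
  expect_equal(res2$p, res$p)

  # two qualifying neurons at identical positions, others spread out
  tb <- tibble::tibble(
    x_mm = c(0, 0, 10, 20, 30, 40), y_mm = 0, subject_id = "S1",
    auroc_perceptual = c(0.9, 0.9, 0.6, 0.6, 0.6, 0.6))
  r3 <- topography_cluster_test(tb, "auroc_perceptual", n_shuffles = 500,
                                seed = 41)
  expect_equal(r3$p, 0)  # smallest attainable

  # fewer than two qualifying neurons: skipped with a message
  tb2 <- tb
  tb2$auroc_perceptual <- 0.6
  expect_message(r4 <- topography_cluster_test(tb2, "auroc_perceptual"),
                 "skipped")
  expect_true(is.na(r4$p))
})
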