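test_that("generation is deterministic under a fixed seed", {
  a <- make_fixture("shared_code", seed = 11, n_neurons = 6L,
                    n_trials_per_condition = 5L)
  b <- make_fixture("shared_code", seed = 11, n_neurons = 6L,
                    n_trials_per_condition = 5L)
  expect_identical(a$trials, b$trials)
  expect_identical(a$rates, b$rates)
  c <- make_fixture("shared_code", seed = 12, n_neurons = 6L,
                    n_trials_per_condition = 5L)
  expect_false(identical(a$rates, c$rates))
})

test_that("empirical condition means recover the cosine rate law", {
  cfg <- pm_gen_config(n_neurons = 4L, n_trials_per_condition = 400L,
                       mix = c(perceptual = 0, mnemonic = 0, both = 1,
                               untuned = 0), baseline = 10, gain = 4)
  ds <- pm_generate_dataset(cfg, seed = 21)
  gt <- ds$provenance$ground_truth
  M <- delay_mean_matrix(ds)
  secs <- 0.96  # 24 bins x 40 ms of averaged Poisson counts
  for (i in seq_len(4)) {
    for (tk in c("perceptual", "memory")) {
      g <- if (tk == "perceptual") gt$gain_perceptual[i] else gt$gain_mnemonic[i]
      phi <- if (tk == "perceptual") gt$pref_perceptual[i] else gt$pref_mnemonic[i]
      for (d in ds$direction_set) {
        sel <- ds$trials$task == tk & ds$trials$direction_deg == d
        lam <- max(0, gt$baseline[i] + g * cos((d - phi) * pi / 180))
        se <- sqrt(lam / (secs * sum(sel)))
        expect_lt(abs(mean(M[sel, i]) - lam), 3 * se + 1e-9)
      }
    }
  }
})

test_that("fixtures have their documented ground-truth structure", {
  sc <- fx("shared_code", n_neurons = 12L, n_trials_per_condition = 5L)
  gt <- sc$provenance$ground_truth
  tuned <- gt$class == "both"
  expect_true(any(tuned))
  expect_equal(gt$pref_perceptual[tuned], gt$pref_mnemonic[tuned])
  expect_equal(gt$gain_perceptual[tuned], gt$gain_mnemonic[tuned])

  nu <- fx("null", n_neurons = 8L, n_trials_per_condition = 5L)
  expect_true(all(nu$provenance$ground_truth$gain_perceptual == 0))
  expect_true(all(nu$provenance$ground_truth$gain_mnemonic == 0))

  ic <- fx("independent_codes", n_neurons = 40L, n_trials_per_condition = 5L)
  gti <- ic$provenance$ground_truth
  expect_false(all(gti$pref_perceptual == gti$pref_mnemonic))

  expect_error(make_fixture("nonexistent"), "unknown fixture")
  expect_error(pm_gen_config(n_neurons = 0L), "degenerate")
  expect_error(pm_gen_config(mix = c(perceptual = 1, mnemonic = 1,
                                     both = 0, untuned = 0)), "summing to 1")
})

test_that("measured auROC increases with generated gain", {
  gains <- c(0, 1, 2, 4, 8)
  per_neuron <- lapply(seq_along(gains), function(k) {
    cfg <- pm_gen_config(n_neurons = 8L, n_trials_per_condition = 30L,
                         mix = c(perceptual = 0, mnemonic = 0, both = 1,
                                 untuned = 0), gain = gains[k])
    ds <- pm_generate_dataset(cfg, seed = 300 + k)
    vapply(seq_len(8), function(j) {
      direction_discriminability(ds, ds$neurons$neuron_id[j],
                                 "perceptual")$auroc
    }, numeric(1))
  })
  med <- vapply(per_neuron, median, numeric(1))
  expect_true(all(diff(med) >= -0.02))  # non-decreasing up to sampling noise
  expect_lt(med[1], 0.7)
  expect_gt(med[5], 0.95)
  # rank order of measured auROC tracks the generated gain/baseline ratio
  rho <- cor(rep(gains, each = 8), unlist(per_neuron), method = "spearman")
  expect_gt(rho, 0.7)
})

test_that("behavioural latent couples rates to outcome only when asked", {
  cp1 <- fx("cp_positive", n_neurons = 40L)
  cl1 <- classify_neurons(cp1, n_shuffles = 200, seed = 31)
  cp_res <- choice_probability(cp1, cl1)
  vals <- c(cp_res$cp_perceptual, cp_res$cp_mnemonic)
  expect_gt(mean(vals, na.rm = TRUE), 0.5)

  nu <- fx("null", n_neurons = 8L, n_trials_per_condition = 5L)
  expect_true(all(nu$provenance$ground_truth$choice_coupling == 0))
})
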