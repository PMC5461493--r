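test_that("auROC matches the pair-enumeration oracle", {
  expect_equal(auroc(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(auroc(c(5, 5, 5), c(5, 5, 5)), 0.5)
  expect_equal(auroc(c(0, 1, 2, 3), c(1, 2, 3, 4)), 0.71875)
  expect_error(auroc(numeric(0), 1), "non-empty")
  set.seed(42)
  for (i in 1:200) {
    a <- sample(0:5, sample(1:20, 1), replace = TRUE)  # heavy ties
    b <- sample(0:5, sample(1:20, 1), replace = TRUE)
    expect_equal(auroc(a, b), auroc_oracle(a, b))
  }
})

test_that("rectification folds auROC to [0.5, 1]", {
  expect_equal(rectify_auroc(0.1), 0.9)
  expect_equal(rectify_auroc(0.5), 0.5)
  expect_equal(rectify_auroc(0.75), 0.75)
  expect_error(rectify_auroc(1.2), "0, 1")
  v <- seq(0, 1, by = 0.05)
  expect_equal(rectify_auroc(rectify_auroc(v)), rectify_auroc(v))
  expect_equal(rectify_auroc(v), rectify_auroc(1 - v))
})

test_that("eta-squared equals the hand ANOVA decomposition", {
  # two groups {0,2} and {4,6}: SSB = 8, SST = 10
  expect_equal(pmdecode:::eta_squared(c(0, 2, 4, 6), c(1, 1, 2, 2)), 0.8)
  # zero within-condition variance, differing means
  expect_equal(pmdecode:::eta_squared(c(1, 1, 3, 3), c(1, 1, 2, 2)), 1)
  # equal condition means
  expect_equal(pmdecode:::eta_squared(c(0, 2, 0, 2), c(1, 1, 2, 2)), 0)
  # identical rates across the board
  expect_equal(pmdecode:::eta_squared(rep(5, 8), rep(1:4, 2)), 0)
})

test_that("direction discriminability picks the best pair and preferred direction", {
  # deterministic rates: respond only to 90 degrees
  ds <- make_tiny_dataset(n_per = 5L, rate_fun = function(i) {
    m <- matrix(2, 40, 55)
    m # filled below per trial
  })
  for (id in names(ds$rates)) {
    hit <- ds$trials$direction_deg == 90
    ds$rates[[id]][hit, ] <- 20
  }
  r <- direction_discriminability(ds, "n001", "perceptual")
  expect_equal(r$auroc, 1)
  expect_equal(r$pref_deg, 90)
  # all trials identical: 0.5 and the lowest angle wins the tie
  flat <- make_tiny_dataset(n_per = 5L)
  r2 <- direction_discriminability(flat, "n001", "memory")
  expect_equal(r2$auroc, 0.5)
  expect_equal(r2$pref_deg, 0)
})

test_that("permutation significance follows the add-one and percentile rules", {
  ds <- make_tiny_dataset(n_per = 8L)
  for (id in names(ds$rates)) {
    hit <- ds$trials$direction_deg == 180
    ds$rates[[id]][hit, ] <- 30  # perfectly separable, above all surrogates
  }
  r <- permutation_significance(ds, "n002", "perceptual", n_shuffles = 500,
                                seed = 5)
  expect_equal(r$p, 1 / 501)
  expect_true(r$significant)
  expect_error(permutation_significance(ds, "n002", "perceptual",
                                        n_shuffles = 0), "at least 1")
  expect_warning(permutation_significance(ds, "n002", "perceptual",
                                          n_shuffles = 50, seed = 1),
                 "coarse")
})

test_that("classification recovers strongly tuned neurons and their class", {
  po <- fx_decode("perceptual_only", n_neurons = 40L)
  cl <- classify_neurons(po, n_shuffles = 300, seed = 17)
  gt <- po$provenance$ground_truth
  tuned <- gt$class == "perceptual"
  expect_gte(mean(cl$class[tuned] == "P"), 0.8)
  expect_lte(mean(cl$class[!tuned] != "X"), 0.15)
  # preferred-direction recovery for tuned neurons
  expect_gte(mean(cl$pref_perceptual[tuned] == gt$pref_perceptual[tuned]), 0.8)

  mo <- fx_decode("mnemonic_only", n_neurons = 40L)
  clm <- classify_neurons(mo, n_shuffles = 300, seed = 18)
  gtm <- mo$provenance$ground_truth
  expect_gte(mean(clm$class[gtm$class == "mnemonic"] == "M"), 0.8)
})

test_that("PM excess test detects coupled significance flags", {
  mk <- function(sp, sm) {
    tibble::tibble(sig_perceptual = sp, sig_mnemonic = sm,
                   class = dplyr::case_when(sp & sm ~ "PM", sp ~ "P",
                                            sm ~ "M", TRUE ~ "X"))
  }
  # perfectly coupled: every significant neuron is significant in both tasks
  coupled <- mk(rep(c(TRUE, FALSE), each = 20),
                rep(c(TRUE, FALSE), each = 20))
  p1 <- pm_excess_test(coupled, n_shuffles = 2000, seed = 3)$p
  expect_lt(p1, 0.01)
  # a single PM neuron: no rearrangement changes the count
  single <- mk(TRUE, TRUE)
  expect_equal(pm_excess_test(single, n_shuffles = 500, seed = 3)$p, 1)
  expect_error(pm_excess_test(mk(FALSE, FALSE)), "no neurons")
})

test_that("discriminability correlation and its shuffle null behave", {
  cl <- tibble::tibble(auroc_perceptual = seq(0.5, 0.9, length.out = 20),
                       auroc_mnemonic = seq(0.5, 0.9, length.out = 20),
                       class = "PM")
  r <- discriminability_correlation(cl, "all", n_shuffles = 500, seed = 7)
  expect_equal(r$r, 1)
  expect_lt(r$p, 0.01)
  expect_error(discriminability_correlation(cl[1:2, ], "all"), "at least 3")
})

test_that("task tuning comparison folds preferred-direction shifts", {
  ic <- fx("independent_codes", n_neurons = 40L, n_trials_per_condition = 30L)
  cl <- classify_neurons(ic, n_shuffles = 200, seed = 29)
  tt <- compare_task_tuning(cl, ic)
  gt <- ic$provenance$ground_truth
  both_sig <- which(!is.na(tt$pref_shift))
  expect_gt(length(both_sig), 5)
  true_shift <- abs(((gt$pref_mnemonic - gt$pref_perceptual + 180) %% 360) - 180)
  expect_gte(mean(tt$pref_shift[both_sig] == true_shift[both_sig]), 0.8)
  expect_true(all(tt$pref_shift[both_sig] %in% c(0, 90, 180)))

  # shared-code fixture: shifts all zero among doubly selective neurons
  sc <- fx_decode("shared_code")
  cls <- classify_neurons(sc, n_shuffles = 200, seed = 37)
  tts <- compare_task_tuning(cls, sc)
  shifts <- tts$pref_shift[!is.na(tts$pref_shift)]
  expect_gte(mean(shifts == 0), 0.9)
})
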