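test_that("direction frames rotate rigidly onto the canonical set", {
  ds <- make_tiny_dataset()
  shift <- function(ds, by) {
    ds$direction_set <- ds$direction_set + by
    ds$trials$direction_deg <- ds$trials$direction_deg + by
    ds
  }
  r30 <- rotate_direction_labels(shift(ds, 30))
  expect_equal(r30$direction_set, c(0, 90, 180, 270))
  r0 <- rotate_direction_labels(ds)
  expect_equal(r0$trials$direction_deg, ds$trials$direction_deg)
  r60 <- rotate_direction_labels(shift(ds, 60))
  # 60 maps to 0
  expect_equal(r60$trials$direction_deg[ds$trials$direction_deg == 0],
               rep(0, sum(ds$trials$direction_deg == 0)))
})

test_that("pseudopopulation construction follows the 30-per-condition protocol", {
  ds <- fx_decode("shared_code")
  pp <- build_pseudopopulation(ds, seed = 51)
  expect_equal(nrow(pp$X), 240)
  expect_equal(as.vector(table(pp$labels$condition)), rep(30L, 8))
  expect_equal(ncol(pp$X), nrow(ds$neurons))
  # only correct trials are sampled
  expect_true(all(ds$trials$outcome[as.vector(pp$map)] == "correct"))
  # per-neuron trial assignment is shuffled independently
  expect_false(identical(pp$map[, 1], pp$map[, 2]))
  # determinism
  pp2 <- build_pseudopopulation(ds, seed = 51)
  expect_identical(pp$X, pp2$X)
  # too few usable trials per condition is a hard error
  small <- fx("shared_code", n_neurons = 6L, n_trials_per_condition = 10L)
  expect_error(build_pseudopopulation(small, seed = 1), "eligible")
})

test_that("diagonal LDA matches hand arithmetic and breaks ties low", {
  # one feature, class means 0 and 10: x = 1 goes to the first class
  m <- diaglda_train(matrix(c(-1, 1, 9, 11), ncol = 1), c("a", "a", "b", "b"))
  expect_equal(diaglda_predict(m, matrix(1)), "a")
  # exact equidistance: lowest class index wins
  expect_equal(diaglda_predict(m, matrix(5)), "a")
  expect_error(diaglda_train(matrix(1:4, ncol = 1), c("a", "a", "a", "a")),
               "2 classes")
  expect_error(diaglda_train(matrix(1:3, ncol = 1), c("a", "a", "b")),
               "2 training rows")
})

test_that("diagonal LDA agrees with an independent Gaussian oracle", {
  set.seed(61)
  for (rep in 1:5) {
    k <- 3
    f <- 4
    mu <- matrix(rnorm(k * f, sd = 2), k, f)
    Xtr <- do.call(rbind, lapply(1:k, function(c) {
      sweep(matrix(rnorm(30 * f), 30, f), 2, mu[c, ], "+")
    }))
    ytr <- rep(1:k, each = 30)
    Xte <- do.call(rbind, lapply(1:k, function(c) {
      sweep(matrix(rnorm(67 * f), 67, f), 2, mu[c, ], "+")
    }))
    m <- diaglda_train(Xtr, ytr)
    mine <- as.integer(diaglda_predict(m, Xte))
    oracle <- diag_gauss_oracle(Xtr, ytr, Xte)
    expect_gte(mean(mine == oracle), 0.95)
  }
})

test_that("preprocessing is fitted on training rows only", {
  set.seed(71)
  Xtr <- matrix(rnorm(200 * 10, mean = 5), 200, 10)
  y <- rep(1:8, length.out = 200)
  Xtr[, 3] <- Xtr[, 3] + y  # one informative feature
  pre <- preprocess_fit(Xtr, y, alpha = 0.01)
  expect_true(3 %in% pre$selected)
  # transform applied to its own training rows: mean 0, sd 1
  Z <- preprocess_apply(pre, Xtr)
  expect_equal(unname(colMeans(Z)), rep(0, ncol(Z)), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, ncol(Z)), tolerance = 1e-10)
  # no leakage: test rows cannot change the fitted parameters
  pre2 <- preprocess_fit(Xtr, y, alpha = 0.01)
  expect_identical(pre$mean, pre2$mean)
  expect_identical(pre$selected, pre2$selected)
})

test_that("confusion summaries match direct counting", {
  lv <- pmdecode:::condition_levels(c(0, 90, 180, 270))$condition
  ident <- diag(30L, 8)
  dimnames(ident) <- list(true = lv, decoded = lv)
  class(ident) <- c("pm_confusion", class(ident))
  s <- decode_summary(ident)
  expect_equal(s$task_accuracy, 100)
  expect_equal(s$dir_perceptual_taskcorrect, 100)
  expect_true(is.na(s$dir_perceptual_taskerror))  # empty partition: absent

  unif <- matrix(10L, 8, 8, dimnames = list(true = lv, decoded = lv))
  class(unif) <- c("pm_confusion", class(unif))
  su <- decode_summary(unif)
  expect_equal(su$task_accuracy, 50)
  expect_equal(su$dir_memory_taskcorrect, 25)
  expect_equal(su$dir_memory_taskerror, 25)
  expect_equal(su$accuracy_8way, 12.5)

  # hand-built: all perceptual|0 trials decoded as memory|0 (direction kept,
  # task missed), everything else on the diagonal
  hand <- diag(30L, 8)
  dimnames(hand) <- list(true = lv, decoded = lv)
  hand[1, 1] <- 0L
  hand[1, 5] <- 30L   # perceptual|0 -> memory|0
  class(hand) <- c("pm_confusion", class(hand))
  sh <- decode_summary(hand)
  expect_equal(sh$task_accuracy, 100 * 210 / 240)
  expect_equal(sh$dir_perceptual_taskcorrect, 100)
  expect_equal(sh$dir_perceptual_taskerror, 100)
  # tidy() row percentages agree with counts
  td <- tidy(hand)
  expect_equal(sum(td$n), 240L)
  expect_equal(unname(td$pct[td$true == lv[1] & td$decoded == lv[5]]), 100)
})

test_that("leave-one-out decoding separates a separable population", {
  ds <- fx_decode("shared_code")
  pp <- build_pseudopopulation(ds, seed = 81)
  conf <- loo_decode(pp)
  expect_equal(unname(rowSums(conf)), rep(30L, 8))  # row sums = tested trials
  s <- decode_summary(conf)
  # no task signal in this fixture, strong shared direction signal
  expect_gt(s$dir_perceptual_taskcorrect, 80)
  expect_gt(s$dir_memory_taskcorrect, 80)
  expect_lt(abs(s$task_accuracy - 50), 15)
  # direction decoding within task
  cd <- loo_direction_decode(pp, "memory")
  expect_gt(glance(cd)$accuracy, 80)
  # the balanced 25/5 scheme gives virtually identical results
  sb <- decode_summary(loo_decode(pp, scheme = "balanced"))
  expect_lt(abs(sb$dir_memory_taskcorrect - s$dir_memory_taskcorrect), 10)
  expect_lt(abs(sb$task_accuracy - s$task_accuracy), 10)
})

test_that("decoding is invariant to a canonical rotation of the labels", {
  cfg <- pm_gen_config(n_neurons = 24L, n_trials_per_condition = 45L,
                       direction_set = c(30, 120, 210, 300),
                       mix = c(perceptual = 0, mnemonic = 0, both = 0.5,
                               untuned = 0.5))
  ds <- pm_generate_dataset(cfg, seed = 83)
  rot <- rotate_direction_labels(ds)
  s1 <- decode_summary(loo_decode(build_pseudopopulation(ds, seed = 5)))
  s2 <- decode_summary(loo_decode(build_pseudopopulation(rot, seed = 5)))
  expect_equal(s1, s2)
})

test_that("accuracy difference test follows the pooled-shuffle protocol", {
  a <- seq(10, 14, length.out = 20)
  b <- seq(1, 5, length.out = 20)
  r <- accuracy_difference_test(a, b, n_perm = 1000, seed = 91)
  expect_equal(r$p, 1 / 1001)  # disjoint distributions: formula floor
  r2 <- accuracy_difference_test(a, a, n_perm = 1000, seed = 91)
  expect_equal(r2$difference, 0)
  expect_gt(r2$p, 0.2)
  expect_lt(r2$p, 0.9)
})

test_that("cross-task decoding generalizes only for shared codes", {
  sc <- fx_decode("shared_code")
  pp <- build_pseudopopulation(sc, seed = 93)
  xt <- cross_task_decode(pp, seed = 95)
  within <- mean(xt$accuracy[xt$train_task == xt$test_task])
  across <- mean(xt$accuracy[xt$train_task != xt$test_task])
  expect_gt(within, 70)
  expect_lt(abs(within - across), 10)

  ic <- fx_decode("independent_codes")
  ppi <- build_pseudopopulation(ic, seed = 93)
  xti <- cross_task_decode(ppi, seed = 95)
  within_i <- mean(xti$accuracy[xti$train_task == xti$test_task])
  across_i <- mean(xti$accuracy[xti$train_task != xti$test_task])
  expect_gt(within_i, 70)
  expect_lt(abs(across_i - 25), 15)  # chance when codes are unrelated
})

test_that("class removal hurts only when the class carries the code", {
  ds <- fx_decode("shared_code", n_neurons = 40L)
  cl <- classify_neurons(ds, n_shuffles = 200, seed = 97)
  res <- class_removal_analysis(ds, cl, seed = 99, n_boot = 8, n_perm = 300)
  # removing PM neurons (the only tuned class here) collapses direction
  # decoding relative to a size-matched control
  pm_dir <- res[res$removed_class == "PM" &
                  res$measure == "dir_memory_taskcorrect", ]
  expect_gt(pm_dir$delta, 20)
  expect_lt(pm_dir$p, 0.05)
  # removing an (almost) empty class changes little
  p_dir <- res[res$removed_class == "P" &
                 res$measure == "dir_memory_taskcorrect", ]
  expect_lt(abs(p_dir$delta), 10)
})

test_that("regional decoding respects the inside/outside protocol", {
  # a minority of tuned neurons, clustered on a wide surface, so the
  # outside set is larger than the inside one
  ds <- fx("clustered_topography", n_neurons = 50L,
           n_trials_per_condition = 50L, extent_mm = c(20, 20),
           mix = c(perceptual = 0, mnemonic = 0, both = 0.3, untuned = 0.7))
  inside <- function(nb) sqrt((nb$x_mm - 2.5)^2 + (nb$y_mm - 2.5)^2) < 3
  res <- region_subset_decode(ds, inside, seed = 103, n_boot = 5)
  expect_true(all(c("inside", "outside", "outside_downsampled") %in% res$subset))
  expect_equal(res$n_neurons[res$subset == "outside_downsampled"],
               res$n_neurons[res$subset == "inside"])
  acc <- function(sub) res$dir_memory_taskcorrect[res$subset == sub]
  expect_gt(acc("inside"), acc("outside_downsampled"))
  expect_error(region_subset_decode(ds, rep(FALSE, 50), seed = 1), "no neurons")
})
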