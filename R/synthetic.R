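#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the statistical structure of delay-period recordings
#' in a two-task (perceptual vs. memory) delayed match-to-sample experiment:
#' cosine direction tuning with independently controllable perceptual and
#' mnemonic coding strength, optional task-dependent preferred directions and
#' firing-rate offsets, temporally dynamic delay codes, behaviour-linked rate
#' fluctuations (for choice probability), and spatial clustering of strongly
#' tuned neurons (for topography).
#'
#' For neuron \eqn{i} on a trial of task \eqn{\tau} with sample direction
#' \eqn{\theta}, the expected rate in bin \eqn{t} is
#' \deqn{\lambda = \max(0,\; b_i + \Delta_i [\tau = memory]
#'   + g_{i,\tau} \cos(\theta - \phi_{i,\tau})\, m_i(t, \tau) + \beta_i u),}
#' where \eqn{m_i} is 1 for stable dynamics and a smooth positive per-neuron,
#' per-task temporal modulation (mean 1, correlation time `tau_ms`, fixed
#' across trials) for dynamic codes, and \eqn{u \sim N(0,1)} is a per-trial
#' latent shared between rates and behaviour. Spike counts per bin are
#' Poisson with mean `lambda * bin_ms / 1000` and stored as rates. The trial
#' outcome is correct with probability `plogis(qlogis(p_correct) + behav_slope * u)`,
#' so `choice_coupling > 0` induces choice probability above 0.5.
#'
#' @param n_neurons Number of neurons.
#' @param n_trials_per_condition Trials per task x direction condition
#'   (default 30; the decoding analyses require at least 30).
#' @param direction_set Four directions separated by 90 degrees.
#' @param bin_ms Bin width in ms.
#' @param mix Named proportions of neuron classes
#'   `c(perceptual=, mnemonic=, both=, untuned=)`; must sum to 1.
#' @param baseline Baseline rate \eqn{b} (spikes/s).
#' @param gain Tuning amplitude \eqn{g} (spikes/s) given to tuned tasks.
#' @param rate_offset_memory Task-wise mean rate shift \eqn{\Delta}
#'   (spikes/s) applied to tuned neurons in the memory task.
#' @param pref_independent If `TRUE`, mnemonic preferred directions are drawn
#'   independently of perceptual ones; otherwise they coincide.
#' @param dynamics Named character vector, e.g.
#'   `c(perceptual="stable", memory="dynamic")`.
#' @param tau_ms Correlation time of the dynamic modulation (ms).
#' @param mod_sd Standard deviation of the dynamic modulation around 1.
#' @param choice_coupling Behaviour-rate coupling \eqn{\beta} (spikes/s per
#'   unit of the trial latent) given to tuned neurons.
#' @param p_correct Marginal probability of a correct outcome at `u = 0`.
#' @param behav_slope Slope of the latent in the outcome model.
#' @param cluster `NULL`, or `list(center_mm=c(x,y), sd_mm=, gain_threshold=)`;
#'   neurons whose largest gain is at or above the threshold are placed at the
#'   cluster, the rest uniformly over `extent_mm`.
#' @param extent_mm Recording surface extent `c(x, y)` in mm.
#' @param subject_id,session_id Metadata tags.
#' @return A `pm_gen_config` list.
#' @export
pm_gen_config <- function(n_neurons = 60L,
                          n_trials_per_condition = 30L,
                          direction_set = c(0, 90, 180, 270),
                          bin_ms = 40L,
                          mix = c(perceptual = 0, mnemonic = 0,
                                  both = 0, untuned = 1),
                          baseline = 10,
                          gain = 3,
                          rate_offset_memory = 0,
                          pref_independent = FALSE,
                          dynamics = c(perceptual = "stable",
                                       memory = "stable"),
                          tau_ms = 300,
                          mod_sd = 1.2,
                          choice_coupling = 0,
                          p_correct = 0.85,
                          behav_slope = 1,
                          cluster = NULL,
                          extent_mm = c(10, 10),
                          subject_id = "S1",
                          session_id = "s01") {
  mix <- mix[c("perceptual", "mnemonic", "both", "untuned")]
  if (anyNA(mix) || abs(sum(mix) - 1) > 1e-8) {
    stop("mix must provide proportions perceptual/mnemonic/both/untuned summing to 1")
  }
  if (n_neurons < 1 || n_trials_per_condition < 1) {
    stop("degenerate config: need at least 1 neuron and 1 trial per condition")
  }
  if (length(direction_set) != 4) stop("direction_set must have 4 directions")
  structure(as.list(environment()), class = "pm_gen_config")
}

# Smooth positive temporal modulation, mean ~1, correlation time tau_ms:
# Gaussian-kernel-smoothed white noise rescaled to mod_sd, floored near zero.
smooth_modulation <- function(nb, bin_ms, tau_ms, mod_sd) {
  halfwidth <- max(1L, ceiling(3 * tau_ms / bin_ms))
  z <- rnorm(nb + 2 * halfwidth)
  k <- dnorm(seq(-halfwidth, halfwidth), sd = max(tau_ms / bin_ms, 1e-6))
  k <- k / sum(k)
  s <- as.numeric(stats::filter(z, k, sides = 2))
  s <- s[(halfwidth + 1):(halfwidth + nb)]
  s <- (s - mean(s)) / max(sd(s), 1e-12) * mod_sd
  pmax(0.05, 1 + s)
}

#' Generate a synthetic dataset with known ground truth
#'
#' See [pm_gen_config()] for the generative model. The returned dataset's
#' `provenance$ground_truth` tibble holds the per-neuron parameters
#' (baseline, task-wise gains and preferred directions, memory rate offset,
#' dynamics, choice coupling, class) used to produce it, enabling recovery
#' tests. The same `seed` always yields an identical dataset.
#'
#' @param config A [pm_gen_config()].
#' @param seed Integer seed.
#' @return A `pm_dataset`.
#' @export
pm_generate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "pm_gen_config"))
  with_pm_seed(seed, generate_impl(config, seed))
}

generate_impl <- function(cfg, seed) {
  nd <- length(cfg$direction_set)
  ntc <- cfg$n_trials_per_condition
  n_trials <- 2L * nd * ntc
  sample_ms <- 1000L
  nb <- (sample_ms + 1200L) %/% cfg$bin_ms
  if ((sample_ms + 1200L) %% cfg$bin_ms != 0) {
    stop("bin_ms must divide the stored epoch (sample 1000 ms + 1200 ms delay)")
  }

  # --- trials ----------------------------------------------------------
  cond <- expand.grid(direction_deg = cfg$direction_set,
                      task = c("perceptual", "memory"),
                      rep = seq_len(ntc), stringsAsFactors = FALSE)
  u <- rnorm(n_trials)
  a0 <- qlogis(cfg$p_correct)
  outcome <- ifelse(runif(n_trials) < plogis(a0 + cfg$behav_slope * u),
                    "correct", "error")
  trials <- tibble::tibble(
    trial_id = seq_len(n_trials),
    task = cond$task,
    direction_deg = cond$direction_deg,
    outcome = outcome,
    delay_ms = sample(1200:2000, n_trials, replace = TRUE),
    session_id = cfg$session_id,
    subject_id = cfg$subject_id
  )
  # interleave tasks randomly, as in the experiment
  ord <- sample.int(n_trials)
  trials <- trials[ord, ]
  trials$trial_id <- seq_len(n_trials)
  u <- u[ord]

  # --- neuron ground truth ---------------------------------------------
  classes <- sample(rep(c("perceptual", "mnemonic", "both", "untuned"),
                        round_mix(cfg$mix, cfg$n_neurons)))
  pref_p <- sample(cfg$direction_set, cfg$n_neurons, replace = TRUE)
  pref_m <- if (cfg$pref_independent) {
    sample(cfg$direction_set, cfg$n_neurons, replace = TRUE)
  } else pref_p
  gP <- ifelse(classes %in% c("perceptual", "both"), cfg$gain, 0)
  gM <- ifelse(classes %in% c("mnemonic", "both"), cfg$gain, 0)
  tuned <- classes != "untuned"
  beta <- ifelse(tuned, cfg$choice_coupling, 0)
  delta <- ifelse(tuned, cfg$rate_offset_memory, 0)

  # positions: strong coders cluster when configured
  pos <- cbind(runif(cfg$n_neurons, 0, cfg$extent_mm[1]),
               runif(cfg$n_neurons, 0, cfg$extent_mm[2]))
  if (!is.null(cfg$cluster)) {
    thr <- cfg$cluster$gain_threshold %||% (cfg$gain / 2)
    strong <- pmax(gP, gM) >= thr
    k <- sum(strong)
    if (k > 0) {
      pos[strong, ] <- cbind(
        rnorm(k, cfg$cluster$center_mm[1], cfg$cluster$sd_mm),
        rnorm(k, cfg$cluster$center_mm[2], cfg$cluster$sd_mm))
    }
  }

  ids <- sprintf("n%03d", seq_len(cfg$n_neurons))
  neurons <- tibble::tibble(neuron_id = ids, x_mm = pos[, 1], y_mm = pos[, 2],
                            subject_id = cfg$subject_id)
  gt <- tibble::tibble(
    neuron_id = ids, class = classes, baseline = cfg$baseline,
    gain_perceptual = gP, gain_mnemonic = gM,
    pref_perceptual = pref_p, pref_mnemonic = pref_m,
    rate_offset_memory = delta, choice_coupling = beta,
    dynamics_perceptual = unname(cfg$dynamics["perceptual"]),
    dynamics_memory = unname(cfg$dynamics["memory"]),
    x_mm = pos[, 1], y_mm = pos[, 2]
  )

  # --- rates ------------------------------------------------------------
  is_mem <- trials$task == "memory"
  theta <- trials$direction_deg * pi / 180
  dt <- cfg$bin_ms / 1000
  rates <- vector("list", cfg$n_neurons)
  names(rates) <- ids
  for (i in seq_len(cfg$n_neurons)) {
    mod <- list(
      perceptual = if (cfg$dynamics[["perceptual"]] == "dynamic")
        smooth_modulation(nb, cfg$bin_ms, cfg$tau_ms, cfg$mod_sd) else rep(1, nb),
      memory = if (cfg$dynamics[["memory"]] == "dynamic")
        smooth_modulation(nb, cfg$bin_ms, cfg$tau_ms, cfg$mod_sd) else rep(1, nb)
    )
    g <- ifelse(is_mem, gM[i], gP[i])
    phi <- ifelse(is_mem, pref_m[i], pref_p[i]) * pi / 180
    tune <- g * cos(theta - phi)                      # per trial
    base <- cfg$baseline + delta[i] * is_mem + beta[i] * u  # per trial
    m <- rbind(mod$perceptual, mod$memory)[is_mem + 1L, , drop = FALSE]
    lam <- pmax(0, base + tune * m)                   # trials x bins
    cnt <- matrix(rpois(length(lam), lam * dt), nrow = n_trials)
    rates[[i]] <- cnt / dt
  }

  pm_dataset(trials = trials, neurons = neurons, rates = rates,
             direction_set = cfg$direction_set, bin_ms = cfg$bin_ms,
             sample_ms = sample_ms,
             provenance = list(seed = seed, ground_truth = gt))
}

# Integer class counts matching the mix proportions (largest-remainder).
round_mix <- function(mix, n) {
  raw <- mix * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Named synthetic fixtures used throughout the test-suite
#'
#' Small datasets (at most 60 neurons, 30 trials per condition) with
#' documented ground truth:
#' \describe{
#'   \item{null}{all gains zero, no choice coupling: every analysis should be
#'     at chance.}
#'   \item{perceptual_only}{half the neurons tuned in the perceptual task
#'     only.}
#'   \item{mnemonic_only}{half tuned in the memory task only.}
#'   \item{shared_code}{half tuned in both tasks with identical preferred
#'     directions and gains (a task-invariant direction code).}
#'   \item{independent_codes}{tuned in both tasks but with independently
#'     drawn preferred directions and a memory-task rate offset, so the tasks
#'     use different codes.}
#'   \item{dynamic_memory}{shared tuning, but the memory-task code is
#'     temporally dynamic while the perceptual code is stable.}
#'   \item{clustered_topography}{tuned neurons spatially clustered.}
#'   \item{cp_positive}{tuned neurons with positive behaviour-rate coupling,
#'     producing choice probabilities above 0.5.}
#'   \item{weak_cosine}{weak cosine tuning in both tasks so population
#'     decoding is imperfect and direction decoding errors are plentiful;
#'     used for the feature-proximity analyses.}
#' }
#'
#' @param name Fixture name.
#' @param seed Integer seed (default 1).
#' @param n_neurons Number of neurons (default 60).
#' @param ... Overrides passed to [pm_gen_config()].
#' @return A `pm_dataset`.
#' @export
make_fixture <- function(name, seed = 1L, n_neurons = 60L, ...) {
  base <- list(n_neurons = n_neurons)
  args <- switch(
    name,
    null = list(mix = c(perceptual = 0, mnemonic = 0, both = 0, untuned = 1)),
    perceptual_only = list(mix = c(perceptual = 0.5, mnemonic = 0,
                                   both = 0, untuned = 0.5)),
    mnemonic_only = list(mix = c(perceptual = 0, mnemonic = 0.5,
                                 both = 0, untuned = 0.5)),
    shared_code = list(mix = c(perceptual = 0, mnemonic = 0,
                               both = 0.5, untuned = 0.5)),
    independent_codes = list(mix = c(perceptual = 0, mnemonic = 0,
                                     both = 0.5, untuned = 0.5),
                             pref_independent = TRUE,
                             rate_offset_memory = 3),
    dynamic_memory = list(mix = c(perceptual = 0, mnemonic = 0,
                                  both = 0.5, untuned = 0.5),
                          gain = 6,
                          dynamics = c(perceptual = "stable",
                                       memory = "dynamic")),
    clustered_topography = list(mix = c(perceptual = 0, mnemonic = 0,
                                        both = 0.6, untuned = 0.4),
                                cluster = list(center_mm = c(2.5, 2.5),
                                               sd_mm = 1)),
    cp_positive = list(mix = c(perceptual = 0, mnemonic = 0,
                               both = 0.5, untuned = 0.5),
                       choice_coupling = 2, p_correct = 0.75),
    weak_cosine = list(mix = c(perceptual = 0, mnemonic = 0,
                               both = 0.5, untuned = 0.5),
                       gain = 1),
    stop("unknown fixture name: ", name)
  )
  cfg <- do.call(pm_gen_config, utils::modifyList(c(base, args), list(...)))
  pm_generate_dataset(cfg, seed = seed)
}
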