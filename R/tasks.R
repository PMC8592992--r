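# Task battery: generators for every simulated experiment's outcome schedule.
# Single-cue tasks carry one outcome per trial; choice tasks carry one
# potential outcome per option per trial (the experiment runner decides what
# the learner observes).

#' Task episode container
#'
#' @param outcomes Numeric vector (single-cue) or matrix with one column per
#'   option/channel.
#' @param rate_true True latent rate(s), same shape as `outcomes`.
#' @param phase Character per-trial phase labels.
#' @param correct_option Optional integer per-trial index of the better
#'   option (choice tasks).
#' @param meta List of generation metadata: task name, condition, parameters,
#'   seed.
#' @return An object of class `task_episode`.
#' @export
task_episode <- function(outcomes, rate_true, phase, correct_option = NULL,
                         meta = list()) {
  n <- NROW(outcomes)
  stopifnot(NROW(rate_true) == n, length(phase) == n)
  if (!is.null(correct_option)) stopifnot(length(correct_option) == n)
  structure(list(outcomes = outcomes, rate_true = rate_true,
                 phase = as.character(phase), correct_option = correct_option,
                 meta = meta),
            class = "task_episode")
}

#' @export
length.task_episode <- function(x) NROW(x$outcomes)

#' Constant-parameter 2x2 design episode
#'
#' A single-cue series generated from the hierarchical model with volatility
#' and stochasticity held constant at known true values (the factorial
#' small/large designs use v in {0.5, 1.5} crossed with s in {1, 3}).
#'
#' @param v_true,s_true True constant volatility and stochasticity, positive.
#' @param n_trials Number of trials (default 200).
#' @param x0 Initial reward rate (default 0).
#' @param seed Optional integer seed.
#' @return A [task_episode()].
#' @export
make_constant_2x2 <- function(v_true, s_true, n_trials = 200, x0 = 0,
                              seed = NULL) {
  stopifnot(v_true > 0, s_true > 0)
  if (!is.null(seed)) set.seed(seed)
  gp <- generative_params(v0 = v_true, s0 = s_true, x0 = x0,
                          n_trials = n_trials)
  gs <- generate_series(gp, fixed_noise = constant_noise(v_true, s_true, n_trials))
  task_episode(outcomes = gs$o, rate_true = gs$x,
               phase = rep("constant", n_trials),
               meta = list(task = "constant_2x2", v_true = v_true,
                           s_true = s_true, n_trials = n_trials, x0 = x0,
                           seed = seed))
}

#' Stable/volatile reward-rate switching episode
#'
#' Single-cue task with alternating stable and volatile blocks. The reward
#' rate is constant at `stable_rate` in stable blocks; in volatile blocks it
#' flips between `volatile_rates[1]` and `volatile_rates[2]` every
#' `switch_every` trials. Outcomes are the rate plus Gaussian noise.
#'
#' @param stable_rate Rate in stable blocks (default 0.8).
#' @param volatile_rates Two rates alternated in volatile blocks (default
#'   0.25, 0.75).
#' @param block_length Trials per block (default 90).
#' @param n_blocks Number of blocks, alternating stable/volatile starting
#'   with `first_block` (default 2: one stable then one volatile block).
#' @param switch_every Trials between rate flips within a volatile block
#'   (default 20).
#' @param outcome_var Outcome noise variance (default 0.01).
#' @param first_block `"stable"` or `"volatile"`.
#' @param seed Optional integer seed.
#' @return A [task_episode()] with phases `"stable"`/`"volatile"`.
#' @export
make_switching_task <- function(stable_rate = 0.8,
                                volatile_rates = c(0.25, 0.75),
                                block_length = 90, n_blocks = 2,
                                switch_every = 20, outcome_var = 0.01,
                                first_block = c("stable", "volatile"),
                                seed = NULL) {
  first_block <- match.arg(first_block)
  stopifnot(stable_rate >= 0, stable_rate <= 1,
            all(volatile_rates >= 0), all(volatile_rates <= 1),
            block_length >= 1, n_blocks >= 1, switch_every >= 1,
            outcome_var >= 0)
  if (!is.null(seed)) set.seed(seed)
  kinds <- rep(c("stable", "volatile"), length.out = n_blocks)
  if (first_block == "volatile") kinds <- rev(rep(c("volatile", "stable"),
                                                  length.out = n_blocks))
  rate <- numeric(0)
  phase <- character(0)
  vol_idx <- 1L
  for (k in kinds) {
    if (k == "stable") {
      rate <- c(rate, rep(stable_rate, block_length))
    } else {
      seg <- ceiling(block_length / switch_every)
      r <- rep(volatile_rates[((vol_idx - 1L + seq_len(seg) - 1L) %% 2L) + 1L],
               each = switch_every)[seq_len(block_length)]
      vol_idx <- vol_idx + seg
      rate <- c(rate, r)
    }
    phase <- c(phase, rep(k, block_length))
  }
  n <- length(rate)
  o <- rate + stats::rnorm(n, 0, sqrt(outcome_var))
  task_episode(o, rate, phase,
               meta = list(task = "switching", stable_rate = stable_rate,
                           volatile_rates = volatile_rates,
                           block_length = block_length, n_blocks = n_blocks,
                           switch_every = switch_every,
                           outcome_var = outcome_var,
                           first_block = first_block, seed = seed))
}

#' Conditioned-suppression (surprise-induced upshift) episode
#'
#' Pretraining pairs the cue with a weak shock (outcome 0.3); in the omission
#' condition the last `n_omission` pretraining trials deliver no shock
#' (outcome 0). Retraining pairs the cue with a strong shock (outcome 1).
#' A small Gaussian noise (variance 1e-2) is added to all outcomes.
#'
#' @param condition `"omission"` or `"control"`.
#' @param n_pretraining Pretraining trials including omission trials
#'   (default 100).
#' @param n_omission Omission trials ending pretraining (default 5).
#' @param n_retraining Retraining trials (default 20).
#' @param weak,strong Weak and strong shock magnitudes (defaults 0.3, 1).
#' @param outcome_var Outcome noise variance (default 1e-2).
#' @param seed Optional integer seed.
#' @return A [task_episode()] with phases `"pretraining"`, `"omission"`
#'   (omission condition only) and `"retraining"`.
#' @export
make_conditioned_suppression <- function(condition = c("omission", "control"),
                                         n_pretraining = 100, n_omission = 5,
                                         n_retraining = 20, weak = 0.3,
                                         strong = 1, outcome_var = 1e-2,
                                         seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(n_pretraining > n_omission, n_retraining >= 1, outcome_var >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (condition == "omission") {
    rate <- c(rep(weak, n_pretraining - n_omission), rep(0, n_omission),
              rep(strong, n_retraining))
    phase <- c(rep("pretraining", n_pretraining - n_omission),
               rep("omission", n_omission), rep("retraining", n_retraining))
  } else {
    rate <- c(rep(weak, n_pretraining), rep(strong, n_retraining))
    phase <- c(rep("pretraining", n_pretraining),
               rep("retraining", n_retraining))
  }
  o <- rate + stats::rnorm(length(rate), 0, sqrt(outcome_var))
  task_episode(o, rate, phase,
               meta = list(task = "conditioned_suppression",
                           condition = condition,
                           n_pretraining = n_pretraining,
                           n_omission = n_omission,
                           n_retraining = n_retraining, weak = weak,
                           strong = strong, outcome_var = outcome_var,
                           seed = seed))
}

#' Partial-reinforcement extinction episode
#'
#' Pretraining presents the cue with reward on every trial (full condition)
#' or on a random half of trials (partial condition), followed by extinction
#' (no reward). Tiny Gaussian noise (variance 1e-4) is added.
#'
#' @param condition `"partial"` or `"full"`.
#' @param n_pretraining Pretraining trials (default 100).
#' @param n_extinction Extinction trials (default 20).
#' @param reinforce_prob Fraction of rewarded pretraining trials in the
#'   partial condition (default 0.5; exactly that fraction of trials is
#'   rewarded, positions randomized).
#' @param outcome_var Outcome noise variance (default 1e-4).
#' @param seed Optional integer seed.
#' @return A [task_episode()] with phases `"pretraining"`, `"extinction"`.
#' @export
make_partial_reinforcement <- function(condition = c("partial", "full"),
                                       n_pretraining = 100, n_extinction = 20,
                                       reinforce_prob = 0.5,
                                       outcome_var = 1e-4, seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(n_pretraining >= 1, n_extinction >= 1, outcome_var >= 0,
            reinforce_prob > 0, reinforce_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (condition == "full") {
    pre <- rep(1, n_pretraining)
  } else {
    pre <- numeric(n_pretraining)
    pre[sample.int(n_pretraining, round(reinforce_prob * n_pretraining))] <- 1
  }
  rate <- c(pre, rep(0, n_extinction))
  phase <- c(rep("pretraining", n_pretraining),
             rep("extinction", n_extinction))
  o <- rate + stats::rnorm(length(rate), 0, sqrt(outcome_var))
  task_episode(o, rate, phase,
               meta = list(task = "partial_reinforcement",
                           condition = condition,
                           n_pretraining = n_pretraining,
                           n_extinction = n_extinction,
                           reinforce_prob = reinforce_prob,
                           outcome_var = outcome_var, seed = seed))
}

#' Serial-prediction (contingency shift) episode
#'
#' Two outcome channels conditioned on the light cue: tone-given-light and
#' reward-given-light. Phase 1 presents a consistent light-tone pairing with
#' reward on a random half of trials (tone on every trial). In the shift
#' condition, phase 2 changes the schedule to light-tone-reward on half of
#' trials and light-nothing (no tone, no reward) on the other half; in the
#' consistent condition phase 2 repeats the phase-1 schedule. Noise variance
#' is very small (1e-6).
#'
#' @param condition `"consistent"` or `"shift"`.
#' @param n_phase1,n_phase2 Trials per phase (defaults 100, 40; phase 2 is
#'   the shorter test phase).
#' @param outcome_var Outcome noise variance (default 1e-6).
#' @param seed Optional integer seed.
#' @return A [task_episode()] whose `outcomes` is an `n x 2` matrix with
#'   columns `tone`, `reward`; phases `"phase1"`, `"phase2"`.
#' @export
make_serial_prediction <- function(condition = c("consistent", "shift"),
                                   n_phase1 = 100, n_phase2 = 40,
                                   outcome_var = 1e-6, seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(n_phase1 >= 2, n_phase2 >= 2, outcome_var >= 0)
  if (!is.null(seed)) set.seed(seed)
  half1 <- sample.int(n_phase1, round(n_phase1 / 2))
  tone1 <- rep(1, n_phase1)
  rew1 <- numeric(n_phase1)
  rew1[half1] <- 1
  if (condition == "consistent") {
    half2 <- sample.int(n_phase2, round(n_phase2 / 2))
    tone2 <- rep(1, n_phase2)
    rew2 <- numeric(n_phase2)
    rew2[half2] <- 1
  } else {
    half2 <- sample.int(n_phase2, round(n_phase2 / 2))
    tone2 <- rew2 <- numeric(n_phase2)
    tone2[half2] <- 1
    rew2[half2] <- 1
  }
  tone <- c(tone1, tone2)
  rew <- c(rew1, rew2)
  n <- length(tone)
  o <- cbind(tone = tone + stats::rnorm(n, 0, sqrt(outcome_var)),
             reward = rew + stats::rnorm(n, 0, sqrt(outcome_var)))
  task_episode(o, cbind(tone = tone, reward = rew),
               phase = rep(c("phase1", "phase2"), c(n_phase1, n_phase2)),
               meta = list(task = "serial_prediction", condition = condition,
                           n_phase1 = n_phase1, n_phase2 = n_phase2,
                           outcome_var = outcome_var, seed = seed))
}

.REVERSAL_SCHEDULES <- list(deterministic_100_0 = c(1.0, 0.0),
                            stochastic_80_20 = c(0.8, 0.2),
                            stochastic_70_30 = c(0.7, 0.3),
                            stochastic_60_40 = c(0.6, 0.4))

#' Probabilistic reversal-learning episode
#'
#' Two options with reward probabilities fixed by the schedule; the
#' contingency reverses once at a trial drawn uniformly from the reversal
#' window. Potential outcomes for both options are Bernoulli draws plus a
#' tiny Gaussian noise.
#'
#' @param schedule One of `"deterministic_100_0"`, `"stochastic_80_20"`,
#'   `"stochastic_70_30"`, `"stochastic_60_40"`.
#' @param n_trials Total trials (default 80).
#' @param reversal_window Inclusive range the reversal trial is drawn from
#'   (default 30 to 50; the reversal trial is the first trial of the reversed
#'   contingency).
#' @param outcome_var Gaussian noise variance added to the binary rewards
#'   (default 1e-6).
#' @param seed Optional integer seed.
#' @return A [task_episode()] with an `n x 2` outcome matrix, phases
#'   `"acquisition"`/`"reversal"`, `correct_option`, and the reversal trial
#'   in `meta$reversal_trial`.
#' @export
make_reversal_task <- function(schedule = names(.REVERSAL_SCHEDULES),
                               n_trials = 80, reversal_window = c(30, 50),
                               outcome_var = 1e-6, seed = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(n_trials >= reversal_window[2], outcome_var >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- .REVERSAL_SCHEDULES[[schedule]]
  rev_trial <- sample(seq(reversal_window[1], reversal_window[2]), 1)
  pre <- rev_trial - 1L
  post <- n_trials - pre
  prob <- rbind(matrix(p, pre, 2, byrow = TRUE),
                matrix(rev(p), post, 2, byrow = TRUE))
  colnames(prob) <- c("option1", "option2")
  o <- matrix(stats::rbinom(2 * n_trials, 1, prob), n_trials, 2) +
    stats::rnorm(2 * n_trials, 0, sqrt(outcome_var))
  colnames(o) <- colnames(prob)
  task_episode(o, prob,
               phase = rep(c("acquisition", "reversal"), c(pre, post)),
               correct_option = ifelse(prob[, 1] >= prob[, 2], 1L, 2L),
               meta = list(task = "reversal", schedule = schedule,
                           probs = p, n_trials = n_trials,
                           reversal_trial = rev_trial,
                           outcome_var = outcome_var, seed = seed))
}

#' Change-point prediction episode
#'
#' The latent rate is piecewise constant: at each change point it is redrawn
#' uniformly in \[0, 10\]. Inter-change intervals are 5 trials plus an
#' exponential draw with rate 0.05 (mean 20), rounded up, so changes never
#' occur within 5 trials of the last. Outcomes are the rate plus Gaussian
#' noise of variance 1 (small) or 9 (large).
#'
#' @param noise_level `"small"` (variance 1) or `"large"` (variance 9).
#' @param n_trials Number of trials (default 200).
#' @param jump_range Range the rate is drawn from (default 0 to 10).
#' @param min_interval Minimum trials between change points (default 5).
#' @param hazard_rate Rate of the exponential inter-change distribution
#'   (default 0.05).
#' @param seed Optional integer seed.
#' @return A [task_episode()] with change-point trials in
#'   `meta$changepoints`.
#' @export
make_changepoint_task <- function(noise_level = c("small", "large"),
                                  n_trials = 200, jump_range = c(0, 10),
                                  min_interval = 5, hazard_rate = 0.05,
                                  seed = NULL) {
  noise_level <- match.arg(noise_level)
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  s_var <- if (noise_level == "small") 1 else 9
  rate <- numeric(n_trials)
  cps <- integer(0)
  t <- 1L
  while (t <= n_trials) {
    len <- min_interval + ceiling(stats::rexp(1, hazard_rate))
    r <- stats::runif(1, jump_range[1], jump_range[2])
    idx <- t:min(t + len - 1L, n_trials)
    rate[idx] <- r
    t <- t + len
    if (t <= n_trials) cps <- c(cps, t)
  }
  o <- rate + stats::rnorm(n_trials, 0, sqrt(s_var))
  task_episode(o, rate, phase = rep("changepoint", n_trials),
               meta = list(task = "changepoint", noise_level = noise_level,
                           outcome_var = s_var, n_trials = n_trials,
                           jump_range = jump_range,
                           min_interval = min_interval,
                           hazard_rate = hazard_rate, changepoints = cps,
                           seed = seed))
}

#' Two-choice probabilistic switching episode
#'
#' Two options with complementary reward probabilities `(p_high, 1 - p_high)`
#' that swap between options every `block_length` trials. Potential outcomes
#' are Bernoulli draws per option plus Gaussian noise of variance 0.01.
#'
#' @param p_high Reward probability of the better option (default 0.75).
#' @param block_length Trials between contingency switches (default 20).
#' @param n_trials Total trials (default 160).
#' @param outcome_var Gaussian noise variance (default 0.01).
#' @param stable_blocks Optional integer: this many *initial* blocks keep the
#'   same contingency (a stable run) before switching begins each
#'   `block_length`; default 0 (switch every block).
#' @param seed Optional integer seed.
#' @return A [task_episode()] with an `n x 2` outcome matrix and
#'   `correct_option`.
#' @export
make_two_choice_task <- function(p_high = 0.75, block_length = 20,
                                 n_trials = 160, outcome_var = 0.01,
                                 stable_blocks = 0, seed = NULL) {
  stopifnot(p_high >= 0, p_high <= 1, block_length >= 1, n_trials >= 1,
            outcome_var >= 0, stable_blocks >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(n_trials / block_length)
  # block b uses orientation 1 (option1 better) or 2, swapping each block
  # after the initial stable run
  orient <- integer(n_blocks)
  cur <- 1L
  for (b in seq_len(n_blocks)) {
    orient[b] <- cur
    if (b > stable_blocks) cur <- 3L - cur
  }
  p1 <- rep(ifelse(orient == 1L, p_high, 1 - p_high),
            each = block_length)[seq_len(n_trials)]
  prob <- cbind(option1 = p1, option2 = 1 - p1)
  o <- matrix(stats::rbinom(2 * n_trials, 1, prob), n_trials, 2) +
    stats::rnorm(2 * n_trials, 0, sqrt(outcome_var))
  colnames(o) <- colnames(prob)
  phase <- rep("switching", n_trials)
  task_episode(o, prob, phase,
               correct_option = ifelse(p1 >= 0.5, 1L, 2L),
               meta = list(task = "two_choice", p_high = p_high,
                           block_length = block_length, n_trials = n_trials,
                           outcome_var = outcome_var,
                           stable_blocks = stable_blocks, seed = seed))
}
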