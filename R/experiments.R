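# Experiment runner: model x task x replication sweeps for each simulated
# study, returning tidy per-replication summary tables.

# deterministic per-replication seed rule (stable across runs, < 2^31)
derive_seed <- function(seed, i) {
  s <- (as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483563
  as.integer(s) + 1L
}

.new_rows <- function(sim, group, condition, statistic, value, seed) {
  data.frame(sim = sim, group = group, condition = condition,
             statistic = statistic, value = value, seed = seed,
             stringsAsFactors = FALSE)
}

# ---- per-figure simulation functions --------------------------------------

.exp_fig1 <- function(cfg) {
  conds <- expand.grid(v = c(0.5, 1.5), s = c(1, 3))
  rows <- vector("list", nrow(conds) * cfg$n_sims)
  k <- 0L
  for (ci in seq_len(nrow(conds))) {
    for (i in seq_len(cfg$n_sims)) {
      sd_i <- derive_seed(cfg$seed, ci * 1000000L + i)
      ep <- make_constant_2x2(conds$v[ci], conds$s[ci],
                              n_trials = cfg$n_trials, seed = sd_i)
      lbl <- sprintf("v=%g,s=%g", conds$v[ci], conds$s[ci])
      k <- k + 1L
      rows[[k]] <- .new_rows(i, "generative", lbl,
                             c("outcome_variance", "lag1_autocorr"),
                             c(stats::var(ep$outcomes),
                               lag1_autocorrelation(ep$outcomes)), sd_i)
    }
  }
  do.call(rbind, rows)
}

# shared 2x2 recovery sweep; `groups` is a named list of model_params
.exp_2x2 <- function(cfg, groups) {
  conds <- expand.grid(v = c(0.5, 1.5), s = c(1, 3))
  win <- (cfg$n_trials - 19):cfg$n_trials
  rows <- vector("list", nrow(conds) * cfg$n_sims * length(groups))
  k <- 0L
  for (ci in seq_len(nrow(conds))) {
    for (i in seq_len(cfg$n_sims)) {
      sd_ep <- derive_seed(cfg$seed, ci * 1000000L + i)
      ep <- make_constant_2x2(conds$v[ci], conds$s[ci],
                              n_trials = cfg$n_trials, seed = sd_ep)
      lbl <- sprintf("v=%g,s=%g", conds$v[ci], conds$s[ci])
      for (g in seq_along(groups)) {
        tr <- run_filter(ep$outcomes, groups[[g]],
                         seed = derive_seed(sd_ep, g))
        k <- k + 1L
        rows[[k]] <- .new_rows(i, names(groups)[g], lbl,
                               c("alpha", "v_hat", "s_hat"),
                               c(summarize_window(tr, "alpha", win),
                                 summarize_window(tr, "v_hat", win),
                                 summarize_window(tr, "s_hat", win)), sd_ep)
      }
    }
  }
  do.call(rbind, rows)
}

.fig2_params <- function(cfg, lesion = "none", lesion_value = NULL) {
  model_params(lambda_v = 0.1, lambda_s = 0.1, v0 = 1, s0 = 2,
               n_particles = cfg$n_particles, prior_mean = 0, prior_var = 100,
               lesion = lesion, lesion_value = lesion_value)
}

.exp_fig2 <- function(cfg) {
  .exp_2x2(cfg, list(healthy = .fig2_params(cfg)))
}

.exp_fig3 <- function(cfg) {
  .exp_2x2(cfg, list(healthy = .fig2_params(cfg),
                     fix_stochasticity = .fig2_params(cfg, "fix_stochasticity"),
                     fix_volatility = .fig2_params(cfg, "fix_volatility")))
}

.exp_fig4 <- function(cfg) {
  mp <- model_params(lambda_v = 0.2, lambda_s = 0.2, v0 = 0.1, s0 = 0.1,
                     n_particles = cfg$n_particles, prior_mean = 0,
                     prior_var = 1)
  tasks <- list(
    omission = function(sd) make_conditioned_suppression("omission", seed = sd),
    control = function(sd) make_conditioned_suppression("control", seed = sd),
    partial = function(sd) make_partial_reinforcement("partial", seed = sd),
    full = function(sd) make_partial_reinforcement("full", seed = sd))
  rows <- vector("list", length(tasks) * cfg$n_sims)
  k <- 0L
  for (ci in seq_along(tasks)) {
    for (i in seq_len(cfg$n_sims)) {
      sd_ep <- derive_seed(cfg$seed, ci * 1000000L + i)
      ep <- tasks[[ci]](sd_ep)
      tr <- run_filter(ep$outcomes, mp, seed = derive_seed(sd_ep, 1))
      probe <- which(ep$phase %in% c("retraining", "extinction"))[1]
      grp <- if (ci <= 2) "suppression" else "reinforcement"
      k <- k + 1L
      rows[[k]] <- .new_rows(i, grp, names(tasks)[ci],
                             c("alpha_first_retraining",
                               "v_hat_end_pretraining",
                               "s_hat_end_pretraining"),
                             c(tr$alpha[probe], tr$v_hat[probe - 1],
                               tr$s_hat[probe - 1]), sd_ep)
    }
  }
  do.call(rbind, rows)
}

.exp_fig5 <- function(cfg) {
  base <- list(lambda_v = 0.2, lambda_s = 0.2, v0 = 0.1, s0 = 0.1,
               n_particles = cfg$n_particles, prior_mean = 0, prior_var = 1)
  control <- do.call(model_params, base)
  anx_switch <- do.call(model_params, c(base, list(
    lesion = "fix_stochasticity", lesion_value = 0.001)))
  anx_choice <- do.call(model_params, c(base, list(
    lesion = "fix_stochasticity", lesion_value = 0.05)))
  beta <- 3
  rows <- vector("list", 4L * cfg$n_sims)
  k <- 0L
  for (i in seq_len(cfg$n_sims)) {
    # part 1: single-cue switching task, relative (volatile - stable) log
    # learning rate by block label
    sd_ep <- derive_seed(cfg$seed, 1000000L + i)
    ep <- make_switching_task(seed = sd_ep)
    for (g in c("control", "anxious")) {
      mp <- if (g == "control") control else anx_switch
      tr <- run_filter(ep$outcomes, mp,
                       seed = derive_seed(sd_ep, match(g, c("control", "anxious"))))
      k <- k + 1L
      rows[[k]] <- .new_rows(i, g, "switching",
                             c("rel_log_lr", "mean_alpha"),
                             c(relative_log_learning_rate(tr, ep$phase),
                               mean(tr$alpha)), sd_ep)
    }
    # part 2: two-choice probabilistic task with an initial stable run, then
    # contingency switches; win-stay/lose-shift and accuracy by stability
    sd_ep <- derive_seed(cfg$seed, 2000000L + i)
    ep <- make_two_choice_task(stable_blocks = 4, seed = sd_ep)
    stab <- label_stability(ep$rate_true[, 1], window = 10)
    for (g in c("control", "anxious")) {
      mp <- if (g == "control") control else anx_choice
      ch <- run_choice_episode(ep, mp, beta = beta,
                               seed = derive_seed(sd_ep, match(g, c("control", "anxious"))))
      wsls <- win_stay_lose_shift(ch$choices, ch$rewards)
      acc <- ch$choices == ep$correct_option
      k <- k + 1L
      rows[[k]] <- .new_rows(i, g, "two_choice",
                             c("win_stay", "lose_shift", "mean_alpha",
                               "accuracy_stable", "accuracy_volatile"),
                             c(wsls$win_stay, wsls$lose_shift, mean(ch$alpha),
                               mean(acc[stab == "stable"]),
                               mean(acc[stab == "volatile"])), sd_ep)
    }
  }
  do.call(rbind, rows)
}

.exp_fig6 <- function(cfg) {
  spec <- cohort_spec(n_sets = cfg$n_sims)
  res <- run_anxiety_cohort(spec, seed = cfg$seed,
                            n_particles = cfg$n_particles)
  .new_rows(res$per_set$set, "cohort", "switching", "spearman",
            res$per_set$spearman, cfg$seed)
}

.exp_fig7 <- function(cfg) {
  base <- list(lambda_v = 0.2, lambda_s = 0.2, v0 = 0.5, s0 = 0.5,
               n_particles = cfg$n_particles, prior_mean = 0, prior_var = 1)
  groups <- list(control = do.call(model_params, base),
                 lesioned = do.call(model_params, c(base, list(
                   lesion = "fix_volatility", lesion_value = 0.25e-6))))
  rows <- vector("list", 4L * cfg$n_sims)
  k <- 0L
  for (ci in seq_along(c("consistent", "shift"))) {
    cond <- c("consistent", "shift")[ci]
    for (i in seq_len(cfg$n_sims)) {
      sd_ep <- derive_seed(cfg$seed, ci * 1000000L + i)
      ep <- make_serial_prediction(cond, seed = sd_ep)
      probe <- if (is.null(cfg$probe_trial)) length(ep) else cfg$probe_trial
      for (g in seq_along(groups)) {
        # first cue (tone channel) carries the probe statistics; the reward
        # channel runs an independent filter sharing no state
        tr_tone <- run_filter(ep$outcomes[, "tone"], groups[[g]],
                              seed = derive_seed(sd_ep, 2L * g))
        tr_rew <- run_filter(ep$outcomes[, "reward"], groups[[g]],
                             seed = derive_seed(sd_ep, 2L * g + 1L))
        k <- k + 1L
        rows[[k]] <- .new_rows(i, names(groups)[g], cond,
                               c("alpha_probe", "v_hat_probe", "s_hat_probe",
                                 "alpha_probe_reward"),
                               c(tr_tone$alpha[probe], tr_tone$v_hat[probe],
                                 tr_tone$s_hat[probe], tr_rew$alpha[probe]),
                               sd_ep)
      }
    }
  }
  do.call(rbind, rows)
}

.exp_fig8 <- function(cfg) {
  base <- list(lambda_v = 0.2, lambda_s = 0.2, v0 = 0.5, s0 = 0.5,
               n_particles = cfg$n_particles, prior_mean = 0, prior_var = 1)
  groups <- list(
    control = list(mp = do.call(model_params, base), beta = 3),
    lesioned = list(mp = do.call(model_params, c(base, list(
      lesion = "fix_volatility", lesion_value = 0.01))), beta = 1))
  schedules <- c("deterministic_100_0", "stochastic_60_40")
  rows <- vector("list", 4L * cfg$n_sims)
  k <- 0L
  for (ci in seq_along(schedules)) {
    for (i in seq_len(cfg$n_sims)) {
      sd_ep <- derive_seed(cfg$seed, ci * 1000000L + i)
      ep <- make_reversal_task(schedules[ci], seed = sd_ep)
      for (g in seq_along(groups)) {
        ch <- run_choice_episode(ep, groups[[g]]$mp, beta = groups[[g]]$beta,
                                 seed = derive_seed(sd_ep, g))
        acc <- ch$choices == ep$correct_option
        k <- k + 1L
        rows[[k]] <- .new_rows(i, names(groups)[g], schedules[ci],
                               c("accuracy_acquisition", "accuracy_reversal"),
                               c(mean(acc[ep$phase == "acquisition"]),
                                 mean(acc[ep$phase == "reversal"])), sd_ep)
      }
    }
  }
  do.call(rbind, rows)
}

.exp_supp_changepoint <- function(cfg) {
  mp <- model_params(lambda_v = 0.4, lambda_s = 0.2, v0 = 5, s0 = 5,
                     n_particles = cfg$n_particles, prior_mean = 0,
                     prior_var = 100)
  rows <- vector("list", 2L * cfg$n_sims)
  k <- 0L
  for (ci in seq_along(c("small", "large"))) {
    lvl <- c("small", "large")[ci]
    for (i in seq_len(cfg$n_sims)) {
      sd_ep <- derive_seed(cfg$seed, ci * 1000000L + i)
      ep <- make_changepoint_task(lvl, n_trials = cfg$n_trials, seed = sd_ep)
      tr <- run_filter(ep$outcomes, mp, seed = derive_seed(sd_ep, 1))
      k <- k + 1L
      rows[[k]] <- .new_rows(i, "healthy", lvl,
                             c("mean_alpha", "mean_s_hat", "mean_abs_error"),
                             c(mean(tr$alpha), mean(tr$s_hat),
                               mean(abs(tr$m - ep$rate_true))), sd_ep)
    }
  }
  do.call(rbind, rows)
}

.EXPERIMENTS <- list(
  fig1 = list(fn = .exp_fig1, n_sims = 1000, full = 10000, n_trials = 200),
  fig2 = list(fn = .exp_fig2, n_sims = 200, full = 10000, n_trials = 200),
  fig3 = list(fn = .exp_fig3, n_sims = 200, full = 10000, n_trials = 200),
  fig4 = list(fn = .exp_fig4, n_sims = 1000, full = 40000, n_trials = NA),
  fig5 = list(fn = .exp_fig5, n_sims = 200, full = 1000, n_trials = NA),
  fig6 = list(fn = .exp_fig6, n_sims = 50, full = 1000, n_trials = NA),
  fig7 = list(fn = .exp_fig7, n_sims = 200, full = 40000, n_trials = NA),
  fig8 = list(fn = .exp_fig8, n_sims = 200, full = 1000, n_trials = NA),
  supp_changepoint = list(fn = .exp_supp_changepoint, n_sims = 200,
                          full = 1000, n_trials = 200))

#' List available experiments
#'
#' @return Character vector of registry keys accepted by
#'   [experiment_config()].
#' @export
list_experiments <- function() names(.EXPERIMENTS)

#' Build and validate an experiment configuration
#'
#' @param experiment Registry key; one of [list_experiments()].
#' @param n_sims Replications (default: a scaled-down per-experiment count;
#'   `full = TRUE` restores the study's original replication count).
#' @param n_particles Particles per filter (default 100).
#' @param seed Master seed; per-replication seeds are derived from it by a
#'   fixed documented rule.
#' @param full Use the full replication count.
#' @param n_trials Series length for the constant-parameter and change-point
#'   designs (default 200).
#' @param probe_trial Probe trial index for the serial-prediction experiment
#'   (default: last trial of phase 2).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, n_sims = NULL, n_particles = 100,
                              seed = 1, full = FALSE, n_trials = NULL,
                              probe_trial = NULL) {
  if (!experiment %in% names(.EXPERIMENTS)) {
    stop("unknown experiment '", experiment, "'; available: ",
         paste(names(.EXPERIMENTS), collapse = ", "))
  }
  entry <- .EXPERIMENTS[[experiment]]
  if (is.null(n_sims)) n_sims <- if (full) entry$full else entry$n_sims
  if (is.null(n_trials)) n_trials <- entry$n_trials
  stopifnot(n_sims >= 1, n_particles >= 1)
  structure(list(experiment = experiment, n_sims = as.integer(n_sims),
                 n_particles = as.integer(n_particles),
                 seed = as.integer(seed), full = isTRUE(full),
                 n_trials = n_trials, probe_trial = probe_trial),
            class = "experiment_config")
}

#' Run a registered simulated experiment
#'
#' Generates the task episodes, runs the configured learner(s) on each
#' replication and computes the experiment's summary statistics.
#' Deterministic given the configuration: per-replication seeds are derived
#' from `config$seed`.
#'
#' @param config An [experiment_config()] object, or a registry key (passed
#'   to [experiment_config()] with defaults).
#' @param ... Passed to [experiment_config()] when `config` is a key.
#' @return An object of class `experiment_result`: list with `result` (tidy
#'   data frame: sim, group, condition, statistic, value, seed) and `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_experiment(experiment_config("fig2", n_sims = 10, seed = 1))
#' aggregate_result(res)
#' }
run_experiment <- function(config, ...) {
  if (is.character(config)) config <- experiment_config(config, ...)
  stopifnot(inherits(config, "experiment_config"))
  res <- .EXPERIMENTS[[config$experiment]]$fn(config)
  rownames(res) <- NULL
  structure(list(result = res, config = unclass(config)),
            class = "experiment_result")
}

#' Run a choice-coupled experiment
#'
#' Thin wrapper over [run_experiment()] that insists the experiment couples
#' the learner to choices through a softmax (the two-choice anxiety task and
#' the probabilistic reversal task).
#'
#' @param config An [experiment_config()] for `"fig5"` or `"fig8"`, or the
#'   key itself.
#' @param ... Passed to [experiment_config()] when `config` is a key.
#' @return An `experiment_result`.
#' @export
run_choice_experiment <- function(config, ...) {
  if (is.character(config)) config <- experiment_config(config, ...)
  if (!config$experiment %in% c("fig5", "fig8")) {
    stop("not a choice experiment: ", config$experiment)
  }
  run_experiment(config)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", x$config$experiment,
      sprintf("(%d sims, %d particles, seed %d)\n",
              x$config$n_sims, x$config$n_particles, x$config$seed))
  print(utils::head(aggregate_result(x), 20))
  invisible(x)
}

#' One closed-loop choice replication
#'
#' Runs one independent particle filter per option. On each trial the
#' weighted posterior means are mapped to choice probabilities by a softmax
#' with decision noise `beta`; the chosen option's observed outcome updates
#' that option's filter, while unchosen options receive a prediction-only
#' update (their noise samples diffuse and Kalman variance grows by the
#' sampled volatility; the mean is unchanged). RNG order per trial: choice
#' draw, then each option's filter in option order.
#'
#' @param episode A choice [task_episode()] (matrix outcomes).
#' @param params A [model_params()] object (shared by all options).
#' @param beta Softmax decision-noise parameter.
#' @param seed Optional integer seed.
#' @return List with per-trial `choices`, `rewards` (observed outcome of the
#'   chosen option), `alpha` (chosen option's learning rate), `p_choice`,
#'   and `values` (matrix of pre-choice posterior means).
#' @export
run_choice_episode <- function(episode, params, beta, seed = NULL) {
  stopifnot(inherits(episode, "task_episode"), is.matrix(episode$outcomes))
  if (!is.null(seed)) set.seed(seed)
  n <- length(episode)
  K <- ncol(episode$outcomes)
  states <- vector("list", K)
  for (k in seq_len(K)) {
    p0 <- init_particles(params)
    states[[k]] <- list(z = p0$z, y = p0$y, m = p0$m, w = p0$w, b = p0$weight)
  }
  choices <- integer(n)
  rewards <- alpha <- p_choice <- numeric(n)
  values <- matrix(NA_real_, n, K)
  for (t in seq_len(n)) {
    vals <- vapply(states, function(s) sum(s$b * s$m), numeric(1))
    values[t, ] <- vals
    p <- softmax_probs(vals, beta)
    ch <- sample.int(K, 1, prob = p)
    o <- episode$outcomes[t, ch]
    for (k in seq_len(K)) {
      res <- .rbpf_trial(states[[k]], if (k == ch) o else NA_real_, params)
      states[[k]] <- res$st
      if (k == ch) alpha[t] <- res$rec[3]
    }
    choices[t] <- ch
    rewards[t] <- o
    p_choice[t] <- p[ch]
  }
  list(choices = choices, rewards = rewards, alpha = alpha,
       p_choice = p_choice, values = values)
}

#' Synthetic trait-anxiety cohort specification
#'
#' Each set contains `subjects_per_set` synthetic subjects split evenly into
#' subsets whose model trait anxiety (the ratio `lambda_v / lambda_s`) is
#' centred on `trait_means`, truncated to `trait_bounds`. Each subject's
#' volatility update rate is drawn uniformly from `lambda_v_range` and the
#' stochasticity update rate follows from the trait ratio.
#'
#' @param n_sets Number of simulation sets (default 1000).
#' @param subjects_per_set Subjects per set (default 30, in 3 subsets of 10).
#' @param trait_means Subset means of trait anxiety (default 0.5, 1, 3).
#' @param trait_bounds Global bounds on trait anxiety (default 0.26, 4).
#' @param lambda_v_range Range of the volatility update rate (default 0-0.2).
#' @param v0,s0 Initial noise values for all subjects (default 0.001).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sets = 1000, subjects_per_set = 30,
                        trait_means = c(0.5, 1, 3),
                        trait_bounds = c(0.26, 4),
                        lambda_v_range = c(0, 0.2), v0 = 0.001, s0 = 0.001) {
  stopifnot(n_sets >= 1, subjects_per_set >= length(trait_means),
            subjects_per_set %% length(trait_means) == 0,
            trait_bounds[1] > 0, trait_bounds[2] > trait_bounds[1],
            all(trait_means > trait_bounds[1]),
            all(trait_means < trait_bounds[2]),
            lambda_v_range[1] >= 0, lambda_v_range[2] < 1, v0 > 0, s0 > 0)
  structure(list(n_sets = as.integer(n_sets),
                 subjects_per_set = as.integer(subjects_per_set),
                 trait_means = trait_means, trait_bounds = trait_bounds,
                 lambda_v_range = lambda_v_range, v0 = v0, s0 = s0),
            class = "cohort_spec")
}

# truncated uniform around a subset mean: half-width chosen as the largest
# value <= mu/2 that keeps the interval inside the bounds, so the subset mean
# is honoured exactly
.draw_trait <- function(n, mu, bounds) {
  h <- min(mu - bounds[1], bounds[2] - mu, mu / 2)
  stats::runif(n, mu - h, mu + h)
}

#' Synthesize and run a trait-anxiety cohort
#'
#' For each set, synthesizes subjects differing only in their update rates
#' (`lambda_v ~ U(range)`, `lambda_s = lambda_v / trait`), runs each on the
#' stable/volatile switching task, computes the relative log learning rate
#' (volatile minus stable), and correlates it with trait anxiety (Spearman)
#' within the set.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed.
#' @param n_particles Particles per filter (default 100).
#' @param task_args Extra arguments to [make_switching_task()].
#' @return List with `per_set` (data frame: set, spearman), `subjects`
#'   (pooled per-subject table), and `median_spearman`.
#' @export
run_anxiety_cohort <- function(spec, seed = 1, n_particles = 100,
                               task_args = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_sub <- spec$subjects_per_set
  per_subset <- n_sub / length(spec$trait_means)
  per_set <- data.frame(set = seq_len(spec$n_sets), spearman = NA_real_)
  subjects <- vector("list", spec$n_sets)
  for (st in seq_len(spec$n_sets)) {
    set.seed(derive_seed(seed, st))
    trait <- unlist(lapply(spec$trait_means, function(mu) {
      .draw_trait(per_subset, mu, spec$trait_bounds)
    }))
    lambda_v <- stats::runif(n_sub, spec$lambda_v_range[1],
                             spec$lambda_v_range[2])
    lambda_s <- lambda_v / trait
    rel <- numeric(n_sub)
    for (j in seq_len(n_sub)) {
      sd_j <- derive_seed(seed, st * 1000L + j)
      ep <- do.call(make_switching_task, c(task_args, list(seed = sd_j)))
      mp <- model_params(lambda_v = lambda_v[j], lambda_s = lambda_s[j],
                         v0 = spec$v0, s0 = spec$s0,
                         n_particles = n_particles, prior_mean = 0,
                         prior_var = 1)
      tr <- run_filter(ep$outcomes, mp, seed = derive_seed(sd_j, 1))
      rel[j] <- relative_log_learning_rate(tr, ep$phase)
    }
    if (stats::sd(trait) == 0 || stats::sd(rel) == 0) {
      warning("zero variance in set ", st, ": correlation undefined")
    } else {
      per_set$spearman[st] <- stats::cor(trait, rel, method = "spearman")
    }
    subjects[[st]] <- data.frame(set = st, subject = seq_len(n_sub),
                                 trait = trait, lambda_v = lambda_v,
                                 lambda_s = lambda_s, rel_log_lr = rel)
  }
  list(per_set = per_set, subjects = do.call(rbind, subjects),
       median_spearman = stats::median(per_set$spearman, na.rm = TRUE))
}

#' Aggregate an experiment result into group x condition summaries
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @param statistic Central tendency: `"mean"` or `"median"`.
#' @param error Dispersion: `"sem"` (sd / sqrt(n)) or `"sem_median"`
#'   (bootstrap standard error of the median).
#' @param n_boot Bootstrap resamples for `"sem_median"` (default 1000).
#' @param boot_seed Seed for the bootstrap (default 1).
#' @return Data frame with one row per (group, condition, statistic): `n`,
#'   `value`, `error`. With a single replication the dispersion is `NA`.
#' @export
aggregate_result <- function(result, statistic = c("mean", "median"),
                             error = c("sem", "sem_median"), n_boot = 1000,
                             boot_seed = 1) {
  statistic <- match.arg(statistic)
  error <- match.arg(error)
  df <- if (inherits(result, "experiment_result")) result$result else result
  stopifnot(nrow(df) > 0)
  key <- interaction(df$group, df$condition, df$statistic, drop = TRUE)
  groups <- split(df, key)
  out <- lapply(groups, function(g) {
    x <- g$value[is.finite(g$value)]
    n <- length(x)
    center <- if (statistic == "mean") mean(x) else stats::median(x)
    disp <- if (n < 2) {
      NA_real_
    } else if (error == "sem") {
      stats::sd(x) / sqrt(n)
    } else {
      set.seed(boot_seed)
      meds <- vapply(seq_len(n_boot), function(i) {
        stats::median(sample(x, n, replace = TRUE))
      }, numeric(1))
      stats::sd(meds)
    }
    data.frame(group = g$group[1], condition = g$condition[1],
               statistic = g$statistic[1], n = n, value = center,
               error = disp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$group, out$condition, out$statistic), , drop = FALSE]
}
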