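test_that("the registry validates keys and resolves replication defaults", {
  expect_error(run_experiment("nope"), "available")
  expect_error(experiment_config("fig99"), "fig1")
  cfg <- experiment_config("fig2")
  expect_equal(cfg$n_sims, 200L)
  expect_equal(experiment_config("fig2", full = TRUE)$n_sims, 10000L)
  expect_equal(experiment_config("fig2", n_sims = 7)$n_sims, 7L)
  expect_setequal(list_experiments(),
                  c("fig1", "fig2", "fig3", "fig4", "fig5", "fig6", "fig7",
                    "fig8", "supp_changepoint"))
})

test_that("experiment results are tidy, traceable and exactly reproducible", {
  cfg <- experiment_config("fig2", n_sims = 5, n_particles = 30, seed = 3)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$result, r2$result)
  df <- r1$result
  expect_named(df, c("sim", "group", "condition", "statistic", "value",
                     "seed"))
  # 5 sims x 4 conditions x 3 statistics
  expect_equal(nrow(df), 60)
  expect_true(all(is.finite(df$value)))
  expect_true(all(df$seed > 0))
  r3 <- run_experiment(experiment_config("fig2", n_sims = 5,
                                         n_particles = 30, seed = 4))
  expect_false(identical(r1$result$value, r3$result$value))
})

test_that("aggregation computes the named center and dispersion", {
  res <- structure(list(result = data.frame(
    sim = 1:3, group = "g", condition = "c", statistic = "x",
    value = c(1, 2, 3), seed = 1L)), class = "experiment_result")
  agg <- aggregate_result(res)
  expect_equal(agg$value, 2)
  expect_equal(agg$error, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(aggregate_result(res, statistic = "median")$value, 2)
  # single replication: dispersion undefined
  one <- structure(list(result = res$result[1, ]),
                   class = "experiment_result")
  expect_true(is.na(aggregate_result(one)$error))
  expect_equal(aggregate_result(one)$value, 1)
  # bootstrap standard error of the median vs an independently coded
  # resampler under the same seed
  x <- c(rexp(20, 1), 5, 9)
  res2 <- structure(list(result = data.frame(
    sim = seq_along(x), group = "g", condition = "c", statistic = "x",
    value = x, seed = 1L)), class = "experiment_result")
  got <- aggregate_result(res2, statistic = "median", error = "sem_median",
                          n_boot = 500, boot_seed = 11)$error
  set.seed(11)
  meds <- numeric(500)
  for (i in 1:500) meds[i] <- median(x[sample.int(22, 22, replace = TRUE)])
  expect_equal(got, sd(meds))
})

test_that("choice episodes couple values to outcomes through the softmax", {
  ep <- make_two_choice_task(seed = 5)
  mp <- model_params(lambda_v = 0.2, lambda_s = 0.2, v0 = 0.5, s0 = 0.5,
                     n_particles = 30, prior_var = 1)
  ch <- run_choice_episode(ep, mp, beta = 3, seed = 6)
  expect_true(all(ch$choices %in% 1:2))
  expect_equal(ch$rewards,
               ep$outcomes[cbind(seq_len(160), ch$choices)])
  expect_true(all(ch$p_choice > 0 & ch$p_choice < 1))
  expect_true(all(ch$alpha > 0 & ch$alpha < 1))
  # beta = 0: choices split roughly evenly regardless of value
  ch0 <- run_choice_episode(ep, mp, beta = 0, seed = 7)
  expect_gt(mean(ch0$choices == 1), 0.35)
  expect_lt(mean(ch0$choices == 1), 0.65)
  # determinism
  expect_identical(ch$choices,
                   run_choice_episode(ep, mp, beta = 3, seed = 6)$choices)
  expect_error(run_choice_experiment("fig2"), "not a choice experiment")
})

test_that("cohort synthesis honors trait bounds, subset means and the ratio rule", {
  spec <- cohort_spec(n_sets = 2, subjects_per_set = 6)
  res <- run_anxiety_cohort(spec, seed = 9, n_particles = 20,
                            task_args = list(block_length = 30,
                                             switch_every = 10))
  subj <- res$subjects
  expect_equal(nrow(subj), 12)
  expect_true(all(subj$trait > 0.26 & subj$trait < 4))
  expect_equal(subj$lambda_s, subj$lambda_v / subj$trait)
  expect_true(all(subj$lambda_v >= 0 & subj$lambda_v <= 0.2))
  expect_equal(nrow(res$per_set), 2)
  expect_true(all(abs(res$per_set$spearman) <= 1, na.rm = TRUE))
  # reproducible
  res2 <- run_anxiety_cohort(spec, seed = 9, n_particles = 20,
                             task_args = list(block_length = 30,
                                              switch_every = 10))
  expect_identical(res$per_set, res2$per_set)
  expect_error(cohort_spec(subjects_per_set = 7), "subjects_per_set")
})
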