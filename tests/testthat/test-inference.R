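test_that("kalman_step reproduces the closed-form update and its limits", {
  st <- kalman_step(m = 0, w = 1, v = 1, s = 2, o = 4)
  expect_equal(st$alpha, 0.5)
  expect_equal(st$delta, 4)
  expect_equal(st$m, 2)
  expect_equal(st$w, 1)
  # noiseless observation: full update
  st <- kalman_step(m = 1, w = 0.3, v = 0.2, s = 0, o = 7)
  expect_equal(st$alpha, 1)
  expect_equal(st$m, 7)
  expect_equal(st$w, 0)
  # perfectly known static value: no update
  st <- kalman_step(m = 1, w = 0, v = 0, s = 2, o = 7)
  expect_equal(st$alpha, 0)
  expect_equal(st$m, 1)
  expect_equal(st$w, 0)
  expect_error(kalman_step(0, 0, 0, 0, 1), "degenerate")
  expect_error(kalman_step(0, -1, 1, 1, 1), "nonnegative")
})

test_that("kalman gain is bounded, monotone in the noise variances, and contracts w", {
  grid <- expand.grid(w = c(0.01, 0.5, 2), v = c(0.05, 0.5, 3),
                      s = c(0.05, 1, 4))
  eps <- 1e-6
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    st <- kalman_step(0, g$w, g$v, g$s, 1)
    expect_true(st$alpha > 0 && st$alpha < 1)
    # w_next identity and contraction
    expect_equal(st$w, (1 - st$alpha) * (g$w + g$v))
    expect_lt(st$w, g$s)
    expect_lt(st$w, g$w + g$v)
    # numerical partials: gain rises with v, falls with s
    expect_gt(kalman_step(0, g$w, g$v + eps, g$s, 1)$alpha, st$alpha)
    expect_lt(kalman_step(0, g$w, g$v, g$s + eps, 1)$alpha, st$alpha)
  }
})

test_that("closed-form filter converges on constant outcomes", {
  kf <- kalman_filter(rep(3, 200), v = 0.1, s = 1, prior_mean = 0,
                      prior_var = 100)
  expect_true(all(diff(kf$alpha) <= 1e-12))
  expect_lt(abs(kf$m[200] - 3), 0.01)
})

test_that("effective sample size follows 1/sum(w^2)", {
  expect_equal(effective_sample_size(rep(0.01, 100)), 100)
  expect_equal(effective_sample_size(c(1, rep(0, 9))), 1)
  expect_equal(effective_sample_size(c(0.5, 0.25, 0.25)), 8 / 3)
  expect_error(effective_sample_size(c(0.5, 0.2)), "normalized")
})

test_that("systematic resampling keeps offspring counts within one of expectation", {
  mk <- function(w) particles(z = seq_along(w), y = seq_along(w),
                              m = seq_along(w), w = rep(1, length(w)),
                              weight = w)
  # uniform weights: every particle exactly once, for any offset
  N <- 8
  for (u in c(0, 0.01, 0.124)) {
    out <- systematic_resample(mk(rep(1 / N, N)), u = u)
    expect_equal(sort(out$z), 1:N)
    expect_equal(out$weight, rep(1 / N, N))
  }
  # (0.5, 0.5) with N = 2: one copy of each for every offset
  for (u in seq(0, 0.499, by = 0.027)) {
    out <- systematic_resample(mk(c(0.5, 0.5)), u = u)
    expect_equal(sort(out$z), 1:2)
  }
  # all weight on one particle: N copies
  out <- systematic_resample(mk(c(0, 1, 0, 0)), u = 0.1)
  expect_true(all(out$z == 2))
  # random weights: |count_i - N w_i| < 1
  set.seed(51)
  for (rep in 1:20) {
    w <- rgamma(30, 1)
    w <- w / sum(w)
    out <- systematic_resample(mk(w), u = runif(1, 0, 1 / 30))
    counts <- tabulate(out$z, nbins = 30)
    expect_true(all(abs(counts - 30 * w) < 1))
  }
})

test_that("particle weighting follows the Gaussian predictive density", {
  # single particle: normalization forces weight 1
  p1 <- particles(z = 1, y = 1, m = 0, w = 1)
  expect_equal(weight_particles(p1, 0.3)$weight, 1)
  # identical particles: symmetry
  p2 <- particles(z = c(2, 2), y = c(2, 2), m = c(1, 1), w = c(0.5, 0.5))
  expect_equal(weight_particles(p2, 0)$weight, c(0.5, 0.5))
  # frozen likelihood-ratio check: particles at m = 0 and m = 3, both with
  # predictive variance w + 1/z + 1/y = 1, outcome 0; ratio = exp(-9/2)
  p3 <- particles(z = c(4, 4), y = c(4, 4), m = c(0, 3), w = c(0.5, 0.5))
  wts <- weight_particles(p3, 0)$weight
  expect_equal(wts[2] / wts[1], exp(-4.5), tolerance = 1e-12)
  # total underflow falls back to uniform with a warning
  p4 <- particles(z = c(1e6, 1e6), y = c(1e6, 1e6), m = c(0, 0),
                  w = c(1e-8, 1e-8))
  expect_warning(w4 <- weight_particles(p4, 1e200), "underflow")
  expect_equal(w4$weight, c(0.5, 0.5))
})

test_that("prediction step preserves the mean of z and respects lesions and zero rates", {
  mp0 <- model_params(lambda_v = 0, lambda_s = 0, v0 = 1, s0 = 2,
                      n_particles = 5)
  ens <- init_particles(mp0)
  expect_identical(predict_particles(ens, mp0), ens) # zero update rates
  # lesioned variable untouched at 1/lesion_value
  mpl <- model_params(lambda_v = 0.3, lambda_s = 0.3, v0 = 1, s0 = 2,
                      n_particles = 50, lesion = "fix_stochasticity",
                      lesion_value = 0.4)
  ensl <- init_particles(mpl)
  set.seed(61)
  out <- predict_particles(ensl, mpl)
  expect_true(all(out$y == 1 / 0.4))
  expect_false(any(out$z == ensl$z)) # volatility still diffuses
  # martingale on z at 1e4 particles
  mp <- model_params(lambda_v = 0.1, lambda_s = 0.1, v0 = 1, s0 = 2,
                     n_particles = 1e4)
  set.seed(62)
  out <- predict_particles(init_particles(mp), mp)
  expect_lt(abs(mean(out$z) - 1), 3 * sd(out$z) / sqrt(1e4))
})

test_that("a zero-update-rate filter trial equals a single Kalman step exactly", {
  mp <- model_params(lambda_v = 0, lambda_s = 0, v0 = 0.5, s0 = 1.5,
                     n_particles = 100, prior_mean = 0, prior_var = 100)
  ft <- filter_trial(init_particles(mp), o = 2.7, params = mp)
  ks <- kalman_step(0, 100, 0.5, 1.5, 2.7)
  expect_equal(unname(ft$record["m"]), ks$m, tolerance = 1e-12)
  expect_equal(unname(ft$record["w"]), ks$w, tolerance = 1e-12)
  expect_equal(unname(ft$record["alpha"]), ks$alpha, tolerance = 1e-12)
  expect_equal(unname(ft$record["v_hat"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(ft$record["s_hat"]), 1.5, tolerance = 1e-12)
})

test_that("a degenerate ensemble triggers systematic resampling to uniform weights", {
  mp <- model_params(lambda_v = 0, lambda_s = 0, v0 = 1, s0 = 1,
                     n_particles = 10)
  ens <- particles(z = rep(1, 10), y = rep(1, 10),
                   m = c(0, rep(50, 9)), w = rep(1, 10),
                   weight = c(0.9, rep(0.1 / 9, 9)))
  expect_lt(effective_sample_size(ens$weight) / 10, 0.5)
  set.seed(71)
  ft <- filter_trial(ens, o = 0, params = mp)
  expect_equal(unname(ft$record["resampled"]), 1)
  expect_equal(ft$ensemble$weight, rep(0.1, 10))
})

test_that("the particle filter collapses onto an independent Kalman recursion", {
  for (seed in 1:3) {
    set.seed(seed)
    o <- rnorm(100, 1, 2)
    mp <- model_params(lambda_v = 0, lambda_s = 0, v0 = 1, s0 = 2,
                       n_particles = 100, prior_mean = 0, prior_var = 100)
    tr <- run_filter(o, mp, seed = seed + 100)
    ko <- kalman_oracle(o, v = 1, s = 2, m0 = 0, w0 = 100)
    expect_lt(max(abs(tr$m - ko$m)), 1e-10)
    expect_lt(max(abs(tr$w - ko$w)), 1e-10)
    expect_lt(max(abs(tr$alpha - ko$alpha)), 1e-10)
  }
})

test_that("run_filter is deterministic, validates input, and keeps trace invariants", {
  set.seed(81)
  o <- rnorm(150)
  mp <- model_params(lambda_v = 0.1, lambda_s = 0.1, v0 = 1, s0 = 2)
  t1 <- run_filter(o, mp, seed = 7)
  t2 <- run_filter(o, mp, seed = 7)
  expect_identical(t1, t2)
  t3 <- run_filter(o, mp, seed = 8)
  expect_false(identical(t1$v_hat, t3$v_hat))
  expect_equal(nrow(t1), 150)
  expect_true(all(t1$alpha > 0 & t1$alpha < 1))
  expect_true(all(t1$ess >= 1 - 1e-9 & t1$ess <= 100 + 1e-9))
  expect_true(all(t1$v_hat > 0 & t1$s_hat > 0 & t1$w > 0))
  expect_error(run_filter(c(1, NA, 3), mp), "trial 2")
  expect_error(run_filter(c(1, 2, Inf), mp), "trial 3")
  expect_error(run_filter(numeric(0), mp), "nonempty")
})

test_that("weights stay normalized and ESS in range across a filtering run", {
  mp <- model_params(lambda_v = 0.15, lambda_s = 0.15, v0 = 0.5, s0 = 1,
                     n_particles = 50, prior_var = 10)
  set.seed(91)
  o <- rnorm(50, cumsum(rnorm(50, 0, 0.5)), 1)
  ens <- init_particles(mp)
  set.seed(92)
  for (t in seq_along(o)) {
    res <- filter_trial(ens, o[t], mp)
    ens <- res$ensemble
    expect_equal(sum(ens$weight), 1, tolerance = 1e-10)
    ess <- unname(res$record["ess"])
    expect_true(ess >= 1 - 1e-9 && ess <= 50 + 1e-9)
  }
})

test_that("lesioned filters hold the lesioned estimate constant over trials", {
  set.seed(101)
  o <- rnorm(60, 0, 2)
  mpv <- model_params(lambda_v = 0.2, lambda_s = 0.2, v0 = 0.3, s0 = 1,
                      lesion = "fix_volatility")
  trv <- run_filter(o, mpv, seed = 1)
  expect_true(all(abs(trv$v_hat - 0.3) < 1e-12))
  expect_gt(sd(trv$s_hat), 0)
  mps <- model_params(lambda_v = 0.2, lambda_s = 0.2, v0 = 0.3, s0 = 1,
                      lesion = "fix_stochasticity", lesion_value = 0.05)
  trs <- run_filter(o, mps, seed = 1)
  expect_true(all(abs(trs$s_hat - 0.05) < 1e-12))
})

test_that("model parameter validation enforces the documented ranges", {
  expect_error(model_params(lambda_v = 1), "lambda_v")
  expect_error(model_params(lambda_s = -0.1), "lambda_s")
  expect_error(model_params(v0 = 0))
  expect_error(model_params(lesion = "fix_volatility", lesion_value = -1),
               "lesion_value")
  mp <- model_params(lesion = "fix_stochasticity", v0 = 1, s0 = 2)
  expect_equal(mp$lesion_value, 2) # defaults to s0
  mp <- model_params(lesion = "fix_volatility", v0 = 1, s0 = 2)
  expect_equal(mp$lesion_value, 1) # defaults to v0
})
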