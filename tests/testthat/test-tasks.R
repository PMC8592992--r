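test_that("every constructor is deterministic given its seed", {
  builders <- list(
    function(s) make_constant_2x2(0.5, 1, n_trials = 50, seed = s),
    function(s) make_switching_task(seed = s),
    function(s) make_conditioned_suppression("omission", seed = s),
    function(s) make_partial_reinforcement("partial", seed = s),
    function(s) make_serial_prediction("shift", seed = s),
    function(s) make_reversal_task("stochastic_60_40", seed = s),
    function(s) make_changepoint_task("small", n_trials = 100, seed = s),
    function(s) make_two_choice_task(seed = s))
  for (b in builders) {
    e1 <- b(42)
    e2 <- b(42)
    expect_identical(e1$outcomes, e2$outcomes)
    expect_identical(e1$rate_true, e2$rate_true)
    e3 <- b(43)
    expect_false(identical(e1$outcomes, e3$outcomes))
    # phase labels cover every trial
    expect_equal(length(e1$phase), length(e1))
  }
})

test_that("switching task follows the stable/volatile schedule", {
  ep <- make_switching_task(outcome_var = 0, seed = 1)
  expect_equal(length(ep), 180)
  expect_true(all(ep$rate_true[ep$phase == "stable"] == 0.8))
  vol <- ep$rate_true[ep$phase == "volatile"]
  expect_setequal(unique(vol), c(0.25, 0.75))
  # flips every 20 trials (the 90-trial block ends mid-segment)
  expect_equal(rle(vol)$lengths, c(20, 20, 20, 20, 10))
  expect_identical(ep$outcomes, ep$rate_true) # noiseless limit
  ep2 <- make_switching_task(seed = 2)
  expect_lt(abs(var(ep2$outcomes - ep2$rate_true) - 0.01) / 0.01, 0.6)
})

test_that("conditioned suppression has the omission structure and magnitudes", {
  om <- make_conditioned_suppression("omission", seed = 1)
  ct <- make_conditioned_suppression("control", seed = 1)
  expect_equal(sum(om$phase %in% c("pretraining", "omission")), 100)
  expect_equal(sum(om$phase == "omission"), 5)
  expect_true(all(om$rate_true[om$phase == "omission"] == 0))
  # omission trials sit at the end of pretraining
  expect_equal(which(om$phase == "omission"), 96:100)
  expect_false(any(ct$rate_true[ct$phase == "pretraining"] == 0))
  expect_true(all(ct$rate_true[ct$phase == "pretraining"] == 0.3))
  expect_true(all(om$rate_true[om$phase == "retraining"] == 1))
})

test_that("partial reinforcement delivers the stated reward rates", {
  pa <- make_partial_reinforcement("partial", seed = 1)
  fu <- make_partial_reinforcement("full", seed = 1)
  expect_equal(mean(pa$rate_true[pa$phase == "pretraining"]), 0.5)
  expect_equal(mean(fu$rate_true[fu$phase == "pretraining"]), 1)
  expect_lt(max(abs(pa$outcomes[pa$phase == "extinction"])), 0.1)
  expect_lt(abs(mean(pa$outcomes[pa$phase == "pretraining"]) - 0.5), 0.05)
})

test_that("serial prediction carries two channels and shifts the tone contingency", {
  co <- make_serial_prediction("consistent", seed = 1)
  sh <- make_serial_prediction("shift", seed = 1)
  expect_equal(ncol(co$outcomes), 2)
  expect_equal(colnames(co$outcomes), c("tone", "reward"))
  # phase 1 identical structure: tone always on, reward on half of trials
  for (ep in list(co, sh)) {
    p1 <- ep$phase == "phase1"
    expect_true(all(ep$rate_true[p1, "tone"] == 1))
    expect_equal(mean(ep$rate_true[p1, "reward"]), 0.5)
  }
  # phase 2: consistent keeps tone on every trial; shift halves it and
  # aligns it with reward
  p2c <- co$phase == "phase2"
  expect_true(all(co$rate_true[p2c, "tone"] == 1))
  p2s <- sh$phase == "phase2"
  expect_equal(mean(sh$rate_true[p2s, "tone"]), 0.5)
  expect_identical(sh$rate_true[p2s, "tone"], sh$rate_true[p2s, "reward"])
})

test_that("reversal task reverses once inside the stated window", {
  for (seed in 1:25) {
    ep <- make_reversal_task("deterministic_100_0", seed = seed)
    expect_equal(length(ep), 80)
    rt <- ep$meta$reversal_trial
    expect_true(rt >= 30 && rt <= 50)
    expect_true(all(ep$rate_true[seq_len(rt - 1), 1] == 1))
    expect_true(all(ep$rate_true[rt:80, 1] == 0))
    expect_equal(ep$correct_option,
                 c(rep(1L, rt - 1), rep(2L, 80 - rt + 1)))
    expect_equal(ep$phase, rep(c("acquisition", "reversal"),
                               c(rt - 1, 80 - rt + 1)))
  }
  st <- make_reversal_task("stochastic_60_40", seed = 3)
  expect_setequal(unique(as.vector(st$rate_true)), c(0.6, 0.4))
  expect_error(make_reversal_task("bogus"))
})

test_that("change-point schedules respect the minimum interval and jump range", {
  for (seed in 1:10) {
    ep <- make_changepoint_task("small", n_trials = 300, seed = seed)
    cps <- ep$meta$changepoints
    expect_true(all(diff(c(1L, cps)) >= 5))
    expect_true(all(ep$rate_true >= 0 & ep$rate_true <= 10))
    # rate constant between change points
    segs <- rle(ep$rate_true)
    expect_equal(length(segs$values), length(cps) + 1L)
  }
  set.seed(1)
  resid <- unlist(lapply(1:20, function(s) {
    ep <- make_changepoint_task("small", n_trials = 300, seed = s)
    ep$outcomes - ep$rate_true
  }))
  expect_lt(abs(var(resid) - 1), 0.05)
  residL <- unlist(lapply(1:20, function(s) {
    ep <- make_changepoint_task("large", n_trials = 300, seed = s)
    ep$outcomes - ep$rate_true
  }))
  expect_lt(abs(var(residL) - 9) / 9, 0.05)
})

test_that("two-choice task has complementary switching contingencies", {
  ep <- make_two_choice_task(seed = 1)
  expect_equal(ncol(ep$outcomes), 2)
  expect_equal(rowSums(ep$rate_true), rep(1, 160))
  expect_equal(unique(rle(ep$rate_true[, 1])$lengths), 20)
  # residual around the binary reward has the stated variance
  set.seed(2)
  resid <- unlist(lapply(1:20, function(s) {
    e <- make_two_choice_task(seed = s)
    e$outcomes - round(e$outcomes)
  }))
  expect_lt(abs(var(resid) - 0.01) / 0.01, 0.1)
  # initial stable run holds the contingency fixed
  eps <- make_two_choice_task(stable_blocks = 4, seed = 3)
  expect_true(all(eps$rate_true[1:80, 1] == 0.75))
  expect_true(all(eps$correct_option[1:80] == 1L))
})
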