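# Independent oracles used to cross-check the implementation.

# Closed-form Kalman recursion, written directly from the update equations
# (independent of the package's kalman_filter and of the particle core).
kalman_oracle <- function(outcomes, v, s, m0 = 0, w0 = 100) {
  n <- length(outcomes)
  m <- w <- a <- d <- numeric(n)
  mc <- m0
  wc <- w0
  for (t in seq_len(n)) {
    gain <- (wc + v) / (wc + v + s)
    d[t] <- outcomes[t] - mc
    mc <- mc + gain * d[t]
    wc <- (1 - gain) * (wc + v)
    m[t] <- mc
    w[t] <- wc
    a[t] <- gain
  }
  list(m = m, w = w, alpha = a, delta = d)
}

# Brute-force conditional counting for win-stay / lose-shift.
wsls_oracle <- function(choices, rewards, thr = 0.5) {
  ws_num <- ws_den <- ls_num <- ls_den <- 0L
  for (t in seq_len(length(choices) - 1L)) {
    if (rewards[t] > thr) {
      ws_den <- ws_den + 1L
      if (choices[t + 1L] == choices[t]) ws_num <- ws_num + 1L
    } else {
      ls_den <- ls_den + 1L
      if (choices[t + 1L] != choices[t]) ls_num <- ls_num + 1L
    }
  }
  c(win_stay = ws_num / ws_den, lose_shift = ls_num / ls_den)
}

# Pull a named statistic out of a tidy experiment result as a vector of
# per-simulation values for one group and condition.
stat_values <- function(res, grp, cond, stat) {
  df <- res$result
  df$value[df$group == grp & df$condition == cond & df$statistic == stat]
}
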