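# Choice rules and behavioral summary statistics.

#' Softmax choice probabilities
#'
#' `p_i` proportional to `exp(beta * value_i)`. Invariant to adding a
#' constant to all values; `beta = 0` gives uniform probabilities and large
#' `beta` concentrates on the argmax.
#'
#' @param values One value per option, finite.
#' @param beta Decision-noise (inverse temperature) parameter, nonnegative.
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' softmax_probs(c(1, 0), beta = 3) # c(0.9526, 0.0474)
softmax_probs <- function(values, beta) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (beta < 0) stop("beta must be nonnegative")
  z <- beta * values
  e <- exp(z - max(z))
  e / sum(e)
}

#' Pavlovian response probability
#'
#' Two-option softmax of the cue's value against a fixed zero alternative:
#' `p = 1 / (1 + exp(-beta * value))`.
#'
#' @param value Learned value of the cue.
#' @param beta Decision-noise parameter, nonnegative.
#' @return Probability in (0, 1).
#' @export
response_prob <- function(value, beta) {
  if (beta < 0) stop("beta must be nonnegative")
  1 / (1 + exp(-beta * value))
}

#' Win-stay / lose-shift rates
#'
#' `win_stay` is the probability of repeating the previous choice after a
#' win, `lose_shift` the probability of switching after a loss. Noisy
#' rewards are binarized at `threshold` (reward > threshold counts as a
#' win). The combined rate is the frequency-weighted mean of the two.
#'
#' @param choices Integer choice per trial (length >= 2).
#' @param rewards Observed reward per trial (same length).
#' @param threshold Win/loss binarization threshold (default 0.5).
#' @return List with `win_stay`, `lose_shift`, `combined`, `n_win`,
#'   `n_lose`. A component with no qualifying trials is `NA` (flagged
#'   undefined, not 0).
#' @export
win_stay_lose_shift <- function(choices, rewards, threshold = 0.5) {
  n <- length(choices)
  stopifnot(n >= 2, length(rewards) == n)
  win <- rewards[-n] > threshold
  stay <- choices[-1] == choices[-n]
  n_win <- sum(win)
  n_lose <- sum(!win)
  win_stay <- if (n_win > 0) mean(stay[win]) else NA_real_
  lose_shift <- if (n_lose > 0) mean(!stay[!win]) else NA_real_
  combined <- if (n_win > 0 && n_lose > 0) {
    (n_win * win_stay + n_lose * lose_shift) / (n_win + n_lose)
  } else if (n_win > 0) win_stay else lose_shift
  list(win_stay = win_stay, lose_shift = lose_shift, combined = combined,
       n_win = n_win, n_lose = n_lose)
}

#' Relative log learning rate (volatile minus stable)
#'
#' Mean natural-log learning rate over volatile-labeled trials minus that
#' over stable-labeled trials; positive when learning is faster under
#' volatility, as in the healthy model.
#'
#' @param trace A `filter_trace` from [run_filter()] (or anything with an
#'   `alpha` column).
#' @param block_labels Character per-trial labels.
#' @param volatile,stable Label values for the two classes.
#' @return Scalar difference of mean log learning rates.
#' @export
relative_log_learning_rate <- function(trace, block_labels,
                                       volatile = "volatile",
                                       stable = "stable") {
  stopifnot(length(block_labels) == nrow(trace))
  a_vol <- trace$alpha[block_labels == volatile]
  a_sta <- trace$alpha[block_labels == stable]
  if (length(a_vol) == 0) stop("no trials labeled '", volatile, "'")
  if (length(a_sta) == 0) stop("no trials labeled '", stable, "'")
  mean(log(a_vol)) - mean(log(a_sta))
}

#' Summarize a trace field over a trial window
#'
#' @param trace A `filter_trace` (or data frame) with the named field.
#' @param field Column name, e.g. `"alpha"`, `"v_hat"`.
#' @param window Integer trial indices (e.g. the last 20 trials, or a single
#'   probe trial).
#' @param statistic `"mean"` or `"median"`.
#' @return Scalar summary.
#' @export
#' @examples
#' # last-20-trial mean volatility estimate:
#' # summarize_window(trace, "v_hat", window = 181:200)
summarize_window <- function(trace, field, window,
                             statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(window) == 0) stop("window is empty")
  if (any(window < 1) || any(window > nrow(trace))) {
    stop("window outside trace length")
  }
  x <- trace[[field]][window]
  if (statistic == "mean") mean(x) else stats::median(x)
}

#' Label trials as stable or volatile by recent contingency switches
#'
#' A trial is labeled `"volatile"` when the true rate changed at least once
#' within its preceding `window` trials, `"stable"` otherwise. The window
#' length is a parameter because published definitions of this trial-wise
#' classification vary.
#'
#' @param rates Per-trial true rate sequence.
#' @param window Look-back window in trials (default 10).
#' @return Character vector of `"stable"`/`"volatile"` labels.
#' @export
label_stability <- function(rates, window = 10) {
  n <- length(rates)
  switched <- c(FALSE, rates[-1] != rates[-n])
  labels <- character(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - window + 1L)
    labels[t] <- if (any(switched[lo:t])) "volatile" else "stable"
  }
  labels
}
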