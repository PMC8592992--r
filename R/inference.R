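# The learner: a conditional Kalman filter over the latent reward rate,
# wrapped in a Rao-Blackwellized particle filter over inverse volatility and
# inverse stochasticity, with lesioned variants that hold one noise variable
# fixed at its initial value.

#' Learner configuration
#'
#' @param lambda_v,lambda_s Update rates for volatility and stochasticity in
#'   \[0, 1): the complement `eta = 1 - lambda` is the persistence of the
#'   multiplicative Beta dynamics the particles follow. `lambda = 0` freezes
#'   the corresponding variable (no diffusion).
#' @param v0,s0 Initial volatility and stochasticity, positive. All particles
#'   start at `z = 1/v0`, `y = 1/s0` with uniform weights, so `lambda = 0`
#'   reduces the filter exactly to a Kalman filter with known noise.
#' @param n_particles Number of particles (default 100).
#' @param prior_mean,prior_var Gaussian prior over the reward rate (default
#'   mean 0, variance 100).
#' @param lesion `"none"`, `"fix_volatility"` or `"fix_stochasticity"`. A
#'   lesioned variable is clamped at `lesion_value` for every particle on
#'   every trial; the model must then explain all experienced noise with the
#'   remaining variable.
#' @param lesion_value Fixed value for the lesioned variable; defaults to
#'   `v0` (volatility lesion) or `s0` (stochasticity lesion).
#' @param ess_ratio_threshold Systematic resampling is triggered when the
#'   effective-to-total particle ratio falls below this (default 0.5).
#'
#' @return An object of class `model_params`.
#' @export
#' @examples
#' mp <- model_params(lambda_v = 0.1, lambda_s = 0.1, v0 = 1, s0 = 2)
model_params <- function(lambda_v = 0.1, lambda_s = 0.1, v0 = 1, s0 = 2,
                         n_particles = 100, prior_mean = 0, prior_var = 100,
                         lesion = c("none", "fix_volatility", "fix_stochasticity"),
                         lesion_value = NULL, ess_ratio_threshold = 0.5) {
  lesion <- match.arg(lesion)
  if (!(lambda_v >= 0 && lambda_v < 1)) stop("lambda_v must lie in [0, 1)")
  if (!(lambda_s >= 0 && lambda_s < 1)) stop("lambda_s must lie in [0, 1)")
  stopifnot(v0 > 0, s0 > 0, prior_var > 0,
            n_particles >= 1, n_particles == floor(n_particles),
            ess_ratio_threshold > 0, ess_ratio_threshold <= 1)
  if (is.null(lesion_value)) {
    lesion_value <- switch(lesion, fix_volatility = v0, fix_stochasticity = s0,
                           none = NA_real_)
  }
  if (lesion != "none" && !(is.numeric(lesion_value) && lesion_value > 0)) {
    stop("lesion_value must be a positive scalar")
  }
  structure(list(lambda_v = lambda_v, lambda_s = lambda_s, v0 = v0, s0 = s0,
                 n_particles = as.integer(n_particles),
                 prior_mean = prior_mean, prior_var = prior_var,
                 lesion = lesion, lesion_value = lesion_value,
                 ess_ratio_threshold = ess_ratio_threshold),
            class = "model_params")
}

#' One Kalman update with known noise variances
#'
#' Given posterior mean `m` and variance `w`, process noise `v` and
#' observation noise `s`, the update after observing outcome `o` is
#' `delta = o - m`, learning rate `alpha = (w + v) / (w + v + s)`,
#' `m_next = m + alpha * delta`, and
#' `w_next = s * (w + v) / (w + v + s)` (algebraically `(1 - alpha)(w + v)`,
#' computed in the former form to avoid cancellation when `alpha` is near 1).
#' All arguments may be vectors (recycled elementwise).
#'
#' @param m,w Posterior mean and variance before the update (`w >= 0`).
#' @param v,s Volatility and stochasticity, nonnegative; `w + v + s` must be
#'   positive.
#' @param o Observed outcome.
#' @return List with `m`, `w`, `alpha`, `delta`.
#' @export
#' @examples
#' kalman_step(m = 0, w = 1, v = 1, s = 2, o = 4) # alpha 0.5, m 2, w 1
kalman_step <- function(m, w, v, s, o) {
  if (any(w < 0) || any(v < 0) || any(s < 0)) {
    stop("w, v and s must be nonnegative")
  }
  total <- w + v + s
  if (any(total == 0)) stop("degenerate input: w + v + s is zero")
  alpha <- (w + v) / total
  delta <- o - m
  list(m = m + alpha * delta, w = s * (w + v) / total,
       alpha = alpha, delta = delta)
}

#' Closed-form Kalman filter with fixed, known noise
#'
#' Plain Kalman recursion over a whole outcome sequence, with volatility and
#' stochasticity known (scalars or per-trial vectors). This is the exact
#' posterior for the reward rate when the noise variances are not learned;
#' the particle filter collapses onto it when both update rates are zero and
#' the initial noise values equal the truth.
#'
#' @param outcomes Numeric vector of outcomes.
#' @param v,s Known volatility and stochasticity (scalar or per-trial).
#' @param prior_mean,prior_var Gaussian prior over the reward rate.
#' @return Data frame with per-trial `m`, `w`, `alpha`, `delta` (posterior
#'   after each outcome).
#' @export
kalman_filter <- function(outcomes, v, s, prior_mean = 0, prior_var = 100) {
  n <- length(outcomes)
  stopifnot(n >= 1, all(is.finite(outcomes)))
  v <- rep_len(v, n)
  s <- rep_len(s, n)
  m <- prior_mean
  w <- prior_var
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("m", "w", "alpha", "delta")))
  for (t in seq_len(n)) {
    st <- kalman_step(m, w, v[t], s[t], outcomes[t])
    m <- st$m
    w <- st$w
    out[t, ] <- c(m, w, st$alpha, st$delta)
  }
  data.frame(trial = seq_len(n), outcome = outcomes, out)
}

#' Particle ensemble constructor
#'
#' @param z,y Inverse volatility and inverse stochasticity samples, positive.
#' @param m,w Conditional Kalman mean and variance per particle (`w > 0`).
#' @param weight Normalized importance weights (must sum to 1).
#' @return An object of class `particles`.
#' @export
particles <- function(z, y, m, w, weight = rep(1 / length(z), length(z))) {
  n <- length(z)
  stopifnot(length(y) == n, length(m) == n, length(w) == n, length(weight) == n,
            all(z > 0), all(y > 0), all(w > 0))
  if (abs(sum(weight) - 1) > 1e-10) stop("weights must sum to 1")
  structure(list(z = z, y = y, m = m, w = w, weight = weight),
            class = "particles")
}

#' Initialize the particle ensemble from learner parameters
#'
#' All particles start at the same point: `z = 1/v0`, `y = 1/s0` (a lesioned
#' variable starts at `1/lesion_value`), Kalman statistics at the prior, and
#' uniform weights.
#'
#' @param params A [model_params()] object.
#' @return A [particles()] ensemble.
#' @export
init_particles <- function(params) {
  stopifnot(inherits(params, "model_params"))
  N <- params$n_particles
  v_init <- if (params$lesion == "fix_volatility") params$lesion_value else params$v0
  s_init <- if (params$lesion == "fix_stochasticity") params$lesion_value else params$s0
  particles(z = rep(1 / v_init, N), y = rep(1 / s_init, N),
            m = rep(params$prior_mean, N), w = rep(params$prior_var, N))
}

#' Prediction step: diffuse the noise samples of every particle
#'
#' Each particle's inverse volatility (and inverse stochasticity) is diffused
#' by the multiplicative Beta dynamics with persistence `1 - lambda`. A
#' variable with `lambda = 0`, or one held fixed by a lesion, is left
#' untouched. Weights are unchanged.
#'
#' @param ensemble A [particles()] ensemble.
#' @param params A [model_params()] object.
#' @return The diffused ensemble.
#' @export
predict_particles <- function(ensemble, params) {
  stopifnot(inherits(ensemble, "particles"), inherits(params, "model_params"))
  z <- ensemble$z
  y <- ensemble$y
  if (params$lesion != "fix_volatility" && params$lambda_v > 0) {
    z <- diffuse_inverse_beta(z, 1 - params$lambda_v)
  }
  if (params$lesion != "fix_stochasticity" && params$lambda_s > 0) {
    y <- diffuse_inverse_beta(y, 1 - params$lambda_s)
  }
  particles(z, y, ensemble$m, ensemble$w, ensemble$weight)
}

#' Weighting step: reweight particles by outcome likelihood
#'
#' Each particle's weight is multiplied by the Gaussian predictive density
#' `N(o | m, w + v + s)` with `v = 1/z`, `s = 1/y`, then normalized.
#' Computation is done on log densities with max-subtraction; if every
#' density underflows to zero the weights fall back to uniform with a
#' warning.
#'
#' @param ensemble A [particles()] ensemble.
#' @param o Observed outcome (finite scalar).
#' @return The ensemble with updated normalized weights.
#' @export
weight_particles <- function(ensemble, o) {
  stopifnot(inherits(ensemble, "particles"), is.finite(o))
  v <- 1 / ensemble$z
  s <- 1 / ensemble$y
  lw <- log(ensemble$weight) +
    stats::dnorm(o, ensemble$m, sqrt(ensemble$w + v + s), log = TRUE)
  mx <- max(lw)
  if (!is.finite(mx)) {
    warning("all particle weights underflowed; falling back to uniform")
    b <- rep(1 / length(lw), length(lw))
  } else {
    b <- exp(lw - mx)
    b <- b / sum(b)
  }
  particles(ensemble$z, ensemble$y, ensemble$m, ensemble$w, b)
}

#' Effective sample size of a normalized weight vector
#'
#' `ESS = 1 / sum(w^2)`, ranging from 1 (degenerate) to N (uniform). Used as
#' the resampling trigger: resample when `ESS / N` falls below the threshold.
#'
#' @param weights Normalized weights (must sum to 1).
#' @return Scalar in \[1, N\].
#' @export
#' @examples
#' effective_sample_size(c(0.5, 0.25, 0.25)) # 2.667
effective_sample_size <- function(weights) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized to sum 1")
  1 / sum(weights^2)
}

# comb selection for systematic resampling: positions u + (0:(N-1))/N against
# the cumulative weights; offspring counts differ from N*w_i by less than 1.
# A position exactly on a boundary cw[i] belongs to particle i+1, so
# zero-weight particles are never selected.
.systematic_indices <- function(weights, u) {
  N <- length(weights)
  cw <- cumsum(weights)
  cw[N] <- max(1, cw[N]) # guard against floating-point shortfall
  findInterval(u + (seq_len(N) - 1) / N, cw) + 1L
}

#' Systematic resampling
#'
#' Selects N offspring with a single uniform offset `u ~ U(0, 1/N)` and the
#' comb `u + k/N` swept across the cumulative weights, then resets weights to
#' uniform. Offspring counts of each particle differ from `N * weight` by
#' less than one, so uniform weights reproduce the ensemble exactly.
#'
#' @param ensemble A [particles()] ensemble with normalized weights.
#' @param u Optional offset in \[0, 1/N) (drawn from the RNG when `NULL`);
#'   exposed for enumeration in tests.
#' @return The resampled ensemble with uniform weights.
#' @export
systematic_resample <- function(ensemble, u = NULL) {
  stopifnot(inherits(ensemble, "particles"))
  N <- length(ensemble$weight)
  if (is.null(u)) u <- stats::runif(1, 0, 1 / N)
  stopifnot(u >= 0, u < 1 / N)
  idx <- .systematic_indices(ensemble$weight, u)
  particles(ensemble$z[idx], ensemble$y[idx], ensemble$m[idx], ensemble$w[idx])
}

# --- internal single-trial core -------------------------------------------
# st: plain list(z, y, m, w, b). Operates on bare vectors for speed; the
# exported filter_trial() wraps it. An NA outcome means "no observation this
# trial": noise samples diffuse and the Kalman variance grows by v, but no
# weighting, resampling or mean update occurs (used for unchosen options in
# choice tasks).
.rbpf_trial <- function(st, o, params) {
  z <- st$z
  y <- st$y
  m <- st$m
  w <- st$w
  b <- st$b
  N <- length(z)
  # step 1: prediction (RNG order: volatility draws, then stochasticity)
  if (params$lesion != "fix_volatility" && params$lambda_v > 0) {
    z <- diffuse_inverse_beta(z, 1 - params$lambda_v)
  }
  if (params$lesion != "fix_stochasticity" && params$lambda_s > 0) {
    y <- diffuse_inverse_beta(y, 1 - params$lambda_s)
  }
  v <- 1 / z
  s <- 1 / y
  if (is.na(o)) {
    w <- w + v
    rec <- c(sum(b * m), sum(b * w), NA_real_, NA_real_,
             sum(b * v), sum(b * s), 1 / sum(b * b), 0)
    return(list(st = list(z = z, y = y, m = m, w = w, b = b), rec = rec))
  }
  # step 2: weighting (log-space), then conditional systematic resampling
  lw <- log(b) + stats::dnorm(o, m, sqrt(w + v + s), log = TRUE)
  mx <- max(lw)
  if (!is.finite(mx)) {
    warning("all particle weights underflowed; falling back to uniform")
    b <- rep(1 / N, N)
  } else {
    b <- exp(lw - mx)
    b <- b / sum(b)
  }
  ess <- 1 / sum(b * b)
  resampled <- 0
  if (ess / N < params$ess_ratio_threshold) {
    idx <- .systematic_indices(b, stats::runif(1, 0, 1 / N))
    z <- z[idx]
    y <- y[idx]
    m <- m[idx]
    w <- w[idx]
    v <- v[idx]
    s <- s[idx]
    b <- rep(1 / N, N)
    resampled <- 1
  }
  # step 3: per-particle Kalman update; outputs are weighted averages under
  # the weights as they stand after the (conditional) resampling step
  total <- w + v + s
  alpha <- (w + v) / total
  delta <- o - m
  m <- m + alpha * delta
  w <- s * (w + v) / total
  rec <- c(sum(b * m), sum(b * w), sum(b * alpha), sum(b * delta),
           sum(b * v), sum(b * s), ess, resampled)
  list(st = list(z = z, y = y, m = m, w = w, b = b), rec = rec)
}

.rec_names <- c("m", "w", "alpha", "delta", "v_hat", "s_hat", "ess", "resampled")

#' Advance the particle filter by one trial
#'
#' Executes the three-step algorithm: prediction (noise diffusion per
#' particle), weighting by outcome likelihood with systematic resampling when
#' `ESS/N` drops below the threshold, and a per-particle Kalman update using
#' that particle's sampled `v = 1/z`, `s = 1/y`. Reported signals are
#' weighted averages across particles, taken after the resampling step.
#'
#' @param ensemble A [particles()] ensemble.
#' @param o Outcome (finite scalar, or `NA` for an unobserved trial in which
#'   case only prediction occurs and uncertainty grows).
#' @param params A [model_params()] object.
#' @return List with `ensemble` (the advanced [particles()]) and `record`
#'   (named numeric: `m`, `w`, `alpha`, `delta`, `v_hat`, `s_hat`, `ess`,
#'   `resampled`).
#' @export
filter_trial <- function(ensemble, o, params) {
  stopifnot(inherits(ensemble, "particles"), inherits(params, "model_params"))
  st <- list(z = ensemble$z, y = ensemble$y, m = ensemble$m, w = ensemble$w,
             b = ensemble$weight)
  res <- .rbpf_trial(st, o, params)
  names(res$rec) <- .rec_names
  list(ensemble = particles(res$st$z, res$st$y, res$st$m, res$st$w, res$st$b),
       record = res$rec)
}

#' Run the particle-filter learner over an outcome sequence
#'
#' Initializes the ensemble from the prior ([init_particles()]) and applies
#' [filter_trial()] to each outcome in turn. Deterministic given
#' `(outcomes, params, seed)`: the seed is set once and the RNG is consumed
#' in a fixed order (volatility diffusion draws, stochasticity diffusion
#' draws, then the resampling offset when triggered).
#'
#' @param outcomes Numeric vector of outcomes; all values must be finite.
#' @param params A [model_params()] object.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A `filter_trace` data frame with columns `trial`, `outcome`, `m`,
#'   `w`, `alpha`, `delta`, `v_hat`, `s_hat`, `ess`, `resampled`.
#' @export
#' @examples
#' tr <- run_filter(rnorm(50), model_params(v0 = 1, s0 = 2), seed = 1)
run_filter <- function(outcomes, params, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  n <- length(outcomes)
  if (n == 0) stop("outcomes must be nonempty")
  bad <- which(!is.finite(outcomes))
  if (length(bad) > 0) {
    stop("non-finite outcome at trial ", bad[1])
  }
  if (!is.null(seed)) set.seed(seed)
  p0 <- init_particles(params)
  st <- list(z = p0$z, y = p0$y, m = p0$m, w = p0$w, b = p0$weight)
  out <- matrix(NA_real_, n, 8, dimnames = list(NULL, .rec_names))
  for (t in seq_len(n)) {
    res <- .rbpf_trial(st, outcomes[t], params)
    st <- res$st
    out[t, ] <- res$rec
  }
  tr <- data.frame(trial = seq_len(n), outcome = outcomes, out)
  tr$resampled <- as.logical(tr$resampled)
  class(tr) <- c("filter_trace", "data.frame")
  tr
}
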