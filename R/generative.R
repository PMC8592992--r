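# Generative model: reward-rate diffusion, outcome emission, and the two
# stochastic dynamics for the noise hyperparameters (volatility, stochasticity).

# floor for Beta draws; a draw of exactly 0 (possible at floating point for
# shape < 1) would zero the inverse-noise chain and make v or s infinite
.EPS_FLOOR <- 1e-12

#' Parameters of the generative process
#'
#' Bundles the parameters governing how outcome time-series are generated:
#' the latent reward rate diffuses as a Gaussian random walk whose innovation
#' variance is the volatility `v_t`, outcomes are the rate plus Gaussian noise
#' of variance equal to the stochasticity `s_t`, and the two noise variances
#' themselves evolve over trials. Two dynamics are supported for the noise:
#' `"beta_multiplicative"` applies multiplicative Beta-distributed noise to
#' the inverse variances (persistence `eta_v`, `eta_s`), and `"gaussian_log"`
#' lets the log variances diffuse as Gaussian random walks (step sd `sigma_v`,
#' `sigma_s`).
#'
#' @param eta_v,eta_s Persistence of inverse volatility / inverse
#'   stochasticity, in (0, 1). The complementary update rate is
#'   `lambda = 1 - eta`. Used by the Beta dynamics only.
#' @param v0 Initial volatility (variance units), positive.
#' @param s0 Initial stochasticity (variance units), positive.
#' @param x0 Initial reward rate. Default 0, matching the prior mean used by
#'   the learner.
#' @param n_trials Number of trials, at least 1.
#' @param dynamics_kind `"beta_multiplicative"` or `"gaussian_log"`.
#' @param sigma_v,sigma_s Random-walk step standard deviations for the
#'   log-space dynamics, nonnegative. Ignored by the Beta dynamics.
#'
#' @return An object of class `generative_params` (a validated list).
#' @export
#' @examples
#' gp <- generative_params(v0 = 0.5, s0 = 1, n_trials = 200)
generative_params <- function(eta_v = 0.9, eta_s = 0.9, v0 = 1, s0 = 2,
                              x0 = 0, n_trials = 200,
                              dynamics_kind = c("beta_multiplicative", "gaussian_log"),
                              sigma_v = 0.1, sigma_s = 0.1) {
  dynamics_kind <- match.arg(dynamics_kind)
  stopifnot(is.numeric(v0), length(v0) == 1, v0 > 0,
            is.numeric(s0), length(s0) == 1, s0 > 0,
            is.numeric(x0), length(x0) == 1, is.finite(x0),
            length(n_trials) == 1, n_trials >= 1, n_trials == floor(n_trials))
  if (dynamics_kind == "beta_multiplicative") {
    if (!(eta_v > 0 && eta_v < 1)) stop("eta_v must lie strictly in (0, 1)")
    if (!(eta_s > 0 && eta_s < 1)) stop("eta_s must lie strictly in (0, 1)")
  } else {
    if (sigma_v < 0) stop("sigma_v must be nonnegative")
    if (sigma_s < 0) stop("sigma_s must be nonnegative")
  }
  structure(list(eta_v = eta_v, eta_s = eta_s, v0 = v0, s0 = s0, x0 = x0,
                 n_trials = as.integer(n_trials), dynamics_kind = dynamics_kind,
                 sigma_v = sigma_v, sigma_s = sigma_s),
            class = "generative_params")
}

#' One multiplicative Beta diffusion step on an inverse noise variable
#'
#' The inverse variance z evolves as `z_t = eta^-1 * z_{t-1} * eps_t` with
#' `eps_t ~ Beta(0.5 * eta / (1 - eta), 0.5)`. Because `E[eps] = eta`, the
#' chain is a martingale: `E[z_t | z_{t-1}] = z_{t-1}`. Draws of `eps` are
#' clamped to a tiny positive floor (1e-12) so the inverse stays finite.
#'
#' @param prev_inverse Previous inverse-variance value, positive.
#' @param eta Persistence in (0, 1); the update rate is `1 - eta`.
#' @param n Number of independent draws (vectorized over particles).
#' @return Numeric vector of length `n`, strictly positive.
#' @export
#' @examples
#' set.seed(1)
#' mean(diffuse_inverse_beta(2, 0.9, n = 1e4)) # close to 2
diffuse_inverse_beta <- function(prev_inverse, eta, n = length(prev_inverse)) {
  if (any(prev_inverse <= 0)) stop("prev_inverse must be positive")
  if (!(eta > 0 && eta < 1)) stop("eta must lie strictly in (0, 1)")
  eps <- stats::rbeta(n, 0.5 * eta / (1 - eta), 0.5)
  eps <- pmax(eps, .EPS_FLOOR)
  prev_inverse * eps / eta
}

#' One Gaussian random-walk step in log space
#'
#' @param prev_log Previous log-variance value(s).
#' @param sigma Step standard deviation, nonnegative.
#' @param n Number of draws.
#' @return `prev_log + rnorm(n, 0, sigma)`.
#' @export
diffuse_log_gaussian <- function(prev_log, sigma, n = length(prev_log)) {
  if (sigma < 0) stop("sigma must be nonnegative")
  prev_log + stats::rnorm(n, 0, sigma)
}

#' Constant noise trajectory
#'
#' Convenience constructor for the constant-parameter designs: volatility and
#' stochasticity held fixed at known true values for every trial.
#'
#' @param v,s Constant volatility and stochasticity, nonnegative (zero gives
#'   the corresponding noiseless limit).
#' @param n_trials Length of the trajectory.
#' @return A `noise_trajectory`: list with per-trial `v`, `s`, `z = 1/v`,
#'   `y = 1/s`.
#' @export
constant_noise <- function(v, s, n_trials) {
  stopifnot(v >= 0, s >= 0, n_trials >= 1)
  noise_trajectory(v = rep(v, n_trials), s = rep(s, n_trials))
}

#' Noise trajectory container
#'
#' Trajectories produced by the stochastic dynamics are strictly positive;
#' zero entries are permitted only for hand-built noiseless limits.
#'
#' @param v,s Per-trial volatility and stochasticity, nonnegative and of
#'   equal length. Inverses `z = 1/v`, `y = 1/s` are stored alongside.
#' @return An object of class `noise_trajectory`.
#' @export
noise_trajectory <- function(v, s) {
  stopifnot(length(v) == length(s), all(v >= 0), all(s >= 0))
  structure(list(v = v, s = s, z = 1 / v, y = 1 / s), class = "noise_trajectory")
}

#' Generate an outcome time-series from the hierarchical model
#'
#' Simulates the full generative process: the noise variances evolve per
#' `params$dynamics_kind` (or follow `fixed_noise` if supplied), the reward
#' rate diffuses as `x_t = x_{t-1} + e_t` with `e_t ~ N(0, v_t)`, and
#' outcomes are emitted as `o_t ~ N(x_t, s_t)`.
#'
#' @param params A [generative_params()] object.
#' @param fixed_noise Optional [noise_trajectory()] overriding the stochastic
#'   noise dynamics (used by the constant-parameter designs); must be at least
#'   `n_trials` long.
#' @return A list of class `generated_series` with elements `x` (latent rate),
#'   `o` (outcomes), `e` (diffusion innovations) and `noise`
#'   (a `noise_trajectory`).
#' @export
#' @examples
#' set.seed(1)
#' gs <- generate_series(generative_params(v0 = 0.5, s0 = 1, n_trials = 100),
#'                       fixed_noise = constant_noise(0.5, 1, 100))
generate_series <- function(params, fixed_noise = NULL) {
  stopifnot(inherits(params, "generative_params"))
  n <- params$n_trials
  if (!is.null(fixed_noise)) {
    stopifnot(inherits(fixed_noise, "noise_trajectory"))
    if (length(fixed_noise$v) < n) stop("fixed_noise shorter than n_trials")
    v <- fixed_noise$v[seq_len(n)]
    s <- fixed_noise$s[seq_len(n)]
  } else if (params$dynamics_kind == "beta_multiplicative") {
    z <- y <- numeric(n)
    z_prev <- 1 / params$v0
    y_prev <- 1 / params$s0
    for (t in seq_len(n)) {
      z_prev <- diffuse_inverse_beta(z_prev, params$eta_v, 1)
      y_prev <- diffuse_inverse_beta(y_prev, params$eta_s, 1)
      z[t] <- z_prev
      y[t] <- y_prev
    }
    v <- 1 / z
    s <- 1 / y
  } else {
    lv <- cumsum(c(log(params$v0), stats::rnorm(n, 0, params$sigma_v)))[-1]
    ls <- cumsum(c(log(params$s0), stats::rnorm(n, 0, params$sigma_s)))[-1]
    v <- exp(lv)
    s <- exp(ls)
  }
  e <- stats::rnorm(n, 0, sqrt(v))
  x <- params$x0 + cumsum(e)
  o <- x + stats::rnorm(n, 0, sqrt(s))
  structure(list(x = x, o = o, e = e, noise = noise_trajectory(v, s)),
            class = "generated_series")
}

#' Lag-1 autocorrelation of a series
#'
#' Pearson correlation between `series[2:n]` and `series[1:(n-1)]`. This is
#' the diagnostic that dissociates the two noise sources: volatility raises
#' the lag-1 autocorrelation of outcomes while stochasticity lowers it.
#'
#' @param series Numeric vector, length at least 3.
#' @return Correlation in \[-1, 1\], or `NA` with a warning when the series
#'   has zero variance (undefined, not silently 0).
#' @export
lag1_autocorrelation <- function(series) {
  if (length(series) < 3) stop("series must have length >= 3")
  a <- series[-length(series)]
  b <- series[-1]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance series: lag-1 autocorrelation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}
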