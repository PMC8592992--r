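---
title: "Joint estimation of volatility and stochasticity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint estimation of volatility and stochasticity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volstoch)
```

## The generative model

A latent reward rate $x_t$ diffuses as a Gaussian random walk and is
observed through Gaussian noise:

$$x_t = x_{t-1} + e_t, \quad e_t \sim N(0, v_t), \qquad o_t \sim N(x_t, s_t).$$

The *volatility* $v_t$ (process-noise variance) and *stochasticity* $s_t$
(observation-noise variance) are themselves latent and dynamic. The default
dynamics place multiplicative Beta noise on the inverse variances
$z_t = 1/v_t$ and $y_t = 1/s_t$:

$$z_t = \eta_v^{-1}\, z_{t-1}\, \epsilon_t, \qquad
  \epsilon_t \sim \mathrm{Beta}\!\left(\tfrac{1}{2}\,\frac{\eta_v}{1-\eta_v},\, \tfrac{1}{2}\right),$$

and independently for $y_t$ with $\eta_s$. Since
$E[\epsilon_t] = \eta_v$, the chain is a martingale:
$E[z_t \mid z_{t-1}] = z_{t-1}$. We parameterize by the *update rates*
$\lambda_v = 1 - \eta_v$ and $\lambda_s = 1 - \eta_s$: larger $\lambda$
means a wider Beta and faster drift of the corresponding noise estimate.
An alternative dynamics (`dynamics_kind = "gaussian_log"`) lets
$\log v_t$ and $\log s_t$ follow Gaussian random walks with step standard
deviations $\sigma_v, \sigma_s$; the inference machinery is unchanged.

Both noise sources inflate outcome variance, but they are identifiable
because they move the lag-1 autocorrelation of outcomes in opposite
directions: volatility makes consecutive outcomes covary (the rate itself
moved), stochasticity decorrelates them (independent measurement noise).
`lag1_autocorrelation()` implements the standard Pearson estimator on the
series and its one-step lag; which estimator to use was an open choice and
this is the conventional one.

### Numerical choices in the generator

* Beta draws with shape $< 1$ can round to exactly 0 in floating point,
  which would pin an inverse variance at zero forever; draws are clamped at
  $10^{-12}$ (`diffuse_inverse_beta`). The clamp is far below any draw that
  occurs in practice and does not measurably bias the moments (checked in
  the test suite against the closed-form Beta moments at $10^6$ draws).
* The initial rate $x_0$ defaults to 0, matching the learner's prior mean.
* Constant-parameter designs are implemented as `fixed_noise` overrides of
  the stochastic dynamics (`constant_noise()`), so "true parameter"
  bookkeeping for recovery studies is explicit rather than emulated with
  degenerate dynamics.

## Inference: Rao-Blackwellized particle filtering

Conditional on $(v_t, s_t)$, inference over $x_t$ is exactly the Kalman
filter with gain $\alpha_t = (w_t + v_t)/(w_t + v_t + s_t)$. The filter
therefore samples only the two noise variables: each of $N$ particles
carries $(z^l, y^l)$ plus its own conditional Kalman statistics
$(m^l, w^l)$ and an importance weight $b^l$. Per trial:

1. **Prediction** — diffuse each particle's $z$ and $y$ by the Beta
   dynamics with persistence $1 - \lambda$ (a variable with $\lambda = 0$,
   or one clamped by a lesion, is left untouched).
2. **Weighting** — multiply each weight by the Gaussian predictive density
   $N(o_t \mid m^l,\, w^l + v^l + s^l)$ and renormalize; if the effective
   sample size $1/\sum_l (b^l)^2$ falls below half the particle count,
   resample systematically (single uniform offset $u \sim U(0, 1/N)$, comb
   $u + k/N$ against the cumulative weights) and reset weights to uniform.
3. **Update** — apply the Kalman recursion per particle with that
   particle's sampled $v^l = 1/z^l$, $s^l = 1/y^l$.

Reported per-trial signals (`m`, `w`, `alpha`, `v_hat`, `s_hat`) are weight
averages across particles, taken with the weights as they stand *after*
the conditional resampling step (uniform when resampling occurred). The
default particle count is 100, which is ample for these one-dimensional
noise posteriors.

### Design and numerical choices in the filter

* **Initialization.** All particles start at $z = 1/v_0$, $y = 1/s_0$ with
  uniform weights and the Kalman statistics at the prior
  ($N(0, 100)$ for the factorial designs, $N(0, 1)$ elsewhere, following
  the study parameterizations). Point initialization makes
  $\lambda = 0$ collapse the filter *exactly* onto the closed-form Kalman
  filter — a property the tests exploit as an oracle — and makes the
  lesioned models exact special cases rather than approximations.
* **Weight carrying.** Weights are carried multiplicatively across trials
  (standard sequential importance sampling) and reset only by resampling.
* **Effective sample size** uses the universal estimator
  $1/\sum b^2$; the resampling trigger is the ratio test at threshold 0.5
  (configurable via `ess_ratio_threshold`).
* **Log-space weighting.** Weights are computed as log densities and
  normalized by max-subtraction; if every density underflows (possible in
  near-deterministic tasks with outcome variance $10^{-6}$) the weights
  fall back to uniform with a warning rather than producing NaNs.
* **Variance update.** $w_{t+1}$ is computed as
  $s(w+v)/(w+v+s)$ rather than the algebraically identical
  $(1-\alpha)(w+v)$, avoiding cancellation when $\alpha \to 1$; the
  identity is asserted in the tests.
* **Resampling boundary.** A comb position exactly equal to a cumulative
  weight selects the *next* particle, so zero-weight particles are never
  selected and uniform weights reproduce the ensemble exactly for any
  offset. Offspring counts deviate from $N b^l$ by less than one.
* **RNG order.** One seeded stream per run, consumed in a fixed order
  (volatility draws, stochasticity draws, then the resampling offset when
  triggered; in choice tasks the softmax draw precedes the filters, which
  advance in option order). Identical inputs and seed give bit-identical
  traces.

### Lesioned models

`lesion = "fix_stochasticity"` (or `"fix_volatility"`) clamps the
corresponding variable at `lesion_value` — by default its initial value —
for every particle on every trial. The clamped module can no longer absorb
its share of experienced noise, so the other module inflates: the
stochasticity-lesioned model reads noisy outcomes as volatility and
*raises* its learning rate with stochasticity; the volatility-lesioned
model reads change as stochasticity and *lowers* its learning rate with
volatility. These reversals, and the accompanying misattribution in the
remaining noise estimate, are the package's central qualitative
predictions and are asserted in the acceptance tests.

## The task battery

Each constructor returns a `task_episode` (outcomes, true rates, phase
labels, correct option for choice tasks, and full generation metadata
including the seed). Defaults follow the simulated designs; where a study
did not print a structural parameter, the package fixes a documented
default and exposes it as an argument:

* **Factorial design** (`make_constant_2x2`): 200 trials, constant
  $v \in \{0.5, 1.5\}$ crossed with $s \in \{1, 3\}$; learner
  $\lambda_v = \lambda_s = 0.1$, $v_0 = 1$, $s_0 = 2$ (the averages of the
  true small/large values).
* **Switching task** (`make_switching_task`): rate 0.8 in stable blocks,
  alternating 0.25/0.75 in volatile blocks, outcome variance 0.01. Block
  structure is not printed in the source designs; the default is one
  90-trial stable block followed by one 90-trial volatile block with the
  rate flipping every 20 trials, the geometry of the two-block switching
  tasks this design emulates. Shorter alternating blocks dilute the
  volatile-stable learning-rate contrast because the stable-state gain
  needs tens of trials to settle.
* **Conditioned suppression** (`make_conditioned_suppression`): 100
  pretraining trials at 0.3 (weak shock), the last 5 replaced by omission
  trials (0) in the omission condition, then retraining at 1 (strong
  shock); noise variance $10^{-2}$; retraining length defaults to 20
  trials (not printed; only the first retraining trial enters the
  headline statistic).
* **Partial reinforcement** (`make_partial_reinforcement`): 100
  pretraining trials rewarded always (full) or on a randomized exact half
  (partial), then 20 extinction trials; noise variance $10^{-4}$.
* **Serial prediction** (`make_serial_prediction`): two outcome channels
  (tone-given-light, reward-given-light) run through two independent
  filters sharing no state; phase 1 (default 100 trials) pairs light-tone
  on every trial with reward on half; the shift condition's phase 2
  (default 40 trials, the shorter test phase) gives light-tone-reward on
  half of trials and light-nothing on the rest. Noise variance $10^{-6}$;
  learner $\lambda = 0.2$, $v_0 = s_0 = 0.5$; the lesioned model fixes
  volatility at $0.25 \times 10^{-6}$. The probe trial for the learning
  rate defaults to the last trial of phase 2 and is exposed as
  `probe_trial` because the originating description can be read as either
  that trial or the first test trial.
* **Probabilistic reversal** (`make_reversal_task`): 80 trials, two
  options, schedules 100/0, 80/20, 70/30, 60/40, one reversal at a trial
  drawn uniformly from 30-50, binary rewards plus noise variance
  $10^{-6}$. Simulated with softmax decision noise 3 (control) vs 1
  (lesioned, volatility fixed at 0.01).
* **Change-point schedule** (`make_changepoint_task`): piecewise-constant
  rate redrawn uniformly in [0, 10]; inter-change intervals of 5 trials
  plus an exponential draw (rate 0.05) rounded *up*, preserving the
  5-trial minimum; outcome variance 1 or 9; learner $\lambda_v = 0.4$,
  $\lambda_s = 0.2$, $v_0 = s_0 = 5$, prior variance 100 (the rate scale
  makes the wide prior the only sensible reading of the study's two prior
  settings).
* **Two-choice switching task** (`make_two_choice_task`): complementary
  reward probabilities (default 0.75/0.25) swapping between options every
  20 trials over 160 trials, binary rewards plus noise variance 0.01; an
  optional initial stable run (`stable_blocks`) supports
  stable-vs-volatile accuracy contrasts. Rewards are emitted as 0/1 plus
  the small Gaussian noise (outcomes are deliberately not binary).

Binary-reward tasks state in their documentation whether outcomes are
binary-plus-noise or rate-plus-noise; both options' potential outcomes are
generated per trial and the experiment runner decides what the learner
observes.

## Choice coupling and behavioral statistics

Choice tasks run one filter per option. The weighted posterior means map to
choice probabilities by softmax with decision-noise $\beta$
($p_i \propto e^{\beta m_i}$); the chosen option's outcome updates its
filter, while unchosen options receive a prediction-only update — their
noise samples diffuse and the Kalman variance grows by the sampled
volatility, the mean unchanged. This is the standard Kalman treatment of an
unobserved channel; the originating designs do not describe unchosen-option
updating, so the rule is isolated in `run_choice_episode()` where it can be
swapped. Pavlovian response probability uses the two-option logistic
`response_prob(value, beta)` against a fixed zero alternative; the exact
mapping was unspecified and this is the documented choice.

`win_stay_lose_shift()` binarizes noisy rewards at a configurable threshold
(default 0.5) and reports conditional rates with undefined components
flagged as `NA` rather than 0. `relative_log_learning_rate()` is the mean
natural-log gain over volatile-labeled trials minus stable-labeled ones.
Trials can be labeled by block (`phase`) or by the trial-wise classifier
`label_stability()`, which marks a trial volatile when the contingency
switched within its preceding 10 trials; the published description of that
classifier reads as its own negation ("no contingency switch" in the
window) which we take to be a wording slip — the window length and the
labeling are parameterized rather than silently fixed.

## The trait-anxiety cohort

Graded anxiety is modeled as the ratio $\lambda_v/\lambda_s$. Each
synthetic subject draws $\lambda_v \sim U(0, 0.2)$ and a trait value from
one of three subsets with means 0.5, 1, 3, truncated to (0.26, 4);
$\lambda_s = \lambda_v / \mathrm{trait}$. The within-subset distribution is
not specified in the originating design; we use a uniform centred on each
subset mean with half-width $\min(\mu - 0.26,\, 4 - \mu,\, \mu/2)$, chosen
so the subset means are honored exactly within the bounds. All subjects
share $v_0 = s_0 = 0.001$. Each runs the switching task; the per-set
Spearman correlation between trait and relative log learning rate is
negative, with the median across sets reported.

## Replication counts and problem sizes

The originating studies repeat simulations 1,000-40,000 times to shrink
standard errors below visibility. The package's defaults are scaled to
200-1,000 replications (50 sets for the cohort), at which every directional
contrast is stable across seeds; `full = TRUE` (CLI `--full`) restores the
original counts. The acceptance script uses 100-1,000 replications per
experiment and completes in a few minutes. Effect *directions* do not
depend on the replication count — only the error bars do — and the test
suite asserts directions, not magnitudes.

## What the simulations do and do not show

The generator produces exactly the environments the model assumes
(Gaussian diffusion, Gaussian observation noise, smoothly drifting noise
variances) plus the structured schedules of the task battery. Passing
tests therefore demonstrate internal consistency — correct inference under
the model's own assumptions and the predicted compensatory lesion effects —
not fit to any empirical dataset. Real conditioning data involve
valence effects, binary outcomes whose variance is tied to their mean,
context and latent-state effects at extinction, and subject heterogeneity,
none of which the generator emulates. Fitting the model to choice data is
out of scope.

## Known limitations

* The particle filter inherits Monte Carlo error; with near-deterministic
  outcomes (variance $10^{-6}$) the posterior over $(v, s)$ is strongly
  bimodal between "everything was volatility" and "everything was
  stochasticity" explanations, and individual runs can lock onto either
  mode (visible as a bimodal first-extinction learning rate in the
  full-reinforcement condition). Means across replications remain stable.
* Inference assumes the Beta-multiplicative dynamics even when data come
  from change-point schedules; this mismatch is intentional (the model is
  meant to be robust to it) but means `v_hat`/`s_hat` are calibrated only
  under matched dynamics.
* Choice tasks use independent filters per option; shared structure across
  options (e.g., coupled reward probabilities) is not modeled.
* No variational inference backend and no parameter fitting to data.
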