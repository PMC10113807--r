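---
title: "Ecological reservoir computing: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological reservoir computing: models, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The idea

Reservoir computing (RC) trains only a linear readout on top of a fixed
dynamical system (the *reservoir*) that nonlinearly transforms an input
stream. `ecoreserv` implements RC where the reservoir is an *ecological*
dynamical system, in three forms:

1. **Simplex-projection (empirical) reservoirs** (`erc_reservoir`). A single
   species' time series is turned into a state-space reconstruction by
   time-delay embedding: library rows
   $(x_t, x_{t-\tau}, \ldots, x_{t-(E-1)\tau})$ with next-step targets
   $x_{t+1}$. One reservoir update is
   $$X_{t+1} = f\!\left(W_{in} u_t + f_{simp}(X_t)\right),$$
   with $f$ the identity and $f_{simp}$ simplex projection: the forecast is
   the weighted average of the next-step values of the $E+1$ nearest library
   neighbours of the current state, with weights
   $w_i = \exp(-d_i/d_{\min})$ normalised to one. The forecast becomes the
   new first coordinate and the remaining coordinates shift down the lag
   register. The reservoir is thus an equation-free ecosystem model driven
   by a hypothetical forcing — scenario exploration run in a loop.
2. **The Lotka–Volterra toy reservoir** (`lv_reservoir`), the smallest
   explicit-equation ecological reservoir (size 2):
   $x' = x(r_x - r_x x + \beta_{xy} y)$,
   $y' = y(r_y - r_y y + \beta_{yx} x)$, with the grid-searched parameters
   $r_x = 3.0$, $r_y = 2.7$, $\beta_{xy} = -0.2$, $\beta_{yx} = 0.2$, driven
   as $X_{t+1} = W_{in} u_t + g(X_t)$.
3. **Echo state networks** (`esn_reservoir`) as the conventional RC
   baseline: $X_{t+1} = \tanh(W_{in} u_t + W X_t)$ with random sparse $W$
   rescaled to a requested spectral radius.

Reservoir states from several species can be **multiplexed**
(column-concatenated) into one large state; the effective reservoir size is
$\sum_i E_i$. The readout is ridge regression,
$W_{out} = (S^\top S + \lambda I)^{-1} S^\top Y$, with $\lambda = 0.05$ by
default, trained after discarding a washout transient (default 50 steps for
in-silico tasks).

`rc_fit()` bundles the chain (drive reservoirs, multiplex, fit readout) into
a classed model object with `predict`, `summary`, `coef`, `residuals`,
`plot` and `simulate` (closed-loop generation) methods.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `E`, `tau` | selected, 1 | embedding dimension and lag; `E` is chosen by leave-one-out simplex skill (Pearson correlation, ties to smallest `E`), `E_max = 10` |
| `input_scale` | 0.3 | input weights are Uniform[-1,1] times this |
| `sparsity` | 0 | fraction of input weights forced to zero |
| `lambda` | 0.05 | ridge penalty |
| `washout` | 50 | initial states discarded before readout training |
| `spectral_radius`, `density` | 0.95, 0.1 | ESN recurrent matrix controls |

Inputs and targets are z-scored with training statistics inside `rc_fit()`
(disable with `standardize = FALSE`); predictions are returned on the
original scale. The one deliberate exception is the LV reservoir: because
its state is an abundance vector with a finite viability basin, inputs are
scaled to $[-1, 1]$ by their maximum absolute value rather than z-scored,
which keeps input kicks ($\le 0.3$ after the input weights) from driving
abundances negative, where the quadratic map diverges.

## Benchmark tasks

* `task_lorenz()` — fixed-step RK4 integration of the Lorenz system
  ($\sigma = 10$, $\rho = 28$, $\beta = 8/3$), observing one component,
  z-scored. The default sampling is `dt = 0.02` with subsampling every 5
  steps, i.e. observations 0.1 time units apart — a standard benchmark
  interval at which one-step-ahead prediction is a genuine forecasting task
  (persistence correlation about 0.87) rather than near-identity copying,
  which is what a finer sampling degenerates to.
* `task_narma()` — the NARMA benchmark family. Order 2:
  $y_{t+1} = 0.4\,y_t + 0.4\,y_t y_{t-1} + 0.6\,u_t^3 + 0.1$; orders 3–10:
  $y_{t+1} = 0.3\,y_t + 0.05\,y_t \sum_{i=0}^{n-1} y_{t-i}
  + 1.5\,u_{t-n+1} u_t + 0.1$, driven by Uniform[0, 0.5] input, zero
  initial history. Under zero input NARMA2 settles on the analytic fixed
  point $(0.6 - \sqrt{0.2})/0.8 \approx 0.19098$, which the tests assert.
* `task_mackey_glass()` — the Mackey–Glass delay differential equation
  ($\beta = 0.2$, $\gamma = 0.1$, exponent 10, $\tau = 17$), RK4 with
  linear interpolation of the delayed state, sampled at unit intervals;
  used for closed-loop generation where the trained one-step readout feeds
  its own output back as the next input.
* `task_uniform()` — i.i.d. uniform input for memory and echo-state-property
  diagnostics.

## Diagnostics

* `nmse()` — $\sum(\hat y - y)^2 / \sum(y - \bar y)^2$.
* `esp_distance()` — the echo state property (ESP) check: run the same
  reservoir from two random initial conditions under an identical input and
  track the Euclidean distance between the state trajectories. With ESP the
  distance collapses (in the simplex reservoir it typically snaps to exactly
  zero once the two states select the same neighbours with numerically
  identical weights); under *different* input sequences it must not. The
  summary criterion `esp_converged()` compares the median of the last 10% of
  the curve against $10^{-3}$ times the median of the first 10%.
* `forgetting_curve()` — for each lag $k$ train a readout to reproduce
  $u_{t-k}$ from the states and evaluate Pearson $r$ on held-out data
  (Pearson $r$ is used throughout; the criterion is pluggable in the
  E-selection, where the same ambiguity arises). The baseline curve is the
  input's own lag-$k$ autocorrelation. Memory capacity is
  $\sum_{k \ge 1} r(k)^2$, truncated at `max_lag = 40` since the curves of
  interest decay within roughly 20 steps.

The ESP battery drives reservoirs with **z-scored** uniform inputs — the
same convention `rc_fit()` applies to every task input — so the diagnostic
probes the reservoir at the drive amplitude it actually experiences. (With
raw [0, 1] inputs the drive is about three times weaker than any task
applies, and convergence within 100 steps becomes marginal for some
species.)

## Synthetic ecological data

Because the empirical series the framework was designed around (fish-catch
records, quantitative prokaryote DNA time series, ciliate microcosm runs)
cannot ship with a package, two generators stand in for them. They are
first-class, tested code — not fixtures.

**Communities** (`simulate_community`): the $S$-species generalisation of
the two-species toy model,
$$x_{i,t+1} = \max\!\left(0,\; x_{i,t}(r_i - r_i x_{i,t} +
\textstyle\sum_{j \ne i} B_{ij} x_{j,t}) + \varepsilon_{i,t}\right),$$
with $\varepsilon \sim N(0, \sigma_p)$. Defaults, chosen once and kept:
$r_i \sim U(2.4, 3.2)$, sparse interactions $B_{ij} \sim U(-0.3, 0.3)$ at
connectance 0.3, $\sigma_p = 0.02$, burn-in 200 steps. The growth-rate range
mixes noisy-equilibrium and period-2/chaotic-edge species, which gives
sustained nonlinear fluctuations while keeping the reconstructed simplex
map predominantly contracting — the regime in which the empirical
reservoirs demonstrably show ESP. Strongly chaotic communities (growth
rates well above 3.2) produce expanding reconstructed maps whose reservoir
states do not synchronise on a 100-step horizon; that regime is available
by passing `r` explicitly but is not the default because it lacks the ESP
that the framework's diagnostics require of a usable reservoir.

**Driven population** (`simulate_driven_population`): a surrogate for a
temperature-driven unicellular population observed 5 times per input step.
The chamber temperature follows a first-order lag toward the set point
(fraction 0.35 of the gap closed per substep — "it takes time to heat the
medium"); the population follows a Ricker map
$p_{s+1} = p_s \exp(r(T)(1 - p_s/K(T)))$ with peaked piecewise-linear
thermal responses for $r$ and $K$; observations have Poisson-like noise
(variance proportional to the mean; zero noise supported). Growth rates are
kept below 1 per substep so the map contracts — trajectories started from
different population sizes synchronise under a common temperature sequence,
mirroring the common-signal synchronization observed in the real
microcosms. Three nutrient presets (low/med/high) differ in $K$ and $r$
scale and produce distinguishable dynamics. The true physiology of a real
ciliate population is explicitly *not* modelled; only the structural
properties (bookkeeping, contraction, temperature memory) matter, and only
those are asserted by tests.

**What passing tests do and do not show.** The generators reproduce the
structural features of the empirical data (noisy nonlinear fluctuation,
ESP, short-term memory, distinguishable conditions), not their spectra,
seasonality, observation error structure, or species interactions. Results
on synthetic data therefore validate the machinery, not ecological claims
about any particular real system.

## The real-time processing chain

`preprocess_counts()` detrends raw counts with a penalized regression
spline (`mgcv::gam`, basis dimension 10 by default) and returns the
relative residual $(c - \hat c)/\max(\hat c, \epsilon)$ — stationary and
approximately mean-zero. `time_multiplex()` reshapes the fine sequence into
a coarse-steps × substeps matrix (256 × 5 for a standard run);
`space_multiplex()` concatenates runs with provenance labels (three runs
give 256 × 15, six give 256 × 30). `recall_task()` fits a 1 × C readout
(no intercept, matching the printed weight-matrix shape) to reproduce the
input `lag` steps back — the "thermometer" readout — and
`horizon_prediction_task()` sweeps prediction horizons against a ridge
regression on the raw input value as the linear baseline. The train/test
protocol follows the replicate structure: replicate-1 runs train, replicate-2
runs test for recall; a temporal 70/30 split for the horizon sweep.

## Numerical choices and degenerate inputs

* Neighbour count fixed at $E + 1$; Euclidean distance, unweighted across
  lag coordinates; ties broken by smaller time label for reproducibility.
* $d_{\min} = 0$: uniform weights over the zero-distance neighbours
  (avoids 0/0).
* Leave-one-out E-selection excludes only the query's own row (no Theiler
  window; an exclusion set is exposed for callers that need one).
* Divergence guards: reservoir runs abort with the step index when any
  state coordinate exceeds $10^6$; closed-loop generation *flags* divergence
  and returns the partial sequence instead of erroring.
* Ridge at $\lambda = 0$ on a singular system raises
  "singular; increase lambda" rather than returning a pseudo-inverse.
* Zero-variance targets in `rc_fit` fall back to unit scale instead of
  dividing by zero.
* `tau > 1` state updates operate on the full lag register of length
  $(E-1)\tau + 1$; the reservoir constructors use $\tau = 1$, the
  convention under which the update rule's shift is exact.

## Problem sizes

The test-suite and acceptance computations use 300-point species libraries,
800 training / 300 test observations for prediction tasks, 10–50 species
communities, ESNs up to $N = 200$, and 1000-step closed-loop runs —
comfortably sized for a laptop while large enough that readouts with up to
~130 multiplexed state columns are well determined.

## Known limitations

* S-maps, convergent cross-mapping, multivariate embeddings and information
  processing capacity profiling are out of scope.
* The simplex reservoir's ESP is an empirical property of the reconstructed
  dynamics, not a guarantee; strongly chaotic libraries give reservoirs
  without ESP (the control diagnostics exist to detect exactly this).
* Multiplexed species reservoirs evolve independently given the shared
  input; interactions between species enter only through each species' own
  reconstructed library.
* The readout is batch ridge; no online/recursive variant, no output
  feedback during training.
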