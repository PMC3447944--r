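---
title: "Inferring lymphocyte transit times through a lymph node"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lymphocyte transit times through a lymph node}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Naive T lymphocytes recirculate continuously between blood and lymph
nodes: they enter a node from blood through high endothelial venules
(HEVs), search the paracortex for dendritic cells bearing their cognate
antigen and, failing to find one, leave through the efferent lymphatic and
return to blood. Long-term cannulation of a single node's efferent
lymphatic in sheep — the only species where this is surgically practical —
yields paired time courses of the percentage of dye-labelled cells in
blood (the input) and in efferent lymph (the output) over 100 h or more.

`lntransit` infers from such a pair the full probability distribution of
*transit times*: the time an individual cell spends inside the node. The
central modelling assumption is a linear time-invariant relation between
input and output,

$$ L(t) \;=\; c \sum_{\theta} B(t - \theta)\, p_\theta , $$

where $B(t)$ is the labelled percentage in blood, $L(t)$ in lymph,
$p_\theta$ the probability that a transit lasts $\theta$ hours and $c$ a
proportionality constant absorbing flow rates and pool sizes. Cells are
assumed to enter the node at a rate proportional to their frequency in
blood, and the blood curve is taken as *measured* — return of labelled
cells to blood after their first transit is not modelled (the closed-loop
simulator, below, quantifies what this simplification costs).

## The analysis grid

All distributions live on fifty two-hour bins $(0,2], (2,4], \dots,
(98,100]$ h, and efflux is modelled at the matching grid times $t = 2, 4,
\dots, 100$ h: fine enough to capture the fast early dynamics, coarse
enough not to over-interpolate the sparse late samples. Three conventions
are worth stating explicitly because the discrete convolution does not
determine them:

* **No zero-lag bin.** Transits shorter than the grid spacing are
  biologically implausible (a cell must cross the node) and a zero-lag
  column would duplicate the input itself, degrading the rank of the
  design matrix. The first bin is $(0,2]$ h.
* **Lag-0 input value.** Row $i$ of the input matrix needs $B(t_i -
  \theta_j)$ down to lag 0; blood at lag 0 is taken as the gridded value
  at the smallest grid time (2 h).
* **Out-of-range samples.** Before the first observation the series is
  back-filled with the first observed value, and beyond the last
  forward-filled. Late profiles are smooth and slowly varying, and flat
  extension avoids spline blow-up. Negative spline interpolants are
  clipped to zero (the data are percentages).

Interpolation is genuine interpolation, never smoothing: observed values
are reproduced exactly, by `approx()` for the linear method and an FMM
cubic spline for `cubic_spline`.

## Deconvolution: simplex-constrained (S-)LASSO

With the grid fixed, the model is $L = cBp$ with $B$ lower triangular. The
constant $c$ is estimated first, by nonnegative least squares *without*
a sum constraint: the L1 norm of the unconstrained solution is the natural
scale estimate, $\hat c = \|\hat q\|_1$ where $\hat q = \arg\min_{q \ge 0}
\|L - Bq\|^2$. The distribution is then the solution of

$$ \min_p \;\|L - \hat c B p\|^2 + \lambda \|Dp\|^2
   \quad\text{s.t.}\quad \textstyle\sum_j p_j = 1,\; p \ge 0 . $$

Because the entries are constrained nonnegative, the LASSO's L1 bound
$\|p\|_1 \le 1$ *is* the probability-simplex constraint, so the estimator
is a convex quadratic program and is solved exactly (Goldfarb–Idnani dual
active-set method). Numerical choices: a relative ridge of $10^{-10}$ on
the Hessian guards against ill-conditioned inputs; solution entries in
$(-10^{-9}, 0)$ are clipped to zero and the vector renormalised; median
transit ties (cumulative probability exactly 0.5 at a bin edge) resolve to
the lower bin.

$D$ is the second-difference operator ($48 \times 50$), so $\lambda$
penalises curvature — the natural reading of a roughness penalty that
keeps the problem quadratic. A first-difference variant is available via
`penalty = "first_diff"`. At $\lambda = 0$ the S-LASSO reduces exactly to
the plain LASSO.

**Choosing $\lambda$.** `concat_and_tune()` mirrors the experimental
logic: draw a training set of `n_train` animals *with replacement*
(duplicates stacked twice), stack their rescaled systems into one
regression, solve the S-LASSO along a grid of $\lambda$, and score each
candidate by the average per-animal SSE of predicted efflux on the animals
never drawn in that repetition. Each held-out animal keeps its own
$\hat c$, because the constant varies across animals and is estimable from
each animal alone. The default grid $\{0, 1, 2, 5, 10, 20, 50, 100, 200\}$
is log-spaced around the smoothing levels at which held-out error
typically bottoms out for three-animal training sets (a few tens). Fifty
repetitions are the default; all resampling is driven by one integer seed
and is bit-reproducible.

**Tail probing.** `tail_constraint_test()` re-solves the problem with the
last $n$ bins pinned to zero (forbidding transits longer than $100 - 2n$
h) and, as a control, with $n$ *random* bins pinned. If held-out error
grows much faster under tail pinning than under random pinning, the long
tail is a real feature of the data rather than a regularisation artifact.
The function returns the comparison table and leaves the interpretation to
the caller.

## Mechanistic models

### Discrete random walk

The node is abstracted as a line of $n$ vertices from the HEV face
(vertex 1) to the efferent exit (vertex $n$). Per time step of `dt_min`
minutes a cell moves forward with probability $q_f$, backward with $q_b$,
or stays with $q_s = 1 - q_f - q_b$. Vertex 1 is reflecting (a backward
move folds into staying — the schematic leaves the boundary open, and
reflection conserves probability without new parameters); vertex $n$ is
absorbing for the first-passage computation, so the $(1, n)$ entry of the
$k$-step transition matrix is the cumulative arrival probability and the
law $f_k$ is its increment. The iteration is a vector–matrix product per
step (O($n$) per step in the tridiagonal fast path, written in C++), never
a dense matrix power. Steps are binned onto the two-hour grid by
$k\,\mathrm{dt} \in ((t-2)\cdot 60,\; t \cdot 60]$; mass beyond 100 h is
reported as `tail_mass` and deliberately *not* renormalised away — a model
whose mass escapes the observation window should pay for it in the fit.

`fit_mc()` is a two-stage exhaustive search, coarse then fine: stage 1
scans $q_s \in \{0, 0.1, \dots, 0.9\}$, drift ratios $q_f/q_b \in \{1/4,
1/2, 2/3, 1, 3/2, 2, 4\}$, $n \in \{5, 10, \dots, 50\}$ and
$\mathrm{dt} \in \{1, 2, 5, 10\}$ min; stage 2 fixes $q_s$, $n$,
$\mathrm{dt}$ at their optima and refines $q_f$ (with $q_f + q_b$ fixed)
on a 0.01 grid. The ranges bracket plausible transit biology (10–100 h).
The returned SSE surface on the $(q_s, q_f/q_b)$ plane at the optimal $n$,
$\mathrm{dt}$ is the drift heat map: on data generated without drift its
valley sits on the $q_f/q_b = 1$ column.

### Steady state under reinjection

Outside antigenic challenge the node neither grows nor shrinks, so exits
balance entries. Closing the chain — vertex $n$ keeps its interior
behaviour but its forward flux re-enters at vertex 1 — gives a single
irreducible loop whose stationary vector $\pi$ ($\pi P' = \pi$, solved as
a linear system) is the predicted cross-sectional occupancy profile. For
near-zero drift it declines from the HEV face towards the exit.

### Continuous laws

The inverse Gaussian $\mathrm{IG}(\mu, \lambda)$ is the exact first-
passage law of Brownian motion with drift: with unit diffusion, barrier
distance $d$ and drift $v$, the passage time is $\mathrm{IG}(d/v, d^2)$.
Density and closed-form CDF are implemented directly (the CDF evaluates
its second term on the log scale to avoid overflow of $e^{2\lambda/\mu}$).
The Gaussian comparator represents synchronised directed migration and is
intentionally naive: its negative-time mass goes to the tail rather than
being truncated-renormalised, so it is scored as specified, not rescued.
Both are discretised by exact CDF differences per bin (adaptive quadrature
is used when only a density is supplied), and fitted by deterministic
multi-start Nelder–Mead on log-parameters (IG starts: $\mu \in \{10,
\dots, 60\}$, $\lambda \in \{10, 50, 100, 500, 1000\}$; convergence
tolerance $10^{-10}$).

## The synthetic-data generator

Real sheep time courses were never deposited, so every inferential claim
is tested by recovery on synthetic experiments with known truth.

The **open-loop** generator mirrors the model structure: blood is
$b_0 e^{-t/\tau}$ with $\tau = 7$ h by default (the middle of the
published 5–20 h lifetime range) and $b_0 = 10\%$; efflux on the grid is
*by definition* $c\,Bp^{\mathrm{true}}$; both channels are then sampled on
a realistic schedule and corrupted by noise. The `cannulation` schedule
reproduces the experimental cadence — blood at 2, 5, 10, 20, 30 min and 1,
2, 3, 4, 6, 12, 24 h, then daily; lymph every 4 h to 48 h, then every
8 h — and `uniform_2h` samples both channels on the analysis grid (the
clean-room setting for recovery tests). Measurement noise defaults to
multiplicative Gaussian with a 5% coefficient of variation; the
experiments report no noise magnitude, so 5% is a generator choice, and
the recovery tests sweep it. Truth families: inverse Gaussian, two-
component IG mixtures (for multimodal truths), point masses, and
random-walk laws. Because the generator needs a proper distribution on the
fifty bins, `make_truth()` by default *conditions the truth on exit within
100 h* (renormalising and recording the excluded tail as a diagnostic);
`condition_on_exit = FALSE` returns the raw binned law.

The **closed-loop** simulator drops the open-loop simplification: labelled
and unlabelled agents cycle blood → vertex 1 → walk → exit from vertex $n$
→ blood, with exponential blood residence. Its exit semantics match the
reinjection chain (a cell occupies vertex $n$ and leaves with probability
$q_f$ per step), which differs from the absorb-on-arrival first-passage
law by one holding time at the last vertex; the Little's-law check
therefore uses the exit-from-$n$ mean transit, obtained by a linear solve.
It verifies two facts the open-loop generator cannot: the steady-state
balance $\bar t = N/F$ (mean transit = node population / entry rate) and
the size of the bias incurred by deconvolving a time course in which
labelled cells *do* return to blood.

What passing the synthetic suite does **not** show: robustness to
non-stationary entry rates (antigen-driven shutdown), label loss or
dilution, heterogeneous cell subpopulations with distinct kinetics, or
real measurement error structure — none of which the generator emulates.

## Stochastic reference simulators

Two agent-level simulators act as independent cross-checks of the
analytic laws. `simulate_walkers()` steps individual walkers through the
chain without touching the transition-matrix code. `brownian_first_passage()`
is an Euler–Maruyama scheme with a Brownian-bridge crossing check inside
every step (crossing probability $\exp(-2(d-x_0)(d-x_1)/\mathrm{dt})$),
which removes the $O(\sqrt{\mathrm{dt}})$ boundary bias of the naive
scheme; at $\mathrm{dt} = 0.01$ h the distributional error is well below
the Monte-Carlo resolution of $10^5$ paths.

## Problem sizes

The shipped tests and the acceptance script run on: cohorts of 3–17
synthetic animals; $10^5$ walkers and $10^5$ Brownian paths for the
Monte-Carlo comparisons; 50 resampling repetitions for smoothing
selection; 20 independent cohorts for the model-ordering check; and
closed-loop populations of 22,000–55,000 agents over 160–240 simulated
hours. These sizes make every stochastic comparison decisive (3 standard
errors or better) while keeping a full run in minutes.

## Known limitations

* The deconvolution assumes time-invariance of the transit distribution
  over the 100 h window; antigen exposure during a run would violate it.
* $\hat c$ and $p$ are estimated sequentially, not jointly; with very
  noisy data the NNLS scale estimate inflates, which the S-LASSO cannot
  undo.
* The one-dimensional walk compresses three-dimensional node geometry into
  a stay probability; its parameters are effective, not anatomical.
* Median transit times are reported on the 2 h grid and inherit its
  resolution.

## A minimal session

```{r example}
library(lntransit)

spec <- truth_spec("inverse_gaussian", list(mu = 30, lam = 60),
                   blood_tau = 7, schedule = "cannulation",
                   noise = "gaussian_multiplicative", noise_param = 0.05,
                   seed = 1)
sim <- simulate_open_loop(spec)
sys <- estimate_c(build_convolution_system(
  interpolate_to_grid(sim$tc, "linear")))
d <- solve_lasso(sys)
transit_summary(d)          # mean and median transit, hours
transit_summary(sim$truth)  # ground truth for comparison
```
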