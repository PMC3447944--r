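# lntransit

How long does a naive T lymphocyte spend inside a single lymph node?
Recirculating T cells enter a node from blood through high endothelial
venules, search it for dendritic cells carrying their cognate antigen, and
leave via the efferent lymphatic. Long-term cannulation experiments in
sheep record the percentage of dye-labelled cells in blood (input) and in
efferent lymph (output) over 100+ hours; `lntransit` turns such a pair of
time courses into the full probability distribution of nodal transit
times, and asks whether that distribution looks like the first-passage law
of a random walk.

The package is aimed at quantitative immunologists and biostatisticians
working on lymphocyte recirculation kinetics, and at anyone who needs a
simplex-constrained deconvolution with honest uncertainty handling.

## The model

Efflux is a scaled convolution of the blood input with the transit-time
distribution *p* over fifty two-hour bins:

    L(t) = c * sum_theta B(t - theta) * p_theta        theta = 2, 4, ..., 100 h

or in matrix form **L = cBp** with **B** lower triangular. Estimation
proceeds in two steps:

1. **Scale**: `estimate_c()` solves the nonnegative least-squares problem
   min ||L − Bq||², q ≥ 0, and takes c as the L1 norm of the solution.
2. **Distribution**: `solve_lasso()` / `solve_slasso()` solve

       min_p ||L − cBp||² + λ||Dp||²   s.t.  Σp = 1, p ≥ 0

   exactly, as a convex quadratic program (with nonnegativity, the LASSO's
   L1 bound *is* the probability-simplex constraint). D is a
   second-difference operator, so λ penalises curvature; λ is tuned by
   resampling concatenated training animals and scoring held-out efflux
   (`concat_and_tune()`).

Against this empirical estimate the package fits three mechanistic
transit-time laws: the first-passage law of a discrete random walk with
stay probability (`fit_mc()`, with a drift heat map and a steady-state
occupancy profile under reinjection), the inverse Gaussian — the exact
Brownian-motion-with-drift first-passage law — and a deliberately naive
Gaussian comparator (`fit_continuous()`). A synthetic-data module
(`simulate_open_loop()`, `simulate_closed_loop()`) generates cannulation
experiments with known ground truth so that every inference step is
testable by recovery.

## Worked example

Simulate one cannulation experiment with a known inverse-Gaussian truth
(mean transit 30 h), then recover the distribution:

```r
library(lntransit)

spec <- truth_spec("inverse_gaussian", list(mu = 30, lam = 60),
                   blood_tau = 7, schedule = "cannulation",
                   noise = "gaussian_multiplicative", noise_param = 0.05,
                   seed = 1)
sim <- simulate_open_loop(spec)
sys <- estimate_c(build_convolution_system(
  interpolate_to_grid(sim$tc, "linear")))
sys
#> <convolution_system> animal sim_inverse_gaussian - 50x50 input matrix, c = 0.919

d <- solve_lasso(sys)
d
#> <transit_distribution> origin lasso: mean 28.6 h, median 24 h
transit_summary(sim$truth)$mean_h
#> [1] 29.7
```

The estimated scale c = 0.919 sits near the generating value 1 despite 5%
multiplicative noise and the irregular sampling schedule, and the
recovered mean transit (28.6 h) lands within a bin width of the truth
(29.7 h — the binned, within-100 h mean of IG(30, 60)).

The published per-animal summaries from the seventeen sheep cannulations
ship with the package:

```r
summarize_lifetimes(sheep_blood_lifetimes()$mean_lifetime_h)$median_h
#> [1] 7.3      # median mean lifetime in blood, hours
summarize_across(sheep_transit_summaries()$mean_h)
#> [1] 30.2     # median of per-animal mean transit times, hours
```

## The analysis workflow

Numbered drivers under `analysis/` rebuild the whole study on a synthetic
seventeen-animal cohort and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | generate the cohort (bimodal truth, per-animal scale and noise) |
| `02_blood_lifetimes.R` | early exponential blood fits, lifetime summary |
| `03_deconvolve.R` | per-animal LASSO distributions, confidence band, transit summaries |
| `04_smoothing_and_tails.R` | S-LASSO smoothing selection (training sets of 3 and 9), tail-constraint probe |
| `05_random_walk.R` | two-stage random-walk fit, drift heat-map surface, steady-state occupancy |
| `06_model_comparison.R` | five-model test-set SSE table |
| `07_closed_loop.R` | agent-based recirculation: Little's law and open-loop bias |

Run them in order from the repository root after installing the package.

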