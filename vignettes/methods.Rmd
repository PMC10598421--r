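---
title: "Models and methods behind phylosprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylosprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosprint)
```

phylosprint implements the full quantitative chain of a phylogenetic
comparative study of locomotor performance, leg armature and web use in
spiders: from raw high-speed-video tracking coordinates and leg measurements
up to trait-evolution models, phylogenetic regressions and bootstrap effect
sizes. This vignette explains each model, its assumptions, the tunable
parameters, and the design choices made where more than one defensible
option existed. Everything stated here about accuracy is computed by the
package's own test suite or by `scripts/acceptance.R`; no external data are
involved.

## Sprint speed from tracking coordinates

A trial is a series of x–y pixel coordinates, one per video frame (100–750
frames per second accepted; rates outside that range only warn). The chain
is:

1. **Velocity.** Per-frame-pair speed
   `v_i = dist(px) / px_per_cm * fps / Δframe` in cm/s, assigned to the
   interval midpoint. Gaps in the frame index are handled by the `Δframe`
   term. The choice of midpoint time stamps is immaterial at these frame
   rates.
2. **Smoothing.** A cubic smoothing spline (`stats::smooth.spline`) with the
   knot count fixed at `floor(N/2) + 1` (N = number of frames; the floor is
   the only sensible integer reading for odd N) and the penalty chosen by
   generalized cross-validation. The spline removes the oscillation of the
   tracked body point caused by the stride cycle, which otherwise inflates
   the maximum. Negative fitted speeds are clipped to zero (speed is a
   magnitude).
3. **Summary.** Sprint speed is the maximum of the smoothed series; mean
   speed is its mean (computing it on raw velocities is available via
   `use_smoothed_mean = FALSE`; the smoothed default is the cleaner
   companion statistic, and the two agree closely since smoothing is
   mean-preserving on these series). Both are reported absolute (cm/s) and
   relative to body length (bl/s).
4. **Aggregation.** Per individual, the maximum sprint over its trials; per
   species, the mean over its individuals.

**Trial inclusion.** Only runs in a roughly constant direction give a clean
sprint estimate. The straightness index (net displacement over path length)
is computed over 25 evenly spaced waypoints rather than raw frame steps:
frame-level tracking jitter inflates the step-sum path length without
changing the direction of travel, and at typical settings (1 px jitter,
250 fps) the raw index would reject every straight run. Loops and reversals
still score near zero at this resolution. Threshold 0.9 and the waypoint
count are configurable; both are package choices, since no quantitative
inclusion rule is fixed by convention. Trials, not frames, are the unit of
inclusion, and trials with fewer than 10 frames are dropped.

## Spination index and relative leg length

From long-format measurement tables (mm): the spination index is the summed
length of all spines visible in prolateral view on the measured front-leg
segments divided by the summed segment lengths (segments measured between
condyles, excluding coxa, trochanter and pretarsus; all spines counted,
including permanently erect dorsal and lateral ones). Relative leg length is
the summed hind-leg segment length over carapace width. Both are
dimensionless and invariant to the measurement unit. Species values average
specimens arithmetically — the natural choice when no within-species error
model is fitted.

## Discrete-trait models of web evolution

Web use (0 = cursorial, 1 = web) evolves as a two-state continuous-time
Markov chain along the time-calibrated tree. Three constraints:

* **ER** — gain and loss at one shared rate (1 free rate);
* **ARD** — gain (`q01`) and loss (`q10`) independent (2 free rates);
* **Dollo-constrained** — `q01 = 0`, so webs can only be lost. Under this
  model the root is fixed in state 1: with gains impossible, any observed
  web demands a web-bearing ancestor. ER and ARD default to an equal root
  prior; both priors are configurable.

Likelihoods use Felsenstein pruning with the closed-form 2×2 transition
matrix; the pruning implementation is verified against exhaustive
enumeration over all internal-state assignments on trees of 2–6 tips to
1e-10. Rates are optimized on the log scale in `[1e-8, 1e3]` per unit branch
length (one-dimensional golden-section search for ER/Dollo, multi-start
L-BFGS-B for ARD). Models are compared by AICc,
`-2 logL + 2k + 2k(k+1)/(n-k-1)` with n = tip count (the common convention),
and normalized evidence weights.

**Ancestral posteriors and stochastic maps.** Marginal node posteriors come
from the standard up–down message-passing pass (equivalent to re-rooting at
each node). Stochastic character maps are drawn exactly: node states by
backward sampling from the pruning partials, then each branch history
conditional on its endpoints by rejection sampling (forcing the first event
into the branch when the endpoints differ), falling back to a uniformization
bridge after 1000 rejections so heavy-rate branches cannot stall. Losses
(1→0) and gains (0→1) are tallied per map; under the Dollo constraint every
map has zero gains by construction, which the tests assert. Map node-state
frequencies are checked against the marginal posteriors (within 0.02 at
10,000 maps), and mean map counts against matched forward simulations.

## Continuous-trait models

Species-level traits follow a multivariate normal with mean `z0` and
covariance `sigma2 * T(C)`, where `C` is the Brownian-motion covariance
(shared root-to-MRCA path lengths) and `T` is:

* **BM** — identity;
* **OU** — single-optimum Ornstein–Uhlenbeck with the optimum tied to the
  root value and a fixed root on an ultrametric tree of height `T`:
  `V_ij = exp(-2α(T - t_ij)) (1 - exp(-2α t_ij)) / (2α)`. Non-ultrametric
  input is an error rather than a silent switch to the random-root form.
* **EB** — early burst, `V_ij = (exp(a t_ij) - 1)/a` with `a ≤ 0` and the
  Brownian limit as `a → 0` (taken exactly below `|a| < 1e-9`);
* **λ** — Pagel's lambda, off-diagonal entries scaled by `λ ∈ [0, 1]`
  (values marginally above 1 from optimization are clipped with a warning).

`z0` and `sigma2` are profiled analytically (GLS estimators) inside a
bounded one-dimensional search over the remaining parameter (`α` in
`[1e-8, 50/T]`, `a` in `[-10/T, 0]`, `λ` in `[0, 1]`); boundary candidates
are always evaluated so the Brownian limits are never missed. Likelihoods
are evaluated through Cholesky factorizations and verified against dense
inverses. Ancestral values (for BM and λ fits) are conditional means of the
joint tip-plus-node normal; for λ the tree is first rescaled (internal
branches × λ, terminal branches stretched to preserve tip depths) so its
tip covariance reproduces the λ transform exactly. Within-species
measurement error is not modelled.

## Phylogenetic regression and effect sizes

`phylo_lm()` regresses a trait on binary ecological predictors (web use,
cribellate silk, ground dwelling; coded 0/1 with the "absent" level as
baseline) with λ- or OU-structured residuals. The transformation parameter
is estimated by maximum likelihood (matching the convention of standard
phylogenetic regression software, not REML), with GLS coefficients profiled
per candidate; t-tests use `n - p` degrees of freedom and the unbiased
residual variance. `λ = 0` reduces exactly to ordinary least squares, and
fixed `λ = 1` matches textbook GLS with a dense inverse to 1e-9; the jointly
estimated fit is cross-checked against an independent GLS implementation
(`nlme::gls` with `ape::corPagel`). Analyses over alternative topologies are
a loop over supplied trees, one result block per tree.

Group effect sizes are unstandardized mean differences (trait units) with
percentile bootstrap confidence intervals, resampling species means within
groups (B = 5000 by default). Percentile-on-raw-differences is the default
because contrasts are most interpretable in bl/s or index units; the
bootstrap is seed-deterministic.

## Synthetic data: what it emulates, and what it does not

The generator module produces every input with known truth: birth–death
trees via `ape::rphylo` (the standard sampler conditioned on the number of
extant tips — preferred over a bare simulate-and-retry loop), binary
characters forward-simulated with their full event histories retained,
continuous traits drawn from the model-implied multivariate normal,
regression tables with a built-in group shift, and trajectories. A synthetic
trajectory integrates a smooth speed profile (default: a raised-cosine bump,
so acceleration is continuous as in a real sprint; a sharp-cornered profile
is available but its peak is intrinsically rounded by any smoother), adds a
sinusoidal body-centre oscillation (default amplitude 0.15 body lengths at
8 Hz — plausible stride values, configurable) and Gaussian pixel jitter
(default 1 px SD; the true jitter distribution of real footage is unknown
and this is an explicit assumption). Defaults: 250 fps, 40 px/cm, 1 cm body
length, 0.8–1 s trials.

Passing tests on these data show the chain recovers what it is supposed to
recover *under the stated noise model*; they cannot rule out problems
specific to real footage (non-Gaussian tracking failures, lens distortion,
fatigue effects) or to real trees (calibration error, topological
uncertainty beyond the supplied alternatives).

**Validation problem sizes** (all computed in the test suite and
acceptance script): enumeration checks on 100 random 2–6-tip trees; simmap
consistency at 10,000 maps on a fixed 6-tip instance; rate recovery at 300
tips (ER, q = 0.3) and 200 tips (BM σ², λ ∈ {0, 0.7}) over 100 seeds each
(median relative error well under 30%); PGLS type-I error at 100 tips over
500 null replicates (within [0.02, 0.09] at nominal 0.05); sprint recovery
within 5% of truth in ≥95/100 seeds; bootstrap CI coverage near 95/100. A
90-terminal synthetic pipeline run exercises the full chain end to end.

## Numerical notes and limitations

* Zero-length branches are rejected by default (`collapse_zero = TRUE`
  collapses them into polytomies); polytomies themselves are retained
  everywhere.
* Ultrametricity is judged at relative tolerance 1e-6 of tree height.
* Pruning partials are rescaled when they underflow, so likelihoods are
  stable to several hundred tips.
* The Mk machinery is hard-wired to two states; multi-state codings, hidden
  rates and model averaging beyond AICc weights are out of scope, as are
  multi-optimum OU, rate shifts and phylogenetic logistic regression.
* `sample_maps` reports the transition counts the printed summaries need;
  per-branch event logs are retained in the returned object.
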