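---
title: "Quantal-content fluctuation analysis: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal-content fluctuation analysis: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcinfer)
```

## The model

A chemical synapse is represented by `M` identical, independent docking
sites in the active zone. Each site is either empty or occupied by a
releasable synaptic vesicle (SV). Around the i-th action potential (AP) of
a train, three per-site probabilities act:

* `pr_i` — each docked SV fuses and releases transmitter with this
  probability when the AP arrives (the *release probability*); a fused
  site empties instantly;
* `pu_i` — each site still occupied after the AP loses its SV before the
  next AP (*undocking*, capturing transient docking and spontaneous
  release);
* `pd_i` — each empty site (including those just emptied by fusion) is
  refilled before the next AP (the *refilling probability*).

All three may vary arbitrarily with the stimulus number, which is how
facilitation (a rising `pr_i`) and upstream-pool depletion (a falling
`pd_i`) enter the framework. Writing `p_i` for the probability that a site
is occupied just before AP i, independence across sites gives a binomial
docked count and a binomial quantal content (QC),

$$b_i \sim \mathrm{Binomial}(M,\; p_i\, p_{r,i}), \qquad
  p_{i+1} = p_i(1-p_{r,i})(1-p_{u,i}) + \bigl(1 - p_i(1-p_{r,i})\bigr) p_{d,i},$$

so the mean QC is $M p_i p_{r,i}$ and the Fano factor is
$FF_i = 1 - p_i p_{r,i} = 1 - \langle b_i\rangle/M$: stronger depression
means noisier release, and the whole transient distribution is available
in closed form at every stimulus (`occupancy_recursion()`, `qc_pmf()`).
For constant probabilities the recursion solves explicitly
(`occupancy_closed_form()`), converging geometrically with factor
$\lambda = (1-p_r)(1-p_u-p_d)$ to the steady-state occupancy
$\bar p = p_d / (p_d + p_u + p_r(1 - p_d - p_u))$.

Two steady-state fluctuation statistics carry the information used for
inference:

$$FF = 1 - \bar p\, p_r, \qquad
  \rho = \frac{-p_d (1-p_r)\, p_r (1-p_d-p_u)}
              {p_r + p_d + p_u(1-p_r) - 2 p_d p_r},$$

the Fano factor and the lag-1 Pearson autocorrelation of the QC sequence.
Both are symmetric in $(p_r, p_d)$ when $p_u = 0$; $\rho$ is never
positive, is bounded below by $-0.125$ (attained only at
$p_r = p_d = 1/2$), and $1 - FF$ bounds both probabilities from below.

## What the estimators do

`empirical_stats()` computes the windowed mean QC, Fano factor and lag-1
correlation of a measured or simulated trace with 95% bootstrap
confidence intervals. The default burn-in of 10 stimuli discards the
initial depression transient of a 50-Hz train; the Fano factor is
bootstrapped on single values and the correlation on consecutive pairs,
since pair resampling is what preserves the lag-1 structure being
estimated (the statistic itself is computed on the raw steady-state
window, not detrended).

`solve_moments()` inverts the two steady-state equations for
$(p_r, p_d)$ at fixed $p_u$. For $p_u = 0$ the system reduces
analytically: with $s = p_r + p_d$ and $q = p_r p_d$, the Fano equation
gives $s(1-FF) = q(2-FF)$ and substitution into the correlation equation
collapses to $q = (1-FF) + \rho\,FF$, so the two probabilities are the
roots of a quadratic — an exact, deterministic inversion that makes the
swap-symmetric double root explicit. For $p_u > 0$ a Newton search from a
fixed 10×10 start grid (residual acceptance 1e-8, duplicate merge at
1e-6) finds all roots. Because the equations cannot distinguish the two
symmetric solutions, an observed normalized depression (steady mean QC
over first-stimulus mean QC) disambiguates: each root's implied
depression $\bar p$ is compared and the closer root flagged `selected`.
Without a depression measurement the high-`pr` root is flagged by
convention.

`fit_transient_ls()` and `fit_time_varying_refill()` fit the normalized
mean-QC time course, the former over constant $(p_r, p_d)$, the latter
over a refilling schedule (five free leading values plus a constant tail
by default, matching how transient refilling manifests at 50 Hz) with the
release probability held fixed. Both use deterministic multi-start
L-BFGS-B inside the open unit box (bounds 1e-6, gradient step 1e-7,
objective tolerance `factr = 10`), so repeated runs give identical
results; equal weights are used across stimuli. The schedule fitter's
MLE mode maximises the compound binomial–Gaussian marginal of evoked
amplitudes,
$\sum_b \mathrm{Bin}(b; M, p_i p_r)\,\mathcal N(a_i;\, b\langle c\rangle,\,
b\,CV_q^2\langle c\rangle^2)$, i.e. per-quantum variance adds linearly in
the released count, with $b = 0$ a point mass at zero amplitude. The sum
over $b$ is truncated to the support where the Gaussian factor is
non-zero, which is exact to double precision and keeps the 3000-stimulus
likelihood fast. If `M` is not supplied it is estimated by a preliminary
least-squares schedule fit and the plug-in
$M \approx \overline{QC}_{ss} / (\bar p\, p_r)$.

`eq_method()` implements the classical Elmqvist–Quastel estimator
(regress QC on cumulative QC over the first `k = 3` stimuli; pool = x-
intercept, `pr` = first QC / pool). Its no-replenishment assumption makes
it exact when `pd = 0` and biased downward otherwise — a bias the test
suite asserts, since it is the reason moment-based inversion and EQ can
disagree strongly on the same recording.

`feasible_region()` evaluates the three closed forms on a regular grid of
the unit square and intersects an upper Fano bound, a lower correlation
bound and a depression window; this is the graphical way to see how
fluctuation statistics confine a depressing synapse to the high-release-
probability corner even before solving any equations.

`rates_to_probs()`/`probs_to_rates()` connect the per-interval
probabilities to continuous-time docking/undocking rates of a two-state
site chain, $p_d = \frac{k_d}{k_d+k_u}(1 - e^{-(k_d+k_u)\Delta t})$ and
its exact inverse. The conversions use `expm1`/`log1p`; the inverse
requires $p_d + p_u < 1$ and becomes intrinsically ill-conditioned as the
chain approaches full mixing within one interval, which is why round-trip
accuracy is only guaranteed away from that boundary.

## The synthetic-data generator

`simulate_trial()` is the literal per-site Bernoulli model with the event
order: fusion at the AP, then undocking of surviving occupied sites, then
refilling of empty sites — at most one transition per site per interval.
This ordering is forced by the recursion itself: the survival term
$p_i(1-p_r)(1-p_u)$ implies a fused site cannot also undock, and the
refill term $(1-p_i(1-p_r))p_d$ implies fusion-emptied sites can refill
in the same interval. An aggregated fast path draws binomial counts on
the occupied/empty totals; it is equidistributed because the sites are
identical and independent, and the suite verifies the two paths against
the exact pmf by chi-square. Every simulation takes an explicit integer
seed; ensembles seed trial `t` with `seed + t - 1`, so any single trial
is reproducible in isolation.

`simulate_random_train()` replaces fixed intervals by i.i.d. exponential
or gamma intervals and recomputes the interval probabilities from the
kinetic rates per sampled gap — rates, not probabilities, are the
primitive there, since only rates make the interval length matter. This
is the regime where the QC is no longer binomial and its Fano factor can
exceed one.

`add_quantal_noise()` converts integer QCs into evoked amplitudes by
summing independent Gaussian quantal sizes (mean $\langle c\rangle$,
coefficient of variation $CV_q$), floored at zero without
renormalisation; at the regimes used here ($CV_q \le 0.5$) the clipped
mass is negligible. The matching closed forms are
$FF^e = \langle c\rangle(FF + CV_q^2)$ and
$\rho^e = \rho\, FF/(FF + CV_q^2)$, derived by the law of total
(co)variance and cross-checked against simulation.

The `generate_fixture("mntb_lso", seed)` preset emulates the auditory
brainstem recordings the inference pipeline targets: 3000 stimuli at
50 Hz, `pr = 0.93`, refilling schedule 0.92, 0.73, 0.66, 0.53, 0.12 then
0.51, `pu = 0`, all sites initially occupied, and quantal noise with a
22 pA mean and CV 0.3. No measured docking-site count is available for
this preparation; the preset uses `M = 100`, a round, realistic count
for a strong inhibitory brainstem connection — the steady-state Fano
factor (≈0.51) and correlation (≈−0.03) that the recovery tests check
are independent of `M`, so this choice affects only the amplitude scale.
What the generator deliberately does *not* emulate: measurement error in
converting postsynaptic currents to QCs, slow drifts in quantal size or
electrode access, heterogeneous site classes, and postsynaptic
saturation. Passing recovery tests on these fixtures therefore
demonstrates correctness of the estimators under the model's own
assumptions, not robustness to every artefact of real recordings.

## Numerical and design choices

* **Schedules** are an explicit prefix plus a constant tail
  (`qc_schedule()`); steady-state formulas always act on tail values.
* **Degenerate parameter sets** (zero steady-state denominators, zero
  first-stimulus QC, constant traces) raise errors naming the offending
  quantity rather than returning limits — silent limits mask
  configuration bugs.
* **Infeasible statistics** (e.g. $\rho < -0.125$ at $p_u = 0$, or
  root pairs falling outside the open unit square) are errors, not
  empty results.
* **Correlation minimiser.** The release probability minimising $\rho$
  at fixed $p_d$ is published in a form that is not a stationary point of
  the correlation expression itself; differentiating the correlation
  gives $p_r^{*2}(1-2p_d) + 2 p_d p_r^* - p_d = 0$, and
  `rho_argmin_pr()` implements that verified root (it agrees with the
  published form at $p_d = 1/2$, where the global minimum sits). The
  test suite checks it against a brute-force grid minimiser.
* **Lag-ℓ correlations** use $\rho_\ell = \rho_1 \lambda^{\ell-1}$ with
  $\lambda$ the subdominant eigenvalue of the per-site occupancy chain —
  the covariance propagates linearly through the chain beyond lag one.
  The form is derived, and the suite verifies it against Monte-Carlo
  correlations at long lags rather than trusting the derivation alone.
* **Optimisers** are all deterministic (fixed start grids, box
  constraints); non-convergence is reported in `diagnostics$converged`,
  never silently.
* **Problem sizes.** The test suite exercises the heavy stochastic
  checks at the sizes the theory calls for — 1e5-trial ensembles for
  pmf chi-square agreement, 1e5-stimulus trains for correlation checks,
  40 seeded 3000-stimulus recordings for bootstrap-coverage checks —
  which keeps the full suite around a few minutes on a single core.

## Limitations

The framework covers one homogeneous pool of independent, identical
sites under the stated event ordering. Heterogeneous site classes
(sums of binomials), interactions between sites, autoreceptor feedback,
postsynaptic receptor dynamics and raw-signal processing (PSC peak
detection) are out of scope. The undocking probability is not separately
identifiable from (FF, ρ) alone — it must be fixed when inverting the
moment equations, and the package exposes that explicitly via
`pu_fixed`.
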