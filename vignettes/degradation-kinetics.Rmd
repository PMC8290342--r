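---
title: "Modelling enzymatic degradation of silk fibroin sponges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enzymatic degradation of silk fibroin sponges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkdeg)
```

## The problem and the models

Lyophilized silk fibroin sponges degrade in protease solution over days to
weeks. Experiments track the remaining sponge mass per day, enzyme, enzyme
activity concentration $C_E$ (U/mL), water-annealing time (a crystallinity
label) and sampling method. `silkdeg` models the substrate concentration
$C_S(t)$ — remaining mass normalized by the *initial* cylinder volume, in
mg/mL — with two nested rate laws derived from the classical enzymatic
pathway $E + S \rightleftharpoons ES \rightarrow E + P$:

$$\frac{dC_S}{dt} = -\frac{k_{cat}\, C_S\, C_E}{K_M + C_S}
\qquad\text{(Michaelis–Menten)},$$

$$\frac{dC_S}{dt} = -k_f\, C_S\, C_E, \quad k_f = k_{cat}/K_M
\qquad\text{(modified first order, the limit } C_S \ll K_M\text{)}.$$

Both assume the enzyme concentration is uniform in space and constant in
time (the experimental designs agitate continuously and replace the enzyme
solution every 48 h), and neither models diffusion into the sponge, enzyme
activity decay between refreshes, or a mechanistic link from β-sheet content
to the constants — water-annealing time is carried only as a condition
label. The binding constants $k_1$ and $k_{-1}$ appear only through
$K_M = (k_{-1}+k_{cat})/k_1$ and are never separately identifiable from mass
loss curves; no function here estimates them.

Internal units are fixed: time in days, $C_E$ in U/mL, concentrations in
mg/mL, $k_f$ in mL/(U·day), $k_{cat}$ in mg/(U·day), $K_M$ in mg/mL.
`convert_rate_units()` re-expresses a fitted $k_f$ per enzyme mass
(mL/(mg·s)) and per mole (L/(mol·s)) given the specific activity (U/mg) and
molecular weight (g/mol). For Proteinase K we use 30 U/**mg** and
28,900 g/mol; note that activity values are sometimes quoted loosely as
"U/mL" in prose, but the conversion arithmetic is only dimensionally
consistent with a specific activity per milligram.

## Solving the saturable model

The Michaelis–Menten rate law is one-dimensional and autonomous, so instead
of stepping an ODE solver we solve its implicit integrated form per time
point:

$$K_M \ln\!\frac{C_{S0}}{C_S} + (C_{S0} - C_S) = k_{cat}\, C_E\, t.$$

`integrate_mm()` runs a safeguarded Newton iteration in $\log C_S$,
bracketed by the closed-form bounds
$C_{S0} e^{-s/K_M} \le C_S \le C_{S0} e^{-s/(K_M+C_{S0})}$ (with
$s = k_{cat} C_E t$), converging to a relative tolerance of $10^{-12}$ in
log-concentration. This is exact up to tolerance, has no step-size
artifacts, and never underflows because the bracket lives in log space;
concentrations are floored at zero on output since the models only reach
zero asymptotically while measured data can be exactly zero. The test suite
cross-checks this route against two independent ones: adaptive Runge–Kutta
integration of the rate law (`deSolve`, relative tolerance $10^{-8}$) and a
Brent-bracketing root finder on the same implicit relation.

## Weighted least squares and the nested 1-D search

All fits minimize $E = \sum_i w_i (C_S(t_i) - C_m(t_i))^2$ with
$w_i = 1/\mathrm{var}_i$, the inverse replicate variance at each day.
Fitting is done on the concentration scale; percent-remaining input is
rescaled by $C_{S0}$ first (the two scales differ by a constant factor per
condition, which changes weights but not the noise-free optimum). Since
replicate variance can be zero — certain once sponges fully degrade — the SD
is floored at 1% of $C_{S0}$ before inversion, and floored days are flagged.

Estimating $k_{cat}$ and $K_M$ jointly is notoriously unstable, so the
package never does: `fit_kcat_at_km()` minimizes over $k_{cat} \ge 0$ at
fixed $K_M$, and `km_error_surface()` repeats this over a log-spaced $K_M$
grid (default $10^{-3}$–$10^6$ mg/mL, 100 points — bracketing a 30 mg/mL
initial concentration by more than four decades each way and containing the
~14.5 mg/mL literature value for silk degradation by elastase). The scalar
minimizations are damped Newton–Raphson iterations: analytic gradient and
Hessian for the exponential model, analytic sensitivity
$\partial C_S/\partial k_{cat} = -C_E\, t\, C_S/(K_M + C_S)$ with a
Gauss–Newton Hessian for the saturable model; convergence at relative step
$< 10^{-10}$ or gradient $< 10^{-12}$, at most 100 iterations, golden-section
fallback. Starting values come from a weighted log-linear regression of
$\ln C_S$ on $C_E t$ (closed form, deterministic), and each grid point
warm-starts from its neighbour's solution scaled to preserve
$k_{cat}/K_M$ — the sweep runs from large $K_M$ downward, where the
log-linear start is most accurate. `fit_first_order()` fits the pooled
exponential directly, sharing one $k_f$ across conditions (each keeps its
own $C_{S0}$); pooling enzyme concentrations of 0.01 and 0.1 U/mL this way
is the standard combined analysis.

## Deciding between the models

For data generated by first-order kinetics, the error surface has a
characteristic degenerate shape: $E$ decreases monotonically as
$K_M \to \infty$ while $k_{cat}/K_M$ plateaus at $k_f$. `classify_kinetics()`
codifies this with two kinds of thresholds:

* **plateau flatness** over the top decade of the grid is numerical —
  relative change of $E$ and of $k_{cat}/K_M$ below $10^{-3}$ (measured
  against $\max E$ over the grid, so that noise-free surfaces whose plateau
  is at machine zero are handled stably);
* **interior-dip depth** is statistical. The models are nested with one
  extra effective parameter, so under first-order truth the best interior
  $K_M$ improves $E$ by roughly a $\chi^2(1)$ draw on the residual scale
  $\hat\sigma^2 = E_{\min}/(N-2)$. A dip only counts as evidence of
  saturable kinetics if it exceeds
  $\max\{10^{-3}\max E,\; \chi^2_{0.95}(1)\,\hat\sigma^2\}$; anything
  shallower is a tie, resolved toward the largest $K_M$ — the more
  parsimonious first-order law.

The statistical margin matters. A fixed relative tolerance classifies a
large share of noisy first-order datasets as saturable, because fitting
$K_M$ to noise *always* buys a few percent of $E$; calibrating the dip
threshold to the nested-model null restores the expected behaviour (about
95–99% of Gaussian-resampled first-order datasets classify as first order at
$\alpha = 0.05$, the package default). With noise-free data
$\hat\sigma^2 = 0$ and the numerical tolerance alone governs, so exact
saturable data with an interior optimum are still detected no matter how
small the residuals.

## Monte-Carlo uncertainty

`mc_generate_replicates()` draws each per-day value from
$\mathcal N(\text{mean}_i, \text{sd}_i)$ — a parametric resampling of the
summary statistics, *not* a bootstrap of raw replicates — keeping the
original weights, truncating negative draws at zero (a config flag retains
them for sensitivity analysis). One root seed spawns one derived sub-stream
per replicate set, so results do not depend on evaluation order.
`mc_first_order_uncertainty()` reports the mean and SD of $k_f$ across
refits (study-scale default 10,000 sets); `mc_mm_degeneracy_fraction()`
classifies the error surface of each resampled set (default 1,000 sets) and
reports the fraction degenerate to first order. Non-converged replicate fits
are dropped and counted rather than redrawn (redrawing would bias the
sample); more than 5% failures raises a warning. Finite-$K_M$ estimates from
the non-degenerate sets are heavily skewed — many sit near the grid
boundary — so they are reported raw and summarized with median/IQR alongside
mean ± SD.

## The synthetic study generator

`simulate_study()` emulates the standard sponge-degradation design: sampling
days 1–7, 11, 14, 21, 28; a continuous method (repeated weighing of the same
sponge, $n = 3$, 3 mm radius × 4 mm height) and a discrete method
(destructive sampling, $n = 5$, 1 mm × 2 mm); initial silk concentration
30 mg/mL (3% wt./v). Replicate noise is Gaussian around the true model
curve, truncated at zero; the default is a constant SD of 10% of $C_{S0}$ at
every day, which reproduces the scatter scale visible in published
degradation curves, and per-day SD vectors can emulate time-varying scatter.
Scenario presets (one per published experimental cell, with the reported
rate constants as synthetic truth) make the pipeline demonstrable end to
end; they are demonstrations, not reconstructions of anyone's raw data.

What the generator does *not* emulate: handling damage from repeated
weighing (the likely cause of continuous-method rate constants differing
from discrete ones — an optional per-method rate factor can impose such a
discrepancy as a scenario, without claiming its cause), wet-vs-oven-dried
mass differences between the methods, batch effects between silk
preparations, and non-Gaussian or autocorrelated replicate errors. Passing
tests on synthetic data therefore validate the estimation machinery, not
these aspects of real experiments.

Two systematic effects of the truncated-Gaussian generator are worth
knowing. Days whose true concentration is far below the noise SD acquire a
positive plateau (the mean of a truncated Gaussian), which biases $k_f$
slightly downward for conditions that degrade early in the window; and
designs whose degradation is essentially complete before the first sampling
day carry almost no information, so estimates there are wide. The recovery
properties in the test suite are framed as aggregate coverage across outer
replicate datasets for exactly this reason.

## Zero-mass days

`day_of_zero_mass()` runs, per day, a two-sided one-sample t-test of the
replicate percent-remaining values against 0% — the comparison is to the
fixed value zero, so no equal-variance issue arises — and reports the
earliest day with $p > \alpha$ (default 0.05). This is "failure to detect
remaining mass", not formal equivalence testing, and is documented as such.
Conventions: all-zero replicates count as similar to zero; zero-scatter
replicates around a positive mean count as clearly nonzero. No
multiple-testing correction is applied across days by default (matching
common practice in degradation studies); Holm adjustment is available via
the `adjust` argument. A useful monotonicity property follows directly:
lowering $\alpha$ can only enlarge the set of days flagged similar to zero.

## Problem sizes and reproducibility

The package defaults target study scale (10,000 / 1,000 Monte-Carlo sets,
100-point $K_M$ grid). The test suite and the acceptance script use reduced
sizes chosen to exercise the same behaviour at interactive cost: 200–500
Monte-Carlo sets, 25–40 grid points, and 3 outer replicates per cell in
recovery sweeps. All randomness flows from explicit seeds; identical seeds
give bit-identical simulated tables, resampled sets, and reports, and the
pipeline writes a manifest (config, seed, versions) sufficient to re-run any
analysis.

## Known limitations

* Model discrimination is asymmetric by design: parsimony ties go to the
  first-order law, so weakly saturable data (with $K_M$ near or above the
  sampled concentration range, or degradation that never approaches the
  Michaelis bend) will read as first order. That is a property of the data's
  information content, not a bug, but it means "first_order_limit" should be
  read as "no evidence of saturation over this concentration range".
* Uncertainty is exclusively the Gaussian parametric Monte Carlo described
  above; there are no Hessian-based confidence intervals and no bootstrap of
  raw replicates.
* Weights treat per-day variances as known once estimated; with $n = 3$–$5$
  replicates they are themselves noisy, which the Monte-Carlo machinery
  propagates only partially (the weights are held fixed across resamples).
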