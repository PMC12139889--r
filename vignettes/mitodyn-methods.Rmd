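---
title: "Modelling mitochondrial fission-fusion dynamics as a relaxation oscillator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mitochondrial fission-fusion dynamics as a relaxation oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodyn)
```

## The model

Mitochondria continually fragment and re-fuse. Fission is driven by the
GTPase DRP1, recruited to the outer membrane by the adaptor proteins
MiD49/MiD51; fusion is driven by the mitofusins MFN1/MFN2 together with
OPA1 and counteracts DRP1 accumulation. The antagonism of an autocatalytic
activator and a delayed inhibitor, coupled through an intermediary, is the
same wiring that makes the Belousov-Zhabotinsky (BZ) chemical reaction
oscillate, and mitodyn models mitochondrial dynamics with the
three-variable Oregonator reduction of that chemistry:

$$
\epsilon \,\dot x = q y - x y + x(1 - x), \qquad
\epsilon' \dot y = -q y - x y + f z, \qquad
\dot z = x - z,
$$

with dimensionless concentrations $x$ (fission factor, DRP1 — the
activator), $y$ (intermediary factor, MiD49/51) and $z$ (fusion factor,
MFN1/2 and OPA1 — the delayed negative feedback). The parameters are the
two time scales $\epsilon$ and $\epsilon'$, the rate constant $q$, and the
stoichiometric feedback factor $f$ that sets how strongly fusion-factor
production responds to the network state. Because
$\epsilon' \ll \epsilon \ll 1$, the intermediary relaxes on a much faster
layer than the activator, producing the sharp-peaked relaxation waveform
typical of the Oregonator rather than a sinusoid.

Four named regimes are built in (`mito_presets()`): the classical
`oregonator` scaling, and the `normal` ($f = 1$), `diseased`
(cancer-like, $f = 0.6$ with faster time scales) and `therapy`
($f = 1.2$) regimes of the mitochondrial mapping. For all four the
interior steady state

$$
x^* = \tfrac{1}{2}\!\left[(1 - q - f) + \sqrt{(1-q-f)^2 + 4q(1+f)}\right],
\quad z^* = x^*, \quad y^* = \frac{f x^*}{q + x^*}
$$

is linearly unstable (`fixed_points()` reports Jacobian eigenvalues and a
stability label), and the flow settles on a limit cycle: sustained
antagonistic oscillation of the fission and fusion machinery.

One naming caveat: in some tabulations of this reaction scheme the roles
of $y$ and $z$ are swapped. The package fixes the convention stated above
— $y$ is the intermediary (MiD49/51), $z$ the fusion factor — and uses it
consistently in every report and plot.

## Numerical choices

**Integration.** The system is stiff ($\epsilon'$ down to $1.2\times
10^{-4}$), so `mito_simulate()` uses `deSolve::ode()` with `lsoda` (an
implicit BDF scheme when stiffness is detected) and the analytic Jacobian.
An explicit default was rejected outright. Defaults: horizon $t_{end} =
100$ dimensionless units (tens of cycles at the presets), dense uniform
output at $\Delta t = 0.001$, relative tolerance $10^{-8}$, absolute
$10^{-10}$. Integration is deterministic: identical inputs give
bitwise-identical trajectories.

**Initial conditions.** No canonical initial state exists for this model;
the default $(0.1, 0.1, 0.1)$ lies off the cycle and away from both fixed
points. Because the cycle is the only attractor in the positive octant at
the preset parameters, any generic positive start reaches the same orbit —
the test suite verifies period agreement within 0.5% across random
starts — and the choice is configurable everywhere.

**Transients.** The first 30% of the horizon is discarded before any
metric is computed (`post_transient()`). The Poincaré return distances
show the approach to the cycle is complete well before that point.

**Positivity.** Concentrations must stay non-negative. Undershoots within
$10\times$ the absolute tolerance are tolerated and reported, never
clipped — clipping would mask solver trouble (`check_positivity()`).

## Oscillation metrics

`oscillation_metrics()` extracts, per variable over the post-transient
window: the period (mean inter-peak interval), frequency (its reciprocal),
amplitude (mean peak minus mean trough value — the full swing, matching
the visual reading of a waveform, not the half-swing), and the trapezoidal
time average as the mean level.

Peaks are local maxima whose topographic prominence exceeds 10% of the
series' global range. Relaxation peaks are sharp and high-prominence, so
this threshold rejects solver ripple without losing the shallower
intermediary oscillations; it is exposed as `prominence_fraction`. Peak
locations are refined by a three-point parabolic fit, which keeps period
estimates stable (below 0.1% movement) under halving of either the output
step or the solver tolerances. A variable with fewer than three prominent
peaks is flagged non-oscillatory rather than given meaningless metrics.

The fission-fusion phase relation is summarised as the mean delay from
each $x$-peak to the next $z$-peak, also expressed as a fraction of the
$x$-period. A peak-to-peak definition was preferred over cross-correlation
because the waveforms are strongly non-sinusoidal; the lag fraction is
stable across cycles (coefficient of variation below 2% at all presets).
"Wavelength" language for time series is read as the temporal period
throughout — the model has no spatial dimension; period, frequency and
amplitude are always reported separately.

## Phase plane and stability boundary

`phase_orbit()` projects the post-transient trajectory onto a variable
pair and quantifies closure via the Poincaré section $\{x = x^*,\ \dot x >
0\}$, anchored at the interior fixed point to guarantee transversality:
consecutive section crossings (linearly interpolated) should coincide on a
limit cycle, and their distances fall below $10^{-3}$ of the orbit
diameter at every oscillatory preset. `orbit_winding()` confirms the fixed
point lies inside the cycle. `nullclines()` returns the closed-form curves
on a 2-D slice (by default the third variable is held at its fixed-point
value, so all three nullclines meet at the fixed point), each point
polished to a derivative residual below $10^{-8}$.

`param_sweep()` re-integrates across a grid of one parameter (default:
seven log-spaced points spanning four-fold below to four-fold above the
preset value, bracketing it symmetrically) and classifies each point as
oscillatory by the three-peaks rule, cross-checked against the sign of the
leading eigenvalue — two independent detectors, so a transient miscount
cannot silently pass. `oscillation_boundary()` locates the stability
boundary by bisection on the leading eigenvalue real part; at normal time
scales the oscillatory window in $f$ closes near $f \approx 2.28$, and
integrations just below/above that value oscillate/decay as the linear
analysis predicts. Parameters are validated but never clamped: sweeps
beyond the preset values are the point of the module.

## Condition contrasts

`condition_report()` integrates the normal, diseased and therapy regimes
and evaluates six named directional verdicts on the relative changes
(disease: fission frequency up, intermediary amplitude down, fusion mean
level up; therapy, against the *diseased* baseline: the reverse
directions). The time-averaged level operationalises "concentration" for
the fusion factor, since bulk comparisons integrate over unsynchronised
oscillations. Verdicts are strict inequalities with a 1% relative-change
deadband, so "no major change" is machine-checkable, and each verdict is a
pure function of the stored deltas. Verdicts that fail numerically are
reported as failures, never suppressed: under the printed presets the
therapy regime in fact oscillates *faster* than the diseased one, so the
"therapy lowers fission frequency" verdict does not hold, while the other
five do. The truth values are invariant to tolerance tightening and to the
choice of positive initial state — they are attractor properties.

## Synthetic observations

`generate_observations()` emulates the structure of a two-condition
expression comparison without any external data: the true signal per
condition is the time-averaged level of each factor, and replicates are
drawn with multiplicative lognormal noise parameterised by its coefficient
of variation (expression-like measurements are positive and right-skewed;
the lognormal is mean-matched so the expected replicate equals the true
level, and its draws are strictly positive, making the non-negativity
truncation vacuous). Defaults — 6 replicates, CV 0.1 — reflect a typical
small-replicate bulk comparison. Draws use R's Mersenne-Twister generator
with inversion sampling, so a seed reproduces a dataset bitwise on any
platform. `contrast_observations()` applies the two-sided Welch
(unequal-variance) t-test per variable.

What the generator does *not* emulate: platform effects, normalisation,
gene-level multiplicity, or any quantitative mapping from model
concentrations to expression units — the mapping from dynamics to "levels"
is a labelled package convention, adequate for testing the contrast logic
(type-I error calibrated at 5% ± 2% under the null; between-condition
signs recovered in ≥ 99% of draws at CV 0.05), not for biological
inference about real measurements.

## Problem sizes and limitations

The shipped tests and the reproduction script integrate at the default
horizon ($t_{end} = 100$, $10^5$ output points) for attractor-level
claims, and at shorter horizons ($t_{end} = 20{-}60$) where only
structural behaviour is exercised; Monte-Carlo calibration uses 1000
null datasets and 200 signal datasets of 6 replicates each.

Known limitations: no stochastic (Gillespie) simulation of the underlying
reaction list — the deterministic ODE reduction *is* the model; no spatial
patterning; no continuation software behind the boundary finder (plain
eigenvalue bisection, which suffices for a single sign change); verdicts
describe this model's behaviour, not a claim about what real tissue must
do.
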