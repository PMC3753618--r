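---
title: "Quantifying locus segregation dynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locus segregation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusdrift)
```

## The problem

During the cell cycle of slow-growing bacteria, the replication-origin
locus sits near mid-cell, is replicated, remains cohered with its sister
for some minutes, and then the two foci separate and move to the
quarter-cell positions — the future mid-cells of the daughters. The motion
is strongly stochastic: individual trajectories are dominated by
fluctuations, and the segregation bias is only visible statistically
across hundreds of synchronized cell cycles. This package implements that
statistical analysis: MSD scaling, step-size statistics, and the
spatially resolved drift velocity from which equilibrium positions,
spring stiffness and an order-of-magnitude force can be read off.

## Coordinates, synchronization and intervals

Positions are fractions of cell length measured from mid-cell, which
removes cell growth from the signal; valid values lie in [−0.5, +0.5] and
out-of-range rows are *dropped*, never clamped, to avoid biasing tail
statistics. Trajectories are synchronized to the splitting of the focus
(t = 0) and oriented left–right using a second, fiducial locus channel so
that directional statistics are comparable across cells.

Two conventions are our own constructions where the underlying
experimental convention is ambiguous:

* **Split detection.** A real split must show two foci for at least
  `sustain = 2` consecutive frames; transient double detections are a
  tracking artefact. The split time is the first frame of the sustained
  run, and a valid full-cycle trajectory has exactly one such run,
  starting after the first frame and lasting to the end of the record.
  Trajectories violating this (re-merging foci, multiple sustained runs,
  no split) are excluded with a logged reason.
* **Interval boundaries.** The four analysis windows are half-open:
  Pre-Replication t < −10, Cohesion [−10, 0), Rapid-Translocation
  [0, 10), Post-Segregation t ≥ 10 (minutes). The split frame itself
  cannot be resolved into two foci, so MSD and step analyses of windows
  opening at t = 0 start at t = 1 min.

## Mean-squared displacement

`compute_msd()` uses the combined time-and-ensemble average: every
(track, start-time) pair with both endpoints inside the window
contributes. For the 10-minute windows this maximizes the number of
pairs; the cost is that pairs within a track are statistically dependent,
which is why `fit_power_law()` bootstraps whole trajectories, not pairs,
for the standard error of the exponent (1000 resamples by default,
seeded). The fit is a least-squares line on log MSD vs log lag; the
intercept is reported as the raw generalized diffusion constant without a
conventional factor of 2, since conventions differ when the exponent is
not 1. Default fit ranges are 1–10 min for post-split windows (the window
length caps usable lags) and 1–20 min pre-split.

Two analytic limits anchor the estimator: noise-free constant-velocity
tracks give exponent 2 to machine precision (the log–log line is exact),
and independent-increment tracks give exponent 1. Calibration tests run
20 independent 400-track ensembles at each exponent in
{0.38, 0.56, 0.74, 1.0} and require the mean recovered exponent within
±0.02.

## Step statistics and the Gaussian null

For steps δx over δt, the drift velocity is v = ⟨δx⟩/δt and the effective
diffusion constant D_eff = var(δx)/(2δt). The Gaussian-excess statistic
compares the empirical fraction of steps beyond k standard deviations
with the tail mass of a moment-matched Gaussian; because no threshold is
canonical we default to k = 2.5 and also report the maximum excess over
k ∈ {2, 2.5, 3}. After the split, the default selection keeps only the
right-destined focus so the bias has a definite sign; mirror-pooling
(left focus with negated positions) is offered because it doubles the
sample under left–right symmetry, which the unimodal occupancy
distributions support.

The lag-h step autocorrelation is pooled within tracks and normalized by
pair counts (mean pair product over mean squared step), so edge steps
that enter no pair do not attenuate the estimate. Closed forms used as
oracles: fractional Gaussian noise of exponent α has lag-1 increment
autocorrelation 2^(α−1) − 1; a sampled Ornstein–Uhlenbeck spring has
−(1 − e^(−δt/τ))/2.

## Drift field, equilibria and relaxation time

`compute_drift_profile()` bins steps by their *start* position (bin width
0.05 relative units, minimum 25 steps per bin by default; under-occupied
bins are flagged absent, not zero). Binning by start position makes the
profile directly comparable to the conditional mean of the sampled spring,

v(x) = −(x − x_eq)(1 − e^(−δt/τ))/δt,

which is the per-bin oracle used in testing. Each bin also records the
occupancy-weighted mean start position `x_mean`; slope fits and
conditional-mean comparisons use `x_mean` rather than the geometric bin
centre, because occupancy varies across a bin wherever the stationary
density is curved and the centre would bias outer bins.

Equilibria are zero crossings of v between adjacent populated bins
(linear interpolation), classified by the sign of a local weighted-fit
slope; a crossing with positive slope is unstable (the mid-cell position
immediately after the split). For stable equilibria the relaxation time
is recovered by inverting the *discrete* slope, τ = −δt/log(1 + s·δt):
for τ = 10 min sampled at 1 min the naive −1/s would misreport τ by
about 5%. The SE of τ is propagated from the weighted-regression slope
SE by the delta method. The default fit window is |x − x_eq| ≤ 0.15,
wide enough for ≥ 6 populated bins at the default occupancy yet inside
the linear regime of the synthetic spring.

## Force inference

In the overdamped Langevin picture the drag force γẋ balances the
applied force, whose time-averaged part produces the drift:
⟨ẋ⟩ = F̄/γ. With the Einstein relation γ = k_BT/D_eff (temperature fixed
at the 30 °C growth temperature, 303 K; k_BT computed, not hard-coded)
and positions converted to metres through a representative cell length
(per-frame lengths are used when the track table carries them), the bin
force is F(x) = γ·v_phys(x). The report annotates, rather than asserts,
the comparison of the peak |F| with a 1 pN motor-scale reference: the
Einstein relation in an active, viscoelastic cytoplasm is an
order-of-magnitude assumption, which the annotation states explicitly.

## The synthetic generator

Three modes, because no single tractable process reproduces every
observed statistic at once — a white-noise spring cannot generate
sub-diffusive scaling, and pure fractional noise has no restoring drift:

1. **White-noise spring** (`simulate_ou_tracks()`): exact
   Ornstein–Uhlenbeck transition sampling (conditional mean
   ρ = e^(−δt/τ), noise variance Dτ(1 − ρ²)), so the stationary variance
   is exactly Dτ and the binned-drift oracle holds exactly. Used for
   drift, equilibrium and relaxation-time ground truth.
2. **Fractional tracks** (`simulate_fbm_tracks()`): increments are
   fractional Gaussian noise sampled by Davies–Harte circulant embedding
   (Cholesky fallback when the embedding fails), giving
   MSD(τ) = 2Dτ^α exactly in expectation. Used for exponent ground
   truth.
3. **Split cycle** (`simulate_split_cycle()`): a full cell cycle —
   spring at mid-cell, split time drawn N(60, 10²) min truncated to the
   cycle, then two daughters spring-centred at ±0.25 — with optional
   fractional driving noise (the fractional increments replace the white
   noise in the spring update; an approximation, as the exact fractional
   spring process is out of scope), an optionally elevated diffusion
   constant in the [−10, 10) min window around the split, localization
   noise (default σ = 0.005 relative units, small and configurable since
   the experimental localization error is not quantified) added to the
   reported positions last, and exponential length growth
   L(t) = L₀·2^(t/T_gen) with L₀ = 2.5 µm for physical conversion.

Defaults emulate the study conditions: ~400 cell cycles, 1-min sampling,
120-min generation time, τ = 10 min, quarter-cell post-split equilibria.
The base diffusion constant defaults to D = 2.5 × 10⁻⁴ rel²/min, chosen
so the stationary fluctuation amplitude √(Dτ) = 0.05 cell lengths is
visually comparable to experimental kymographs; the experimental value
in physical units is not printed in the sources we reproduce, so this is
a representative placeholder, configurable throughout.

What the generator does **not** emulate: focus-detection dropouts and
localization-error correlations, asymmetric segregation pathways,
cell-to-cell parameter variability, and any coupling between the two
daughters after the split. Passing tests therefore validate the
estimators on data with known ground truth; they do not certify the
biological conclusions on real microscopy data.

## Problem sizes and numerics

Simulation-based tests use 150–400 cells (or tracks) of 30–120 frames —
matching the scale of the emulated experiment — with fixed seeds;
estimator-recovery tolerances (±0.03 on exponents, ±15% on τ, ±10
percentage points on the epoch-resolved D_eff increase) reflect the
Monte-Carlo spread at that scale. Degenerate inputs are handled
explicitly: zero-variance steps give D_eff = 0 and no excess statistic;
lags with non-positive MSD are dropped from log–log fits and fewer than
three surviving lags is an error; a drift profile with no sign change
yields an empty (valid) equilibrium set; a non-restoring slope is an
error for the relaxation-time fit, not a negative τ.

## Known limitations

* The spring + fractional-noise mode is an approximation to a true
  fractional Langevin process; its drift profile is still exactly the
  spring's, but its MSD interpolates between the fractional and confined
  regimes.
* The relaxation-time SE is a delta-method propagation of the slope SE,
  not a full trajectory bootstrap.
* Post-split focus identity in loaded data relies on the focus labels in
  the track table (plus `label_foci()` relabelling by destination side);
  no nearest-neighbour re-linking across detection dropouts is
  performed.
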