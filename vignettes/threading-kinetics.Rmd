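---
title: "Two-step threading intercalation kinetics from constant-force stretching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step threading intercalation kinetics from constant-force stretching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threadkin)
```

## The measurement and the model

A double-stranded DNA molecule is held at constant force in an optical trap
while a bis-intercalating ligand binds from solution. Each intercalation
event locally lengthens the duplex, so the complex extension, recorded as a
per-base-pair excess `dx(t)` over the bare-DNA extension at the same force,
reports the binding reaction in real time. For a dimeric ligand whose two
aromatic moieties insert sequentially, the binding of one ligand at a site
follows the two-step scheme

    L + site  <=>[k1*C / k_-1]  mono  <=>[k2 / k_-2]  bis

where `k1` (nM^-1 s^-1) is the bimolecular on-rate of the first moiety,
`k_-1` its off-rate, and `k2`, `k_-2` the forward and reverse rates of the
unimolecular conversion to the doubly intercalated state. The slow step is
rate-limited by a conformational change that threads the linker between the
two moieties through the duplex, not by intercalation itself.

The mean site occupancies obey a linear two-state-plus-empty kinetic
system, so a trace that starts from ligand-free DNA relaxes as a
bi-exponential,

    dx(t) = dx_eq - dx_f e^(-k_f t) - dx_s e^(-k_s t),

whose rates are the two eigenvalues of the 2x2 relaxation matrix. When the
first step is much faster than the second (`k1*C + k_-1 >> k2 + k_-2`) the
eigenvalues reduce to the pre-equilibrium forms `k_f = k1*C + k_-1` and
`k_s = k2 * k1*C / (k1*C + k_-1) + k_-2`. Both the exact eigenrates
(`observed_rates_exact()`) and the pre-equilibrium approximation
(`observed_rates_preequilibrium()`) are implemented; the ratio
`(k1*C + k_-1)/(k2 + k_-2)` is reported as a diagnostic, with a warning
below 10 (the literature only requires "much greater"; 10 is this
package's configurable operational threshold).

Force enters through Bell's model: each elementary rate scales as
`k(F) = k0 exp(F x / kBT)` with a signed transition distance `x` (nm), and
each equilibrium constant as `K(F) = K0 exp(-F x0 / kBT)` with
`x0 = x_plus - x_minus`. Positive distances mean the complex lengthens
towards the transition state, so force accelerates that step. `kBT`
defaults to 4.05 pN nm (20 degrees C) and is an argument everywhere.

## Elasticity and occupancy

Extensions are converted to occupancies with the extensible worm-like
chain. The WLC interpolation

    x(F) = x_max * (1 - 1/(2*sqrt(F*A/kBT)) + F/S)

is used as written — no exact numerical WLC solution is substituted —
because the reference polymer parameters were themselves obtained with this
interpolation, and mixing elasticity models would bias the occupancy scale.
Fractional occupancy is the linear interpolation
`theta = (x - x_ds(F)) / (x_sat(F) - x_ds(F))` between the bare and
saturated curves; it is returned unclipped by default (with a warning
outside [-0.05, 1.05]) so that fitting stages see unbiased values, and is
clamped only on explicit request.

`fit_wlc()` is an unweighted least-squares fit by default — the source fits
state no weighting scheme — with an optional per-point `sigma`. The
packaged saturated-curve fixture uses the five-force grid 5, 10, 20, 35,
50 pN; the original five constant-force saturation points are not listed
anywhere, so this grid is a documented package choice spanning the entropic
and enthalpic regimes.

## The two analysis routes

**Kinetic route.** Each trace is fitted to the bi-exponential
(`fit_trace()`); the fast/slow rates at several concentrations are
decomposed into the four elementary rates (`decompose_rates()`); the rates
at several forces are extrapolated to zero force by log-linear Bell fits
(`fit_force_dependence()`). Equilibrium constants follow from the rates,
`Kd1 = k_-1/k1`, `K2 = k2/k_-2`, `Kd = Kd1/K2`.

**Equilibrium route.** The same trace fits also yield amplitudes. The
equilibrium amplitude follows the simple isotherm
`dx_eq = dx_sat * (C/Kd)/(C/Kd + 1)`, and under the assumption that the two
intercalation events lengthen the complex equally, the fast mode carries a
share `f/2` of it, where `f = (C/Kd1)/(C/Kd1 + 1)` is the mono-state
probability. The amplitude ratio `dx_f/dx_s = (C/Kd1)/(C/Kd1 + 2)` then
depends only on `Kd1`. Fitting occupancy and ratio versus concentration per
force, and the resulting constants versus force, gives an independent
zero-force parameter set (`equilibrium_route()`). The half-share constant
(0.5) is a module-level setting, not an inline literal, so its sensitivity
can be probed.

`consistency_report()` places the two routes side by side with ratios and
overlap-within-uncertainty flags; the two routes agree only
semi-quantitatively on real data, and the packaged reference table
preserves that disagreement rather than reconciling it.

### Decomposition variants

`decompose_rates()` defaults to the two-stage fit that mirrors the
published procedure: a linear fit of `k_f(C)` fixes the first-step rates,
then a linear fit of `k_s` against the pre-equilibrium factor fixes the
second-step rates. This is transparent and stable, but it inherits the
pre-equilibrium approximation: with the reference rates the validity ratio
is only ~5-7 at 20 pN and low concentration, and simulated noiseless
pipelines show a resulting systematic error exceeding 10% on the worst
rate (`k2`). Two
alternatives are provided:

* `"exact"` — a per-force joint fit of all four rates to the exact
  eigenvalues, removing the approximation bias;
* `"global"` — one pooled fit of the whole force-concentration grid with
  the Bell law coupling forces (`fit_global_bell()`), eight parameters
  against every measured rate pair.

The global variant exists because the bis-state off-rate `k_-2` is nearly
unidentifiable at a single high force, where it is a small additive offset
to `k_s`: per-force estimates are censored at zero often enough to bias the
Bell extrapolation of `k_-2` and its transition distance. Pooling the grid
resolves this, at the price of assuming the Bell law globally instead of
testing it per force. The package's own parameter-recovery studies use the
global variant for exactly this reason; the default remains the two-stage
fit so that the standard analysis reproduces the published procedure.

### Numerical choices

* Trace fits use Levenberg-Marquardt with non-negativity bounds on
  amplitudes and rates, initialised by exponential peeling (tail fit for
  the slow mode, log-linear fit of the early residual for the fast mode)
  plus a small set of restarts at fast/slow rate ratios of 5-80. Restarts
  are scored by residual sum of squares with a 2% penalty on solutions
  whose modes collapse (ratio < 3) or whose slow rate falls below
  0.5/duration — the latter are drift surrogates, not resolved modes.
* A nested-model comparison guards against inventing a second mode: if a
  single exponential fits within the improvement expected from two extra
  degrees of freedom, the single-mode result is returned with
  `single_mode = TRUE`.
* Fitted modes are ordered so `k_f >= k_s`; results with `k_f/k_s < 3` are
  flagged `modes_resolved = FALSE` (the reference system separates its
  modes roughly ten-fold).
* The start-of-trace constraint `dx_f + dx_s <= dx_eq` is enforced with a
  tolerance of five residual standard deviations, since noise legitimately
  lets a fitted trace start slightly below zero excess extension.
* Joint and global fits optimise log-rates (positivity, scale-free steps)
  with distances bounded to ±1 nm, from three starting points (data-driven,
  generic magnitudes, flat), keeping the best by deviance.
* Rate series are inverse-variance weighted when per-point uncertainties
  are available, unweighted otherwise; estimates are invariant to uniform
  rescaling of the uncertainties.

## The free-energy landscape

`build_landscape()` places the five states — non-intercalated, first
transition state, mono, second transition state, bis — on the elongation
axis built from the transition distances (`x1 = x_+1 - x_-1`, etc.), with
the bis state as the zero-energy reference. The non-intercalated minimum
sits at `ln(C/Kd)` (in kBT), so it is level with the bis state at `C = Kd`
and is the only state whose energy moves with concentration. Barriers
follow from rates through the attempt-rate convention
`dG = kBT ln(k0_attempt / k)`, with `k0_attempt = 1 s^-1` by default;
absolute barrier heights are meaningful only relative to this convention
and are always reported with it.

The mono-state energy has two conventions because the zero-force reference
values were fitted independently and are not mutually consistent: the
ratio of the two fitted dissociation constants (`ln(Kd1/Kd) = ln(35/15) =
0.85 kBT`) and the independently fitted second-step constant
(`ln(K2) = ln(1.8) = 0.59 kBT`). `mono_convention` selects one explicitly;
neither is silently preferred, and both printed values are reproduced.

```{r landscape}
fx <- flex_ru2_parameters()
l <- build_landscape(fx$rates0, fx$distances, Kd = fx$kinetic$Kd,
                     Kd1 = fx$kinetic$Kd1, concentration = 15)
l
barrier_heights(l, "mono", "forward")
```

## What the synthetic generator emulates — and what it does not

`simulate_trace()` generates constant-force traces whose mean follows the
two-step scheme exactly: the mean-field backend integrates the linear ODE
for the site fractions (and is verified against the closed-form
bi-exponential to 1e-9), while the Gillespie backend simulates `n_sites`
independent sites with exponential waiting times (verified to converge on
the mean field at large `n_sites`). The extension readout gives a
mono-intercalated site half the saturated per-site elongation, matching
the equal-step assumption of the amplitude analysis.

Default study conditions mirror the constant-force protocol: forces 20, 30
and 50 pN; ligand 1, 3, 5 and 7 nM; 600 s traces at 1 Hz. Measurement
noise defaults to 0.002 nm/bp — no instrument noise figure is published,
so this is an order-of-magnitude choice at which the two modes remain
visibly resolvable, and it is configurable, as is an optional linear drift
(default zero). Free ligand is held constant (flow-cell excess, no
depletion), and each simulated trace starts from ligand-free DNA, as in
the experiments where every relaxation uses a fresh molecule.

The key simplification is site independence: no neighbour exclusion, no
cooperativity, no sequence heterogeneity. This matches the simple-isotherm
analysis the pipeline implements, which means parameter recovery on these
simulations validates the estimation machinery, not the isotherm
assumption itself. Real traces also carry instrument drift and correlated
noise that the i.i.d. Gaussian model understates. Note also that the
scheme's true equilibrium occupancy (with its half-length mono state)
differs from the two-state isotherm by a few percent at intermediate
saturation, so the equilibrium-route `Kd` carries a small model bias even
on perfect data — visible in the consistency report of any simulated
experiment.

## Parameter recovery: what is checked, at what size

The recovery study (in the test suite and the acceptance script) simulates
the full 3-force x 4-concentration grid, 600 s at 1 Hz, noise 0.002
nm/bp, and runs `analyze_experiment(decomposition = "global")` end to end:
20 replicate pipelines, with medians compared against the generating
zero-force rates (tolerance: factor of 2) and transition distances
(±0.05 nm), plus one noiseless pipeline (rates within 10%; distances
essentially exact). These sizes keep the whole study around ten seconds
while the medians are stable to the seed set; they are the package's
chosen problem sizes for routine verification.

The reference parameter tables themselves (polymer rows, zero-force rates,
distances, binding constants) are fitted values from the original
stretching experiments; without the raw tweezers data they are not
independently reproducible, and they enter here as generator truth and
fixture values only.

## Known limitations

* The pre-equilibrium default decomposition is biased where the time-scale
  separation is marginal (low force, low concentration); use `"exact"` or
  `"global"` when that matters.
* `k_-1` and `k1` estimates at the lowest force ride on small fast-mode
  amplitudes near the noise floor; their zero-force extrapolations have
  heavy-tailed errors across replicates (medians are well behaved, single
  experiments less so).
* The landscape is a zero-force construction; force-tilted landscapes are
  not implemented.
* No neighbour-exclusion (lattice) binding model; occupancies near
  saturation on real DNA will deviate from the simple isotherm.
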