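# threadkin

Analysis of two-step ("threading") DNA bis-intercalation kinetics measured
by constant-force single-molecule stretching.

When a dimeric intercalator such as a flexibly linked ruthenium complex
binds DNA held at constant force in an optical trap, every intercalation
event lengthens the duplex, and the extension-versus-time trace records the
binding reaction directly. For ligands whose two aromatic moieties insert
sequentially,

    L + site  ⇌[k1·C / k₋1]  mono  ⇌[k2 / k₋2]  bis

the relaxation is bi-exponential,
`dx(t) = dx_eq − dx_f·e^(−k_f t) − dx_s·e^(−k_s t)`, with rates given by the
eigenvalues of the linear scheme (pre-equilibrium limit:
`k_f = k1·C + k₋1`, `k_s = k2·k1C/(k1C + k₋1) + k₋2`). Every elementary
rate is force-dependent through Bell's model,
`k(F) = k⁰·exp(F·x†/kBT)`, so fitting rates across forces yields the
zero-force rates and the signed transition-state distances x†, and from
them the equilibrium constants (`Kd1 = k₋1/k1`, `K2 = k2/k₋2`,
`Kd = Kd1/K2`), the per-step elongations (`x_i = x₊i† − x₋i†`), and the full
zero-force free-energy landscape of the non-, mono- and bis-intercalated
states.

The package is written for single-molecule biophysicists analysing
constant-force trace data — and for anyone who wants to study how well such
a multi-stage pipeline recovers known parameters, since it ships a
synthetic-trace generator (mean-field ODE and stochastic Gillespie
backends) that emulates the whole experiment.

What it provides, as classed S3 fitting functions with
`print`/`coef`/`predict` methods:

* `fit_wlc()` / `wlc_extension()` — extensible worm-like-chain elasticity,
  and `occupancy_from_extension()` for the extension-to-occupancy scale;
* `fit_trace()` — bi-exponential relaxation fits with exponential-peeling
  initialisation, restarts and nested-model guards;
* `decompose_rates()` — elementary rates from rate-vs-concentration series
  (two-stage pre-equilibrium, joint, or exact-eigenvalue fits);
* `fit_force_dependence()` / `fit_global_bell()` — Bell-law extrapolation
  to zero force, per rate or globally across the whole grid;
* `equilibrium_route()` — the independent amplitude-based estimate of the
  binding constants, and `consistency_report()` to compare routes;
* `build_landscape()` / `barrier_heights()` — the free-energy profile
  versus elongation at a stated concentration and attempt rate;
* `simulate_trace()` / `simulate_experiment()` — synthetic data;
  `analyze_experiment()` — the full pipeline in one call;
* `flex_ru2_parameters()` — packaged reference parameters of the
  flex-Ru2/dsDNA system (polymer table and zero-force binding table).

## Worked example

Simulate a full constant-force experiment (3 forces × 4 concentrations,
600 s at 1 Hz, 0.002 nm/bp noise) from the packaged zero-force truth, and
run the complete analysis:

```r
library(threadkin)
fx  <- flex_ru2_parameters()
sim <- simulate_experiment(seed = 1, noise_sd = 0.002)
an  <- analyze_experiment(sim$traces, decomposition = "global", quiet = TRUE)
an
#> Two-step intercalation analysis: 12 traces, 3 forces (global decomposition)
#>
#> Zero-force elementary rates (kinetic route):
#> Elementary two-step intercalation rates at 0 pN
#>   k1    0.002016 +/- 0.00063 nM^-1 s^-1
#>   k_m1  0.06941 +/- 0.015 s^-1
#>   k2    0.005624 +/- 0.0011 s^-1
#>   k_m2  0.003852 +/- 0.00082 s^-1
#> Transition distances (nm):
#>     k1   k_m1     k2   k_m2
#>  0.181 -0.062  0.084 -0.168
```

The generating truth was k1 = 1.8e-3 nM⁻¹s⁻¹, k₋1 = 0.068 s⁻¹,
k2 = 5.8e-3 s⁻¹, k₋2 = 3.6e-3 s⁻¹ with distances (0.19, −0.06, 0.08,
−0.15) nm: every rate is recovered well within a factor of two and every
distance to a few hundredths of a nanometre. The analysis object also
carries the per-force rates, the amplitude-route constants, and a
kinetic-vs-equilibrium consistency table.

The zero-force free-energy landscape at the reference parameters, with the
ligand concentration set to the overall Kd (which levels the end states):

```r
l <- build_landscape(fx$rates0, fx$distances, Kd = fx$kinetic$Kd,
                     Kd1 = fx$kinetic$Kd1, concentration = 15)
l
#> Zero-force free-energy landscape (C = 15 nM, attempt rate 1 s^-1, mono convention: Kd_ratio)
#>  label elongation energy_kBT
#>    non       0.00      0.000
#>    TS1       0.19      3.612
#>   mono       0.25      0.847
#>    TS2       0.33      5.997
#>    bis       0.48      0.000
```

Read: intercalation of the first moiety lengthens the complex by 0.25 nm
over a 3.6 kBT barrier; threading the linker to reach the bis state adds
0.23 nm more over the dominant second barrier; at 15 nM ligand the bound
and unbound ends of the profile are isoenergetic. Barrier heights are
relative to the stated 1 s⁻¹ attempt rate.

## The methods vignette

`vignettes/threading-kinetics.Rmd` documents the model and its
assumptions, the decomposition variants and why the recovery study uses
the global Bell-constrained fit, the numerical choices (initialisation,
restarts, flags, tolerances), what the synthetic generator does and does
not emulate, and the known limitations.
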