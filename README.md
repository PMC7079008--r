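# redoxkin

Kinetic analysis of protein disulfide-bond reduction from spectroscopic
time courses.

## What problem this solves

Reducing a structural disulfide (SS) bond with TCEP or DTT is a routine
step in protein chemistry, but in compact folds — Trp-cage miniproteins
being the canonical example — the reaction can take hours to days, far
longer than standard protocols assume, and it may never complete because
dissolved oxygen re-oxidizes the free thiols. `redoxkin` is for anyone who
monitors such a reduction by near-UV CD or ¹H NMR and wants defensible
rate constants, half-lives and uncertainties out of the raw traces.

## The model

A four-reaction mass-action mechanism (concentrations in mmol/L, time in
minutes):

```
SS + Red  --k1-->  2SH + Ox      (second-order reduction)
2SH + O2  --k2-->  SS            (second-order reoxidation)
2SH       --k3-->  SS_precip     (first-order precipitation)
   Ø      --k4-->  O2            (zero-order oxygen ingress)
```

integrated with a stiff ODE solver and fitted to observed concentration
series by Levenberg–Marquardt least squares with Student-t confidence
intervals (n − p degrees of freedom). Around the core sit:

* the closed-form second-order half-life
  `t½ = ln(2 − c_SS,0/c_Red,0) / (k1 (c_Red,0 − c_SS,0))` with its
  excess-case rules,
* Arrhenius analysis (`Ea = −slope·R` from ln k vs 1/T),
* the exponential dependence of half-life on outer helix length
  (`t½ = a·exp(b·n)`),
* the steric factor `x = n·RMSD / helicity` and CSD cage descriptors,
* signal conversions: CD ellipticity → concentration (affine map), NMR
  integral ratios → concentrations, CPMG intensity ratios → R₂,
* a convex two-component factorization of thermal far-UV CD spectrum
  ensembles (folded/unfolded fractions),
* a synthetic-data generator with known ground truth for every stage.

## Worked example

Simulate the reference monitoring experiment (0.113 mmol/L protein,
18-fold molar excess of TCEP, 40 log-spaced samples to 3300 min, 2 %
Gaussian noise) and recover the rate constant:

```r
library(redoxkin)

design <- synthetic_design(truth = rate_constants(k1 = 8.03e-4),
                           ss0 = 0.113, red0 = 18 * 0.113,
                           t_end_min = 3300, n_points = 40,
                           noise_sigma = 0.02, seed = 42)
syn <- synth_time_course(design)
fit <- fit_mechanism(syn$series)
fit
#> Redox mechanism fit: 80 points, 1 parameter(s), SSE = 0.0004603
#>     estimate std_error ci_half_width rel_sd_pct identifiable
#> k1 0.0008132 9.999e-06      1.99e-05       1.23         TRUE
```

The true `k1 = 8.03e-4 L mmol⁻¹ min⁻¹` is recovered within 1.3 %, with a
95 % interval of ±2.0e-5 and a relative standard deviation of 1.2 %. The
implied half-life under these conditions:

```r
half_life(fit$estimates[["k1"]], 0.113, 18 * 0.113)
#> [1] 425.6967   # minutes; ~431 min at the true k1
```

Temperature dependence and the helix-length correlation, from published
rate-constant tables:

```r
arrhenius_fit(c(15, 25, 37), c(3.05e-4, 7.68e-4, 1.15e-3))
#> Arrhenius fit: Ea = 44.46 kJ/mol, ln A = 10.568, R^2 = 0.937

helix_length_fit(c(17, 9, 3, 0), c(909, 67, 14, 1))   # TCEP series
#> t_1/2 = 2.067 min * exp(0.3707 * n), R^2 = 0.949

# extrapolate the DTT regression to the longest variant (n = 17)
extrapolate_half_life(helix_length_fit(c(9, 3, 0), c(1659, 115, 62)), 17)
#> [1] 30461.71   # minutes, i.e. ~21 days
```

So each residue added to the outer helix multiplies the reduction
half-life by ~1.45 (`e^0.371`), and an 18-residue difference spans three
orders of magnitude — the quantitative statement of how fold compactness
shields a disulfide.

A config-driven pipeline (`run_pipeline()`, stages `simulate`, `fit`,
`halflife`, `arrhenius`, `lengthfit`, `deconv`, `descriptors`, `synth`)
and a thin CLI wrapper (`inst/scripts/redoxkin`) cover scripted use; see
`vignettes/redox-kinetics.Rmd` for the modelling assumptions and design
choices.

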