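---
title: "Modelling disulfide-bond reduction kinetics with redoxkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disulfide-bond reduction kinetics with redoxkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxkin)
```

## The problem

Structural disulfide (SS) bonds stabilize small protein folds, and reducing
them with TCEP or DTT is a routine preparative step — yet in compact folds
such as the Trp-cage miniproteins the reaction can take orders of magnitude
longer than standard protocols assume. Quantifying *how fast* a given
disulfide is reduced, from CD or NMR time courses, is therefore a kinetic
estimation problem: convert the raw spectroscopic signal to concentrations,
fit a mass-action mechanism, and derive interpretable quantities
(half-lives, activation energy, structure–rate correlations).

`redoxkin` implements that pipeline end to end.

## The kinetic model

Four reactions, with fixed package-wide units (mmol/L, minutes):

| reaction | rate law | constant |
|---|---|---|
| reduction `SS + Red -> 2SH + Ox` | `k1·[SS]·[Red]` | `k1`, L mmol⁻¹ min⁻¹ |
| reoxidation `2SH + O2 -> SS` | `k2·[2SH]·[O2]` | `k2`, L mmol⁻¹ min⁻¹ |
| precipitation `2SH -> sink` | `k3·[2SH]` | `k3`, min⁻¹ |
| oxygen ingress `source -> O2` | `k4` | `k4`, mmol L⁻¹ min⁻¹ |

Six species are tracked (`ss`, `sh`, `red`, `ox`, `o2`, `precipitated`);
mass conservation (`ss + sh + precipitated` and `red + ox` constant) is
structural in the mechanism and is verified to ≤ 1e−6 relative drift over
10⁴ minutes in the test suite.

Modelling assumptions, stated explicitly:

* **A single effective `k1`.** TCEP's one-step and DTT's two-step exchange
  chemistries are both collapsed into one effective bimolecular constant;
  microscopic thiol pKa equilibria and pH dependence are out of scope.
* **Literal reoxidation stoichiometry.** One O₂ is consumed per SS bond
  re-formed; the true half-stoichiometric chemistry is not modelled.
* **Precipitation is first-order** in the reduced species, and the
  precipitated pool is non-reactive.
* **Oxygen ingress is zero-order** (`k4`). Whether gas–liquid transfer is
  better described as film-limited is not decidable from published data;
  zero-order matches the source-reaction notation. An optional saturation
  cap (`o2_sat`) switches ingress off above a ceiling, disabled by default
  because the default experiments never approach saturation.
* **Initial dissolved O₂ is never measured** in these experiments; it is a
  free initial condition (`o2_0`, default 0, optionally fitted).

Integration uses `deSolve::lsoda` (stiff-capable) with `rtol = 1e-8`,
`atol = 1e-10`. Solver undershoot below zero is clipped only within
100·`atol`; anything larger aborts with a diagnostic naming the state —
silent clipping of real negativity would mask a mis-specified model.

A closed-form oracle for the pure second-order case (`ss_second_order()`)
is exported; the integrator is required to match it to 1e−6 relative, and
the two paths are kept strictly independent.

## Half-life

For pure second-order reduction the half-life of the oxidized species is

$$t_{1/2} = \frac{\ln(2 - c_{SS,0}/c_{Red,0})}{k_1\,(c_{Red,0} - c_{SS,0})}$$

valid when the reducing agent is in excess. When the protein is in excess
by at most a factor of two, the two concentrations swap roles; beyond
twofold excess the oxidized pool can never halve and `half_life()` returns
`NA`. At exactly equal concentrations the continuous limit `1/(k1·c0)`
applies; the implementation switches to it within a relative difference of
1e−9 so the function is continuous there.

Both pathways to a half-life are provided — the closed form above, and the
half-crossing time of a simulated trajectory — because published tables do
not say which was used; the two agree to 0.1 % in the reduction-only case.

## Parameter estimation

`fit_mechanism()` minimizes the unweighted sum of squared concentration
residuals (oxidized, plus reduced where observed) with Levenberg–Marquardt
(`minpack.lm::nls.lm`). Choices that matter:

* **Log-space parameters.** All fitted quantities are positive, so they are
  estimated as logarithms. This enforces positivity without constraints and
  makes convergence insensitive to the start over at least ±100×
  (verified by a multi-start test); there is one stable optimum for the
  default fit.
* **Unweighted residuals.** No weighting scheme is published for these
  experiments; equal weights are the neutral choice.
* **Default free set `{k1}`.** Reoxidation, precipitation and oxygen
  ingress are often statistically non-significant on reduction-phase data;
  they are opt-in (`free = c("k1","k2",...)`), and a parameter whose
  Jacobian column is numerically null is flagged unidentifiable and
  reported with an infinite confidence interval rather than silently.
* **Student-t intervals.** Standard errors come from the Jacobian at the
  optimum (`σ²(JᵀJ)⁻¹`, delta method back to the natural scale) and CI
  half-widths use `qt(1 − α/2, n − p)` with `n` observations and `p`
  parameters; the relative standard deviation is `100·SE/estimate`.

The Jacobian is computed by central differences (step 1e−5 in log space)
at the optimum rather than reusing the solver's internal approximation, so
the uncertainty report does not depend on the optimizer's last step size.

Two derived regressions are ordinary least squares in log space:
`arrhenius_fit()` (ln k vs 1/T, `Ea = −slope·R`) and `helix_length_fit()`
(ln t½ vs outer helix length `n`, giving `t½ = a·exp(b·n)`). For the
published TCEP series the shortest variant's half-life is entered as
exactly 1 min (it is only printed as "≈1"); this convention reproduces the
printed coefficients. `n` is the number of residues N-terminal of the
first cysteine. R² for a perfectly flat response is defined as 1 (the line
fits exactly).

## Signal conversions

* **CD ellipticity** is affine in the oxidized concentration, so
  `ecd_to_concentration()` applies
  `c(t) = (θ∞ − θ(t))/(θ∞ − θ0) · [SS]₀`. CD alone cannot fix the absolute
  scale, so `[SS]₀` must be supplied externally. When `θ∞` is not given it
  is estimated as the mean of the final 10 % of points (configurable);
  noise overshoot outside `[0, SS₀]` is clipped and counted. The map is
  invariant to shifting or rescaling the whole trace.
* **NMR integrals** of the oxidized/reduced indole resonance give
  `ss = total·Int_ox/(Int_ox + Int_red)`. Normalization by the DSS
  reference integral cancels in the ratio but is retained as a drift
  diagnostic. Total protein is conserved exactly by construction.
* **CPMG rates** are `R₂ = −ln(I/I_ref)/t_CPMG`; a crosspeak brighter than
  the reference yields a negative rate that is *kept* (with a warning) so
  that noise statistics remain unbiased.

## Spectral ensemble factorization

`deconvolve_spectra()` decomposes a temperature/variant-indexed ensemble of
far-UV CD spectra into a small number of pure component curves and convex
per-spectrum weights, by alternating constrained least squares:

1. *weights step* — for each spectrum, least squares constrained to the
   probability simplex (solved exactly by enumerating active sets, which is
   cheap for the 2–4 components this method is meant for);
2. *components step* — unconstrained least squares per wavelength.

Each step solves its subproblem exactly, so the reconstruction SSE is
non-increasing; the iteration stops when its relative change drops below
`tol = 1e-8` (or at `max_iter = 1000`). Components are initialized from
the most mutually distant input spectra and, on output, ordered by their
222 nm ellipticity with the most negative first — the helical, folded
"C-type" curve has the strongly negative 222 nm band, so component 1 is
the folded one and `folded_fraction()` reports its percentage.

This is deliberately a *simplified* convex factorization, not a
reproduction of full convex constraint analysis (CCA+), which adds a
simplex-volume criterion. When the two pure extremes are present in the
ensemble the factorization is exact (SSE < 1e−12 in the tests); on real
ensembles whose extremes are not pure, published component percentages are
matched only qualitatively. An ensemble whose numerical rank is below the
requested component count has non-unique weights; the result is computed
via a pseudoinverse and flagged `degenerate` with a warning, rather than
erroring, so that the boundary case of identical spectra remains usable.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth. Its defaults *are* the reference study conditions:

* **Time courses** (`synth_time_course()`): 0.113 mmol/L protein, 18-fold
  molar excess of reducing agent, 40 samples to 3300 min, log-spaced so
  sampling is denser in the early reduction phase (as in the monitoring
  experiments; the first nonzero sample sits at `t_end/500`), additive
  i.i.d. Gaussian noise with sd 2 % of the initial protein concentration.
  The raw-signal tables (NMR integrals, ECD trace) are generated from the
  noisy concentrations, so the conversion functions invert them exactly —
  the noise model lives on the concentration scale because no instrument
  noise model is published. Noise is *not* clipped at zero: near-zero
  late-time readings may be slightly negative, as in real
  baseline-subtracted data, and clipping would bias `k1` recovery.
* **Melt ensembles** (`synth_melt_ensemble()`): two fixed basis curves
  (sums of Gaussian bands shaped like the folded C-type and unfolded
  U-type far-UV CD curves) mixed by a logistic folded fraction per variant,
  12 variants × 17 temperatures (5–85 °C) = 204 spectra by default, with
  melting midpoints spread over 25–80 °C and steepness 0.12 °C⁻¹ — values
  typical of miniprotein thermal unfolding.

What the generator does **not** emulate: baseline drift, wavelength-
dependent or correlated noise, peak overlap and phasing artefacts in NMR,
photomultiplier noise physics, or ensembles lacking pure extremes. Passing
the recovery tests therefore shows the estimators are correct and
well-calibrated under idealized noise — not that they are robust to every
instrumental artefact of real data.

Seeds are mandatory whenever noise is requested, and identical designs
with identical seeds are bit-identical.

## Structure descriptors

`steric_factor()` computes `x = n·RMSD/helicity` — outer helix length times
its backbone RMSD over its mean per-residue Hα chemical-shift deviation —
with `x = 0` by convention for a variant with no outer segment. CSD
aggregates use the absolute-value convention (signs of raw deviations are
dropped), which is an assumption: the published cage composites are
positive sums. Random-coil reference shifts are not embedded; CSDs are
consumed pre-computed. Computed steric factors agree with published ones
only to ~3 % because the published *inputs* are rounded to 2 decimals.

## Problem sizes and runtime choices

The validation suite uses 100–200 seeded replicates for bias/coverage
studies of `k1` recovery, 50 seeds for the noisy factorization study, and
40-point series per fit — sizes at which the Monte-Carlo error on a median
bias is well below the 2 % band being checked, while a full test run stays
under half a minute. Coverage of the nominal 95 % interval is required to
be ≥ 90 % rather than exactly 95 % because with 40 points the linearized
(Wald-type) interval is only asymptotically exact.

## Known limitations

* Only one mechanism topology is supported; no model selection beyond the
  identifiability flag.
* No hierarchical multi-experiment fitting and no Bayesian uncertainty;
  intervals are linearized and can undercover for strongly nonlinear
  parameter effects.
* The factorization matches published folded/unfolded percentages only
  qualitatively (see above).
* Printed half-lives in the source tables derive from *fitted* initial
  concentrations; predictions from nominal concentrations agree with them
  only within ~15 %, and the tests assert exactly that.
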