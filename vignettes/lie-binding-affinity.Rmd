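---
title: "Empirical binding free energies and quench-titration dissociation constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical binding free energies and quench-titration dissociation constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lieassay)
```

## The model

The linear interaction energy (LIE) ansatz treats the binding free energy of
a ligand as a linear function of ensemble-average interaction-energy
differences between its bound and free states,

$$\Delta G_{bind} = \alpha \langle U_{vdw} \rangle + \beta \langle U_{elec}
\rangle + \gamma \langle U_{cav} \rangle,$$

where the van der Waals, electrostatic and cavity terms come from a surface
generalized Born (SGB) continuum-solvent calculation (the cavity term is
proportional to exposed ligand surface area) and the three coefficients are
calibrated on a training set of compounds with measured affinity. This
package consumes the energy terms as data — producing them requires docking
and ensemble-simulation software that is out of scope — and owns everything
downstream: the least-squares calibration, prediction, model statistics and
the thermodynamic bridge to measured dissociation constants,

$$\Delta G = RT \ln K_D, \qquad R = 0.00199\ \mathrm{kcal\,mol^{-1}K^{-1}},
\quad T = 298\ \mathrm{K},$$

with $K_D$ carried in µM in all interfaces and converted to mol/L only
inside the logarithm. Both constants are defaults of `thermo_constants()`
and can be overridden.

### Fitting conventions

`fit_lie()` solves the ordinary least-squares problem by QR decomposition.
The default fit has **no intercept**, because the calibrated equation for
the packaged tables is the pure three-term form; `include_intercept = TRUE`
exists for sensitivity analysis. Coefficient signs are stored as fitted
(β and γ typically negative). Rank deficiency is detected from the singular
values of the design matrix at a relative threshold of $10^{-10}$ and
reported with the collinear columns. `loo_predictions()` refits with each
compound held out — useful because the training table shipped with the
package has a prediction column that the rounded published coefficients do
not regenerate (deltas of 0.03–0.13 kcal/mol), unlike the second table,
which regenerates to within print rounding. The source does not say how that
column was produced; the package therefore treats it as data, flags it in
`reproduce_report()`, and asserts nothing about it. Where the package
*reproduces* published prediction columns it deliberately uses the rounded
printed coefficients (0.072, −0.006, −0.951), since those demonstrably
regenerate the second table; full precision is kept internally everywhere
else.

### The noscapine K_D discrepancy

The training table prints K_D = 152 ± 1.0 µM for noscapine alongside an
experimental ΔG of −5.246 kcal/mol, but −5.246 back-converts to ≈144 µM —
the value the same source states elsewhere (144 ± 1.0 and 144 ± 2.8 µM).
The fixtures store all variants verbatim (`load_fixture("table1_kd_variants")`);
`validate_affinity_table()` flags the row (tolerance ±0.0015 kcal/mol,
covering last-digit rounding of three-decimal prints) and no layer of the
package silently reconciles it.

## The quench-titration pipeline

A titration of receptor (2 µM tubulin in the packaged conditions) with
increasing ligand is reduced to a dissociation constant in four steps:

1. **Inner-filter correction.** If the ligand absorbs at the excitation or
   emission wavelength, observed fluorescence is corrected multiplicatively:
   $F_{corr} = F_{obs} \cdot 10^{(A_{ex}+A_{em})/2}$.
2. **Saturation estimate.** $\Delta F_{max}$ is $1/\hat\beta_0$ from the
   unweighted OLS of $1/\Delta F$ on $1/[L]_{total}$ — exactly linear for an
   ideal single-site curve. A non-positive intercept means the curve does
   not saturate and is an error.
3. **Occupancy.** $a = \Delta F / \Delta F_{max}$ per point. The zero-ligand
   point defines $f_0$ and is excluded from reciprocal fits; points with
   $\Delta F \le 0$ (noise at low ligand) or $a > 1.05$ (inconsistent with
   the estimated saturation) are dropped with a warning.
4. **Regression.** $K_D$ is the slope of $1/a$ on $1/[L]_{free}$ from the
   linearised model $1/a = K_D/[L]_{free} + 1$.

### Free-ligand handling

The default mode is `total-as-free`: with receptor at 2 µM against $K_D$ in
the tens of µM, ligand depletion by binding is a second-order effect, and
total concentration is the natural first estimate. The optional
`iterative-depletion` mode refines $[L]_{free} = [L]_{total} - a\,[R]_{total}$
and refits until the $K_D$ estimate is stable to $10^{-6}$ relative (cap 100
iterations); simulations in the test suite show it strictly improves
accuracy when $K_D$ is comparable to the receptor concentration (e.g. 5 µM
against 2 µM receptor).

### Intercept constraint and an algebraic caveat

The linearised model fixes the intercept at 1. By default the intercept is
fitted freely and reported as a model-consistency diagnostic, with a
constrained option (`constrained_intercept = TRUE`) matching the fixed
"+ 1". One subtlety discovered while validating the pipeline: when
$\Delta F_{max}$ is estimated from the *same* double-reciprocal fit on the
*same* points, the free intercept equals 1 **identically** — the occupancy
regression is the saturation regression rescaled by $\Delta F_{max}$. The
intercept is therefore only an informative diagnostic when the saturation
value is supplied independently (`delta_f_max =`), and the consistency
property "intercept → 1 as noise → 0" is tested that way.

Reciprocal transforms amplify relative error where $\Delta F$ is small; the
fits are unweighted because the method being implemented specifies plain
double-reciprocal regression. Users with very noisy low-ligand points should
prefer a dense grid at moderate-to-high occupancy.

## What the simulators emulate

`simulate_quench_titration()` is the forward model of the assay: occupancy
$a = L/(K_D + L)$ with $L$ either total ligand (`ideal`) or the exact
positive root of the mass-balance quadratic
$L_f^2 + (K_D + R - L_t)L_f - K_D L_t = 0$ (`depletion`); fluorescence
$F = f_0 - a\,\Delta F_{max}$ plus additive Gaussian noise. Defaults mirror
the packaged assay conditions: ligand grid 0, 10, 25, 50, 100, 150, 200 µM
(within the assay's 0–200 µM span), receptor 2 µM, $f_0 = 1000$ a.u.,
$\Delta F_{max} = 400$ a.u. ($f_0$ and $\Delta F_{max}$ are arbitrary-unit
choices at a realistic signal-to-saturation ratio; no instrument scale is
stated for the assay). Noise is additive Gaussian on fluorescence —
instrument-like — and may be given as a fraction of $f_0$ because assay
scatter scales with signal; the zero-ligand reference is kept noiseless,
standing in for the heavily averaged baseline of a real titration. Beer's
law absorbance columns ($A = \varepsilon L$) can be emitted for exercising
the inner-filter correction, but the emitted fluorescence is *not*
attenuated: the generator provides clean signal plus the absorbances a user
would measure.

What the simulator does **not** model: photobleaching and drift, spectral
bandpass effects, multi-site or cooperative binding, and non-Gaussian
outliers. Passing recovery tests on simulated data therefore demonstrates
the correctness of the estimator pipeline under the single-site model, not
robustness to every pathology of real instrument data.

`simulate_lie_table()` draws energy components uniformly from the spans
observed in the packaged compound tables (u_vdw ∈ [−66, −46],
u_elec ∈ [7, 130], u_cav ∈ [0.4, 2.1] kcal/mol) and adds Gaussian noise to
the linear free energy. Both simulators use a call-local seeded generator
and never disturb the caller's RNG stream.

## Numerical choices

* Least squares via QR; the test suite cross-checks against an explicit
  normal-equations solve to $10^{-8}$.
* Singular-design threshold: smallest singular value below $10^{-10}$ of
  the largest.
* Depletion iteration: relative $K_D$ change below $10^{-6}$, at most 100
  iterations, with the trace included in any convergence error.
* Table-validation tolerance ±0.0015 kcal/mol against three-decimal prints.
* Occupancy overshoot tolerance 0.05 before a point is dropped; survivors
  marginally above 1 are clipped to 1 for the reciprocal.
* Problem sizes: recovery studies use 60–100 replicate titrations of 7
  points and LIE tables of up to 50 compounds — ample for the desk-scale
  statistics involved, and the whole suite runs in seconds.

## Known limitations

* The LIE calibration here is plain OLS: no regularised or robust variants,
  matching the method being packaged.
* Direct nonlinear isotherm fitting ($\Delta F$ vs $L$) is deliberately not
  the primary path; the package implements the double-reciprocal procedure
  as specified, documenting its error-amplification caveat instead of
  replacing it.
* IC50 and cell-cycle fixtures are data-only context; no dose–response
  fitting is provided.
* Published one-way ANOVA F statistics for the affinity and IC50 tables are
  not reproducible from the tabulated means ± SD at n = 3;
  `anova_oneway_from_summary()` computes the textbook statistic from any
  summaries, and `reproduce_report()` records the recomputed value without
  asserting agreement.
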