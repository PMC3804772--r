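# lieassay

Empirical binding free-energy analysis for protein–ligand affinity work,
built around two classic desk-scale methods:

1. **The linear interaction energy (LIE) model with surface generalized Born
   (SGB) energy components.** Binding free energy is modelled as a weighted
   sum of ensemble-average bound-minus-free interaction energies,

   ΔG_bind = α⟨U_vdw⟩ + β⟨U_elec⟩ + γ⟨U_cav⟩,

   with the coefficients fitted by ordinary least squares to compounds of
   known affinity and then used to predict ΔG for new compounds. Predicted
   and experimental scales meet through the thermodynamic relation
   ΔG = RT·ln K_D (R = 0.00199 kcal mol⁻¹ K⁻¹, T = 298 K; K_D in mol/L).

2. **Dissociation constants from fluorescence-quench titrations.** A ligand
   that quenches a receptor's intrinsic tryptophan fluorescence yields, after
   inner-filter correction F_corr = F_obs·10^((A_ex+A_em)/2), a fractional
   occupancy a = ΔF/ΔF_max; the saturating change ΔF_max comes from the
   double-reciprocal regression of 1/ΔF on 1/[L], and K_D is the slope of
   the linearised single-site model 1/a = K_D/[L_free] + 1.

The package targets medicinal-chemistry and chemical-biology users ranking
tubulin-binding noscapinoid analogues (or any single-site ligand series):
it ships the published noscapinoid compound tables as verbatim fixtures,
simulators for both data types, and a reproducibility report that recomputes
everything in the tables that is arithmetic rather than measurement.

## Worked example

```r
library(lieassay)

# predict binding free energies from the published rounded coefficients
co <- lie_coefficients(0.072, -0.006, -0.951)
predict_dg(co, load_fixture("table2"))[c("6f", "6j")]
#>        6f        6j
#> -6.188997 -4.923282

# the strongest binder's measured K_D, converted to a free energy
dg_from_kd(38)     # 38 uM
#> [1] -6.035713

# estimate K_D from a (here simulated) quench titration:
# true K_D 38 uM, 2 uM receptor, ligand 0-200 uM, 1% fluorescence noise
sim <- simulate_quench_titration(quench_sim_config(
  kd_true = 38, noise_sd = 0.01, noise_as_fraction = TRUE, seed = 42))
estimate_kd(sim)
#> K_D estimate: 31.91 uM  (total-as-free)
#>   reciprocal fit: slope = 31.91 uM, intercept = 1, R2 = 0.9973
#>   dF_max = 369.2, 6 points used
```

The predicted values −6.189 and −4.923 kcal/mol bracket the free-energy
range of the eleven third-generation analogues (compound 6f is the tightest
binder, 6j the weakest); the single noisy titration recovers the generating
K_D of 38 µM to within the scatter expected from six points at 1% noise
(across 100 replicate titrations the median estimate is within 10% of
truth — see the test suite).

`reproduce_report()` prints the full audit: the recomputed predicted-ΔG
column (max |Δ| = 0.0008 kcal/mol against the printed values), the
experimental ΔG columns regenerated from K_D (6/7 and 5/5 rows consistent),
the three squared correlations (0.780, 0.615, 0.675), and the standing
inconsistencies in the source tables (the noscapine K_D row, whose stated
free energy implies 144 µM rather than the tabulated 152 µM, and the
training-table prediction column, which the rounded coefficients do not
regenerate).

A thin command-line wrapper over the same functions is installed at
`system.file("exec", "lieassay.R", package = "lieassay")` with subcommands
`dg`, `kd`, `predict`, `fit`, `assay-fit`, `simulate`, `reproduce`.

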