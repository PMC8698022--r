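# scsolub

Thermodynamic modeling of solid drug solubility in supercritical carbon
dioxide with cubic equations of state.

## The problem

Supercritical-CO2 processes for pharmaceuticals (RESS particle formation,
extraction) need the equilibrium mole fraction `y2` of the solid drug in
the fluid as a function of temperature and pressure. The standard
compressed-gas model,

```
y2 = (P2sub / (P * phi2)) * exp(v2s * P / (R * T))
```

combines the solid's sublimation pressure `P2sub`, its molar volume
`v2s`, and the solute fugacity coefficient `phi2` from a cubic equation
of state (Redlich-Kwong, Soave-Redlich-Kwong, or Peng-Robinson). For
drug-like solids `P2sub` is ~1e-12 to 1e-9 bar, unmeasurable, and the
model's dominant input; practitioners either regress it from the
solubility data as a second adjustable parameter or estimate it
independently. This package, built around the penicillin G / penicillin V
case, implements:

* **EoS primitives** — RK/SRK/PR parameters, analytic cubic volume
  solving, CO2 density (`pure_params()`, `solve_volume()`,
  `co2_density()`);
* **mixtures** — van der Waals and Lorentz-Berthelot combining rules and
  the closed-form solute fugacity coefficient (`cross_params_lb()`,
  `phi2_classical()`), plus the Schmitt-Reid infinite-dilution modified
  PR form in which the solute's `(a2, b2)` are fitted directly and no
  solute critical properties are needed (`phi2_schmitt_reid()`);
* **the solubility model** with full or simplified Poynting correction
  (`solubility()`);
* **sublimation-pressure tools** — Clausius-Clapeyron representation,
  OLS fitting, enthalpy extraction, and the discrepancy diagnostics for
  regressed values (`fit_clausius()`, `pressure_discrepancy()`,
  `psub_discrepancy_table()`, `psub_enthalpy_table()`);
* **density-based correlations** — Mendez-Santiago-Teja and Bartle fits,
  a studentized-residual data-consistency check, and the three-step
  pipeline that produces an EoS-independent sublimation-pressure model
  (`mst_fit()`, `bartle_fit()`, `consistency_check()`,
  `estimate_new_psub()`);
* **AARD regression** — seeded multi-start minimization of the average
  absolute relative deviation over `k12` (+ per-isotherm `P2sub`) or
  `(a2, b2)` (`fit_classical()`, `fit_schmitt_reid()`);
* **a synthetic-data generator** emulating the two penicillin study
  designs (3 isotherms, N = 18 / N = 24, 100-350 bar, multiplicative
  lognormal noise, constructed outliers) with the generating truth
  attached for recovery testing (`generator_config()`,
  `generate_dataset()`, `penicillin_fixture()`).

See the vignette `vignettes/solubility-modeling.Rmd` for the model
derivations, conventions, and design rationale.

## Worked example

The published per-isotherm sublimation pressures regressed for
penicillin G by two equations of state disagree wildly even though the
fit quality hardly changes:

```r
library(scsolub)
psub_discrepancy_table("penG")
#>   temperature_K psub_rk_bar aard_rk_pct psub_srk_bar aard_srk_pct discrepancy_pct
#> 1        313.15    3.55e-12          23     2.82e-12           21        25.88652
#> 2        323.15    2.24e-11          23     4.57e-11           21        50.98468
#> 3        333.15    1.44e-10          23     3.09e-09           21        95.33981

round(psub_enthalpy_table("penG"), 1)   # implied sublimation enthalpies, kJ/mol
#>    rk   srk
#> 160.5 302.8
```

Discrepancies of 26-95% and implied enthalpies of 160-300 kJ/mol
(implausibly large for a molecule of this size) are the case against
treating `P2sub` as a free regression parameter. The forward model with a
Clausius-Clapeyron sublimation model:

```r
pen_g <- solute_properties("penicillin G", v2s = 2.261e-4,
                           sr = schmitt_reid_params(12.8, 1.98e-4))
psub <- sublimation_model(26.2, 85300)  # ln P2sub(Pa) = 26.2 - 85300/(RT)
solubility(c(313.15, 333.15), 20e6, pen_g,
           clausius_pressure(psub, c(313.15, 333.15)))
#> [1] 2.53e-05 3.63e-05
```

The full pipeline on a synthetic penicillin-G-like study (known truth,
8% noise, two constructed off-line points):

```r
ds <- generate_dataset(penicillin_fixture("penG", noise_cv = 0.08,
                                          seed = 1, outliers = TRUE))
est <- estimate_new_psub(ds, density_source = "eos")
est
#> Sublimation-pressure estimate from solubility data
#>   dropped points: 7, 13
#>   MST:    C' = 30.56 (AARD 8.05%, R^2 0.9915)
#>   Bartle: b = -7777.04 K -> dHs = 64.7 kJ/mol (AARD 7.69%)
#> <sublimation_model> ln P2sub(Pa) = 30.56 - 6.466e+04/(R T)  [dHs = 64.7 kJ/mol]
```

The consistency check drops exactly the two constructed outliers (rows 7
and 13, the 100-bar points of the upper isotherms), and both correlations
describe the cleaned data to ~8% AARD. Regressing the Schmitt-Reid
parameters on the cleaned data against the generating sublimation model
recovers the truth (`a2 = 12.8`, `b2 = 1.98e-4`) to within the noise:

```r
truth <- attr(ds, "truth")
clean <- ds[setdiff(seq_len(nrow(ds)), est$flagged), ]
fit_schmitt_reid(clean, truth$solute, truth$psub, seed = 1)
#> <fit_result> mode = schmitt_reid  (N = 16, converged, 1408 objective evals)
#>   a2    12.5463
#>   b2    0.000193798
#>   psub  0.00141391  0.00389686  0.0101059
#>   AARD global: 5.72%
#>   AARD at 313.15 K: 5.49%
#>   AARD at 323.15 K: 5.32%
#>   AARD at 333.15 K: 6.38%
```

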