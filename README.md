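# rehydkin

Rehydration kinetics modelling and quality analysis of dehydrated sweet
corn kernels.

Dried vegetables are rehydrated before use, and how fast and how completely
they take water back up depends on the blanching pretreatment (hot water,
steam, microwave) and the drying air temperature. `rehydkin` is aimed at
food process engineers studying that question: it fits sorption models to
moisture-versus-time soaking curves, scores the fits, derives the physical
quality metrics of the dried/rehydrated product, and clusters the
pretreatment-by-temperature treatments by their property profiles.

## Models

With `X(t)` the dry-basis moisture content (g water / g dry matter) at
soaking time `t` (min), `X_w0` the initial moisture and `X_eq` the
equilibrium moisture, the package fits:

- **Peleg**: `X(t) = X_w0 + t / (k1 + k2·t)`, with rate constant `k1`
  (min·g dm/g water) and capacity constant `k2` (g dm/g water); the
  `t → ∞` limit gives `X_eq = X_w0 + 1/k2`.
- **Weibull**: `X(t) = X_eq + (X_w0 − X_eq)·exp(−(t/β)^α)`, with shape `α`
  (dimensionless) and scale `β` (min), the time at which 63 %
  (`1 − e⁻¹`) of the total moisture change has occurred regardless of `α`.
- **Logarithmic**: `X(t) = X_eq + (X_w0 − X_eq)·ln(k·t)`, linear in
  `ln t`; its least-squares fit is closed form.

Goodness of fit uses `R²`, `RMSE = sqrt(SSE/N)` and the reduced
chi-square `χ² = SSE/(N − Z)`; `rank_models()` orders fits by `R²`, then
`RMSE`, `χ²` and parsimony. Quality metrics are the rehydration ratio
(rehydrated over dried mass), per-interval and average rehydration rates,
the geometric mean diameter `D_g = (L·W·T)^{1/3}` and the CIE76 total
color difference `ΔE` against the fresh kernel. Treatments are clustered
on z-scored property profiles (Euclidean distance, Ward/average/complete
linkage) into dendrograms exported as Newick.

A seeded generator reproduces the study design — 4 pretreatments
(control, hot-water, steam, microwave blanching) × 4 drying temperatures
(55–70 °C), sampled every 5 min up to 60 min — so the whole pipeline runs
without the unpublished raw measurements.

## Worked example

```r
library(rehydkin)

spec  <- synthetic_spec(seed = 7)
curve <- generate_curve(spec, "control", 55)
fits  <- fit_rehydration_models(curve)
rank_models(fits)[[1]]
#> <model_fit> weibull model, condition control_55
#>   parameters: alpha = 1.0305, beta = 38.911, Xeq = 4.4975
#>   Xeq = 4.4975 g/g | R2 = 0.9980, RMSE = 0.0484, chi2 = 0.00305 (N = 13, Z = 3)
fits$peleg
#> <model_fit> peleg model, condition control_55
#>   parameters: k1 = 8.6523, k2 = 0.14044
#>   Xeq = 7.2189 g/g | R2 = 0.9977, RMSE = 0.0516, chi2 = 0.00314 (N = 13, Z = 2)
```

The Weibull fit edges out Peleg here (`R² = 0.998` vs `0.9977`), and the
fitted scale `β ≈ 39 min` says this slow 55 °C curve needs ~39 min to
reach 63 % of its total uptake. The Peleg capacity constant recovers the
generating value (`k2 = 0.140` vs 0.146), giving an equilibrium moisture
of `0.099 + 1/0.140 ≈ 7.2` g/g — an extrapolation well beyond the 60-min
soak, hence its sizeable sampling spread.

A full run fits all 48 condition × model combinations, derives the
quality table and writes the dendrograms:

```r
report <- run_pipeline(run_config(synthetic = TRUE, seed = 3))
report$averages
#>      model n_curves    R2    chi2   RMSE
#> 1    peleg       16 0.998 0.00205 0.0410
#> 2  weibull       16 0.998 0.00216 0.0395
#> 3 proposed       16 0.987 0.00804 0.0726

head(report$quality[, c("pretreatment", "temperature_C", "RR", "Dg_mm", "deltaE")], 4)
#>   pretreatment temperature_C    RR Dg_mm deltaE
#> 1      control            55 2.913 7.955  31.42
#> 2      control            60 3.123 8.013  29.65
#> 3      control            65 3.311 8.212  28.14
#> 4      control            70 3.496 8.388  26.65
```

Rehydration ratio rises and color change falls with drying temperature,
as expected for control kernels. A shell wrapper with `generate`, `fit`,
`metrics`, `cluster` and `run-all` subcommands lives at
`inst/cli/rehydkin.R`.

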