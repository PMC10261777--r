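---
title: "Modelling rehydration of dehydrated sweet corn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rehydration of dehydrated sweet corn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rehydkin` models the water uptake of dehydrated sweet corn kernels soaked
in boiling water, across a 4 blanching-pretreatment × 4 drying-temperature
design, and analyses the quality of the dried and rehydrated product. This
vignette is the package's account of the science and of the design choices
made where the method left room.

## The models and their assumptions

All moisture contents are **dry basis** (g water / g dry matter) and times
are minutes. The dry basis is an explicit design choice: reported
equilibrium moistures of 3–7 g/g are consistent with a fresh kernel at
75 % wet-basis moisture (3 g/g dry basis), whereas wet-basis fractions
could never exceed 1. Conversions are provided
(`moisture_wb_to_db()` / `moisture_db_to_wb()`), but all model code assumes
the caller already works dry-basis.

Three empirical sorption models describe a curve $X(t)$ rising from the
initial moisture $X_{w0}$:

* **Peleg** — $X(t) = X_{w0} + t/(k_1 + k_2 t)$. Hyperbolic saturation:
  $k_1$ (min·g dm/g water) sets the initial uptake rate ($1/k_1$ is the
  slope at $t=0$), $k_2$ (g dm/g water) the capacity, with
  $X_{eq} = X_{w0} + 1/k_2$ as the $t \to \infty$ limit. Monotone
  increasing, concave; it cannot represent sigmoidal uptake.
* **Weibull** — $X(t) = X_{eq} + (X_{w0}-X_{eq})\,e^{-(t/\beta)^\alpha}$.
  A stretched exponential: $\alpha$ (dimensionless) controls the curve's
  character ($\alpha < 1$ gives a steep start, $\alpha = 1$ is the
  single-exponential model), and $\beta$ (min) is the time at which the
  normalized change $(X - X_{w0})/(X_{eq} - X_{w0})$ reaches
  $1 - e^{-1} \approx 63\,\%$ — for *every* $\alpha$, which is why $\beta$
  is read as "the 63 % rehydration time".
* **Logarithmic** — $X(t) = X_{eq} + (X_{w0}-X_{eq})\ln(k t)$, with rate
  parameter $k$ (1/min). The model is linear in $\ln t$ with slope
  $X_{w0} - X_{eq}$, so for an *increasing* curve the fitted $X_{eq}$
  necessarily sits **below** $X_{w0}$ (typically negative). The package
  implements the model exactly as formulated and reports the fitted
  $X_{eq}$ without reinterpretation; it is the curve's value at $t = 1/k$,
  not a physical equilibrium. Two further consequences are handled
  explicitly: the model is undefined at $t = 0$, so zero-time points are
  excluded from evaluation and fitting (the first soaking sample is at
  5 min), and for small $k$ the curve is negative over the whole sampling
  window — a regime in which no physical soaking curve can be generated,
  which is why the synthetic round-trip studies draw $k$ in the
  non-negative-moisture regime (about 0.55–0.85 1/min for a 5–60 min grid
  with $X_{eq} \in [-1.8, -0.5]$).

## Fitting

`fit_peleg()` and `fit_weibull()` minimize the sum of squared moisture
residuals with Levenberg–Marquardt trust-region least squares
(`minpack.lm::nlsLM`, `ftol = ptol = 1e-10`, at most 1000 evaluations).
$X_{w0}$ is always fixed at the measured $t=0$ moisture, never fitted:
it is a measured quantity, and fixing it keeps the parameter counts at
$Z = 2$ (Peleg), $3$ (Weibull), $2$ (logarithmic).

Starting values matter more than the optimizer. Peleg starts from its own
linearization $t/(X - X_{w0}) = k_1 + k_2 t$, an ordinary least-squares
fit over the points that have risen above $X_{w0}$. Weibull starts at
$\alpha = 1$, $X_{eq}$ at 1.05× the maximum observed moisture, and $\beta$
at the sampled time closest to the 63 % level of that initial change;
box constraints keep $\alpha \in (0, 5]$, $\beta > 0$ and
$X_{eq} \ge 0.5 \max X$. The logarithmic fit needs no optimizer at all:
ordinary least squares of $X$ on $\ln t$ gives intercept $a$ and slope
$b$, and then $X_{eq} = X_{w0} - b$ and $k = \exp((a - X_{eq})/b)$ — the
exact global minimum. A flat curve (nothing above $X_{w0}$, or zero
slope) raises a degenerate-curve error; an optimizer failure is flagged
as non-converged with statistics withheld, and the pipeline excludes such
fits from averages while reporting the exclusion count.

Fit quality uses $R^2 = 1 - SS_{res}/SS_{tot}$ (about the observed mean),
$RMSE = \sqrt{SS_{res}/N}$ and the reduced chi-square
$\chi^2 = SS_{res}/(N - Z)$, so $\chi^2 (N - Z) = RMSE^2 N$ holds as an
identity. Residuals are computed on moisture content directly by default;
`residual_on = "moisture_ratio"` rescales them by the fitted total change
$(X_{eq} - X_{w0})$ for users who prefer dimensionless residuals. Model
ranking sorts by $R^2$, breaking ties by $RMSE$, then $\chi^2$, then
fewer parameters — parsimony last because the statistics already penalize
nothing for complexity except through $\chi^2$'s degrees of freedom.

## Quality metrics

The rehydration ratio is strictly the mass quotient
(rehydrated / dried). Rehydration rates are reported both per sampling
interval (finite differences) and as the endpoint average
$(X_N - X_0)/(t_N - t_0)$; the two answer different questions and neither
is privileged. The geometric mean diameter is $(LWT)^{1/3}$ of the three
mutually normal kernel dimensions. Color difference is the original CIE76
Euclidean $\Delta E$ in CIELAB — deliberately not CIEDE2000, to stay
comparable with the bulk of the food-drying literature, which reports
CIE76.

## Treatment clustering

The "compound correlation" analysis is agglomerative hierarchical
clustering of the 16 treatments on their property profiles. Columns are
z-scored first (population SD, divisor $n$; zero-variance columns are
dropped with a warning) so that milligram-scale and unitless properties
weigh equally. Distance is Euclidean; the default linkage is Ward
(`hclust` method `ward.D2`, the genuine Ward criterion on Euclidean
distances), which favours the compact, balanced temperature clusters this
kind of design produces; average and complete linkage are available.
Two default feature sets mirror the two published dendrogram panels:
*physical* (dried and rehydrated mass, $D_g$, rehydration ratio,
$\Delta E$) and *overall* (physical plus total sugar, ascorbic acid and
sensory score). Trees are cut at a fraction of the root merge height
(default 0.5). Newick export writes branch lengths as height differences
between a node and its parent, so root-to-leaf path lengths equal the
root merge height; children are ordered by their smallest input row,
making the output deterministic.

## The synthetic-data generator

No raw soaking curves were published, so the generator emulates the study
conditions: 13 samples at 0, 5, …, 60 min, one curve per condition,
generated from the Peleg model with the per-condition $(k_1, k_2)$
reported for the design (the only complete per-condition parameter sets
available), plus additive Gaussian noise of SD 0.05 g/g truncated below
at zero — a mild bias source at near-zero moistures, documented rather
than corrected. The initial moisture defaults to 0.05 g/g dry basis: the
reported equilibrium values equal $1/k_2$ to the printed digit, implying
a near-zero effective initial moisture, and ~5 % dry-basis residual
moisture is realistic for kernels dried to constant mass.

The treatment-property table draws each property from per-condition means
that interpolate linearly in temperature inside each pretreatment's
reported span (rehydration ratio 2.23–3.54, $\Delta E$ 11.12–31.23,
total sugar 5.21–7.41 g/100 g, ascorbic acid 4.24–6.01 mg/100 g, sensory
score up to 8.62 for microwave blanching at 70 °C). Sample colors are
placed at the target $\Delta E$ from a fresh-kernel reference
(L\*, a\*, b\* = 72, 5, 48, a typical fresh sweet-corn yellow) along a
fixed browning direction (darker, redder, less yellow), so recomputing
$\Delta E$ recovers the configured mean. Reported per-kernel masses and
the reported rehydration-ratio spans are not mutually consistent (masses
imply ratios near 4.5–5.4, the spans say 2.88–3.54); the generator keeps
the *definition* consistent instead, setting rehydrated mass = dried
mass × ratio with dried masses of 0.10–0.12 g, and the ratio always
computed from the mass quotient.

`structured_treatment_matrix()` generates tables with controlled
temperature-to-pretreatment effect ratios for studying what the
dendrogram's root split reflects. Its temperature response is
threshold-like (scores −1, −0.6, 0.6, 1 across 55–70 °C) rather than
equally spaced: structural damage to kernel tissue accelerates above
roughly 60 °C, so properties shift more between 60 and 65 °C than within
either regime — which is also the only response shape under which "the
root split separates 55/60 from 65/70" is a determinate outcome rather
than a tie between adjacent-temperature merges.

What the generator does **not** emulate: replicate-level measurement
structure (one curve per condition, no triplicates), kernel-to-kernel
heterogeneity, leaching of solubles during soaking, any mechanistic
(Fickian) diffusion geometry, and temperature dependence beyond the four
dryer settings. Passing tests on synthetic data therefore demonstrate
correctness of the estimators and pipeline plumbing under the stated
noise model — not that these models describe any particular new corn
variety.

## Numerical choices and test problem sizes

Seeds are explicit everywhere; each curve's noise derives from the spec
seed and the condition index, so a single curve regenerates identically
regardless of generation order. Parameter-recovery studies use 200
synthetic curves per model at noise SD 0.05 g/g (median relative
parameter error ≤ 10 %) plus noise-free round trips recovered to 1e-6;
grid-search cross-checks use 20 curves per model against exhaustive SSE
grids (400×400 for Peleg; 25×25×25 and 200×200 for the three- and
two-parameter models). The equilibrium-moisture extrapolation for the
slowest (55 °C) curve carries ~5 % sampling SD at this noise level —
60 min of soaking ends far from equilibrium — so calibration checks on
it use the median of 15 seeded refits.

## Limitations

Parameter uncertainty (bootstrap or profile intervals) is out of scope,
as are multi-start global optimization, information-criterion model
selection, Arrhenius-type temperature laws, and any figure rendering
beyond machine-readable outputs. The logarithmic model's good fit
statistics should be read with its geometry in mind: it buys linearity in
$\ln t$ at the price of an unbounded, non-physical extrapolation on both
ends of the time axis.
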