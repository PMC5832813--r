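---
title: "Scaling bioturbator effects on sediment resuspension to population metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling bioturbator effects on sediment resuspension to population metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioturbr)
```

## The model and its assumptions

Bioturbating macrofauna loosen cohesive sediment through feeding,
burrowing and movement, raising the equilibrium mass of resuspended
sediment (MRS, g m⁻²) that a given bed shear stress can hold in
suspension. `bioturbr` models this effect through a single integrative
predictor, the areal metabolic rate of the bioturbator population:

1. **Individual metabolism.** `I = a M^b` (mW), with body mass `M` in
   mg ash-free dry weight (AFDW). The default exponent is the canonical
   `b = 0.75` of metabolic scaling theory; an empirical ln-linear form
   (`ln I` linear in ln-mass, inverse temperature and trait indicators,
   evaluated in J day⁻¹ and converted to mW by exactly 1000/86400)
   accepts any published coefficient table via configuration, so the
   package never hard-codes a particular respiration model.
2. **Population metabolism.** `I_TOT = N I` (mW m⁻²). Density `N` is an
   experimental design variable and treated as error-free, so the CI of
   `I_TOT` is `N` times the CI of `I`.
3. **Resuspension.** `R_TOT = c + d I_TOT` (g m⁻²), fitted by ordinary
   least squares. `c` captures purely physical resuspension, `d` the
   biotic effect per unit of metabolic power. Functional-group variants
   (interaction, additive, none) are compared by bidirectional AIC
   stepwise selection.
4. **Per-milliwatt effect.** `R_BIO = (R_TOT − R_CONTROL)/I_TOT`
   (g mW⁻¹), which may legitimately be negative when a treatment
   resuspends less than the defaunated control.
5. **Temperature.** Only the metabolic term responds to temperature,
   via the Boltzmann–Arrhenius factor
   `exp(−(E/k)(1/T − 1/T_ref))`; the abiotic constant `c` is assumed
   temperature-invariant. This is an explicit modelling assumption, not
   a finding: warming could also alter sediment properties or
   behaviour, which the model does not represent.

The key identifying assumption throughout is that sediment reworking is
proportional to energy expenditure, so that functional identity matters
only through metabolism. On the packaged dataset this holds: stepwise
selection discards the functional-group terms (AIC path
270.40 → 268.13 → 265.71).

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `b` (allometric exponent) | — | 0.75 | canonical metabolic-theory value; configurable because realised exponents vary taxonomically (the packaged lugworm rates realise ≈ 0.85) |
| `a` (normalization) | mW mg⁻⁰·⁷⁵ | 0.011 | least-squares calibration of `ln I − 0.75 ln M` over the packaged dataset; only used when rates are regenerated from mass, the dataset carries its own `I` column |
| `energy_density` | J mg⁻¹ | 21.5 | average energy density of macrozoobenthic tissue, used by ln-linear coefficient tables that expect mass in energy units |
| `E` (activation energy) | eV | 0.65 | mid-range value for aquatic ectotherm respiration. `E` is not identifiable from the fixed-temperature dataset, so every `temperature_scenario()` exposes it as a visible argument rather than burying it |
| `k` (Boltzmann) | eV K⁻¹ | 8.617×10⁻⁵ | physical constant, pinned in the configuration |
| `T_ref` | °C | 18 | the temperature at which the packaged experiments were run; interfaces take °C and convert internally by +273.15 |
| `R_CONTROL` | g m⁻² | 32.25 ± 1.73 | mean defaunated-control resuspension at 0.18 Pa. Default mode is a single global mean; a `per_flume` mode exists because flume protocols use internal controls, but per-flume values are rarely published |
| `itot_tolerance` | mW m⁻² | 0.5 | consistency check between `N I` and a supplied `I_TOT` column; printed rounding of `I` at two decimals exceeds this at densities of a few hundred, so the validator flags (and keeps) such rows |

## Uncertainty semantics

The ±95% columns are symmetric half-widths treated as 1.96 standard
deviations. Inputs to a conversion step are assumed independent
Gaussian — the conservative default when the covariance of length,
mass and respiration calibrations is unknown. Two propagation routes
are provided and cross-checked:

* `propagate_delta()` — first order,
  `ci_out² = Σ (∂f/∂x_i · ci_i)²`, with central-difference derivatives
  (relative step `max(|x|, 1.5e-8) · eps^{1/3}`, which stays inside the
  domain of positive-argument maps such as powers and logs);
* `propagate_monte_carlo()` — Gaussian simulation with a mandatory
  seed, reported as mean ± 1.96 sd.

The two agree within 5% for smooth maps at the relative CIs found in
the dataset (≲ 30%); the delta method is the default, Monte Carlo the
audit. Whether first-order or simulation-based propagation produced the
dataset's own printed CIs is unknowable from the data, which is one
reason both are shipped.

## Regression conventions

* **AIC** is `−2 logLik + 2(p + 1)` under the Gaussian likelihood, the
  residual variance counting as a parameter — i.e. `stats::AIC()` on an
  `lm`. The suite pins this against the closed form
  `n log(2π RSS/n) + n + 2(p+1)`.
* **CIs and p-values** use t quantiles on `n − p` degrees of freedom
  (at n = 32 the difference from normal quantiles is visible in the
  third decimal).
* **Categorical coding**: treatment contrasts with the deep-burrowing
  group as reference level.
* **Stepwise**: starts from the full interaction model; each step
  evaluates every hierarchy-respecting single-term drop or add within
  the scope of the full formula and takes the move with the lowest AIC,
  stopping when no move improves it. Ties go deterministically to the
  first candidate in scope order. Because the candidate lattice here is
  tiny (three to five models), the tests also verify the selection
  against exhaustive enumeration.
* **Leverage sensitivity**: `leverage_exclusion_refit()` drops the `k`
  treatments with the largest `I_TOT`; all rows tied at the boundary
  are dropped and the effective count reported.
* **Degenerate inputs**: a constant response has no variance to
  explain, so `R²` is reported as 0 rather than the 0/0 that naive
  formulas produce; rank-deficient designs fail loudly, naming the
  collinear columns.

### Rank versus product-moment correlations

`correlation_report()` returns both Spearman and Pearson estimates.
On this dataset they differ materially — metabolism vs resuspension:
0.76 (rank) vs 0.83 (product-moment); density vs resuspension: 0.56
(rank) vs 0.37 (product-moment) — because the predictors are strongly
right-skewed and the two extreme high-metabolism treatments carry much
of the linear association. Correlation values quoted for data of this
shape are ambiguous unless the flavour is named, so the package always
reports both; `spearman_correlation()` itself is strictly rank-based
(average ranks for ties, large-sample t approximation for the
p-value).

## The synthetic generator

`generate_table()` emulates the structure of the flume study: the fixed
32-treatment design (species, functional group, mass, density — by
default the packaged design, deliberately including its two
high-leverage treatments), individual rates from the metabolic spec,
and for each treatment two replicate runs
`R_r = c + offset_group + d I_TOT + ε_treatment + ε_replicate` with
Gaussian noise; `R_TOT` is the replicate mean with a CI from the
replicate spread. Defaults are matched to the packaged dataset:
`c = 35`, `d = 0.36`, treatment-level σ = 15 g m⁻² (giving R² ≈ 0.68 on
the fixture design). The between-replicate σ defaults to 5 g m⁻² — the
replicate variance is not recoverable from the published treatment
means, so this is a free package choice sized to the typical
replicate-spread CIs in the dataset. Values are not truncated at zero:
realistic configurations never approach zero, and truncation would bias
parameter-recovery studies.

What the generator does **not** emulate: hydrodynamic time series,
deposition–erosion dynamics, density saturation (overlapping areas of
influence at extreme densities), and — unless the `heteroscedastic`
flag is set — any variance increase with metabolic rate. Passing
recovery tests therefore show that the statistical pipeline is correct
under the stated noise model, not that the noise model is a complete
description of flume data.

Validation problem sizes, chosen to make Monte Carlo error negligible
at desk scale: 500 simulated studies for CI coverage (nominal 95%,
accepted band 91–99%) and slope unbiasedness (mean within 0.02 of the
true 0.36), 200 replicates for the AIC-penalty property, 10⁵ draws for
delta-vs-Monte-Carlo agreement.

## Known limitations

* The dataset analyses treatment means of two replicates; no
  replicate-level or mixed-effects modelling is attempted, and no
  weighting by the (strongly heterogeneous) response CIs.
* `R_BIO` uses the global-mean control; if per-flume controls were
  available the estimates would shift slightly.
* The linear `R_TOT`–`I_TOT` relation has substantial prediction error
  (residual σ ≈ 14.5 g m⁻²) and is sensitive to its two
  highest-metabolism observations (slope 0.36 with them, 0.17
  without — same sign, still significant).
* Temperature projections extrapolate a fixed-temperature experiment
  through a metabolic factor only; they assume density, behaviour and
  sediment physics are unchanged by warming.
* Unit ranges: masses in mg AFDW, rates in mW, densities ≤ a few
  hundred m⁻²; the model is not meant for densities where areas of
  influence overlap.
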