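---
title: "Model-based geostatistical mapping of grain selenium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistical mapping of grain selenium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(grainse)
```

This vignette is the package's account of the statistical model it
implements, the choices that were genuinely open, and what its synthetic
tests do and do not demonstrate.

## The model

A regional soil–crop survey observes, at each of ~500 sites, the grain Se
concentration of whichever staple cereal (teff or wheat) grows there,
eleven soil properties, and the values of gridded environmental
covariates. Writing y₁ for the log Se concentration of the target grain,
y₂ for the other grain and y₃ for a soil-based prediction of the target
grain (computable at *every* site because soil is measured everywhere),
the three variables are modelled jointly as

$$\mathbf{y} = X\boldsymbol\tau + \boldsymbol\eta + \boldsymbol\varepsilon ,$$

where the spatially correlated effects $\boldsymbol\eta$ share a single
Matérn correlation function and are coupled across variables by a
positive semi-definite covariance matrix $S$ (a linear model of
coregionalization), and the nugget effects $\boldsymbol\varepsilon$ are
spatially independent but may be correlated across variables
(covariance $T$). Because teff and wheat never grow at the same site,
their nugget covariance is a *structural* zero, imposed exactly through
the parameterization. Prediction at an unsampled location is the E-BLUP
— the universal (co)kriging predictor with the fixed-effect estimation
term included in the prediction error variance — so observations of y₂
and y₃ sharpen predictions of y₁ wherever the fitted cross-correlations
are non-zero.

### Parameters that matter

* `kappa` (dimensionless, default grid {0.25, 0.5, 1, 1.5, 2, 3}) —
  Matérn smoothness. It is never estimated jointly with the other
  covariance parameters; `profile_kappa()` fixes it at each grid value
  and the profile log-likelihood picks one. Joint estimation of κ and φ
  is notoriously ill-conditioned; profiling matches how the parameter is
  actually chosen in practice.
* `phi` (km) — Matérn distance parameter, estimated. Distance enters as
  h/φ with no √(2κ) rescaling, so φ values are comparable across κ only
  qualitatively.
* `T`, `S` — nugget and spatially correlated covariance matrices,
  parameterized through Cholesky factors (log diagonals) so every
  optimizer iterate is positive semi-definite, with the teff–wheat
  nugget entry pinned at zero by zeroing the corresponding factor
  element.
* `w0`, `payout` (both 0.05) — α-investing wealth and reward. The spend
  rule is α_j = W(j−1)/(1 + j − k_j) with k_j the index of the most
  recent rejection; each test costs α_j/(1−α_j), each rejection earns
  `payout`. The cited α-investing literature offers several schedules;
  this one satisfies the marginal-FDR theorem and its control is
  verified by simulation in the test suite rather than assumed.
* `rda` (55 μg/day), `serving` (300 g/day) — risk threshold provenance;
  their ratio, 0.183 mg/kg, is the concentration below which a daily
  serving fails to supply the allowance.

### Numerical choices

* Likelihood evaluations profile β out by GLS through one Cholesky
  factorization; REML adds ½log|XᵀV⁻¹X|.
* The covariance optimization runs a Nelder–Mead simplex from a
  moment-based start (per-variable empirical-variogram split of nugget
  versus spatial variance; empirical residual correlations, shrunk, for
  the cross terms), optionally from additional dispersed starts, then a
  BFGS polish. Objective tolerance 1e−6.
* Matérn evaluations use closed forms at half-integer κ and the Bessel
  function K_κ otherwise, with ρ ≡ 1 below h/φ = 1e−10 (Bessel underflow
  guard). Covariance factorizations add escalating jitter from 1e−10
  only on failure.
* Likelihood-ratio deviances that come out marginally negative
  (optimizer noise) are clamped to zero with a warning.
* Empirical variograms use Matheron's estimator on left-closed,
  right-open bins; empty bins are reported, not dropped. Nested
  variogram fits use pair-count weights refreshed into Cressie weights
  N(h)/γ(h)² over three passes.
* Factorial kriging solves one global ordinary-kriging system per
  covariate (all data on the left side, the chosen component's
  covariance on the right); by linearity, mean + nugget + short + long
  components reproduce the ordinary-kriging estimate exactly, which the
  tests assert to 1e−8. Above 2000 data the system is built on an evenly
  thinned subset.
* Leave-one-out cross-validation holds covariance and fixed-effect
  estimates fixed (re-estimating them ~500 times would be
  disproportionate and is not what re-prediction requires) and uses the
  Gaussian conditional identity on the precision matrix, which equals
  deletion and re-solving of the kriging system.

## The synthetic survey generator

There is no released survey, so `assemble_survey()` generates surveys
with the statistical structure the analysis assumes. Its defaults *are*
the study conditions of the test suite:

* 475 primary sites, stratified over a 400 × 300 km frame of 0.5-km grid
  nodes (one uniform draw per roughly equal-area stratum), plus 25 close
  pairs placed uniformly in the 100–1000 m annulus around a spread
  subset of primaries. The published cube-method sampler is deliberately
  not re-implemented; stratified uniform sampling preserves the two
  properties the analysis relies on — spread and near-uniform inclusion.
  The frame extent is chosen to match the scale of the real surveyed
  region (hundreds of km): with a Matérn κ = 2, φ = 15 km process, a
  much smaller frame would contain so few effective replicates of the
  spatial process that coregionalization parameters are not estimable at
  survey size — a property of the statistics, not of the code.
* One crop per site by a Bernoulli(0.5) draw (the realized teff/wheat
  split of the real survey is not public; the fraction is a config knob,
  not a claim).
* Soil properties with marginal skewness above 1 are generated
  log-normally (means and spreads on the scale of the published summary
  table), so the transform rule has true positives; the remainder are
  near-symmetric. A share of each property's log-scale variance is
  spatially structured.
* Grain log Se = crop-specific linear function of the true (transformed)
  soil predictors + a coefficient on the *long-range component* of
  precipitation (teff only; the wheat model mirrors the
  no-covariate-selected outcome) + coregionalized crop effects
  (variances and correlations patterned on the published trivariate
  fit: nugget correlations {0, 0.43, 0.20}, spatial correlations
  {0.44, 0.52, 0.42}, κ = 2, φ = 15 km) + nugget. Soil properties and
  covariates with zero coefficient are included so selection faces
  genuine null hypotheses.
* Covariate grids (10-km cells) are mean + long-range (30 km) +
  short-range (3 km) + white-noise fields with variance shares
  0.6/0.3/0.1.

What the generator does *not* emulate: real road-network access bias,
cropland masks, within-plot compositing of the five sub-samples,
detection limits, and non-Gaussian tails. Passing tests therefore show
that the machinery is correct and calibrated *under the model's own
assumptions*; they cannot show robustness to the ways real surveys
violate those assumptions.

## Design decisions that were genuinely open

* **Skewness estimator** — the population moment coefficient
  m₃/m₂^{3/2}; the simplest estimator consistent with the published
  summary-table magnitudes.
* **PBI grouping** — the phosphorus buffer index is computed as
  (P_s + 4.59·P_Olsen)/P_c^0.41, the single-addition form of the cited
  soil-P method; the typeset source equation is ambiguous, so the
  adopted grouping is stated here prominently.
* **ML versus REML** — fixed-effect selection tests use ML (LR tests on
  fixed effects are invalid under REML); the final predictive fit uses
  REML. Whether the original trivariate fits used ML or REML is not
  stated anywhere; REML is this package's documented choice.
* **Selection refits** — by default every selection step re-estimates
  the covariance parameters by ML (`refit_each = TRUE`). The
  `refit_each = FALSE` mode estimates them once under the null model and
  runs the sequential GLS likelihood-ratio tests at that fixed
  covariance; the resulting p-values are still asymptotically valid, and
  mFDR control — which requires only valid p-values — is unaffected.
  The fast mode is what the large replicate simulations use.
* **Adjusted R²** — defined as 1 − [RSS/(n−p)]/[TSS/(n−1)] on
  fixed-effects-only predictions of the target variable (0 for a
  constant-only model); no published definition exists to match, so
  printed values elsewhere are not comparable.
* **Close-pair placement** — uniform in the annulus; the field manual's
  fallback rules (duplicate field, next sample location) are protocol,
  not statistics, and are not simulated.
* **FKA support** — covariates are decomposed on the full grid and then
  extracted at sites (not decomposed on the sample support); the local
  mean is folded into the long-range surface.
* **Verbal scale** — the calibrated-language bins (<0.01 exceptionally
  unlikely, <0.10 very unlikely, <0.33 unlikely, 0.33–0.66 about as
  likely as not, >0.66 likely, >0.90 very likely, >0.99 virtually
  certain) are config-overridable; the source names the scale but not
  its bin edges.

## Problem sizes in the test suite

The simulation tests run at sizes chosen so that each property is
actually identifiable at desk scale: single-variable parameter recovery
at 150 sites; trivariate cross-correlation recovery at the survey's full
400 sites over the full regional frame, because the teff–wheat spatial
correlation (the two crops are never co-located) is weakly identified —
its profile likelihood is about one log-likelihood unit flat over ±0.3
at smaller sizes, so no optimizer effort can recover it there; FDR
control with replicate surveys of 150–200 sites and an exponential
(κ = 0.5) spatial component for speed; SSPE calibration at 250 sites.
The smoothness-recovery experiment simulates its fields with a small
nugget share (τ² = 0.1 of a unit total variance): κ is identified by the
near-origin behaviour of the variogram, and a heavy nugget masks exactly
that, making the profile likelihood over κ flat regardless of sample
size. Inside fitting loops the Matérn correlation for non-half-integer κ
is evaluated through a cubic-spline interpolant of the Bessel form
(absolute error below 1e−6, asserted in tests); all user-facing
evaluations are exact. The spirit of every check is unchanged by these
sizes; the test tolerances state what is actually asserted.

## Known limitations

* Isotropic, single-correlation-structure models only; no anisotropy, no
  per-variable ranges.
* ML/REML estimation of coregionalization correlations for variable
  pairs that are never co-located is weakly identified without close
  pairs; confidence in those estimates should come from profile
  likelihoods, not standard errors.
* No mean-unbiased lognormal back-transform is provided (the median
  back-transform and log-scale threshold probabilities cover the mapping
  use-case).
* The pipeline assumes one projected plane with km coordinates
  throughout; no datum or projection handling.
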