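---
title: "Quantifying microbial robustness from plate phenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbial robustness from plate phenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Robustness is the stability of a cellular function — a growth rate, a lag
phase, a product yield — across a defined set of perturbations. It is
distinct from tolerance (the ability to keep growing under stress) and from
mean performance: a strain can ferment well on average and still swing
wildly between conditions. Despite its importance for bioprocesses and
synthetic biology, robustness is rarely put on a number. This package
implements a complete workflow for doing so with microplate phenomics: fit
growth kinetics from plate-reader time series, compute performance
functions from endpoint chemistry, and score each strain × function over a
perturbation space.

```{r, eval = FALSE}
library(phenorobust)
sim <- simulate_experiment(seed = 1)          # 3 strains x 29 conditions x 3 reps
cal <- calibration_model(cdw_slopes = sim_cdw_slopes(sim$strains))
res <- run_pipeline(sim$timeseries, sim$layout, sim$endpoints, cal = cal)
res$robustness
```

## The robustness score

For a function $i$ of strain $S$ measured over a perturbation space $P$
(values $x_1, \dots, x_n$, one per perturbation), robustness is the
negative mean-normalized Fano factor:

$$R_{S,i,P} = -\,\frac{\sigma^2 / \bar{x}}{m}$$

where $\sigma^2$ is the (sample) variance across perturbations, $\bar{x}$
their mean, and $m$ the mean of the same function pooled over **all**
strains, perturbations and replicates in the analyzed dataset. Properties
that motivate this choice:

* $R \le 0$, with $R = 0$ (perfect stability) exactly when the variance is
  zero. Larger (less negative) is more robust.
* Division by $m$ makes $R$ dimensionless and puts functions measured at
  different orders of magnitude (a growth rate of 0.4 h⁻¹, a yield of
  0.05 g/g) on one comparable scale. The price is that $R$ is always
  relative to the dataset in which $m$ was computed; `m` is therefore
  recomputed per analysis and stored in every result.
* Because the Fano factor divides by the mean once (not twice, as the
  squared CV does), it does not explode for functions whose means lie
  between 0 and 1.

Two comparison metrics are provided on the same interface. The coefficient
of variation $\sigma/\bar{x}$ (`cv_robustness`; lower is more robust) and a
Kitano-style control-ratio score $\sum_p \psi(p)\, f(p)/f(0)$
(`kitano_robustness`; requires a control condition $0$, equal frequencies
$\psi$ by default). Every result carries a `higher_is_more_robust` flag so
downstream ranking never guesses an orientation.

## The four criteria and how the audit probes them

A usable robustness score should satisfy four criteria: (1) testing more
perturbations should not change $R$, only its statistical significance;
(2) positive and negative deviations from the reference level should both
lower $R$; (3) a higher (orientation-corrected) $R$ should reflect
genuinely lower dispersion; (4) $R$ should be dimensionless and comparable
across magnitudes. `criteria_audit()` evaluates each by Monte-Carlo
simulation and returns pass/fail with effect sizes.

Operationalizations worth spelling out, since each was a design decision:

* **Criterion 1, Kitano.** Kitano's formulation weights each perturbation
  by its frequency $\psi(p)$ — a property of the environment, not of how
  many conditions the experimenter assayed. The audit therefore evaluates
  the score in its frequency-weighted-sum form with $\psi$ fixed when the
  baseline space is defined; enlarging the tested space then scales $R$
  roughly linearly, a clear failure. The normalized (mean-ratio) form used
  by `kitano_robustness()` by default hides this by silently renormalizing
  the weights to whatever was tested.
* **Criterion 2.** Datasets $\{c-d,\,c+d\}$ versus $\{c,\,c\}$: the
  dispersed pair must score strictly worse. For the control-ratio score
  symmetric deviations cancel exactly — values $\{1, 3\}$ against control
  2 give $R = 1.0$, indistinguishable from perfect stability. Fano and CV
  both penalize.
* **Criterion 3.** One-sided degradation effects at two dispersion widths;
  the lower-dispersion dataset must rank more robust in ≥ 95% of
  replicates. All three metrics pass under their native orientations.
* **Criterion 4.** Two sub-checks: (a) rescaling all values by
  $k \in \{10^{-3}, 1, 10^3\}$ (with $m$ and the control rescaled along)
  must leave $R$ unchanged to $10^{-9}$ relative; (b) under Poisson-like
  noise (variance proportional to the mean, the standard model for
  count-like biological readouts; the dispersion parameter is the
  variance-to-mean ratio), a dataset with *lower* dispersion but mean in
  (0, 1) must still outrank one with *higher* dispersion and mean in
  (1, 10). The CV fails (b): dividing by a small mean amplifies rather than
  normalizes, so small-mean functions look spuriously fragile. For the
  Fano check the two datasets share the pooled $m$, exactly as
  `normalization_mean()` pools across the strains of one function.

With 1000 replicates per criterion the audit verdict is: Fano passes all
four; CV fails 4; the control-ratio score fails 1, 2 and 4. These verdicts
are asserted in the test suite.

## Growth kinetics

Growth curves arrive as Growth-Profiler green values (GV) or OD600.
`fit_growth_curve()` fits a cubic smoothing spline to the natural log of
the blank-corrected signal against time, with smoothness chosen by
generalized cross-validation (overridable via `spar`):

* $\mu_{max}$ is the maximum of the spline's first derivative, located on
  a dense grid (10× the input resolution by default); ties break to the
  earliest time, deterministically.
* The lag phase is the tangent construction: the $x$ coordinate where the
  line of slope $\mu_{max}$ through the inflection point meets the
  horizontal through $y_0$ (the spline value at the first timepoint),
  i.e. $\lambda = t_{inf} - (y_{inf} - y_0)/\mu_{max}$. Negative results
  clamp to 0 with a warning — a lag is physically nonnegative.
* $R^2$ is the coefficient of determination of the spline against the log
  data, on the log scale where the fit lives.
* **QC rule:** if $R^2 < 0.99$ (strict inequality, threshold
  configurable) the well is treated as not grown: $\mu_{max} := 0$, lag
  := NA. The rule is idempotent. Flat noisy baselines fail it naturally
  because a GCV spline through noise explains little variance.

Growth parameters are fitted on the GV-scale log signal directly: the
log-slope is invariant to linear rescaling, and the GV→OD calibration is
nearly linear over the growth range. Only endpoint values are converted to
OD, via

$$\mathrm{OD} = a\,\Delta^b + c\,\Delta^d + e\,\Delta^f,
  \qquad \Delta = \mathrm{GV} - \mathrm{GV}_{blank}$$

with published instrument constants as defaults ($a = 0.019$, $b = 1$,
$c = 3.82\times10^{-6}$, $d = 2.66$, $e = 3.111\times10^{-22}$,
$f = 10.5$, $\mathrm{GV}_{blank} = 26.3$): a dominant linear term plus two
power-law corrections, zero at the blank, monotone, continuous. The
conversion is a pluggable callable (`od_fun`) so another instrument's
calibration can be substituted without touching the pipeline.

## Performance functions

Five functions per well by default: $\mu_{max}$ (1/h), lag (h), CDW (g/L),
biomass yield and ethanol yield (g/g). Yields are computed on **total
consumed sugars** $\sum_s \max(\mathrm{initial}_s - \mathrm{final}_s, 0)$
over glucose, mannose, xylose, galactose and arabinose:

$$Y_{EtOH} = \frac{\mathrm{ethanol}}{\mathrm{consumed}}, \qquad
  Y_X = \frac{\mathrm{CDW}_{final} - \mathrm{CDW}_{inoc}}{\mathrm{consumed}}$$

CDW comes from the 48-h OD via a strain-specific gravimetric slope.
Numerical conventions, each configurable:

* The inoculum biomass (starting OD 0.02 × slope) is subtracted in the
  biomass yield — the numerator should be biomass *produced*
  (`subtract_inoculum = FALSE` disables).
* Yields are recorded missing when consumption falls below `min_consumed`
  (default 0.5 g/L, about five times the enzymatic-assay noise): below
  that floor the ratio divides one measurement error by another and can
  take arbitrarily large values, which would dominate any dispersion
  statistic. This generalizes the obvious "consumed ≤ 0 → undefined" rule.
* Additional readouts (biosensor signals, reporter fluorescence) can be
  added via `register_function()` and flow through the same machinery.

## Replicate slices, SEM and strain comparison

The headline $R$ for a strain × function is computed on **replicate
slices**: replicate $r$'s values across all perturbations form one slice,
$R$ is computed per slice, and the mean of the slice scores is reported
with their standard error (n = number of usable slices, typically 3).
Perturbations missing within a slice (e.g. lag of non-growing wells) are
dropped from that slice and counted in `n_missing`. A pooled mode
(`pooled = TRUE`) treats all replicates as one sample and reports no SEM.

Strain pairs are compared per function with an unpaired two-sided t test
on the slice scores — Welch by default, since three slices per group give
no basis for assuming equal variances (Student's available via
`var_equal = TRUE`) — and Holm–Bonferroni adjustment applied within each
function's family of strain pairs, matching how per-function significance
is reported. Groups with zero variance on both sides are handled
explicitly (p = 1 at equal means, p = 0 flagged `degenerate` otherwise)
rather than erroring. Sample variance (denominator $n-1$) is the default
estimator throughout, appropriate for small perturbation counts; the
population estimator is available (`var_type = "population"`), under which
duplicating every perturbation leaves the Fano score exactly unchanged
(with sample variance the drift is the known $O(1/n)$ degrees-of-freedom
factor).

`tradeoff_table()` pairs each strain × function's mean performance (over
exactly the records that entered the robustness computation) with its $R$,
producing the tidy table from which robustness–performance trade-offs are
read.

## The synthetic generator

`simulate_experiment()` produces complete experiments — time series,
layout, endpoints, ground truth — emulating the study design this workflow
targets: 3 strains × 29 single-component lignocellulosic conditions × 3
technical replicates, one 96-well plate per strain, 0–48 h sampled every
30 min.

* **Growth model.** The log blank-corrected signal follows a modified
  Gompertz curve $y(t) = y_0 + A\exp(-\exp(\mu_{max} e/A(\lambda - t) + 1))$,
  chosen because its maximum log-slope is exactly $\mu_{max}$ and its
  tangent construction recovers the lag in closed form. One subtlety: the
  tangent lag of the curve *as observed from* $t_0$ is
  $\lambda + (y(t_0) - y_0)/\mu_{max}$, which exceeds $\lambda$ noticeably
  for slow growers (up to ~3 h at $\mu = 0.05$ h⁻¹) because the curve
  never quite touches its baseline. The generator reports this analytic
  tangent lag (`lag_tangent`) as ground truth, so lag recovery is exact by
  construction rather than approximately so.
* **Effects.** Each condition carries multiplicative effects on rate, lag,
  capacity and yields (aldehyde-like conditions degrade everything, the
  harshest abolishes growth; weak acids mainly cut capacity and biomass
  yield; pentoses are neutral to mildly beneficial). Each strain carries a
  sensitivity exponent $s$ (effective multiplier $= \text{mult}^s$;
  defaults 0.6 / 1.0 / 1.4), building in a known dispersion ordering that
  ranking tests can verify. The ordering guarantee is cleanest on the
  yield functions: for $\mu_{max}$ the growth-abolishing condition
  contributes a strain-independent 0 (per the QC rule) whose absolute
  deviation scales with the strain mean, which legitimately compresses the
  $\mu_{max}$ ordering.
* **Noise.** Multiplicative lognormal on the signal (σ = 0.02; plate
  readers scale their noise), additive Gaussian on concentrations
  (0.1 g/L, enzymatic-assay scale) and OD (0.02), all truncated at
  physical zero and all configurable; `noise = NULL` gives exact noiseless
  data for closure tests. A single master seed drives everything through
  deterministic per-well substreams, so reproducibility is a hard
  contract.
* **What it does not emulate.** Mechanistic inhibitor kinetics, diauxie,
  evaporation or edge effects, correlated (plate-position) noise, or real
  hydrolysate chemistry. Passing recovery tests therefore demonstrates
  that the estimators invert the stated generative model, not that they
  are unbiased on arbitrary real plates.

## Validation scales

The checks shipped in the test suite use: noiseless closure and recovery
on the full 3 × 29 × 3 design (yields match ground truth to 1e-9; fitted
$\mu_{max}$ within 5% relative and lag within 0.5 h); 100 noiseless
Gompertz curves spanning $\mu_{max} \in [0.05, 0.5]$ h⁻¹ and
$\lambda \in [0, 10]$ h for parameter recovery; 100 noisy seeds for the
ranking frequency of the built-in sensitivity ordering (checked on ethanol
yield); 1000 Monte-Carlo replicates per audit criterion; and brute-force
oracle equivalence of all three metrics at $10^{-12}$.

## Known limitations

* $m$ ties every $R$ to the analyzed dataset; scores from different
  datasets are not directly comparable (recompute on the union).
* The GV→OD functional form is a calibration convention; for other
  instruments supply `od_fun`.
* Perturbation frequencies other than equal are accepted
  (`perturbation_space(weights = ...)`) but only exercised by the audit;
  estimating realistic frequencies from field data is out of scope.
* With n = 3 slices the Welch test is conservative; printed p-values on
  real data should be read as ordering evidence, not sharp error rates.
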