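---
title: "Post-prandial energetics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-prandial energetics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdaflux)
```

`sdaflux` analyses the digestive energetics of small aquatic animals — the
kind of dataset produced when a fish is fed a meal and followed through the
post-prandial period with intermittent-flow respirometry, static flux
chambers, weekly weighing and qPCR. This vignette is the package's account of
the science it implements: the models, the parameters that matter, the
numerical choices, and what the synthetic-data generator can and cannot tell
you about real data.

## Oxygen consumption from intermittent-flow traces

During a sealed *measure* phase the animal draws down chamber oxygen; a
*flush* phase then renews the water. For each measure cycle the package fits
an ordinary least-squares regression of oxygen concentration (µmol l⁻¹)
against time (h) and converts the slope $b$ into a mass-specific rate

$$\dot{M}_{O_2} = -\,b \, \frac{V_{chamber} - V_{fish}}{M} \quad
  [\mu \text{mol O}_2\, \text{g}^{-1}\, \text{h}^{-1}],$$

with volumes in litres and body mass $M$ in grams. The fish displaces part of
the chamber, so the effective volume is chamber minus fish volume; fish
density is taken as 1 g ml⁻¹ when no volume is supplied.

Cycle quality control (`qc_config()`) rejects regressions that a respirometry
operator would reject by eye:

* `min_r2 = 0.9` — a poorly fitting decline usually means activity or mixing
  artefacts;
* `max_positive_slope = 0` µmol l⁻¹ h⁻¹ — oxygen must not rise while the
  chamber is sealed;
* `min_points = 5` — slopes from fewer samples are too uncertain.

A perfectly flat cycle has an undefined coefficient of determination (zero
total variance). It is treated as a perfect fit — and passes QC with a rate
of zero — only when the residual standard deviation is below $10^{-9}$;
anything else that flat-lines with scatter fails on `min_r2`.

## Standard metabolic rate

SMR is the floor of the rate series once the post-prandial response has
decayed. `estimate_smr()` takes the mean of the lowest `smr_quantile`
(default 0.2) fraction of qc-passing rates in the SMR window, by default the
final 25% of a 24-h record.

Two smoothing choices deserve explanation. Low-quantile estimators are the
standard way to find a metabolic floor, but applied to noisy cycle values
they chase the noise downward: the mean of the sub-quantile tail of a
Gaussian sits about $1.4\sigma$ below the true mean, which for a typical
cycle noise of 0.25 µmol g⁻¹ h⁻¹ is a ~5% underestimate of SMR — and every
unit of SMR error propagates into the magnitude integral multiplied by the
response duration. `estimate_smr()` therefore first applies a long rolling
median (`smr_smooth_cycles = 13`, about three hours of 15-min cycles). A
rolling median leaves monotone stretches of a series untouched, so it does
not distort the approach to the floor; near the record ends the window stays
at full width anchored inside the series (rather than shrinking), because a
half-smoothed final cycle is exactly the kind of spurious dip a low-quantile
estimator would select. SDA extraction, which needs to follow the shape of
the response, uses a separate light rolling median (`smooth_cycles = 3`).

## The specific dynamic action response

Fed animals enter the respirometer, so the response window opens at the first
qc-passing cycle. The response is considered over when the (smoothed) rate
stays at or below $SMR \times (1 + \texttt{end\_tolerance})$ — default 10%
above SMR — for `consecutive_below = 3` consecutive cycles; the end point is
the midpoint time of the first cycle of that run, clipped to the record end
if the animal never recovers. The run is searched from the smoothed peak
onward: read literally, "first run of below-threshold cycles" would terminate
the response at its own onset, since the rate starts near SMR and rises.

From the response window the package reports:

* **net peak** — maximum smoothed excess over SMR (µmol O₂ g⁻¹ h⁻¹);
* **duration** — end minus start (h);
* **magnitude** — trapezoidal time-integral of $\max(\dot{M}_{O_2} - SMR, 0)$
  (µmol O₂ g⁻¹). Because magnitude is an area its natural unit has no
  per-hour term; the `magnitude_rate_units` field repeats the same number
  under the per-hour label often used in print, without rescaling.

Two exclusion rules mirror practice: animals whose fraction of qc-failing
cycles exceeds `max_fail_fraction = 0.4` are excluded as too active for a
reliable estimate, and responses shorter than `min_duration = 4` h are
excluded as likely meal regurgitation (a ~3-h response is the signature
case).

## Nitrogen and acid–base budgets

Static flux chambers turn concentration changes into whole-animal fluxes:

$$J_X = \frac{([X]_f - [X]_i)\, V}{M\, t}
  \quad [\mu\text{mol (or } \mu\text{Eq)}\ \text{kg}^{-1}\, \text{h}^{-1}],$$

with chamber water volume $V$ (l), body mass $M$ (kg) and interval length $t$
(h). The sign convention is fixed throughout the package: excretion into the
water (accumulation) is positive. Titratable alkalinity comes from acid
titration to the pH 4.0 endpoint; a two-stage titration (automatic to pH 4.3,
manual to 4.0) is handled by summing the stage volumes. The net acid–base
flux is $J_{TAlk} - J_{TAmm}$; negative values indicate net base uptake
(acid excretion), positive values net base excretion.

The cumulative ammonia budget integrates only the above-baseline excess,
$\sum_k \max(J_k - J_{baseline}, 0)\, M\, t_k$, clamping sub-baseline
intervals to zero; the baseline is user-supplied (typically a pre-feed or
unfed-control mean — the package deliberately does not guess it). Dividing
the excess by the ammonia contained in the meal expresses how much of the
excretion direct absorption could account for; values above 100% are flagged
as catabolic in origin.

Ammonia speciation follows Henderson–Hasselbalch,
$[NH_3] = TAN / (1 + 10^{pK' - pH})$ and $P_{NH_3} = [NH_3]/\alpha_{NH_3}$.
The apparent $pK'$ and the solubility $\alpha_{NH_3}$ depend on temperature
and ionic strength, so they are explicit parameters of
`speciation_params()` rather than hidden constants; the defaults are
freshwater values near 23°C at an assumed ionic strength of 125 mmol l⁻¹.

### The oxygen cost of acid secretion

Gastric acid secretion is ATP-driven at one proton per ATP, so an acid load
can be priced in oxygen: $cost = load / \rho$ with $\rho$ the H⁺:O₂
stoichiometry. Published estimates of $\rho$ span 5.0 (ideal pump) down to
2.3 (allowing proton back-leak), so `acid_cost()` takes $\rho$ explicitly and
the two bounds bracket the true cost. The load itself is either supplied
directly or computed as buffer capacity × pH shift × ration. Dividing the
cost by the SDA magnitude gives the share of the post-prandial response
attributable to acid secretion directly — a few percent in a small teleost,
which is the quantitative argument that most of the SDA reduction seen in
achlorhydric animals must come from downstream protein handling, not from
the pump itself.

## Growth and expression arithmetic

Growth uses the standard instantaneous rate
$g = (\ln M_2 - \ln M_1)/\Delta t$, reported as $G = 100\,g$ in % day⁻¹
(weekly weighing, $\Delta t = 7$ d by default); weekly rates telescope
exactly to the whole-trial rate in log space, which the tests exploit. Feed
conversion is feed intake over mass gain; an interval without growth yields a
flagged `NaN` rather than an error so trial tables keep their rows. Condition
is Fulton's $K = 100 M_b / L^3$.

Relative expression uses the $2^{-\Delta\Delta C_t}$ model. Normalizing
against the geometric mean of several reference genes is, on the $C_t$
scale, simply the arithmetic mean of their $C_t$ values — that is the
default; averaging the reference genes arithmetically on the linear scale is
available as an option, as is an efficiency-corrected base
$(1+E)^{-\Delta\Delta C_t}$. The plain base-2 model is the default because
it is the convention the quantification is usually reported under;
efficiencies are carried in the table either way. Technical replicates are
averaged per sample and gene before any differencing.

## Group comparisons

`compare_groups()` encodes the conventional physiology testing cascade:
Shapiro–Wilk normality per group at α = 0.05, then a median-centred Levene
test choosing between Student's and Welch's t-test, with a Wilcoxon rank-sum
fallback when normality fails — and a recorded decision trail so the chosen
branch is auditable. Endpoints with known unequal variances (the four
respirometry summaries) should force `policy = "welch"`. The repeated-
measures design (genotype × week, subjects as the repeated unit) is fitted by
`rm_anova()` as a univariate ANOVA with a subject error stratum, followed by
Tukey-adjusted pairwise week contrasts; the choice of a median-centred
Levene test is a convention, as is the univariate (rather than multivariate)
treatment of the within-subject factor.

## What the synthetic generator emulates — and what it does not

`sim_config()` fixes the study conditions the package is designed around:
12 animals per genotype; SMR means 5.42 (wild-type) and 5.10 (knockout)
µmol O₂ g⁻¹ h⁻¹; a wild-type response peaking at 3.03 µmol O₂ g⁻¹ h⁻¹ with a
15.25-h duration; a −21.8% knockout effect on magnitude and −11% on duration
(the knockout peak is derived from these two effects, so the magnitude
contrast is exact by construction); Gaussian cycle noise of
0.25 µmol O₂ g⁻¹ h⁻¹; chamber water samples at 0, 3, 6, 9 and 24 h; an
8-week growth trial (3 control, 2 drug, 3 recovery weeks) with a 45.2%
growth depression from the second treatment week through the second recovery
week; and a −1 log₂ knockout effect on the intestinal satiation transcript.

Choices that the data themselves do not pin down were made once and
documented here:

* **Response shape.** The excess-rate curve is a smoothstep rise to an apex
  at 45% of the duration followed by a square-root fall reaching exactly zero
  at the duration. The compact support makes "duration" a well-defined
  generator truth, and the steep terminal fall means the threshold-crossing
  end rule recovers that truth to within a few percent; its closed-form area
  ($peak \times (t_{apex}/2 + 2(D - t_{apex})/3)$) is the magnitude truth.
* **Between-animal spread.** Standard deviations of 0.4 (SMR), 0.35 (peak)
  and 1.0 h (duration) describe moderate inter-individual variation — enough
  that group means are estimated with realistic uncertainty, while an
  a-priori power calculation puts the documented −21.8% magnitude contrast
  at ~95% power for a Welch test at n = 12 per group.
* **Flux contrasts.** The generator must reproduce two published-style
  contrasts with different bases — a 3.65-fold group ratio of post-feed
  ammonia flux and a 5-fold ratio of cumulative excess above baseline.
  Solving both at the first post-feed interval gives baseline multipliers of
  10.8 (wild-type) and 2.96 (knockout), decaying with a 9-h half-life.
* **Oxygen samples** are back-computed from each cycle's rate through the
  chamber mass balance, so `compute_mo2()` inverts the generator *exactly*
  in the noise-free limit — the round-trip identity the test suite leans on.

The generator deliberately does **not** emulate: within-cycle biological
drift (each sealed phase is exactly linear), right-skewed activity noise
(cycle noise is symmetric Gaussian, which is *harder* on a low-quantile SMR
estimator than real, activity-dominated noise), background microbial
respiration, temperature or oxygen-saturation drift, chamber mixing lags, or
mechanistic gut chemistry. Passing parameter-recovery tests therefore shows
that the estimators are consistent and unbiased under a clean, known
data-generating process — not that they are robust to every artefact of a
live recording.

## Numerical notes and degenerate inputs

* Integrals are trapezoidal on the observed cycle grid; the magnitude of a
  piecewise-linear response with knots on the grid is recovered exactly, and
  a brute-force Riemann oracle agrees to $10^{-9}$ relative.
* Rolling medians use an odd window; at the series edges the SDA smoother
  shrinks its window symmetrically while the SMR smoother keeps full width
  anchored inside the series (see above).
* The low-quantile SMR mean takes $\max(1, \lfloor n q \rfloor)$ values, so
  tiny windows still return an estimate; fewer than `min_cycles_for_smr`
  qc-passing cycles in the window is an error, not a guess.
* A response that never exceeds SMR has duration 0, peak 0 and magnitude 0.
  Constant data through `rm_anova()` report F = 0 and p = 1 rather than the
  0/0 artefact of a zero-variance fit. Constant samples in
  `compare_groups()` fail the normality gate by definition and fall to the
  rank test, whose degenerate all-ties p-value is reported as 1.
* Problem sizes in the test suite are desk-scale by design: cohorts of 12+12
  animals at 96 cycles each, 100-replicate power checks, 1000-point oracle
  sweeps. They complete in about a minute while leaving the Monte-Carlo
  margins (±10% recovery bands, ≥90% detection rates) comfortably wide.

## Known limitations

Percent air saturation is not converted to concentration (supply µmol l⁻¹,
or pre-multiply by your own solubility factor); background respiration
correction is limited to subtracting a user-supplied blank slope; the
acid-cost model prices only the pump itself, not mucus or bicarbonate
secretion; and the flux chamber model assumes instantaneous mixing and no
volatilization. Blood acid–base status is out of scope — the package budgets
what crosses the animal–water interface.
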