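---
title: "Muscle assessment with multi-frequency bioimpedance: model, fitting and simulation"
author: "muscleBIA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle assessment with multi-frequency bioimpedance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleBIA)
```

## The measurement and the model

Multi-frequency bioimpedance analysis (mfBIA) drives a small alternating
current through a muscle at many frequencies — here a sweep of 256
frequencies from 4 to 1000 kHz — and records the complex impedance at each.
At low frequency, cell membranes block current, which is confined to the
extracellular fluid; at high frequency, membranes are shorted and current
uses both compartments.  In the complex plane (reactance magnitude against
resistance) a recording traces a depressed circular arc between the
zero-frequency resistance $R_0$ and the infinite-frequency resistance
$R_\infty$, described by the single-dispersion Cole model

$$Z(f) = R_\infty + \frac{R_0 - R_\infty}{1 + (j f/f_c)^\alpha},$$

where $f_c$ (the centre frequency) is the frequency of maximal reactance at
the arc apex and $\alpha \in (0, 1]$ is the dispersion exponent: $\alpha = 1$
gives an undepressed semicircle, smaller $\alpha$ a flatter arc (maximum
reactance $\tfrac{R_0 - R_\infty}{2}\tan\tfrac{\alpha\pi}{4}$).

From the fitted state the package derives the eight parameters conventional
in muscle mfBIA, with the 50 kHz readout computed from the fitted model
(model evaluation is noise-robust; interpolating raw samples is not):

* $R$, $X_c$: model resistance and reactance at 50 kHz (ohm);
* $Z = \sqrt{R^2 + X_c^2}$ and $PA = \arctan(X_c/R)$ in degrees;
* $R_e = R_0$: extracellular resistance; $R_i = R_e R_\infty/(R_e - R_\infty)$:
  intracellular resistance (the hidden branch of the parallel circuit);
* $M_c = 1/(2\pi f_c (R_e + R_i))$: membrane capacitance, with $f_c$
  converted from kHz to Hz so the result is in farad.

Physiologically, $Z$, $R$ and $R_e$ reflect muscle density and local
hydration, $X_c$ and $PA$ membrane energy storage and fibre size, $f_c$
resting tension/tissue density, and $R_i$ and $M_c$ cellular metabolic and
membrane transport activity.

### A note on membrane-capacitance units

The normative table packaged with this package labels $M_c$ "pF" exactly as
printed in its source, yet inserting the same table's $f_c$, $R_e$, $R_i$
means into the defining formula yields values of order $10^{-8}$ F — tens of
nanofarad, numerically on the same scale as the printed "pF" numbers
(men biceps: `r round(mcFrom(42.3, 114.0, 140.8) * 1e9, 2)` nF vs printed
17.5).  The unit label is therefore treated as ambiguous: the package stores
$M_c$ in farad, reports in nF (the scale the printed numbers actually live
on) and uses the printed $M_c$ values only in unit-free comparisons
(percent changes and z-scores), never rescaled silently.

## Fitting a spectrum

`fitCole()` is deterministic and has two stages:

1. **Algebraic circle initializer** (`fitCircle()`, a Kasa fit): linear least
   squares on the algebraic circle residual, exact for points on a circle.
   The real-axis intercepts give starting $R_0$ and $R_\infty$; the
   depression angle of the centre below the real axis,
   $\phi = (1-\alpha)\pi/2$, gives a starting $\alpha$; the frequency of
   maximal measured reactance starts $f_c$.
2. **Levenberg–Marquardt refinement** of all four parameters on the stacked
   complex residuals, equally weighted per frequency (no weighting is
   implied by standard practice; reciprocal-magnitude weighting is a
   switch).  The optimiser works on unconstrained transforms — logs of
   $R_\infty$, $R_0 - R_\infty$ and $f_c$, logit of $\alpha$ — so every
   iterate is a valid parameter set and the $R_\infty < R_0$, $0 < \alpha
   \le 1$ constraints can never be violated.  Convergence tolerances are
   `ftol = ptol = 1e-14` with a 200-iteration cap; non-convergence is
   flagged in the diagnostics rather than raised.

On noiseless 256-point sweeps the generating parameters are recovered to
better than $10^{-6}$ relative; at 1% proportional noise the median absolute
relative error of each parameter is below 1% (both are asserted in the test
suite).  `qualityCheck()` mirrors the visual plausibility screen applied
during acquisition: it rejects a fit whose complex-plane RMSE exceeds 5% of
the arc width $R_0 - R_\infty$, whose data span less than half of the model
arc's central angle $\alpha\pi$, or whose fitted $f_c$ lies outside the
swept range (an extrapolated apex).  The thresholds are arguments, and the
defaults are deliberately conservative screens, not statistical tests — the
acquisition-time criterion they emulate was itself visual.

## The normative reference layer

`loadReference()` ships mean ± SD for 8 muscles × 2 genders × 8 parameters
(n = 25 healthy adults aged 20–69 per cell).  Two comparison tools sit on
top:

* `percentChange()` / `genderContrastTable()`: women-versus-men percent
  changes with the men's mean as baseline, rounded half away from zero to
  integers to match the printed style.  Recomputing the contrast table from
  the packaged means reproduces the printed integer in most cells; the
  remainder differ by exactly one percent point because the printed values
  were computed from unrounded subject-level data.  Those cells carry both
  values and a flag — the printed value stays authoritative for display,
  the recomputed one for tests.
* `zscoreAgainstReference()`: per-parameter $z = (x - \mu)/\sigma$ for a new
  recording against its muscle/gender cell, flagging $|z| > 2$.  Normality
  of each cell is an assumption here; for the heavy-tailed cells (see
  below) the z-score is a screening index, not a calibrated percentile.

One packaged cell is printed with an SD larger than its mean (women triceps
$f_c$ 63.3 ± 95.4, likely extreme skew or a typo), and one more sits at the
same pathology (women rectus femoris $f_c$ 53.7 ± 69.3).  They are stored
verbatim and flagged where they matter (generation, below).

## Cohort statistics

The comparison machinery reproduces the reference study's procedure:

* **Gender contrasts** always use the two-sided Mann–Whitney test (some
  underlying data sets were non-normal), men as baseline, one value per
  subject — bilateral gastrocnemius recordings are averaged within subject
  first, matching the n = 25 per gender of the normative table.
* **Age contrasts** pool the 20s+30s decades against the 50s+60s decades
  within gender (the 40s are excluded by design; pooling buys power at
  n = 50).  Data are first screened with Shapiro–Wilk and a variance-ratio
  F-test at the same 0.05 level; both pass → pooled two-tailed unpaired
  t-test, otherwise Mann–Whitney.  The named tests are choices: the source
  procedure names "normal distribution and equal variance" tests but not
  which; Shapiro–Wilk has the best small-n power and the F-ratio is the
  classical companion of the pooled t-test.  Both are configurable, as is
  Welch's t-test in place of the pooled form (the pooled form matches the
  classical textbook the procedure cites).
* Mann–Whitney p-values are exact (equal to enumeration over all rank
  assignments) for tie-free samples with $n_a + n_b \le 16$, and a
  tie-corrected normal approximation with continuity correction otherwise.
* Significance means $p \le 0.05$ ("$p > 0.05$ nonsignificant" taken at
  face value).  No multiple-testing correction is applied, matching the
  procedure being reproduced.
* Percent changes always use group means (not medians), even on the
  nonparametric branch, because the printed percentages align with the
  printed means.

## The synthetic cohort generator

No subject-level data are deposited with the source study, so the package
includes a generator whose defaults *are* the study design: 5 men and 5
women per age decade from 20 to 69 (50 subjects), eight muscles with
bilateral gastrocnemius (450 spectra), 256 log-spaced frequencies from 4 to
1000 kHz, and 1% proportional Gaussian noise applied independently to the
resistance and reactance samples.  Demographics are sampled around the
published per-decade weight/height means.

Calibration (`calibrateGenerator()`) inverts the printed normative means
into Cole state per muscle × gender cell:

* $R_e$, $R_i$ and $f_c$ are sampled directly from truncated normal
  distributions with the printed means and SDs, and $R_\infty$ is derived
  through $R_\infty = R_e R_i/(R_e + R_i)$.  Sampling in $(R_e, R_i)$ space
  rather than $(R_0, R_\infty)$ space is deliberate: $R_i$ is convex in
  $R_\infty$, so sampling $R_\infty$ and deriving $R_i$ would inflate the
  $R_i$ mean by second-order terms of order
  $R_0^2/(R_0 - R_\infty)^3 \cdot \mathrm{Var}(R_\infty)$ — tens of ohms in
  the high-variance cells — while direct sampling makes the printed means
  exact targets by construction.
* Truncation (default lower bound 10% of the cell mean, keeping every
  sampled resistance and frequency positive) would itself shift the mean of
  high-CV cells upward — the women abductor $R_i$ cell (mean 133.9, SD
  214.7) by tens of ohms.  The sampler therefore solves for the underlying
  location whose *truncated* mean equals the printed mean (1-D root solve on
  the truncated-normal mean formula).  The truncated SD is consequently
  somewhat below the printed SD in those heavy cells; means were chosen as
  the exact targets because every downstream comparison (percent change,
  z-score, contrast) is anchored on means.
* $\alpha$ is fixed per cell by a root solve so that the model reactance at
  50 kHz at the cell means equals the printed $X_c$ mean.  This is the
  reason the model carries a dispersion exponent at all: with $\alpha = 1$
  the men-biceps cell would put $X_c(50\,\mathrm{kHz})$ at 25.1 ohm against
  a printed 18.1 ohm.  Solved values across the sixteen cells lie between
  0.59 and 0.85, squarely in the physiological range for skeletal muscle.
  A target $X_c$ above the $\alpha = 1$ semicircle value is geometrically
  unreachable and raises a calibration-infeasible error naming the cell.
  Fixing $\alpha = 1$ remains available as a fit switch (`fixAlpha`).
* The two $f_c$ cells whose printed SD is not below the mean have the
  sampling SD capped at the mean (flagged in the calibration table);
  without the cap a normal model for $f_c$ is unusable.
* Bilateral gastrocnemius parameters are drawn with within-subject
  correlation 0.8 through a Gaussian copula (side-to-side similarity is
  biologically expected but unquantified; the value is a config knob).
  No other cross-parameter covariance is assumed beyond the structural
  correlation that $R_\infty$ inherits from $(R_e, R_i)$ — the printed
  summaries cannot identify one.

One cohort uses one RNG stream seeded from the config seed; subjects draw
from it sequentially, so cohorts are reproducible bit-for-bit, subjects are
mutually independent, and changing only the seed changes the data but no
calibration constant.

**What the generator does not emulate:** inter-parameter correlations
within a subject beyond the structural one, frequency-dependent artifacts
(electrode contact, inductive segments), disease or exercise effects, and
any age trend (the default `age_effect = 1` encodes the reference finding
of no age effect; the multiplier exists to study power).  Tests passing on
synthetic cohorts therefore validate the pipeline's correctness and
calibration, not the biology of real recordings.

The emergent (non-calibrated) parameters are a useful cross-check: the
cohort means of $R$ and $Z$ at 50 kHz land within 10% of the printed means
even though nothing calibrates them — the single-dispersion model is
consistent with the printed table's structure.  The emergent $X_c$ cell
mean sits a few percent above its printed value because the reactance of
the mean parameters is not the mean reactance (Jensen again); this is a
known, accepted approximation of the generator.

## Numerical and design choices

* Reactance is handled as a positive magnitude (the negated imaginary part
  of impedance) throughout, matching plotting convention; spectra with
  slightly negative noisy reactance samples at the sweep ends are accepted.
* Percent rounding is half-away-from-zero (printed style), not banker's.
* Degenerate inputs fail loudly: $R_\infty \ge R_0$ (unbounded $R_i$),
  collinear circle points, non-positive frequencies, constant samples in
  the normality screen (routed nonparametric instead of tested).
* The t-test resolves zero-pooled-variance limits by continuity: equal
  means give $p = 1$, unequal $p = 0$, both flagged degenerate.
* Problem sizes in the shipped test suite were chosen to keep the full run
  in a few CPU-minutes while leaving no stochastic assertion marginal:
  fit-recovery uses 100 replicates of 256-point sweeps, the null
  calibration of the age contrast 1000 parameter-level cohorts, and the
  end-to-end recovery check one rendered cohort of 100 subjects per
  gender-decade cell for a single muscle.

## Limitations

* Single-dispersion Cole only: no double-dispersion tissue models, no
  fat/water composition estimation, no whole-body BIA equations.
* The normative table covers eight muscles in one healthy adult cohort
  (20–69 years); z-scores outside that population are extrapolation.
* Significance bands of the printed contrast table are stored metadata —
  they cannot be recomputed without the original subject-level data.
* The printed group means of $Z$ and $PA$ are assumed to be means of
  per-subject values; they are not exactly functions of the printed group
  mean $R$ and $X_c$ ($\arctan(18.1/84.2) = 12.1^\circ$ against a printed
  mean $PA$ of $13.1^\circ$), which is consistent with that assumption.
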