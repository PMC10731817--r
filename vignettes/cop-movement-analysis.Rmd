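---
title: "COP movement analysis for infant spontaneous-movement screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{COP movement analysis for infant spontaneous-movement screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantsway)
```

## The measurement model

An infant lying supine on a force plate continuously shifts its center of
pressure (COP) as it moves. The COP is the point of application of the
resultant ground-reaction force; unlike wearable sensors it captures the
global movement of all body parts at once, without touching the infant. The
method implemented here quantifies the COP trajectory during the
fidgety-movements (FMs) period and feeds two resultant-direction summaries —
velocity variability and signal complexity — into published prediction
equations for the dichotomous GMA outcome (absent vs normal FMs) and for the
MOS-R total score.

The processing chain is fixed by the study protocol it reproduces:

1. 3-minute supine recording, COP sampled at 50 Hz (a factor of 10 above the
   3 Hz upper bound of infant spontaneous-movement frequency);
2. 4th-order 10 Hz low-pass Butterworth filter;
3. the first 10 s discarded as acclimation time, the last 170 s analyzed
   (8500 samples);
4. movement parameters computed in the medial–lateral (X) and caudo-cephalic
   (Y) directions and for the resultant (R);
5. parameters normalized by the infant's current height and weight.

## Conventions where the source is silent

The study's parameter-formula sheet is not public, so every parameter is
pinned to the standard posturography definition and stated explicitly in its
function's documentation; each convention below is a deliberate design
choice.

**Filtering.** The named design is "fourth-order 10 Hz low-pass Butterworth";
whether it was applied causally or zero-phase is unstated. The default here
is zero-phase (forward–backward), because phase lag would bias the velocity
estimates that dominate the models; `zero_phase = FALSE` preserves the
causal single pass. The forward–backward pass is run over the series
extended by odd (point-reflected) padding whose length is set from the
slowest filter pole so startup transients decay below double precision
before the retained window. Filtering precedes trimming: the discarded 10 s
lead absorbs any residual edge effect.

**Velocity.** Forward differences scaled by the sampling rate,
$v_i = (x_{i+1}-x_i) f_s$. The resultant instantaneous velocity is the
magnitude of the planar velocity vector $\sqrt{v_x^2+v_y^2}$ — the dominant
stabilometry convention — not the derivative of the resultant displacement.
With this choice the mean resultant speed times the window duration
telescopes exactly to the planar path length, which ties the velocity and
distance parameters together. Velocity SD uses the sample (N−1) denominator;
skewness is the adjusted Fisher–Pearson statistic, defined as 0 for a
zero-variance series so degenerate inputs do not crash the battery.

**Resultant displacement.** $r_i = \sqrt{(x_i-\bar x)^2 + (y_i-\bar y)^2}$,
the distance from the window-mean COP. It is translation-invariant by
construction; `average_distance` is its mean and
`instantaneous_distance_rms` its quadratic mean (which always dominates the
arithmetic mean).

**Prediction ellipse.** The 95% ellipse is the prediction ellipse of the
sample covariance $\Sigma$ of the centered coordinates: area
$\pi\,\chi^2_2(0.95)\sqrt{\det\Sigma}$ with $\chi^2_2(0.95)=5.991$, axes
$2\sqrt{\chi^2_2(0.95)\lambda_i}$, orientation the leading eigenvector's
angle folded into $(-\pi/2, \pi/2]$ (an axis has no sign). A rank-deficient
covariance yields area 0 with a degeneracy flag rather than an error.

**Approximate entropy.** Pincus ApEn$(m, r, N)$ with Chebyshev distance and
self-matches included, $m = 2$ and $r = 0.2\,\mathrm{SD}$ — the de facto
standard for physiological series, adopted because the study states no
parameters. ApEn of a zero-variance series is defined as 0. The kernel is a
compiled O(N²) template count with early exit; a naive R double loop and an
independent library implementation serve as oracles in the tests. One
caveat discovered in testing: for exactly periodic series ApEn can be
marginally negative (order 1e-5) because the $m$ and $m+1$ template sets
have different sizes; the statistic is reported unclamped.

**Normalization.** Every length-dimensioned parameter (mm and mm/s) is
divided by current height (cm) and/or current weight (kg); areas are divided
twice; dimensionless parameters (velocity skewness, ApEn) and the ellipse
orientation are never rescaled. `height_weight` is the default because both
quantities differ systematically between clinical groups. The numeric scale
on which the published coefficients were estimated is not fully recoverable
from the source, so every report records the scheme used — users comparing
probabilities against the 0.15 threshold on differently scaled predictors
should recalibrate with `refit_logistic()`.

## The prediction equations

The logistic model ships with coefficients $\beta_0 = -3.354$,
$\beta_{IV} = -0.010$ (normalized resultant velocity SD) and
$\beta_{ApEn} = 0.895$ (resultant ApEn). The source prints two conflicting
values for the ApEn coefficient (0.0895 in the equation footnote, 0.895 in
the coefficient column); 0.895 is used because only it reproduces the
printed odds ratio $e^{0.895} = 2.447$ and the stated "2.44 times" risk
phrase. A probability at or above the threshold 0.15 classifies as absent
FMs; the tie goes to the positive class because a screening context favors
sensitivity.

The MOS-R model is log-linear. The logarithm base is unstated in the source;
base 10 is the default because the all-ones reference prediction
$10^{1.294} \approx 19.7$ lies inside the legal MOS-R range $[5, 28]$,
whereas $e^{1.294} \approx 3.65$ cannot (it would clamp to 5 always); a
config switch (`log_base`) preserves natural log. Estimates are clamped to
$[5, 28]$ with a flag. All three predictors must be strictly positive: a
negative velocity skewness is a hard domain error by default (the source's
handling of non-positive values is unreported), which the pipeline degrades
to a report without a MOS-R estimate while still emitting the
classification; an optional positive `shift` is available but off by
default.

Model diagnostics (likelihood-ratio χ², Nagelkerke R², Hosmer–Lemeshow with
deciles of risk and neighbor-merging of degenerate groups) are implemented
for refits; the published cohort's diagnostic values cannot be reproduced
without its data.

## Diagnostic accuracy

Proportion intervals use the exact Clopper–Pearson method (Beta quantile
form). The method is a reconstruction: the source does not name its CI
method, but exact intervals reproduce its printed sensitivity interval
(55–98 for 11/13), specificity interval (73–90 for 73/88), accuracy interval
(74–90 for 84/101) and NPV lower bound (91 for 73/75). The printed
predictive-value bounds are the exception — the exact PPV interval for 11/26
is ≈ 23–63 versus the printed 30–55, and the exact NPV upper bound rounds to
100 versus the printed 99 — so PPV/NPV intervals are reported by the same
exact method with this documented caveat. Display rounding is half-up to
integer percent; full precision is retained internally.

## What the simulator emulates — and what it does not

No recordings are deposited with the study, so the simulator is an
engineering stand-in that gives independent knobs for exactly the two
contrasts the models use. Per axis,

$$s(t) = A\, e^{d\,m(t)}\, b(t) + c\, w(t) + \text{offset},$$

where $b(t)$ is Gaussian noise synthesized in the frequency domain on the
movement band (flat to 1 Hz, $1/f$ amplitude decay to 3 Hz — movement energy
is in-band by construction), $m(t)$ is a slow (0.05–0.2 Hz) unit-SD
modulator so $e^{d m(t)}$ is a positive amplitude envelope, and $w(t)$ is
low-amplitude white noise (1.5 mm at unit gain). The envelope depth $d$
scales with `velocity_variability_gain` (normal 1.0, absent 0.35): a deeper
envelope spreads the speed distribution, raising the velocity SD. The
broadband weight $c$ is `complexity_gain` (normal 0.2, absent 0.6): more
broadband content raises ApEn. Carrier amplitude is 15 mm — millimetric sway
with centimetric excursions, plausible for a supine infant on a plate.
Anthropometrics are drawn from 55–68 cm and 4500–8000 g.

Cohorts add per-infant lognormal heterogeneity (CV 0.3) on envelope depth,
complexity gain and carrier amplitude. This is deliberate: with point-mass
regime parameters the two groups are perfectly separable in ApEn, the
logistic-refit likelihood has no maximum, and `refit_logistic()` correctly
raises a separation error. Heterogeneous gains are also simply the more
faithful cohort model.

Passing tests on simulated data therefore demonstrate that the pipeline
recovers by construction the directional contrasts (lower velocity
variability and higher complexity in the absent-FMs regime) and that the
numerics are correct end to end. They do not validate the published
coefficients on real infants: the simulator makes no attempt to mimic real
spectral fine structure, intermittency of fidgety bursts, crying/fussing
artifacts, or the empirical covariance between predictors.

## Numerical and testing choices

* Sampling-rate tolerance: inferred vs declared rate must agree within 1%;
  no resampling is attempted.
* Low-|Fz| samples in force-dialect inputs are masked and held at the last
  valid COP (leading runs back-filled), never interpolated: length is
  preserved for trimming without inventing motion. Default liveness
  threshold 1 N against an infant weight of roughly 50–70 N.
* Degenerate conventions: skewness(constant) = 0, ApEn(constant) = 0,
  degenerate ellipse area 0 with flag, undefined diagnostic metrics reported
  as NA with a flag.
* Logistic refits use IRLS with tolerance 1e-8 and at most 100 iterations;
  perfect separation and non-convergence are distinct errors.
* Test problem sizes: ApEn oracle equivalence on 50 series of N ≤ 300;
  ellipse closed form at n = 10 000; coefficient recovery from the printed
  model at n = 2000 (within 3 SE); regime sign recovery on a simulated
  cohort of 400 recordings at the full 180 s duration; Clopper–Pearson
  coverage over 2000 binomial draws.

## Known limitations

* The published coefficients are applied as printed; their predictor scale
  (normalization scheme) is an unresolved ambiguity of the source, recorded
  in every report.
* Only the absent-vs-normal FMs contrast is modeled; abnormal FMs were
  absent from the study sample and are out of scope.
* No frequency-domain sway parameters, sample/multiscale entropy, or
  sway-density analysis; no ROC machinery; no vendor binary formats (C3D,
  proprietary Kistler files).
* MOS-R items that do not reach the COP (mouth movements, smiles) are
  invisible to any force-plate method; an estimate near the observed 1.8
  point error of the source is the realistic ceiling, not exactness.
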