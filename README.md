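# infantsway

Quantitative assessment of infant spontaneous movements from force-plate
center-of-pressure (COP) recordings.

## The problem

Prechtl's General Movements Assessment (GMA) during the fidgety-movements
(FMs) period (3–5 months post-term) is the most sensitive observational
predictor of cerebral palsy, but it requires scarce certified assessors.
When an infant lies supine on a force plate, the trajectory of the center of
pressure — the point of application of the resultant ground-reaction force —
reflects the kinematics of the whole-body movement repertoire. `infantsway`
implements a published screening method built on that idea, for clinicians
and movement scientists who have a force plate but not necessarily GMA
expertise:

* **Signal input** — delimited force-plate exports, either raw force/moment
  channels (`time,Fx,Fy,Fz,Mx,My,Mz`; COP computed as
  `COPx = −(My + Fx·z0)/Fz`, `COPy = (Mx − Fy·z0)/Fz`) or precomputed COP
  coordinates (`time,copx,copy`).
* **Preprocessing** — the published chain: 50 Hz sampling check, 4th-order
  10 Hz low-pass Butterworth filter (zero-phase by default), the first 10 s
  discarded as acclimation time, the last 170 s analyzed.
* **Movement parameters** per medial–lateral (X), caudo-cephalic (Y) and
  resultant (R) direction: instantaneous velocity statistics (SD, RMS,
  skewness, range), path lengths, displacement RMS, mean distance, the 95%
  prediction ellipse (area `π·χ²₂(0.95)·√det Σ`), and approximate entropy
  ApEn(m = 2, r = 0.2·SD) — with normalization by the infant's current
  height and weight.
* **Prediction models** — the published equations as first-class objects:

  * absent-FMs logistic classifier
    `P(absent) = 1/(1 + exp(−(−3.354 − 0.010·IV_std_R + 0.895·ApEn_R)))`,
    classification threshold 0.15;
  * MOS-R (Motor Optimality Score-Revised, range 5–28) estimator
    `log10(MOS-R) = 1.294 + 0.172·log10(IV_std_R) − 0.219·log10(IV_skew_R)
    − 0.265·log10(ApEn_R)`.

* **Evaluation** — confusion matrices, sensitivity/specificity/accuracy/
  PPV/NPV with exact Clopper–Pearson intervals, predictor screening,
  logistic refitting (model χ², Nagelkerke R², Hosmer–Lemeshow test).
* **Simulator** — synthetic 180 s supine COP recordings in two regimes
  (normal-FMs-like vs absent-FMs-like) so the whole pipeline is testable
  without clinical data.

## Worked example

```r
library(infantsway)

rec  <- simulate_cop_recording(simulation_config("normal", seed = 42))
path <- file.path(tempdir(), "sim_normal_42.csv")
write_cop_csv(rec, path)

report <- run_analysis(path, dialect = "cop", subject = rec$subject)
print(report)
```

```
== COP analysis report (infantsway 0.1.0) ==
<subject sim_normal_42> height: 60.35894 cm, weight: 5283.077 g, group: normal_FM
analyzed 8500 samples at 50 Hz; filter: order 4, 10 Hz low-pass (zero-phase)
normalization: height_weight
IV R (Std) = 0.4095, IV R (Skew) = 2.0761, ApEn R = 0.5838
<fm_classification> P(absent FM) = 0.0554 -> normal_FM (threshold 0.15)
MOS-R estimate = 16.6
```

8500 samples are the last 170 s of the 180 s recording at 50 Hz. The three
printed predictors are the height-and-weight-normalized resultant velocity
SD, its skewness, and the resultant approximate entropy; the logistic
equation turns the first and last into P(absent FMs) = 0.055, below the 0.15
screening threshold, so the recording is classified as normal fidgety
movements, and the log-linear model estimates a MOS-R of 16.6 points.

Diagnostic accuracy of label sets is evaluated with exact intervals:

```r
dm <- diagnostic_metrics(confusion_counts(tp = 11, fp = 15, tn = 73, fn = 2))
print(dm)
#> sensitivity  85% (95% CI: 55-98)  [11/13]
#> specificity  83% (95% CI: 73-90)  [73/88]
#> accuracy     83% (95% CI: 74-90)  [84/101]
#> ppv          42% (95% CI: 23-63)  [11/26]
#> npv          97% (95% CI: 91-100)  [73/75]
```

A command-line front end with `analyze`, `batch`, `simulate` and `evaluate`
subcommands ships in `inst/cli/infantsway`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "infantsway", package = "infantsway"))')" \
    analyze --dialect cop --height 62 --weight 6000 recording.csv
```

## Scope notes

The package operates on COP time series; video recording and the
observational GMA/MOS-R scoring protocol are out of scope. The shipped model
coefficients are the published ones — the cohort data behind them are not
public — and `refit_logistic()` plus the model-file JSON schema exist so
users can recalibrate on their own cohorts. See the methods vignette
(`vignettes/cop-movement-analysis.Rmd`) for the model assumptions, parameter
conventions, simulator design and known limitations.
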