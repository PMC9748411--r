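# turtleBIS

Calibration of bioelectrical impedance spectroscopy (BIS) against
CT-derived adipose tissue in sea turtles, as a tested, reproducible R
pipeline.

## The problem

Field studies of sea turtle populations need a quantitative measure of
nutritional status. Body condition indices such as Fulton's
K = mass/SCL³ × 10⁴ are easy to collect but predict adipose tissue poorly.
BIS — resistance of the body to a weak alternating current at one or many
frequencies — predicts *nonadipose* (conductive) tissue mass from an
impedance index, and adipose tissue follows by difference with body mass:

```
nonat (kg) = b0 + b1 · length²/R + b2 · body_mass + b3 · time_after_capture
adipose (kg) = body_mass − nonat
```

where `length²/R` (cm²/Ω) uses straight or curved carapace length and one of
the resistances extracted from a BIS sweep (Rinf, R0, R50, Ri, Xc50), all
tied together by the Cole dispersion model
`Z(f) = Rinf + (R0 − Rinf)/(1 + (i f/fc)^α)`. Because BIS is purely
predictive it must be calibrated against a reference method — whole-body CT,
where adipose tissue occupies a characteristic negative Hounsfield-unit
band.

The package implements the whole protocol for anyone calibrating an
impedance device against imaging, in turtles or other taxa:

* **Synthetic data** — cohorts with Cole-consistent impedance
  (`generate_cohort()`) and voxel CT phantoms with ground-truth adipose and
  false-positive masks (`build_phantom()`), so every downstream stage is
  testable without any data download.
* **CT quantification** — HU-range estimation (`estimate_hu_range()`),
  inclusive thresholding (`threshold_segment()`), oracle- or rule-based
  false-positive removal (`remove_false_positives()`), and volume/mass
  accounting (`quantify()`), with minimal NIfTI I/O.
* **Calibration** — OLS fitting (`fit_calibration()`), exhaustive AICc
  ranking of candidate indices (`select_model()`), seeded 2/3–1/3 split
  validation (`split_validate()`), prediction (`predict_adipose_mass()`),
  and the published coefficient sets as fixtures (`printed_equation()`).
* **Agreement** — Bland–Altman bias/LOA with exact t-based CIs
  (`bland_altman()`), maximum allowed difference by inverting the
  Lu et al. (2016) agreement power formula (`max_allowed_difference()`),
  Passing–Bablok regression (`passing_bablok()`), Lin's concordance
  (`lin_ccc()`), and median/mean absolute percentage error (`mape()`).
* **Pipeline** — `run_pipeline()` chains simulate → scan → quantify →
  calibrate → agree with a checksummed manifest; a thin CLI wrapper lives
  at `inst/cli/turtlebis.R`.

## Worked example

Simulate a 49-animal cohort, calibrate on a seeded 33/16 split, and run the
agreement battery of the test-set predictions against the CT reference:

```r
library(turtleBIS)
co  <- generate_cohort(49, seed = 7)
sv  <- split_validate(co, "SCL2/R50", seed = 1)
sv$model
#> Nonadipose mass calibration [SCL2/R50], n = 33
#>   nonat = -0.002299 -0.2506*index +1.05*mass -0.09654*time
#>   R2 = 0.9990, RMSE = 0.187 kg, F = 9319 (3, 29), AICc = -8.93

agreement_report(sv$test_predictions$at_mass_ref,
                 sv$test_predictions$at_mass_pred)
#> Bland-Altman (n = 16): bias = 0.078 [-0.033, 0.189]
#>   LOA: -0.330 [-0.524, -0.136] to 0.486 [0.293, 0.680] (bias +/- 1.96 SD, SD = 0.208)
#>   proportional bias slope = -0.1858 [-0.3349, -0.0368]
#>   max allowed difference = 0.762 (power 0.80, alpha 0.05)
#>   CCC = 0.9436, Pearson r = 0.9662, MAPE(median) = 21.04%
#> Passing-Bablok (n = 16): slope = 0.8291 [0.6954, 1.0575], intercept = 0.1875 [0.0474, 0.2681]
```

Reading: the fitted coefficients sit near the generating equation
(−0.03, −0.29, 1.07, −0.11) with RMSE at the 0.19 kg noise scale; the
test-set bias of 0.08 kg is the population-level accuracy, the LOA
(−0.33, 0.49 kg) bound an individual prediction, and both limits fall
inside ±0.76 kg, the smallest difference this sample size can resolve at
80% power — i.e. the two methods agree at the resolvable margin.

Predicting from the published field equation instead:

```r
m <- printed_equation("final_scl_r50")
predict_adipose_mass(body_mass = 10, index = 3.375, time = 1, m)
#> [1] 0.41875
```

## Acceptance script

`scripts/acceptance.R` recomputes the headline published quantity from
scratch with the installed package — the maximum allowed difference for the
CCL²/Rinf model (n = 49, 80% power, α = 0.05) from the published bias/SD
summaries, by numeric inversion of the agreement power formula:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

The trained segmentation network of the original protocol is out of scope;
oracle- and rule-based removal stand in behind the same interface. Volumes
are read/written as uncompressed NIfTI-1 (no DICOM support). See the
methods vignette (`vignettes/bis-ct-calibration.Rmd`) for the model,
the generator's stated world, numerical conventions, and limitations.
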