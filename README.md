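# slicecov

Estimating how much of a liver tumor was covered by a thermal ablation
zone — from a **single axial CT slice pair** instead of full 3D
segmentation and registration.

## The problem

Percutaneous radiofrequency ablation of hepatocellular carcinoma is judged
by *percent tumor coverage*: the fraction of the pre-treatment tumor
volume that lies inside the devascularized ablation zone on follow-up
contrast CT,

```
coverage = 100 · V(tumor ∩ ablation) / V(tumor).
```

Measuring it properly needs 3D segmentation of both regions plus elastic
registration of the two scans — too slow and tool-heavy for routine
ablation confirmation. `slicecov` implements the slice-based shortcut: take
one axial image at the isocenter of the tumor and one at the isocenter of
the ablation zone, push both through a convolutional backbone, subtract the
feature vectors element-wise, and let a 100-tree random forest map the
difference vector to a coverage estimate — either one of four clinical
classes (≤50 / 50–70 / 70–90 / ≥90 %, i.e. incomplete → complete ablation)
or the percentage itself. The geometric intuition: well-covered tumors
have both isocenters on nearly the same axial plane, so shared landmarks
(ribs, diaphragm edge, liver texture) cancel in the feature difference;
poor coverage means different planes and a large residual.

The package is aimed at researchers developing ablation-confirmation
tools: it provides the full pipeline (ground truth, slice standardization,
leakage-safe augmentation cohorts, feature differencing, predictors,
ROC/error reports) plus a synthetic phantom generator, so every stage is
testable without patient data.

## Worked example

Generate three phantom cases with prescribed coverage, inspect the ground
truth, and standardize a slice:

```r
library(slicecov)

cohort <- generate_cohort(3, c(95, 70, 30), seed = 7)
cohort[, c("case_id", "target_coverage", "true_coverage", "axial_shift_mm")]
#> # A tibble: 3 × 4
#>   case_id  target_coverage true_coverage axial_shift_mm
#>   <chr>              <dbl>         <dbl>          <dbl>
#> 1 case_001              95          95.2           4.58
#> 2 case_002              70          70.0          15.3
#> 3 case_003              30          30.1          23.5
```

Low coverage is realized by displacing the ablation center axially —
case_003's ablation isocenter sits 23.5 mm (almost 5 slices) away from the
tumor's, which is exactly the signal the slice features pick up.

```r
case <- generate_case(cohort$spec[[3]], case_id = cohort$case_id[3])
percent_tumor_coverage(case$tumor_mask, case$ablation_mask)
#> # A tibble: 1 × 6
#>   tumor_volume_cm3 ablation_volume_cm3 covered_volume_cm3 percent_coverage
#>              <dbl>               <dbl>              <dbl>            <dbl>
#> 1             28.0                43.4               8.42             30.1
#> # ℹ tumor_equiv_diameter_cm <dbl>, ablation_equiv_diameter_cm <dbl>

standardized_roi_slice(case$pre_volume, case$tumor_mask, "case_003", "tumor")
#> <slice_image> case_003/tumor (original), 300x300 px, axial index 21

class_of(c(42, 65, 88, 95))
#> [1] <=50  50-70 70-90 >=90
#> Levels: <=50 < 50-70 < 70-90 < >=90
```

A 28 cm³ tumor corresponds to an equivalent sphere diameter of 3.8 cm —
`equivalent_sphere_diameter(31.8)` reproduces the 3.9 cm mean tumor size
of the population the phantoms emulate.

The whole pipeline — simulate, slice, augment, featurize, train, evaluate —
runs through one call:

```r
run <- run_pipeline(run_config(n = 150, level = 1, seed = 1))
glance(run$reg_reports$rf)    # held-out MSE/RMSE/MAE, error correlations
glance(run$class_report)      # accuracy, macro AUC / TPR / TNR
autoplot(run$class_report)    # one-vs-rest ROC curves
```

At this bundled benchmark scale (150 phantoms, 120:30 case split,
random-convolution backbone) the forest regressor's held-out MAE lands
around 10–14 percentage points — far below the 23–26 points of
label-permuted null refits — and the 4-class macro one-vs-rest AUC around
0.73–0.88 depending on the seed. See the vignette
(`vignettes/slice-coverage-estimation.Rmd`) for the model, the phantom's
assumptions, and what these numbers do and do not show.

A thin CLI covering simulate / coverage / evaluate / run-all lives at
`inst/cli/slicecov.R`:

```sh
Rscript inst/cli/slicecov.R simulate --n 20 --seed 7 --out phantoms/
Rscript inst/cli/slicecov.R coverage --tumor t.nii.gz --ablation a.nii.gz
```

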