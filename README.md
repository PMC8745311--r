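# fundusdr

Automated diabetic retinopathy (DR) screening from colour fundus
photographs, and the diagnostic-test statistics used to validate screening
graders against an ophthalmologist reference standard.

Population DR screening programmes photograph both eyes of every diabetic
patient (typically three captures per eye from a non-mydriatic camera) and
ask a grader — a physician or an algorithm — for a categorical call per
patient: retinopathy present (`DR`), absent (`NODR`), or image quality too
poor to decide (`UNG`, ungradable). `fundusdr` implements both halves of
that problem at desk scale:

* **A classical image-analysis pipeline** in the style of first-generation
  automated retinal image analysis systems: quality gating (sharpness,
  illumination, saturation inside the circular field), vessel-tree
  extraction from the green channel by multi-orientation morphological
  black-top-hat filtering, optic-disc and macula localization defining a
  fovea-centred polar coordinate frame in disc-diameter (dd) units,
  detection of dark lesions (microaneurysms `MA`, hemorrhages `HEM`) among
  the dark residual objects left after vessel suppression, detection of
  bright lesions (exudates `EX`, cotton-wool spots `CWS`) by white-top-hat
  filtering, and an annotated overlay (red markers for dark lesions, blue
  for bright, polar grid at 1 and 2 dd).

* **Grading rules**: an image is `DR` whenever lesions are seen — regardless
  of quality — else `UNG` if the quality gate failed, else `NODR`. Eyes are
  staged on the International Clinical DR severity scale
  (`NODR < MILD < MOD < SEV < PROL`, with the 4-2-1 rule for severe
  disease), macular edema (DME) is called when a bright lesion lies within
  1 dd of the fovea, patients take their worst eye's stage, and
  sight-threatening DR (STDR) means DME or severe-or-worse disease.

* **The validation battery**: rater cross-tabulations with UNG handling,
  sensitivity/specificity/predictive values with Wald
  continuity-corrected intervals, likelihood ratios with log-method
  intervals, Cohen's kappa with the Fleiss–Cohen–Everitt large-sample
  variance and an inverse-variance homogeneity test, single-operating-point
  ROC areas `AUC = (Se + Sp)/2` with comparison, Fagan post-test
  probabilities, and pooled two-proportion z-tests.

* **A synthetic generator** producing fundus images with full ground truth
  (field, disc, fovea, vessel raster, lesion list, intended gradability and
  stage) and screening cohorts with simulated error-prone raters, so the
  entire pipeline is testable without patient data.

## Worked example

```r
library(fundusdr)

# a synthetic right eye with moderate non-proliferative DR and macular edema
cfg <- sample_lesions(synth_image_config(seed = 3), stage = "MOD", dme = TRUE)
gen <- generate_eye_image(cfg)
an  <- analyze_image(gen$image)
an
#> <image_analysis> synthetic OD#1 gradable=TRUE lesions=13 (EX 4 HEM 5 MA 4)
an$frame
#> <retinal_frame> disc (512, 309) r=58.1; fovea (213, 300); dd=116.3 px
grade_eye(list(an))
#> <eye_grade> OD DR stage=MOD dme=TRUE
```

The detected disc sits 10 px (0.08 dd) from its true position (515, 300),
the fovea 2 px from (215, 300), and the eye grade matches the generated
truth:
moderate DR with macular edema — hence a sight-threatening patient if this
is the worst eye.

The statistics side works from per-patient diagnosis vectors or bundled
example tables. `screening_tables()` ships the cross-tabulations of a
3520-patient screening programme in which an automated grader (`ALG`) and
the screening physicians (`PCP`) were each compared with an
ophthalmologist consensus (`OPH`):

```r
tabs <- screening_tables()
diagnostic_accuracy(to_2x2(tabs$alg_oph))
#> Diagnostic validity (n = 2496)
#>   TP 455  FP 379  FN 80  TN 1582
#>   Prevalence                 21.43% (19.80-23.06)
#>   Sensitivity                85.05% (81.93-88.16)
#>   Specificity                80.67% (78.90-82.45)
#>   Positive Predictive Value  54.56% (51.12-58.00)
#>   Negative Predictive Value  95.19% (94.13-96.25)
#>   Likelihood Ratio +         4.40 (3.99-4.85)
#>   Likelihood Ratio -         0.19 (0.15-0.23)
cohen_kappa(collapse_gradability(tabs$alg_oph))
#> Cohen's kappa = 0.3623 (0.3274-0.3972), p_o = 0.7972, p_e = 0.6819, n = 3520
```

A sensitivity of 85% at 21% prevalence moves a positive patient's disease
probability from 21% to 55% (`fagan_posttest(0.2143, 4.40)`), while a
negative result moves it to 5% — the automated grader is a strong
rule-out, moderate rule-in test.

## Command line

A thin CLI wraps the same functions (`inst/cli/fundusdr`):

```sh
Rscript inst/cli/fundusdr synth    --out cohort --n 10 --seed 1
Rscript inst/cli/fundusdr analyze  --manifest cohort/manifest.csv --out results
Rscript inst/cli/fundusdr validate --test results/diagnoses.csv \
    --reference cohort/truth.csv --out report
```

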