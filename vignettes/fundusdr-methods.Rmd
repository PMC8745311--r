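---
title: "Methods: screening pipeline, grading rules and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening pipeline, grading rules and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusdr)
```

`fundusdr` couples a classical fundus-image analysis pipeline for diabetic
retinopathy (DR) screening with the statistics used to validate screening
graders against a reference standard, and a synthetic data generator that
makes both testable without patient images. This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic evidence does and does not establish.

## Conventions

Pixel coordinates are 1-based with `x` the column and `y` the row (the R
matrix convention). All retinal distances are expressed in disc-diameter
(dd) units, so nothing downstream depends on the pixel origin. The
coordinate frame is centred on the fovea; `theta` is measured from the
fovea-to-disc axis, positive toward the superior retina (up in the image),
which makes a horizontal mirror of the image map `theta` to `-theta` and
leave all counts and types unchanged — a property the test suite checks.
Quadrants are the four 90° sectors of this frame, as required by the 4-2-1
severity rule. Rasters are 8-bit RGB rescaled to `[0, 1]`.

## The image pipeline

**Quality gate** (`assess_quality`). The circular field is fitted from the
largest connected region of luminance above a floor (holes closed), and
three metrics are computed inside it: *sharpness*, the mean squared
residual of the green plane against a 2-px Gaussian smooth, normalised by
the squared mean intensity (a band-pass energy; plain gradient energy stops
discriminating at exactly the blur levels that matter, because it is
dominated by slowly blurring large-scale edges); *illuminated fraction*,
the share of field pixels above a luminance floor of 0.22; *saturation
fraction*, the share at the 8-bit maximum. An image is gradable iff
sharpness ≥ 9.8e-5, illumination ≥ 0.75 and saturation ≤ 0.10. The
thresholds were calibrated once against the generator's degradation sweep
so that the gate flips where the generator documents failure (blur sigma 4,
exposure scale 0.5, vignetting 0.75) and then frozen in
`inst/extdata/default_params.yml`. Exactly at the blur boundary the metric
can sit marginally on either side under combined degradations; the
generator therefore renders its ungradable patients well past the boundary
(sigma 8).

**Vessels** (`segment_vessels`). Dark elongated structures are the maximum
black-top-hat response over 12 line orientations (length 17 px, roughly
twice the widest vessel), thresholded at an absolute contrast of 0.045.
Components are then classified by shape with the distance transform:
*vessel-like* components have area exceeding three times their inscribed
disc area — i.e., they are elongated — and are darker (component median)
than the field median by at least the threshold. The darkness condition
encodes the dark-vessel assumption: on a contrast-inverted image the
corridors between bright vessels are elongated but sit at background
intensity, and are rejected. Small enclosed holes (vessel crossings, the
ring-shaped response of a wide dark blob) are filled before classification,
but a hole touching a blob-like component is left open, so a lesion sitting
inside a vessel loop is never absorbed into the tree. The skeleton is the
Lantuéjoul morphological skeleton and is a subset of the mask by
construction.

**Landmarks** (`locate_landmarks`). The optic disc is the brightest
plausible circular region of the vessel-filled, smoothed green plane: the
top 1.5% of in-field pixels are labelled, the largest component of
plausible disc area wins (ties broken toward the brighter), and the radius
is then refined as the equivalent radius of the half-maximum connected
component around that centre. We chose the half-maximum component because
the percentile mask alone systematically underestimates the radius (it
keeps only the disc core) and a radial mean profile overestimates it when
vessels cross the rings; the half-max area is unbiased for a soft-edged
disc and robust to both. A minimum peak prominence of 0.08 over the field
median guards against "finding" a disc in a field that has none. The fovea
is the darkest windowed region in an annulus 2–3 dd from the disc within
±30° of the disc horizontal, searched on both sides since laterality is
not assumed.

**Dark lesions** (`detect_dark_lesions`). The residual of a grayscale
closing (35-px disc brush) below the green plane is thresholded at a
contrast of 0.055 and labelled. The connected vessel tree forms one
residual component far above the lesion area range and is removed by the
structural area filter (8–1600 px²); residual pixels on the dilated vessel
mask are zeroed; candidates inside exclusion zones (0.75 dd around the disc
centre, where converging vessels are dense, and 0.3 dd around the fovea,
which is itself a dark blob) are dropped. A candidate is a microaneurysm if
small and circular (area ≤ 90 px², circularity `4πA/P² ≥ 0.7`), a
hemorrhage otherwise.

**Bright lesions** (`detect_bright_lesions`). A wide grayscale closing
(31-px brush) first removes *all* dark structure; otherwise every dark
object sheds a bright halo in the subsequent white-top-hat (the top-hat of
a plane with pits reports the walls around the pits). The top-hat (35-px
brush) is thresholded at 0.055, a guard band of about 20 px along the field
rim is cleared (the top-hat reacts to the field boundary), and components
touching the disc circle dilated by 0.25 dd are excluded so the disc is
never reported as a lesion. Exudates are separated from cotton-wool spots
by boundary sharpness: mean gradient magnitude on the component boundary of
at least 0.06 means a hard (exudate) edge.

All detector parameters live in `default_params()` and were calibrated once
against the synthetic generator at its default geometry, then frozen.
Defaults assume images of roughly the default scale (600 px, disc radius
≈ 60 px); the structural area windows are in pixels.

## Grading

An image with lesions is `DR` regardless of quality; otherwise `UNG` if the
gate failed, otherwise `NODR`. An eye merges the candidates of its (up to
three) captures by union, deduplicating centroids closer than 0.1 dd in
frame coordinates — union maximises sensitivity, which is the screening
posture. ICDR staging: proliferative on the neovascularization flag; severe
on the 4-2-1 rule (hemorrhages in 4 quadrants, venous beading in ≥ 2, or
IRMA in ≥ 1); mild only when microaneurysms are the sole finding; moderate
for any other lesion evidence. Venous beading, IRMA and neovascularization
enter as annotation flags — the pixel pipeline does not detect them, so
detector-driven grading saturates at moderate disease plus macular edema.
DME is operationalised as a bright lesion within 1 dd of the fovea.
Patients take the worst eye's stage; DME in any eye counts; STDR means DME
or severe-or-worse.

Where one eye is ungradable and the other shows lesions, the patient is
called `DR`: we give lesions precedence over gradability at patient level
by analogy with the image-level rule that lesions count regardless of
quality. The opposite convention (`UNG` first) is available via
`ung_precedence = "ung_over_dr"`, because screening programmes differ in
whether an ungradable eye forces re-examination regardless of the fellow
eye.

## The synthetic generator

`generate_eye_image` renders a 45°-style macula-centred field: radially
shaded orange background on a dark surround, a bright soft-edged disc
placed nasally (disc radius one tenth of the image width), a recursive
random branching vessel tree rooted at the disc that avoids the foveal
avascular zone, a Gaussian foveal depression 2.5 dd temporal to the disc,
then lesions, then degradation (Gaussian blur, radial vignetting, global
underexposure) last, with 8-bit quantisation for byte-identical
reproducibility. Microaneurysms are small dark circular blobs, hemorrhages
larger irregular unions of jittered sub-discs, exudates hard-edged bright
blobs, cotton-wool spots Gaussian-profiled bright blobs; all contrasts are
multiplicative on the local background. `sample_lesions` draws layouts
consistent with an intended stage, keeping lesions clear of the rim guard
band, the disc neighbourhood, the vessel tree (centre at least one lesion
radius plus 0.1 dd away) and each other; moderate-stage hemorrhages are
confined to three quadrants so the 4-quadrant severe criterion can never
trigger by accident. Repeat captures of one eye share geometry and lesions
and differ only in pixel noise (`noise_seed`).

Cohorts (`generate_cohort`) draw a stage per patient (defaults follow a
large screening population: 79% NODR, 9.2% mild, 11.2% moderate, 0.33%
severe, 0.22% proliferative among gradable patients, i.e. 21% DR
prevalence; macular edema in 21% of moderate-or-worse patients; 11.6%
ungradable). The worst eye carries the patient stage, the fellow eye a
uniform stage no worse. Ungradability is an independent per-patient event
rendered as heavy blur in both eyes; by default stages are drawn for every
patient independently of gradability (`stage_conditional_on_gradable`
switches to forcing ungradable patients to NODR, for programmes that count
sight-threatening prevalence over the whole intake instead). Simulated
raters emit `UNG` with their own probability independently of truth —
grader gradability judgments correlate with image quality in reality, but
only marginal ungradable rates are available to condition on — and
otherwise call `DR` with probability equal to their sensitivity (truth DR)
or one minus specificity (truth NODR).

What passing the synthetic suite shows: the pipeline's operators interlock
correctly (detection, geometry, staging, aggregation, statistics) under
controlled contrast, noise and degradation. What it does not show:
performance on real fundus photographs, whose lesion morphology, media
opacity, pigmentation variation and camera differences the renderer does
not attempt; thresholds frozen here would need re-calibration on real data.

## Validation statistics

Proportion intervals use the Wald formula with continuity correction,
`p ± (z·SE + 1/(2n))`; likelihood-ratio intervals use the log method.
These two choices reproduce the printed intervals of the bundled study
tables exactly, which identifies them as the conventions of the
epidemiological software that produced those tables. Cohen's kappa uses the
Fleiss–Cohen–Everitt large-sample variance; the homogeneity test is the
inverse-variance-weighted chi-square on `m` kappas with `m − 1` degrees of
freedom, whose empirical size at nominal 5% is confirmed by simulation in
the acceptance suite. The single-operating-point ROC area is
`(Se + Sp)/2` — the area of the polygon through `(0,0)`, `(1−Sp, Se)`,
`(1,1)` — with variance propagated from the binomial variances of `Se` and
`Sp`, and AUCs are compared with an unpaired z-test (the paired variant
used in some studies is under-identified without patient-level data).
Two proportions are compared with the pooled z-test (optionally
continuity-corrected), delegated to `stats::prop.test`. Fagan's post-test
probability is the odds-scale Bayes update; at a table's own prevalence the
positive update equals the PPV identically, which the tests assert to
machine precision.

Degenerate inputs are reported, not thrown, wherever a report must survive
them: indexes with zero denominators are `NA`, a rater with no `UNG` calls
gets an `NA` gradability kappa, and an all-negative sample gets `NA`
sensitivity and AUC blocks.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; images quantise to 8 bits
so renders are byte-identical across runs. The test and acceptance suites
use a 20-image lesion suite (about 250 lesions), 2000-patient simulated
cohorts for parameter recovery, and 2000 replicate pairs (n = 500 each) for
the homogeneity-test calibration — sizes at which binomial 95% bands are
tight enough to detect real bias while the whole suite runs in a few
minutes on one CPU.

## Known limitations

* Severe and proliferative stages are reachable only through annotation
  flags; pixel detection covers the four basic lesion types.
* The three captures of an eye are merged by candidate union without
  spatial registration; on real images with eye movement this would
  double-count lesions near the deduplication radius.
* DME from a hard 1-dd exudate rule is a proxy for a clinical judgment
  ("signs suggestive or evident of macular edema") that cannot be encoded.
* Detector thresholds are pixel-scale-dependent and frozen for the default
  600-px geometry.
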