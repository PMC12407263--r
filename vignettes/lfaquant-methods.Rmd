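---
title: "Models and methods behind lfaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lfaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lfaquant)
```

`lfaquant` simulates and quantifies colorimetric lateral flow assay (LFA)
strips of the kind used for point-of-care biomarker panels: gold
nanoparticle conjugates form reddish lines on a pale nitrocellulose
membrane, and the darkness of each line encodes analyte concentration.
This vignette documents the models, the conventions and the numerical
choices, and what the synthetic experiments do and do not demonstrate.

## Assay response models

Each analyte carries a concentration-to-signal model
(`analyte_response()`). The sandwich test line follows saturating binding
with an optional high-dose hook,

$$S(c) = s_{\max}\,\frac{c}{k_d + c}\cdot\frac{1}{1 + c/c_{hook}},$$

and the competitive antigen line (three-line designs) decays as
$A(c) = a_{\max}/(1 + c/k_c)$. These are the simplest forms with the
qualitatively correct behaviour: zero signal at zero analyte, saturation,
a non-monotone hook above $c_{hook}$, and a strictly decreasing
competitive line. With a finite hook the test line peaks at
$\sqrt{k_d\,c_{hook}}$; the default CRP model uses
$k_d = c_{hook} = 10\ \mu g\,mL^{-1}$ so the maximum sits exactly at the
hook onset, which makes the low window $[0, 10]$ monotone increasing and
the region above it monotone decreasing — the property the two-curve
inversion relies on.

Default panels: CEA (ng/mL, calibrated 0–50, $k_d = 400$ so the response
is nearly linear across the window), CA-125 (U/mL, 0–1000,
$k_d = 8000$), CRP (µg/mL, 0.1–500, three-line hook design). The large
$k_d$ values for the sandwich assays are deliberate: the emulated strips
show close-to-linear calibration across their clinical windows, which is
what well-optimized gold-nanoparticle assays report.

## The synthetic renderer and its noise model

`render_strip()` draws each line as a Gaussian absorbance band (the
nominal line width is its FWHM) and attenuates the three colour channels
with Beer–Lambert factors biased to a red-dominant pigment, so the green
channel carries the most contrast. The expected inverted-profile peak
height for a nominal signal $s$ is the transfer function
`render_transfer(s)` $= G_0\,(1 - e^{-k_g s})$.

The default `noise_spec()` combines:

* multiplicative amplitude noise per line (5% relative SD) — the dominant
  replicate-to-replicate variation, chosen so extracted intensities have
  replicate CV comfortably below 10%;
* additive pixel noise (SD 0.008) and a smooth illumination gradient
  (±2%), which exercise background subtraction;
* line placement jitter (SD 2.5 px) and width jitter (8%), the striping
  machine tolerance — without it, per-pixel peak labels would be a fixed
  position set and segmentation would degenerate to memorization;
* a smooth low-frequency absorbance mottle (SD 0.01, correlation ~12 px)
  emulating residual staining of the membrane (for whole-blood samples:
  lysed cells and retained haemoglobin), which creates faint bumps the
  segmenter must not mistake for lines.

The generator does **not** emulate photorealistic blood staining, clot
shadows, perspective distortion beyond small rotations, camera
compression artefacts, or membrane texture physics. Passing tests
therefore demonstrate correctness of the computational pipeline under a
controlled, honest noise regime — not clinical performance on real
smartphone photographs.

Pad scenes (`render_pad_scene()`) composite a strip onto a darker,
fibrous background with rotations within ±15°, brightness gains in
[0.7, 1.3] and placement offsets; the ground-truth zone box is
transformed by the same affine map. Every stochastic operation takes an
explicit seed and leaves the caller's RNG untouched.

## Imaging conventions

The readout zone detector is deterministic: membrane segmentation by
thresholding the per-pixel channel minimum, angle estimation from mask
second moments, derotation, marginal-run strip boxing (with gap closing
across dark lines), then zone inference from sub-pixel line-peak
positions using the layout convention that the outer lines sit at
fractions 0.25 and 0.80 of the zone length. A single visible line is
taken to be the control at 0.80. The confidence score maps the strongest
peak's SNR through $\mathrm{snr}^2/(\mathrm{snr}^2 + 400)$ into [0, 1];
a zone is accepted iff confidence ≥ 0.8, and feature-less images return
confidence 0 rather than raising.

Profiles are the per-column trimmed mean (10%) of the green channel of
the rectified zone crop, inverted so darker lines become peaks, linearly
resampled to exactly 512 samples, with the background level the 10th
percentile of the profile. Line intensity is the absolute contrast of
the segment extremum against that background, which makes it invariant
to adding a constant to the profile. The colour channel and the
transverse aggregation are package conventions (both configurable): the
channel default follows from the red-dominant line pigment, the trimmed
mean suppresses specular highlights.

Readout classification counts candidate peaks above a noise-scaled
prominence threshold (`max(6·noise SD, 0.04)` above the median) with
quadratic apex refinement, and maps 1/2/3 peaks to control-only,
test+control, test+antigen+control. Zero peaks means no control line,
which is a failed LFA and raises an `lfa_invalid_test` condition.

## The peak-segmentation network

The segmenter is a fully connected network: input 512, hidden 256 with
ReLU and dropout 0.5 (training only), one logistic output node, trained
with binary cross entropy, Adam (lr $10^{-3}$), 100 epochs, batch size
10, on an 80/20 train/held-out split. Two variant-specific models are
trained — one for two-peak and one for three-peak readouts — plus
optionally a pooled model for comparison.

A single output node must produce a per-pixel probability, which leaves
the input encoding open. The package evaluates the network once per
position on a circularly shifted copy of the min–max-normalized profile
centred on that position (element 257 is the pixel itself), with the
window's first element replaced by the normalized position. This keeps
the architecture literally 512–256–1 while giving the model full profile
context and translation awareness. The interpretation is recorded in the
model metadata so alternative encodings can be swapped without changing
the pipeline contract.

Adjacent shifted windows are nearly identical, so each epoch draws a
label-stratified random subset of 48 positions per profile instead of
all 512; every profile is visited every epoch and training remains
deterministic given the seed. Inference evaluates all 512 positions with
dropout off. Probabilities of exactly 0.5 count as peak (≥ threshold).
Masks are post-processed into maximal runs; runs shorter than 4 samples
(≈ the physical floor of a printed line width at 512 resolution) are
discarded; the apex is the profile extremum within the run.

Training profiles are acquired the way real captures are: the strip is
composited onto a pad scene under varied lighting and small rotations,
the detector locates the zone, and the profile is extracted from the
rectified detected crop, while the per-pixel labels (±2 SD of each
visible line's rendered centre) live on the true zone grid. The small
residual registration error of detection is therefore part of the
learning task, which keeps held-out metrics away from the degenerate
100% regime. Corpora span each assay type's full concentration range,
including blanks and faint lines, so the models learn absent as well as
present peaks.

## Calibration, detection limits and the hook-effect inversion

`fit_calibration()` averages replicate intensities per concentration and
fits ordinary least squares against $c$ (CEA, CA-125) or $\log_{10} c$
(CRP, whose window spans 3.5 decades). The limit of detection inverts
the limit of the blank, $\mu_{blank} + 3\sigma_{blank}$, through the
calibration, floored at zero, and is defined for increasing
(sandwich-line) curves only. SNR is mean signal over noise SD; CV is
$100\,s/\bar x$ with the sample SD.

CRP quantification is piecewise: a low curve (sandwich line, 0.1–10
µg/mL, increasing) and a high curve (antigen line, 10–500 µg/mL,
decreasing). The branch is chosen by comparing the measured antigen
intensity with the high curve's predicted value at the 10 µg/mL
crossover — the antigen line is monotone over the whole range, so this
is well-posed where inverting the hooked test line is not. Inverted
concentrations are clamped to the curve's valid range and flagged; values
below the LOD are reported as "< LOD" rather than as numbers.
Interpretation bands come from a fixed thresholds table shipped as YAML
(CEA 5/20 ng/mL, CA-125 35/100 U/mL, CRP 10 µg/mL boundary) and are
advisory, never diagnostic.

## Fluidics design equations

The volume-control calculator implements the Laplace meniscus pressure of
a rectangular channel, $\Delta P = 2\gamma\cos\theta\,(1/w + 1/h)$;
Hagen–Poiseuille flow in a cylindrical capillary,
$Q = \pi r^4 \Delta P/(8\mu L)$; and Washburn filling,
$L^2 = \gamma D \cos\theta\, t/(4\mu)$, with the exact inverse for fill
time. Everything is SI internally with µL/mm helpers at the boundary.
Blood is treated as Newtonian with a configurable effective viscosity
(3–4 mPa·s is conventional); applying Hagen–Poiseuille to a
shear-thinning fluid is an engineering approximation, which is why the
viscosity is an explicit, overridable parameter. Reference volumes of the
two wearable prototypes (150 µL retention reservoir; 60 µL inlet + 25 µL
channel) are exposed as constants.

## Numerical and design choices

* Dataset splits: nearest-integer rounding for all partitions except the
  last, which takes the remainder — sizes always sum to n (549 at
  70/20/10 gives 384/110/55).
* Readout classes are defined by the number of visible lines, so a
  three-line strip with a fully competed antigen line classifies as
  two-peak; role assignment is by nearest expected layout position with
  the control mandatory.
* Precision/recall use the 0-on-empty-denominator convention.
* Degenerate inputs: constant profiles normalize to zero; empty masks
  yield empty segment lists; blank images yield confidence-0 detections;
  stage failures produce structured invalid-test reports, never partial
  results.
* Problem sizes in the test suite are deliberately compact: 500-profile
  corpora and three seeds for the segmentation experiments, 50 scenes
  for detection, 200 strips for classification, 90 strips for the
  replicate-precision figure. They are chosen to characterize the
  pipeline, not to approach the scale of a wet-lab dataset.

## Known limitations

The rendering transfer from nanoparticle surface density to RGB colour is
a package convention — no quantitative relationship is established in the
literature for these strips, so absolute intensities are arbitrary units
and only relative/calibrated quantities are meaningful. The detector
assumes one strip per image and rotations within ±15°. The segmentation
models are trained on the package's own synthetic regime; their held-out
metrics say nothing about photographs of real strips. Clinical
thresholds are illustrative defaults for an advisory readout.
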