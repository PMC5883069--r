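---
title: "Models and methods behind fluoroscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluoroscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoroscan)
```

This vignette documents the models implemented by `fluoroscan`, the tunable
parameters and their defaults, the design choices made where several designs
were defensible, and what the synthetic-data tests do and do not demonstrate
about real acquisitions.

## The measurement model

A modulated (PAM) fluorescence acquisition yields four co-registered frames
per bed position. With all PSII reaction centres open in the dark-adapted
state, weak measuring light elicits the minimal fluorescence $F_o$; a
saturating pulse transiently closes all centres and yields the maximal
fluorescence $F_m$. Under actinic light (200 µmol photons m⁻² s⁻¹ here,
chosen to emulate ambient growing light), the steady-state fluorescence $F$
and the light-adapted maximum $F_m'$ are recorded. The two efficiency
indicators are

$$F_v/F_m = \frac{F_m - F_o}{F_m}, \qquad
  \Phi_{PSII} = \frac{F_m' - F}{F_m'},$$

computed per pixel over the plant mask. Two reflectance frames at 510 and
550 nm give the third indicator, the relative reflectance $550/510$ — a
ratio, so it needs no reflectance calibration board and cancels illumination
non-uniformity to first order. Healthy working levels under this protocol:
$F_v/F_m \approx 0.80$ (affected below 0.75), $\Phi_{PSII} \approx 0.40$
(stressed approaching 0.30), $550/510 > 1.5$. These bounds are the defaults
of `normal_ranges()` and are configurable.

Degenerate pixels (denominator below 1% of the frame's 99th-percentile
value, e.g. non-fluorescing background caught inside a mask) are marked
undefined rather than producing unstable ratios; noise-driven negative
indicator values are clamped to 0 and counted (`n_clamped`), keeping maps
pixel-aligned with their masks. Summaries use the *population* standard
deviation — the plant's pixels are the whole population of interest, not a
sample — and type-7 (linearly interpolated) quartiles.

## The synthetic scene generator

No public raw acquisitions exist for this instrument class, so the package
generates its own ground-truthed scenes. A scene (`scene_spec()`, default
520 × 696 px — the camera resolution — with 4 plants of 6 leaves) places
elliptical leaves radiating from each plant centre; the outer half of the
leaves are tagged *old*, the inner *new*. Healthy tissue carries exactly
$F_v/F_m = 0.80$, $\Phi_{PSII} = 0.40$ and a greenness driver ("chroma")
mapped linearly to a 550/510 ratio of 1.6 — all centred in the normal
ranges above.

The imaging model (`imaging_model()`) renders physiology into counts by
inverting the indicator formulas: $F_m$ = `fm_gain` (3000 counts) × chroma ×
vignetting, $F_o = F_m(1 - F_v/F_m)$, and $F_m' = F_m(1 - q)$ with the
light-adapted quenching factor $q = 0.6\,(F_v/F_m - \Phi_{PSII})$. Any
$q$ in (0, 1) makes the stack invert exactly; tying it to the efficiency
gap makes quenching grow as operating efficiency falls, which is the right
direction physiologically, without attempting NPQ kinetics (out of scope).
Optics and sensor: radial quadratic vignetting (15% at the corner), additive
Gaussian read noise (sd 5 counts), optional signal-variance shot noise
(enabled by default), and a 12-bit ADC that clips to [0, 4095] and rounds to
integer counts whenever noise is enabled. With noise off, counts stay
continuous so that render → analyse recovers the generating field to float
round-off — the algebraic round trip the test suite asserts at $10^{-6}$.
The instrument does not report its noise floor or background intensity;
the defaults (background 30 counts, read sd 5) are engineering choices that
keep the plant-mean indicator error below 0.02, and they are parameters,
not constants.

### Stress time courses

Severities are day-indexed on a 9-day reference experiment; monitoring fewer
days observes a *prefix* of the same course (never a compressed version —
compressing drought into 5 days would make it indistinguishable from
disease by rate).

* **Drought** acts uniformly (stomatal closure). $\Phi_{PSII}$ falls as
  $0.40 - 0.15\,s$; the severity ramp $(0, .15, .30, .50, .70, .85, 1, 1, 1)$
  is shaped so the canopy mean traces the observed course — about 0.4 on
  day 1, about 0.3 on day 5, plateau near 0.25 from day 7 (the wilting
  floor). $F_v/F_m$ and 550/510 are touched only above a severe-drought
  threshold ($s > 0.7$), reaching 0.72 and 1.4 at full severity: late-stage
  declines, as observed.
* **Nitrogen deficiency** lowers all three indicators linearly with day,
  with new leaves lagging the trajectory by 2 days (nitrogen is remobilised
  from old leaves first). Old leaves fall harder ($F_v/F_m$ floor 0.45 vs
  0.69 for new), so the spatial SD of $F_v/F_m$ rises from ≈ 0.01 to ≈ 0.11
  — the heterogeneity signature.
* **Disease** seeds 2 circular lesions per plant (positions drawn from a
  dedicated `lesion_seed`) whose radius grows with severity, reaching full
  size after 4 days of unchecked growth; severity tops out on day 5, much
  faster than nutrient stress. Inside a lesion all three quantities drop to
  30% of healthy — necrotic tissue. The default growth rate scales with the
  mean plant size in view so lesion coverage is resolution-independent.

Footprint-mean $\Phi_{PSII}$ is non-increasing in severity for all three
stresses (a property test), and all generation is bit-reproducible from
`(spec, model, seed)`.

## Segmentation

Two routes, as the instrument software would offer:

* **Fluorescence threshold** (`segment_fluorescence_threshold()`): the
  non-plant area barely fluoresces, so the $F_m$ histogram is strongly
  bimodal. Otsu's criterion is applied on the *log-transformed* frame: on
  the linear scale, a scene containing dim necrotic lesions (≈ 30% of
  healthy $F_m$) becomes trimodal and Otsu splits dim from bright plant
  tissue instead of plant from background; the log scale compresses the
  high-intensity gap and keeps the split at the background boundary. The
  threshold is floored at the estimated background mean + 5 background SDs
  so near-empty frames yield an empty mask (with a warning) instead of
  splitting noise.
* **Two-class k-means** (`segment_kmeans()`): each pixel contributes the
  feature vector $(R_{510}, R_{550}, R_{550}/R_{510})$, standardised;
  clustering starts from a deterministic farthest-point initialisation
  derived from the seed. On inputs up to 4096 px, 19 additional seeded
  restarts are run and the lowest within-cluster-SSE partition kept: on
  unstructured small inputs a single Lloyd run missed the exhaustive
  minimum-SSE 2-partition in roughly 40% of random cases, while with
  restarts it matched it in every case tried; on full frames the
  plant/background bimodality makes the single start optimal and restarts
  would multiply runtime ~20×. The *plant* cluster is the one with the
  higher mean 550/510 (vegetation is relatively green) — labelling is
  independent of cluster indices.

`clean_mask()` removes 4-connected components below 25 px (noise specks);
it is idempotent and never grows a mask. Against generator ground truth,
both routes hold Jaccard ≥ 0.95 at default noise across seeds (they are
typically at 1.0).

## Diagnosis rules

Qualitative stress signatures become rules through a few numeric cutoffs
(`rule_cfg()`), all configurable:

| parameter | default | rationale |
|---|---|---|
| declining slope | −0.01 / day | separates drift from real decline; healthy series slope ≈ 0 |
| rapid slope | −0.05 / day | disease collapses ≈ −0.08/day in its steepest window; drought ≈ −0.03 |
| heterogeneity SD | 0.08 | healthy canopies sit near 0.01–0.03; N-deficiency exceeds 0.10 |
| lesion patchiness | 0.4 | independent impairment at density *p* scores ≈ *p*; compact lesions ≈ 0.9 |
| impairment threshold | 0.35 ($F_v/F_m$) | lesion-grade necrosis (≈ 0.24) vs physiological decline (≥ 0.45) |

Two of these deserve explanation. *Rapid decline* is measured as the
steepest least-squares slope over any 3-consecutive-day window, not the
full-series slope: a disease series plateaus once lesions engulf the plant,
so its full-series slope looks moderate even though the collapse phase is
unmistakable. The *impairment threshold* for the patchiness score sits far
below the 0.75 "affected" bound: both N-deficient old leaves and lesions
are spatially contiguous, so a clumping index computed at 0.75 cannot
separate them — but only necrotic lesion tissue falls below 0.35.

The patchiness score itself is the mean, over impaired plant pixels with at
least one in-plant 4-neighbour, of the fraction of those neighbours that are
also impaired; under spatially independent impairment at density $p$ its
expectation is $p$, which the test suite checks at ±0.03.

Every ≥ 3-day prefix of a trajectory is labelled from its own cumulative
evidence, and the diagnosis is the **latest consistent** (non-healthy,
non-indeterminate) label. This keeps the early-drought call available by
day 5, lets it upgrade to severe later, and prevents trailing recovered
days from erasing an established diagnosis. When the disease and
nitrogen-deficiency rules both fire, disease wins: acting before an
infection spreads costs less than a false nutrient alarm. Temperature and
other confounders are outside the rule table; `classify_stress()` accepts a
free-text exclusion note that is carried into the JSON report.

## Calibrations

* **Water potential.** The $\Phi_{PSII}$–water-potential relation is steep
  between −0.5 and −1.0 MPa (0.43 → 0.28) and nearly flat from −1.0 to
  −2.5 MPa (0.28 → 0.21): the indicator is sensitive exactly where early
  intervention is possible. Only these working points are trusted — no
  functional form is published — so the operational curve is a monotone
  piecewise-linear interpolation through the three anchors, clamped with a
  warning outside them, with an exact inverse (round trip tested to
  $10^{-9}$).
* **Total nitrogen.** $F_v/F_m$ reflects leaf total nitrogen linearly; the
  calibration is ordinary least squares with `tidy()`/`glance()` accessors.
  The synthetic nutrition preset draws total N uniformly on 10–50 mg N g⁻¹
  dry weight (the axis units are a package choice; none are published) with
  $F_v/F_m = 0.50 + 0.006\,N$ and Gaussian noise whose sd (0.038) is
  calibrated so the default dataset (n = 60, seed 7) reproduces the
  published coefficient of determination $R^2 = 0.85$ — a
  calibrated-to-observation preset, not a derived noise level.
* **Nessler assay.** The standard series (0–10 mL of 10 mg L⁻¹ ammonium
  sulfate, OD₄₈₀) is fitted by least squares against the nitrogen mass per
  tube (volume × concentration × the N mass fraction of (NH₄)₂SO₄,
  28.014/132.14); the sample absorbance is inverted on that line and scaled
  by the digestion bookkeeping (50 mL digest / 1 mL aliquot / 0.1 g dry
  sample) to mg N per g dry weight. Absorbances above the top standard are
  refused (dilute and re-read) rather than extrapolated.

## Numerical and I/O choices

Stacks are stored as multi-page 16-bit TIFF (page order $F_o, F_m, F,
F_m', R_{510}, R_{550}$) with a JSON metadata sidecar, keeping the image a
plain standard container; counts round to integers on write, which is
lossless for everything the (quantising) camera model produces. Bed-scan
tiles are abutted, not blended — the instrument images disjoint positions.
Pseudo-colour maps use fixed scales (0–0.85 for the fluorescence
indicators, 0–2.0 for 550/510) so day-series panels are comparable, render
undefined pixels black, and are byte-deterministic. Coordinates are
row-major with the origin at the top-left.

## Problem sizes and what the tests show

The acceptance-level checks run the full 520 × 696 default scene; the
property suites (segmentation quality across 10 seeds, classifier accuracy
on 40 labelled series) use a 174 × 232 two-plant scene, which preserves
every structural feature (multiple plants, leaf age classes, vignetting,
lesions) at about a tenth of the pixel count — a deliberate size choice so
the whole suite runs in well under ten minutes.

The generator emulates the features that drive the analysis — frame
algebra, plant/background contrast, leaf-age structure, lesion patchiness,
sensor noise — and not those it deliberately ignores: leaf optics and
radiative transfer, NPQ kinetics, 3-D canopy geometry and self-shading,
leaf growth or movement across days, curling of infected leaves, and
ambient-light leakage (acquisitions are assumed dark-adapted, as in
night-time operation). Passing tests therefore demonstrate that the
analysis chain is correct and robust at realistic noise levels, not that
the classifier's numeric cutoffs transfer unchanged to any particular
instrument; on real data the `normal_ranges()` and `rule_cfg()` defaults
are starting points to be checked against control plants.
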