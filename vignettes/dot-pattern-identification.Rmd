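---
title: "Identifying individual fish from their skin dot pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying individual fish from their skin dot pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Farmed salmonids carry a pattern of dark melanophore dots on their flanks
that is individually distinctive and stable over months. **finprint**
implements a fully automatic photo-identification workflow built on that
signature — an alternative to invasive PIT tagging for fish that are
photographed laterally on a uniform green background — together with a
synthetic image generator that stands in for real photographs, so the whole
pipeline can be exercised, profiled and validated without animal data.

```{r setup}
library(finprint)
```

## The pipeline at a glance

1. **Segmentation.** Background pixels are found by thresholding hue and
   saturation in HSL space (the photographic tent uses a saturated green
   backdrop); the fish is the largest connected non-background component,
   holes filled.
2. **De-skew and landmarks.** The object is rotated level by the negative of
   its second-moment (ellipse) orientation and standardized head-left. Four
   landmarks follow: NP, the narrowest column before the tail fin (which
   also defines the body length, because tail-fin segmentation is
   unreliable); UP, the dorsal-fin beginning, found by fitting straight
   lines to the left and right halves of the upper border inside the 3/8–5/8
   length window and intersecting them; EP, the eye, the centroid of pixels
   darker than 20 (8-bit) in the anterior third before UP; and BP, the belly
   border below UP.
3. **ROI.** The skin rectangle from EP to UP horizontally and from
   `UP.y + (BP.y − UP.y)/20` down to `BP.y/2` vertically is cut and resized
   to a width of 1000 px (height preserving aspect), removing growth-induced
   scale.
4. **Dot detection.** A five-layer convolutional classifier (three 3×3
   convolutions with ReLU and 2×2 max-pooling, then two fully connected
   layers with a softmax pair) labels 25×25 windows slid at 5-px steps over
   the posterior two thirds of the ROI; windows with dot probability above
   0.30 become candidates, and candidates closer than 15 px are merged by
   single-linkage clustering into dot centroids. A deterministic,
   training-free blob detector (`detect_dots_blob()`) offers the same output
   contract for workflows that do not want a learned component.
5. **Matching.** The distance between two dot patterns is the mean of the
   smallest ¾ of per-dot nearest-neighbour distances (the largest quarter is
   discarded as mis-detections), minimized over an exhaustive translation
   grid — ±30 px in 5-px steps for images taken days apart, ±50 px across
   months, because the ROI itself displaces as the fish grows. A query is
   assigned to the gallery fish with the minimal final distance; patterns
   whose dot counts differ by more than a factor of two are not compared.
6. **Enrollment for the long term.** All patterns of one fish are aligned to
   the pattern with the minimal mean distance to the rest; reference points
   re-found within 20 px in at least `max(3, ⌊N/3⌋+1)` of the N patterns
   form the *representative pattern* used as the long-term template.
7. **HOG alternative.** A histogram-of-oriented-gradients descriptor
   (64×64-normalized right-anchored ROI subregion, 10-px border offsets,
   2-px cells, 2×2-cell blocks, 9 unsigned bins) compared by the minimal
   Euclidean distance under sliding-window scanning of the unknown ROI.
   Block normalization makes it illumination-invariant; it codes all texture
   (including reflections), which is why the dot-based matcher is the
   primary method.

## A worked example

Ten synthetic fish, three images each, blob detection, nearest-neighbour
identification:

```{r example, eval = FALSE}
cohort <- generate_cohort(10, 3, session_templates(1, dot_jitter_sd = 3),
                          seed = 42)
patterns <- cohort_patterns(cohort, detector = "blob")
st <- run_short_term(patterns)
st$report
#> <accuracy_report> overall 100 %
#>  session_pair  n correct accuracy
#>           all 10      10      100
```

## What the generator emulates — and what it does not

`generate_identity()` and `render_fish()` emulate the acquisition conditions
reported for the original datasets: one fish per image, head-left lateral
view on a saturated green background, in-plane rotation within ±45°,
translation, per-image multiplicative illumination change, 4–40 dots per
fish (8–30 by default), and growth of ×1.6 in length and ×1.9 in height
across a four-session series. Dots drift between sessions by 4.5 px/axis in
normalized-ROI units, which reproduces pattern displacements of the
magnitude the original study measured by manually labeling dots (≈9/8 px
per axis before attributing half to labeling error). The fish itself is a
parametric silhouette, not a salmon mesh: it guarantees exactly the features
the landmark detectors use, nothing more.

Three generator choices deserve explanation:

* **Dorsal anchoring of dots under growth.** Body height grows faster than
  length (×1.9 vs ×1.6), but the generator scales the dots' depth below the
  dorsal border with *length* growth. Scaling it with height would shear the
  pattern vertically by ~19% between the first and last session — far more
  change than manual validation of real fish observed (≈5 px residual after
  alignment). The pigment band rides on the back; the extra height growth is
  belly depth. The net effect of growth is then a mostly uniform vertical
  ROI shift of up to ~30 px, which is precisely what the wider ±50 px
  long-term shift search absorbs.
* **Dot spacing.** Identities enforce a minimal dot spacing of
  `max(2·radius + 6, 32)` normalized px. The detection contract merges
  candidates closer than 15 px, and the sliding window answers positively up
  to ~7 px around a dot, so two true dots closer than ~30 px could fuse into
  one centroid; the spacing floor keeps dots individually resolvable, as
  they are in the species being emulated.
* **Dot density and the learned detector.** Sliding-window detection
  answers positively in a cloud of window positions around each dot; the
  15-px candidate clustering can chain the clouds of two dots closer than
  about 40 px into one centroid. Real melanophore patterns are sparse
  enough that this rarely matters, and the deterministic blob detector
  (whose non-maximum suppression radius is 7 px) resolves the generator's
  32-px minimum spacing without merging — which is why the cohort-scale
  validations use it. Training the patch classifier with
  `near_dot_fraction ~ 0.15` sharpens localization for scanning use.
* **Underwater (aquarium) conditions** are approximated only as Gaussian
  blur plus a wider illumination range (`blur_sigma`,
  `illumination_range`); light scattering is not physically modeled, and the
  degraded-accuracy aquarium results of the original study are therefore
  out of scope here. Passing tests on this generator show the pipeline's
  logic is correct under the stated nuisances — they do not certify
  performance on real photographs, which add specular reflections, missing
  scales, fin damage and depth-of-field effects.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `roi_config()$green_hue`, `sat_min` | 90–150°, 0.3 | background chroma gate; recalibrate for a new rig |
| `roi_config()$eye_threshold` | 20/255 | eye-pixel gray cutoff |
| `detect_dots(step, p_min, cluster_cutoff)` | 5 px, 0.30, 15 px | scan stride, dot probability, merge radius |
| `match_config(max_shift, shift_step)` | 30 (short) / 50 (long), 5 px | translation search extent and step |
| `match_config(trim_fraction)` | 3/4 | kept fraction of query dots |
| `match_config(count_ratio_max)` | 2 (inclusive) | dot-count comparability pruning |
| `build_representative(accept_dist)` | 20 px | support radius for consensus points |
| `hog_config()` | 64, 10, 2, 2×2, 9 bins | HOG geometry; subregion presets ½, ⅔, ¾ |

The matching distance is deliberately asymmetric (query dots matched into
the template); the trim count is `⌈¾·n_query⌉` so even a 1-dot pattern
yields a distance. An optional uniform-scale grid (`scale_grid`) exists
behind a config flag but is off by default: translation alone matches the
primary method, and the normalized ROI already removes most scale.

## Numerical choices and degenerate inputs

Ties resolve deterministically everywhere: the shift grid lexicographically,
galleries by the smallest fish id, the narrowest-column search to the
rightmost minimal column. Near-parallel fin border fits fall back to the
highest border point; a fish with undefined orientation (a disk) is passed
through un-rotated; an ROI smaller than one window yields an empty pattern
with a warning, and empty patterns refuse to enter the distance (an error,
not a silent 0). The head side is decided by where the sub-threshold (eye)
pixels lie, falling back to the wider half. The lower ROI bound is read as
`BP.y/2` in the bounding-box frame (`belly_fraction` in `roi_config()`
exposes the divisor, as the midpoint reading `(UP+BP)/2` is also
defensible). The classifier stops early on a vanishing *training* loss
rather than held-out accuracy, so the reported test accuracy is untouched
by the stopping rule. All generators restore the caller's RNG state; every
randomized stage takes an explicit seed.

## Problem sizes used in validation

The packaged test-suite and the acceptance script reproduce the headline
experiments at their original scale — 328 fish × 3 images for short-term
uniqueness, 30 fish × 4 sessions × 6 images with growth for long-term
stability, 535 + 535 patches for the classifier — using the deterministic
blob detector for the cohort runs (the learned detector is validated
separately at patch and single-image level; at 5-px stride a CNN pass over
one ROI costs ~10 s in pure R, which multiplies poorly across 1,700 cohort
images). The HOG identification demonstration uses a 5-fish cohort with a
coarser 12-px scan stride; HOG separability does not depend on gallery size
for noiseless renders, and the texture route is the secondary matcher here.

## Known limitations

* The fish silhouette is schematic; detectors tuned on it (green thresholds,
  blob contrast) need recalibration for real imagery.
* Closed-set identification only: a query whose fish is absent from the
  gallery is still assigned to the nearest enrolled fish, as in the emulated
  study; no rejection threshold is provided.
* Right-side views and multi-fish scenes are out of scope.
* Underwater degradation is a tunable approximation, not a calibrated model.
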