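---
title: "Counting grapevine flowers by regional maxima of lightness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting grapevine flowers by regional maxima of lightness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(inflocount)
```

## The counting problem and the physical model

Grapevine yield is largely set by flowering and fruit set, so the number of
flowers per inflorescence at the pre-flowering stage (BBCH 55) is a quantity
viticulturists want early and non-destructively. `inflocount` counts flowers
in a photograph of a single inflorescence taken against dark cardboard.

The physical assumption doing the work is geometric: a flower button is
quasi-spherical, so under directional illumination it reflects the light
source towards the camera from essentially one point. In the CIE 1976 L\*a\*b\*
representation of the photo, each flower therefore contributes one compact
*regional maximum* of the lightness channel L\*: a connected plateau of
equal-valued pixels whose neighbours are all strictly darker. Counting
flowers reduces to counting such maxima inside the inflorescence region,
after discarding maxima whose size or shape is incompatible with a specular
highlight.

This assumption is also the method's main limitation: anything else that
produces a compact bright peak (a water droplet, a bright rachis patch) is a
potential false positive, and a flower whose highlight is hidden — occluded
by a neighbour in a compact cluster, or facing away from the light — is a
false negative. The acquisition guidance (face the sun, cast an even shadow,
use the dark backing) exists to keep those failure modes rare.

## Pipeline stages and their parameters

`count_flowers()` composes six operations; every tunable lives in
`pipeline_config()`.

**Downscaling** (`target_megapixels`, default 2). Images above the target
are resized by the area-based linear factor sqrt(target/current) with
bilinear interpolation, never upscaled. The target bounds the computational
load while leaving typical flower highlights several pixels wide. Bilinear
interpolation was chosen over block averaging because at the scale factors
this pipeline sees (0.3–0.7) the two are indistinguishable for peak
detection, and EBImage provides a fast compiled implementation.

**ROI segmentation** (`lightness_threshold` = `"auto"`, `chroma_ceiling` =
15, `speck_fraction` = 1e-4). A pixel is background when its L\* is below a
threshold *and* its chroma is below the ceiling; the dark cardboard is both
dark and achromatic, while inflorescence pixels are bright or coloured, so
the dual rule tolerates exposure changes (a uniform exposure gain moves both
classes along L\* but hardly changes the classification). The automatic
threshold is the *triangle method* on a 256-bin histogram of L\*: the
protocol produces a dominant compact background peak plus a long-tailed
bright class, the histogram shape the triangle rule is designed for. (A
between-class-variance rule such as Otsu's places the cut mid-foreground
under a long-tailed bright class and clips dim flower-rim pixels — we
observed exactly that on generated scenes — so it is not used.) The
automatic threshold is floored at L\* = 10 so that an all-dark frame is
classified entirely as background and raises a segmentation error asking for
re-acquisition, rather than splitting sensor noise. Foreground components
below 0.01% of the image area are removed as specks.

**Candidate detection** (`connectivity` = 8, `min_candidate_area` = 1,
`h_maxima` = 0). Regional-maximum plateaus are found by a single-pass
flood-fill over equal-valued pixels (compiled code), with pixels outside the
ROI invisible: plateaus touching the ROI boundary are eligible, because
boundary flowers are real, but a plateau covering the entire ROI is
degenerate and discarded (a constant region carries no peak information).
8-connectivity is the blob-detection default; 4-connectivity is available.
Because the definition uses only value *comparisons*, the candidate set is
exactly invariant under any strictly increasing remapping of the lightness
values — a property the test suite asserts. `h_maxima` optionally suppresses
peaks of prominence below a given L\* depth via grayscale morphological
reconstruction before detection; it is off by default since the shipped
filters handle the shallow-noise regime, but it is the right knob for very
noisy sensors (together with `min_candidate_area` = 2).

**Size filter** (`size_filter_k` = 3). Candidates with area above
median + k·MAD of the candidate-area population are removed (raw MAD, i.e.
no consistency constant). The estimate is computed *once* from the input
population — a single pass, asserted by a test — and only an upper cut is
applied, because the defect this filter targets is oversized regions (merged
highlights, bright patches). With MAD = 0 (a perfectly homogeneous
population) the fence degenerates to median + k so that equal-area
candidates are never pruned.

**Shape filter** (`elongation_threshold` = 2). A highlight on a sphere is
quasi-circular, so candidates whose equal-second-moment ellipse has a
major/minor axis ratio above the threshold are removed; this is what
eliminates elongated stem glints. Degenerate moments are handled explicitly:
regions of up to 3 pixels are pinned to elongation 1 (they carry no shape
information), and larger collinear regions are re-evaluated with half-pixel
quadrature (adding the 1/12 variance of a unit pixel to the diagonal of the
coordinate covariance), which makes a 1-pixel-wide line of length n come out
with elongation ≈ n·sqrt(12)/2 rather than an undefined ratio.

The filters run in the order size → shape; the order matters only when the
size fence is estimated from a population still containing elongated
candidates, and the sequential single-pass order is the simplest
deterministic choice.

## Evaluation protocol

`match_detections()` implements point matching with the redundant-detection
rule: candidate pairs (detection, truth) within `radius` are taken greedily
in increasing distance order, each detection and each truth point matched at
most once. Unmatched detections are false positives — including *redundant*
detections of an already-matched flower — and unmatched truths are false
negatives. Greedy matching (rather than optimal bipartite matching) is used
because the redundancy rule is order-defined and greedy makes it
deterministic; for truths separated by more than twice the radius the two
coincide exactly, and the suite checks both that identity and near-agreement
on random instances. Recall and precision are TP/(TP+FN) and TP/(TP+FP); a
zero denominator leaves the metric missing (never zero), and set-level
figures are unweighted per-image means that skip missing values.

The default radius is half the median nearest-neighbour distance among the
truth centers of the image. The original field protocol relied on a human
scorer's judgment of correspondence, which no fixed pixel radius can
reconstruct; this rule is a declared substitute that scales with flower size
and spacing instead of hard-coding a constant.

## What the synthetic scenes emulate — and what they do not

`generate_scene()` renders: a near-black, low-chroma background (default
L\* = 3); each flower as a Lambertian-shaded sphere (ambient floor 0.35,
greenish-white albedo) with one Gaussian specular spot centred at the
diffuse maximum, bright enough to saturate a few pixels — as real specular
highlights do — so each flower carries exactly one dominant plateau; a
multiplicative illumination gradient along a random direction (default 25%
across the frame); per-channel Gaussian sensor noise (default sigma 1.5 on
the 0–255 scale) followed by 8-bit quantization; and elongated anisotropic-
Gaussian distractor streaks (aspect ≥ 3, default 3 per image) that
specifically exercise the shape filter. `crowding` places a fraction of
flowers in contact with a host (centre distance 0.8 of the radius sum,
random occlusion order), emulating compact cultivars; it defaults to 0 so
that the documented separation guarantee holds for default scenes, and is
exercised at nonzero levels by the difficulty-monotonicity tests.

Scene geometry defaults — 600×800 px, ~50 flowers of radius 8–14 px,
minimum separation 34 px — are desk-scale calibration constants chosen once
and frozen: no field statement fixes flower size in pixels at analysis
resolution, so these are explicitly *not* reconstructions of field imagery.
Determinism is part of the contract: identical `scene_params` (including
`seed`) give bit-identical rasters, and benchmark sets derive per-image
seeds from a master seed.

Passing the synthetic benchmark therefore shows that the pipeline correctly
implements the intended signal model (isolated saturating highlights on
shaded spheres over a dark achromatic ground, plus the listed nuisances). It
does *not* show field performance: real inflorescences add leaf and rachis
clutter, inter-reflections, depth-of-field blur, highlights split by
raindrops, and cultivar-specific compactness, none of which are rendered.
Field recall in the mid-80s% with precision in the mid-90s% is the
reference operating point the synthetic bounds mirror; the generator's
default difficulty is deliberately *cleaner* than the field, and the
acceptance bounds are one-sided lower bounds, not estimates of field
accuracy.

## Numerical and degenerate-input choices

- Coordinates are (row, col) with 1-based pixel centres inside R; the CSV
  interchange format is 0-based, converted once at the I/O boundary.
  `detection_result` stores analyzed-scale centres plus the scale factor;
  `centers_original()` maps back bijectively.
- Plateau equality is exact floating-point equality — appropriate because
  L\* derives from quantized 8-bit input, so plateaus are genuine repeated
  values, and it is what makes the monotone-invariance property exact.
- The downscale dimension search rounds the row count, derives the column
  count from the aspect ratio, and decrements until the pixel budget is met,
  keeping the aspect ratio within half a pixel.
- Ties in greedy matching (equal distances) are broken by detection then
  truth index; TP/FP/FN are invariant to detection order regardless.
- Degenerate metric denominators (no truths; no detections) propagate as
  missing values with a warning, and aggregation skips them.
- An image whose candidates are all filtered away yields count 0, which is a
  valid result, not an error; an image with no segmentable foreground is an
  error, because it violates the acquisition protocol.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at sizes chosen to make the
full pipeline measurable in seconds: 30 scenes of 600×800 px with 40–60
flowers for the benchmark bounds; 200 random 30×30 maps against the
brute-force plateau oracle; 20 small scenes × 3 remappings for monotone
invariance; 500 fuzzed instances for the matching identities; 20 seeds per
level for difficulty monotonicity. These are the package's own desk-scale
choices; the statistical conclusions they support are the bounds asserted in
`tests/testthat/test-acceptance.R`, nothing finer.

## Known limitations

- No estimate of the true 3-D flower number per inflorescence is attempted;
  the output is the 2-D visible count, which upstream work relates to the
  real count by regression.
- The segmentation rule assumes the dark-backing protocol; scenes without it
  (foliage background) will segment poorly and are out of scope.
- The shape filter cannot remove *compact* non-flower highlights; precision
  on real imagery depends on the scene being free of such distractors.
- Very high noise (sigma ≳ 5 DN at default contrast) floods the detector
  with small spurious maxima faster than the statistical filters can remove
  them; `h_maxima` and `min_candidate_area` are the mitigation knobs.
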