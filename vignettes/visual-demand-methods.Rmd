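---
title: "Quantifying everyday visual demands: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying everyday visual demands: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visdemand)
```

## The problem

People living with low vision use sight aids for a wide range of everyday
tasks — reading package labels, finding items on a shelf, crossing roads —
and the design requirements of wearable low vision aids (LVAs) depend on
what those scenes actually look like: their contrast, texture, fine
detail, the angular size of the attended object, and the practical context
(duration, lighting, distance, hands in use). `visdemand` implements a
complete pipeline for quantifying such demands from egocentric snapshot
frames and their human coding: per-image computational metrics, angular
size estimation with logMAR conversion, a closed 14-classifier scene-coding
schema with inter-rater repeatability, task mapping onto a 48-item visual
functioning questionnaire (VA LV VFQ-48) vocabulary, and dual task-ranking
statistics.

Because no recording corpus ships with the package, a synthetic-data module
generates images and coding tables with analytically known ground truth.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic world does and does not establish.

## Image substrate

All metrics operate on a `linear_gray_image`: an integer raster of linear
luminance on the 16-bit scale [0, 65535].

- **Loading.** PNG and TIFF, 8/16-bit, grayscale or RGB. 8-bit values are
  multiplied by 257 so both depths share one scale; grayscale files are
  replicated to three channels. Inputs are assumed already undistorted,
  white-balanced and de-noised — interactive, tool-specific corrections
  that precede this pipeline.
- **Linearization.** The standard sRGB inverse transfer function per
  channel (linear below the 0.04045 breakpoint, power 2.4 above), applied
  on the unit interval and rescaled with rounding.
- **Grayscale.** BT.601 luminance weights `0.2989 R + 0.5870 G + 0.1140 B`,
  rounded to integers. Two consequences worth knowing: the conventional
  4-digit weights sum to 0.9999, so equal channels reproduce to 1 part in
  10^4 rather than exactly; and round-tripping is clean in the
  encode-then-decode order (within ±1 count) but not in the
  decode-then-encode order, where integer quantization in the compressive
  dark toe costs up to ~6 counts. BT.709 weights can be passed instead via
  the `weights` argument.
- The pipeline keeps integer 16-bit images throughout (rather than carrying
  floating-point linear values); the metric thresholds below are defined
  against that integer scale.

## The five scene metrics

`metric_config()` pins every tunable; defaults follow the conventions of
the MATLAB Image Processing Toolbox routines that this family of metrics
historically presupposes (256-bin tonal histograms, symmetric padding for
the entropy filter, replicate padding for the range filter).

**Contrast** — the tonal span actually used by the scene:
`(I_max − I_min) / 2^16 × 100`, where `I_max`/`I_min` are the means of the
`ceiling(0.005 N)` brightest/darkest pixels. The tail is count-based after
a full sort; ties are irrelevant to the mean. The divisor is `2^16` exactly
as conventionally printed, so the maximum attainable contrast is
`65535/65536 × 100 ≈ 99.998`, not 100.

**Global entropy** — Shannon entropy (bits) of the 256-bin tonal histogram,
divided by `log2(256) = 8` so a constant image scores 0 and a uniform
histogram scores 1. The divisor is a declared choice: "normalized to 0–1"
admits several denominators, and 8 bits is the one under which the local
cutoff below is meaningful.

**Textured area** — per-pixel Shannon entropy of the 9×9 neighborhood
(256 tonal bins, symmetric padding), thresholded at 3 bits; the percentage
of pixels above threshold. The 3-bit cutoff is taken as given (it was set
experimentally in the literature as the value separating texture from
noise); the selection experiment is not reproduced here.

**High-spatial-frequency area** — per-pixel tonal range (max − min) of the
3×3 neighborhood (replicate padding), thresholded at 10% of the 16-bit
range, `round(0.1 × 2^16) = 6554` counts; the percentage above threshold.

**Edge area** — percentage of pixels flagged by a Sobel detector: kernels
`[1 2 1; 0 0 0; −1 −2 −1]/8` (and transpose) on the unit-scaled image with
replicate padding, squared gradient magnitude `g`, automatic cutoff
`4 × mean(g)`, no thinning. The reference edge routine this emulates also
thins its edge map, so areas here are upper bounds relative to it. The
relative cutoff has a counter-intuitive consequence worth documenting: a
fine checkerboard, where more than a quarter of pixels carry gradient,
raises the mean enough that *nothing* exceeds `4 × mean(g)` and the edge
area is 0; a step edge or coarse board behaves as expected. With the
relative threshold, edge area is also invariant to global tonal rescaling.

Numerical notes: windowed metrics refuse images smaller than their window
(a classed dimension error); entropy uses `0·log 0 ≡ 0`; all five outputs
are deterministic for fixed input and config. Adding a constant to every
pixel (without clipping) leaves contrast and high-frequency area unchanged
for any shift, but the entropy metrics only for shifts by whole tonal bins
(multiples of 256 counts), since other shifts re-split bin boundaries.

The local filters are compiled (Rcpp); brute-force R oracles with explicit
padding live in the test suite, and the acceptance suite requires exact
count agreement between the two routes on random small images.

## Object angular size and logMAR

The recording camera is modeled as `camera_model()`: 1920×1080 frames,
120° horizontal field of view, vertical field derived from the aspect
ratio (67.5°). Because frames are undistorted, the angular mapping is
linear in pixels: `deg = span_px / dim_px × fov_deg`. A pinhole-projection
mapping (`2 atan(...)`) would differ in the periphery, but the proportional
mapping is the one under which the published worked examples reproduce, so
it is the default and only mapping.

logMAR is computed from the whole object (or single letter) angle in
arcminutes: `logMAR = log10(60 × deg)`, with **no** 1/5 letter-detail
factor. This convention was verified against all seven published
degree→logMAR pairs (2.0° → 2.08, 5.6° → 2.53, 7.7° → 2.66, 0.1° → 0.78,
45.4° → 3.44, 4.7° → 2.45, 37.8° → 3.36); with the 1/5 factor none of them
reproduce. Reported values are rounded to 2 decimals; raw values are kept
unrounded internally.

`summarize_object_sizes()` converts the *summary statistics* (mean, SD,
min, max in degrees) to logMAR, rather than summarizing per-object logMAR
values — the published numbers match the former convention (the logMAR of
a degree SD is a scale conversion, not a dispersion of logMAR values; both
interpretations are defensible, and the one that reproduces the printed
pairs is adopted). The small-object fraction uses a strict `< 2°`
inequality.

## Scene coding and agreement

The shipped schema (`default_scene_schema()`) contains the 14 classifiers
with closed category sets: task duration (ad hoc 0–5 min, short, medium,
long), location, familiarity, light type, brightness, object distance,
focus plane, periphery, visual scanning, hands, walking, coping-strategy
use, ability to complete alone, and time of day. Validation errors name
the offending classifier and value. Time-of-day bins are half-open and
lower-inclusive (`[6,12) → "6-12"` etc.); only the bin labels are
conventionally given, so the boundary rule is a declared choice.

The six-point difficulty scale collapses to a binary code in which only
"unable" maps to `unable_alone`: inability is defined as the task not being
completable at all or only with help, and every other level — including
"very difficult" — describes a completed task.

Task labels are matched against a 48-item questionnaire vocabulary by
exact comparison after case folding and whitespace normalization;
non-matches are flagged bespoke. **The shipped vocabulary is a
reconstruction**: the adapted wording of 12 questionnaire items was never
published, and the questionnaire/bespoke split of the observed labels is
partly a judgment call. Both are flagged in the data file
(`inst/extdata/task_vocabulary.json`, fields `adapted` and `is_bespoke`)
and the file is editable; it also carries the published ranking shares,
which double as default task probabilities for simulation.

Inter-rater repeatability is raw percent agreement per classifier —
`100 × matches / n` — with no chance correction, since that is how such
repeatability columns are conventionally reported. Cohen's kappa is
provided as an optional extra (`cohen_kappa()`), returning `NA` in the
degenerate both-coders-constant case. Published per-classifier
repeatability values are *not* reproduced as targets: they are not integer
multiples of 1/27, so the exact computation behind them is unknowable.

## Aggregation

`rank_tasks()` produces the dual ranking: snapshot frequency (every
occurrence counts; the denominator is all records) and participant
prevalence (each participant counts at most once per task; the denominator
is all participants — these percentages deliberately do not sum to 100).
Ties break alphabetically so output is deterministic and
permutation-invariant. Rendered tables round to whole percent but keep one
decimal below 1% (so a 0.5% entry does not print as 0%); machine output
keeps full precision and records its denominators, because small
differences in the published word-count denominator could not be resolved
from the source.

`word_frequency()` tokenizes case-folded text on non-alphanumeric
boundaries, applies an editable stemming map (e.g. "reading" → "read"),
drops an editable stop-word list, and reports percentages relative to the
retained tokens — the denominator is always recorded rather than assumed.

## The synthetic world

The generators state a fixed world; their defaults are not tuned to test
outcomes.

- Image fixtures (`gen_constant`, `gen_checkerboard`, `gen_noise`,
  `gen_half_noise`, `gen_ramp`, `gen_tail_controlled`,
  `gen_object_scene`) each store the metric entries they control
  analytically, *with tolerances attached to the fixture*, and the test
  suite confirms every stored entry by running the pipeline. Examples: the
  tail-controlled fixture places exactly `ceiling(0.005 N)` pixels at each
  requested tail value so its contrast is exact by construction; the
  half-noise fixture expects 50% textured area ± 4 points, the slack
  covering the 9×9 windows straddling the seam.
- Coding fixtures: `gen_coding_dataset()` draws tasks and classifier
  categories i.i.d. from planted multinomials. Default task probabilities
  are the published snapshot-frequency shares; default classifier
  probabilities use the study's reported marginals where stated (75% ad
  hoc, 78% indoors, 58% home, 48% natural light, 68% within reach, 69%
  single focus plane, 17% walking, 43% coping strategy, 71% able alone,
  42%/37% morning/afternoon), with residual mass split plausibly among
  unreported categories (e.g. brightness 15/60/25, scanning 50/50) — chosen
  once and documented here.
- `gen_dual_coder()` plants an agreement rate `r`: coder B copies coder A
  with probability `r` and otherwise draws uniformly among the *other*
  k−1 categories, so disagreeing draws never collide and the expected raw
  agreement is exactly `r`. The fixture stores that exact expectation.
- Reproducibility: all generators run under a pinned RNG
  (Mersenne-Twister / Inversion / Rejection) seeded per call, restore the
  caller's RNG state, and are bit-identical across platforms.

What a green synthetic suite establishes: that the metric implementations
agree exactly with independent brute-force definitions, that the
conversion and counting rules reproduce every published worked example,
and that planted parameters are recovered at stated sample sizes. What it
does not establish: anything about real egocentric footage — the study's
headline distributions (mean contrast 93.1%, 44% textured area, 75% ad hoc
tasks, 49% "read", …) depend on 612 snapshots that were never deposited,
so those numbers define output shapes here, not reference values. Synthetic
images contain no optics (vignetting, defocus, motion blur, sensor noise
correlation), and synthetic coding tables contain no coder psychology —
category confusions are uniform, which real coders' are not.

## Known limitations

- The PNG/TIFF codecs cover exactly the formats the pipeline specifies
  (uncompressed baseline TIFF; non-interlaced PNG without alpha). Anything
  else raises a classed format error naming the property.
- The edge detector's relative threshold makes the edge-area metric
  unstable for scenes whose gradient mass is spread over more than ~25% of
  pixels (see above); this mirrors the behavior of the emulated automatic
  threshold rather than fixing it.
- Percent agreement is reported without chance correction by design;
  k-sensitive chance agreement (100/k for uniform coders) is demonstrated
  in the tests and kappa is available where correction matters.
- The task vocabulary's adapted wordings are provisional reconstructions;
  matching is exact-after-normalization, so rewording an item requires
  editing the data file, not the code.
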