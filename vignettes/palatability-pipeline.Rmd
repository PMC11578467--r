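---
title: "Geometric facial measures for objective palatability assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric facial measures for objective palatability assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TasteFace)
```

## The problem

Palatability — how acceptable a medicine tastes — drives adherence in
children, yet the standard instrument, a 5-point hedonic smiley-face
scale, is a coarse self-report that young children fill in with help
from an adult. An alternative is to watch the child's face. Rather than
classifying emotions (taste-elicited expressions are reflexive motor
responses and need not reflect liking), the approach implemented here
works directly on the raw geometry: a face-mesh estimator produces a
few hundred indexed 3D landmarks per video frame while the child tastes
a flavoured strip (control, sweet, sour, bitter), and the pipeline
reduces each frame to twelve interpretable geometric measures. The
variability of those measures over a tasting video is then related to
taste identity and hedonic rating, and a tree ensemble ranks which
measures carry the palatability signal.

`TasteFace` implements the full chain — stream ingestion, frame
selection, measure extraction, variability statistics, importance
ranking — plus a synthetic landmark-stream generator with known ground
truth, so every stage is testable end to end without videos or any
external download.

## Data model and frame selection

A `LandmarkStream` holds one tasting video: ordered `LandmarkFrame`s
(indexed 3D coordinates in estimator-normalised units, plus a validity
flag), and a `SectionAnnotation` marking two task sections with
inclusive 0-based frame bounds: **SI**, from strip insertion until just
before removal, and **SII**, the post-tasting span from just after
removal until the footage stops being usable. Frames on which the
estimator failed (child turns away, face covered) stay in the stream
with `valid = FALSE`; they are excluded from all measure computation
and never interpolated — gaps simply shorten the series. The retained
fraction is reported per stream (`validFraction`), and the generator's
default failure rate is 2.6%, matching the reported share of
unprocessable frames in home-recorded tasting videos.

Of the estimator's 368 mesh points, 53 key landmarks outline the
regions the measures need: two 5-point eyebrows (inner to outer), two
closed eye-contour polygons, the nose tip, the inner eye corners, the
mouth corners, and the mid upper/lower lip. The shipped index map
(`defaultLandmarkMap()`) is deliberately data, not code: no
authoritative list of the region indices exists, so the JSON map is an
editable approximation that users should adapt to their estimator.
Left/right is always the observer's left/right.

## The twelve measures

All measures are computed per frame — every frame, whether the
expression is neutral, transitioning or at its peak — because peak
frames cannot be identified reliably and the dynamics themselves are
informative. To cancel camera distance and zoom, every distance is
divided by the per-frame **reference distance** `r`, the Euclidean
distance between the right inner eye corner and the nose tip; the
polygon areas are divided by `r²` so they are equally dimensionless.
Angles are intrinsic and need no scaling.

| Measure (L/R or upper/lower)  | Construction |
|---|---|
| eyebrow elevation | distance from the median of the 5 brow points to the nose tip, / `r` |
| eyebrow tilt | angle between the total-least-squares line through the 5 brow points and the inner-eye-corner line, folded into [0°, 90°] |
| eyebrow shape | interior angle at the middle brow point between the segments to the two endpoints, in [0°, 180°] |
| palpebral aperture | absolute shoelace area of the eye-contour polygon, / `r²` |
| lip elevation | mid-lip (upper/lower) to nose-tip distance, / `r` |
| mouth corner | mouth-corner to nose-tip distance, / `r` |

Three constructions deserve comment.

**The eyebrow median.** The median of a 2D point set is not unique. We
use the coordinate-wise median, but taken in the face-intrinsic frame
whose x-axis is the inner-eye-corner line: a median along image axes is
not rotation-equivariant, and the whole measure set is required to be
invariant under in-plane similarity transforms (translation, rotation,
uniform scale). With the intrinsic frame, that invariance holds to
machine precision and is enforced by property tests.

**The tilt line fit.** The line through the five brow points is fitted
by total least squares (the principal axis of the 2×2 covariance), not
by regressing y on x: ordinary regression is not rotation-equivariant.
The angle against the inter-ocular axis is reported unsigned in
[0°, 90°]; whether a signed convention is preferable is unresolved in
the source material, and the unsigned form is the safer default for
variability statistics.

**2D by default.** All measures use the x–y image-plane projection
(angles and shoelace areas are planar constructs, and estimator depth
is its least reliable coordinate); a `mode = "3d"` switch lets the
distance measures use full 3D if wanted.

Degenerate frames (zero reference distance, coincident fit points) are
dropped with a warning and counted — never imputed. A 5-frame centred
moving average (`movingAverage`) is provided for display; all
statistics and classifier features use unsmoothed series.

## From frames to statistics

`summariseVideo` reduces a video's measure series to twelve sample
standard deviations (n−1 denominator — the source does not state a
denominator, so the unbiased-variance convention is used throughout).
By default the SDs are computed over SI and SII concatenated: reactions
frequently continue after the strip is removed, and the display
convention for example traces also spans both sections. SI-only and
SII-only are configuration options.

Group statistics mirror the study design:

* **Kruskal–Wallis** (`kruskalWallis`) on the hedonic ratings, by
  taste across the cohort and by sex/age/strip-order within each taste.
  The H statistic is tie-corrected and referred to chi-square on k−1
  degrees of freedom for k groups.
* **One-way ANOVA** (`anovaMeasures`) of the per-video SDs, separately
  by taste and by hedonic score — two main-effect analyses rather than
  a factorial model, and on per-video SDs rather than frame-level
  values (both points are undetermined in the source; per-video SDs
  are the unit everywhere else in the pipeline, so they are the
  default here too).
* **Box-plot summaries** (`groupedDistributions`): median, type-7
  (linear-interpolation) quartiles, and 1.5·IQR whiskers clamped to
  the most extreme inlying points.

No multiple-testing correction is applied, matching the original
analysis; the report records the number of tests run so readers can
apply their own.

## Importance ranking

`rankImportanceTrees` fits an extremely-randomised trees classifier —
200 trees, √p candidate features per split with one random cut-point
each, no bootstrap, minimum 5 samples to split and 2 per leaf — and
averages impurity-based importances, normalised to sum to one, over 20
refit seeds (single-seed tree importances are unstable at a few hundred
rows). Ties break by the canonical measure order, and the per-seed
importances are kept so ranking stability can be inspected.

`rankImportancePCA` is the stability cross-check: features are
standardised, and each measure is scored by its squared loadings on the
above-average-eigenvalue components (Kaiser rule), weighted by
explained-variance share. The restriction to leading components is what
gives the score discrimination: over *all* components the
variance-weighted squared-loading sum is identically 1/p for every
column of standardised data. `compareRankings` reports top-k overlap
and Spearman correlation between the two rankings.

`classifyCV` evaluates taste/score classification with subject-grouped
cross-validation — no child's videos appear on both sides of a split,
since per-subject idiosyncrasies would otherwise leak identity and
inflate accuracy. The hyperparameter list exposes `mtry` besides the
stated defaults; note that with very few informative features and small
n, √p candidate sampling can dilute a lone signal feature.

## The synthetic generator

`generateCohort` emulates the study's data-generating structure, not
its pixels. Each synthetic child receives one control video plus three
taste videos in one of the three randomised strip orders; ages are
drawn from the published cohort age-frequency table (5–11 years,
median 8.5), sexes at the published 36:28 ratio, and hedonic scores
from a per-taste distribution (`hedonicModel`) encoding the expected
pattern — sweet peaked at 5, bitter at 1, control at 3, sour spread
out. Each video is built as:

1. a mirror-symmetric neutral face template laid out for the 53-point
   map;
2. **expression events** — region-level displacements (brow raise,
   mouth-corner pull, lip raise/depression, eye squint as contour
   contraction toward the centroid) with ramp/pulse/sustained temporal
   profiles, amplitudes expressed as fractions of the inter-ocular
   distance and scaled by a per-subject log-normal gain;
3. **rigid nuisance motion** — translation and in-plane rotation
   random walks and a smooth multiplicative scale drift about the face
   centroid, which the rescaled measures must (and do) cancel;
4. **isotropic Gaussian landmark noise**, default SD 0.0025 normalised
   units ≈ 2% of the template's inter-ocular distance — the error
   scale typical of face-mesh estimators, which report mean landmark
   errors of a few percent of the inter-ocular distance;
5. **Bernoulli frame drop-out** at the 2.6% default.

The default per-taste effect profiles loosely encode the qualitative
observations (bitter → lower-lip activity, sweet → brow raise); they
are configuration, not hard-coded truth. `eyebrowOnlyEffects` plants a
signal in one measure family only (amplitudes control 0.01, sour 0.05,
bitter 0.09, sweet 0.14, right brow 1.25× the left), the ground truth
used by the recovery tests: cohorts generated this way must rank an
eyebrow-elevation variant first in the trees importance and show the
trees and PCA top-3 overlapping.

What the generator does **not** model: non-rigid skin deformation and
co-articulated regions, out-of-plane head pose, estimator noise that is
correlated across landmarks or frames, lighting, or any inter-subject
reaction typology. Passing the recovery tests therefore demonstrates
that the pipeline's inference chain is sound — it recovers planted
effects through rigid motion, noise and drop-out — not that real
children's videos will show the same effect sizes.

## Numerical and reproducibility choices

* Section bounds are inclusive, frame indices 0-based; SI ∪ SII
  partitions the analysed span.
* Even smoothing windows are rejected (centred convention); window 1
  is the identity.
* Coordinates survive CSV/JSON round trips to ≥12 significant digits.
* All randomness flows from explicit seeds: cohorts are byte-for-byte
  reproducible, tree fits are refit per listed seed with one thread,
  and two runs of the report stage with the same config and seed
  produce byte-identical output files (manifests deliberately carry no
  timestamps).
* Test-suite and acceptance problem sizes were chosen as the smallest
  that make the stochastic checks stable: 1000 random frames for the
  geometry oracles, 1000 null replicates for test calibration, a
  40-subject (160-video, 100-frame) cohort with 20 refit seeds for
  importance recovery, and 100 streams of 500 frames for the drop-out
  check.

## Known limitations

The default landmark map is an approximation (the exact region indices
of the source analysis are unpublished); the video adapter — calling an
external face-mesh estimator on MP4 input — is out of the core and not
exercised by tests; the pipeline makes no attempt to reproduce the
original study's test statistics, which depend on unreleased raw
ratings and videos; and hedonic-score ANOVA requires at least two
videos per score level, which small cohorts may not provide (the
report then skips that table and says so).
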