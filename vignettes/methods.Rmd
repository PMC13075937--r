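---
title: "Quantifying behavioral individuality across environmental contexts"
author: "flyIndiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral individuality across environmental contexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyIndiv)
```

## The problem

Individual flies differ consistently in how they behave: how much they
walk, how fast, how strongly they fixate a visual target, how much they
avoid the open center of an arena. Whether those individual differences
survive a change of environment — temperature, illumination, arena
shape, or even the switch from walking to tethered flight — is the
scientific question this package serves. It provides the full chain
needed to ask it quantitatively:

1. video tracking of single walking flies in circular (Buridan-type)
   and Y-maze arenas, one fly per region of interest (ROI);
2. heading tracking of a single tethered flying fly from close-up
   silhouette images;
3. a behavioral parameter suite grouped into exploration, attention and
   anxiety traits;
4. individuality statistics: cross-context Pearson correlation,
   percentile-rank differences with a ridge regression over binary
   context-change predictors, and hierarchical mixed models whose
   intraclass correlation coefficient (ICC) measures repeatability;
5. a synthetic-data layer that renders arena videos with known ground
   truth and simulates cohorts with a known individuality structure, so
   every stage is testable without any recorded data.

## Walking tracker

The tracker assumes dark flies on bright, back-lit arenas. A background
image is the per-pixel **maximum** of the video's first and last frame:
any fly that moved between the two vanishes, because at each pixel the
brighter (fly-free) value wins. Per frame, the absolute difference to
the background is restricted to each ROI and thresholded (default 25
gray levels on the 0–255 scale, a user-set parameter); blobs of at
least `minBlobArea` pixels are candidate flies. One blob is the fly;
with several, the blob nearest the previously stored position wins
(deterministic lowest-label tie-break); with none, the last known
position is carried with `detected = FALSE` until the fly reappears.
Frames before the first detection are back-filled from it. These rules
make the output length always equal the frame count.

ROI discovery is automatic: adaptive thresholding (neighborhood 1/8 of
the smaller frame dimension — large uniform arenas survive as a bright
rim that hole-filling completes), connected components, area filtering
(components below a quarter of the largest are discarded as noise; an
explicit area band can be supplied instead), then a per-component
circle fit. ROIs are sorted into rows by 1-D clustering of centroid y
with tolerance equal to half the median ROI radius, and by x within a
row; ids are assigned row-major, so ordering is a pure function of
centroid coordinates. The mm-per-pixel scale comes from the known
physical arena diameter (49 mm for the multi-arena platform, 120 mm
for the classic single platform) divided by the fitted pixel diameter.
Lens distortion is corrected with the standard Brown–Conrady
radial–tangential model; the coefficients are accepted as input (the
calibration estimation itself is out of scope).

Converted trajectories use arena coordinates — origin at the ROI
center, x right, y up, in mm — and time in seconds from the frame
index and rate. The **walking filter** then advances the position only
when the displacement from the last *updated* position (the anchor)
reaches the walking threshold `tau` (default 0.8 mm/frame, inclusive).
Measuring from the anchor rather than the previous frame means
sub-threshold jitter around a spot never registers, while genuinely
slow locomotion still updates once the fly has moved `tau` away.

## Flight tracker

A tethered fly is segmented at two Gaussian blur scales: the strong
blur erases thin structures (legs, folded wing edges) so that
thresholding yields the body alone; subtracting the (slightly grown)
body from the weak-blur mask leaves the appendages. The body axis is
the orientation of the moment ellipse (second central moments), mapped
to [0, 180)° counter-clockwise from image +x. To resolve head from
abdomen, the mask is centered on its centroid and rotated so the axis
lies on x; the half-plane with the **smaller** pixel sum is the head
side (head plus thorax are narrower than the abdomen), so the heading
is the axis or the axis + 180°. Exactly tied halves, degenerate
(isotropic) masks and fly-free frames carry the previous value and are
flagged — never interpolated. A frame counts as not flying when the
appendage pixels in the lateral sectors (bearings more than ~22° off
the body axis, beyond a guard ring of 6 px around the body) exceed 5%
of the body pixel count: folded wings flare laterally beyond the body
outline.

Defaults: strong sigma 5 px and weak sigma 2 px at the renderer's
default fly size (~60 px body length), scaling linearly with fly size.
The strong scale was chosen from the geometry of the silhouette: it
must erase ~4 px wing strokes while preserving the ~10 px-wide head
lobe; a substantially larger sigma starts to erode the head itself,
which degrades both the axis fit and the quadrant head rule.

Rotational velocity is computed after unwrapping: successive heading
differences are mapped to the shortest signed arc (−180, 180] and
cumulatively summed. On a synthetic fly rotating at the optomotor
pre-test speed of 120°/s (90 fps), the tracker recovers the rate to
well within 2% — this is the check `scripts/acceptance.R` re-runs.

## Behavioral parameters

Walking (from a filtered trajectory at frame rate $r$):

* **percent time walked** $= 100 \cdot \#\{\text{updated frames after
  the first}\} / (n - 1)$;
* **walking speed**: mean anchor-to-anchor step length × $r$, over
  updated frames only (speed while walking, not diluted by pauses);
  undefined (NA) for a fly that never walked;
* **vector strength**: mean resultant length
  $R = \lvert n^{-1} \sum_k e^{i\theta_k} \rvert$ of the movement
  directions of updated steps, with angles **doubled** first (axial
  statistic) because the two stripes sit 180° apart — a fly shuttling
  between opposite targets is perfectly "oriented". Using positional
  bearings from the arena center instead is exposed as an option;
* **angular velocity**: mean signed shortest-arc direction change × $r$
  (turning bias);
* **centrophobicity**: fraction of frames at radial distance beyond
  80% of the arena radius. Under uniform occupancy this edge ring
  holds $1 - 0.8^2 = 0.36$ of the area, which is the neutral baseline;
  no baseline subtraction is applied.

Flight (from a heading series): **number of pauses** (maximal
non-flying runs of at least 0.2 s by default), **absolute angular
velocity** (mean absolute shortest-arc change × rate), **vector
strength** and signed **angular velocity** over headings, and the
**median axial heading** (headings folded mod 180°, doubled, circular
median — the sample point minimizing summed absolute wrapped
deviation, exact ties resolved by the circular mean of the minimizers —
then halved back).

Occupancy heatmaps cap their color scale at the 95% quantile of the
*nonzero* bin counts, so empty arena corners do not distort the scale.
Flies that never moved (no updated frame; no flying frame) are set
aside by `excludeNonmovers()` rather than contributing zeros.

## Individuality statistics

**Cross-context correlation.** Per-fly trait values in two contexts are
correlated (Pearson) over complete pairs; p-values use the t transform
with $n-2$ df. Zero variance yields a missing value, not a spurious
coefficient. Group means are compared with a paired t-test after a
Shapiro–Wilk normality check whose result is reported alongside — the
test is never switched silently.

**Rank statistics and ridge GLM.** Trait values are converted to
within-group percentile ranks, $(\mathrm{rank}-1)/(n-1)\times 100$ with
average ties, which are invariant under any monotone transform of the
trait. For a pair of contexts, each fly's absolute rank difference is
the response, and five binary predictors code which context features
changed: time (day), temperature, vision (stripes or illumination),
arena, and behavioral state (walking vs flight). Because these
predictors are collinear by design, the model is ridge regression:
predictors are z-scored on the full data, the penalty is selected by
seeded five-fold cross-validation over 25 log-spaced values of
$\lambda$ from $10^{-6}$ to $10^6$ (25 points is a declared choice;
the endpoints are fixed), and the intercept is unpenalized, so at
$\lambda \to \infty$ predictions collapse to the mean rank change and
at $\lambda \to 0$ the fit equals ordinary least squares (verified to
$10^{-6}$ in the tests). Inference is by bootstrap: rows of $(X, y)$
resampled jointly 1000 times, refit at the selected $\lambda$; the
bootstrap standard deviation is the SE and the two-sided p-value is
the normal tail of (full-data coefficient)/SE — with 1000 replicates
the normal reference is indistinguishable from a t with high df, and
the df for a bootstrap t is not otherwise defined. Degenerate
resamples (a constant column) are redrawn, capped at 10× the requested
replicates. Per-trait models are the default; pooling traits is left
to the caller by concatenating designs. Raw p-values are reported
without multiplicity correction.

**Hierarchical mixed model.** Per trait, value ~ context fixed effects
(each numeric factor code that varies: day 1–3, temperature in °C,
stripes 0–2, light 0/1, arena 0/1, behavioral state 0/1) + a random
intercept per fly, fitted by REML with lme4. REML is the standard
choice when variance components are the quantity of interest, since ML
biases them downward. ICC = between-fly variance / total variance.
Collinear factor codes are pruned by QR before fitting. Singular fits
(between-fly variance at the boundary) are reported with a flag, not
an error. Fixed effects get Wald 95% CIs — profile likelihood CIs are
prohibitively slow inside a 1000× bootstrap and agree closely at these
sample sizes. The ICC's CI is a nonparametric bootstrap: flies are
resampled with replacement keeping each resampled fly's full context
set, duplicates relabeled as distinct, and the 2.5/97.5 percentiles of
the refitted ICCs are reported; more than 10% failed refits flags the
CI unreliable.

## The synthetic-data layer

The generator defines the study conditions under which everything is
tested; none of it claims biological realism beyond what the pipeline
needs.

*Cohorts.* A fly's trait value is grand mean + fly intercept
($\sigma^2_b$) + fixed effects × factor codes + residual
($\sigma^2_w$) — exactly the structure the mixed model assumes, so
closed-form oracles exist: the implied ICC is
$\sigma^2_b/(\sigma^2_b+\sigma^2_w)$ and the population cross-context
Pearson r equals the ICC. A context's `rankDisruption` $d$ replaces
the intercept with $\sqrt{1-d}\,b_i + \sqrt{d}\,\eta$, preserving
marginal variances while scaling the cross-context correlation by
$\sqrt{(1-d_A)(1-d_B)}$: $d=0$ reproduces pure rank preservation,
$d=1$ destroys it — the dissociation between group-mean shifts and
individual consistency in one dial.

*Walks.* A two-state (walk/pause) correlated random walk: the
stationary walking fraction equals the profile's activity (mean pause
bout 1 s), step length is speed/rate, and the direction evolves by
Gaussian turn noise plus two pulls — an axial pull toward the nearer
of the two opposite stripe bearings (so axial vector strength responds
monotonically to the attraction weight) and an outward pull scaled by
relative radius (so centrophobicity responds monotonically to the edge
bias). Positions reflect off the wall, and per-frame state and
direction are recorded as ground truth.

*Videos.* Bright arena disks on a dark surround, one dark anti-aliased
ellipse per ROI per frame oriented along the movement direction,
optional Gaussian pixel noise, and a frame-indexed ground-truth table
in pixels. A generator form renders frames on demand so long videos
never materialize in memory. The tethered-fly renderer draws a pear
silhouette — wide abdomen lobe, narrower head lobe — because the
head-assignment rule compares pixel sums about the centroid, and for a
mildly tapered convex shape that comparison is nearly balanced (the
centroid almost splits the count); the two-lobe shape gives the rule
the same margin a real fly's narrow head and wide abdomen provide.
Folded wings are thin strokes flaring rear-laterally well beyond the
body outline, thin enough for the strong blur to erase and long enough
to survive the guard ring.

What the fixtures do **not** emulate: body-pitch changes, legs,
shadows, reflections, uneven illumination, compression artifacts, or
multi-fly occlusions. Passing tests therefore demonstrate correctness
of the algorithms under their stated assumptions, not robustness to
every artifact of real recordings.

## Numerical choices and degenerate inputs

* Angles are degrees everywhere; differences wrap to (−180, 180], with
  +180 chosen at the boundary. Image y points down; arena/mathematical
  y up; the conversion happens exactly once, in `toMm()` and in the
  moment computation.
* The walking threshold comparison is inclusive (≥ tau); equidistant
  blob ties resolve to the lowest label; both choices are documented
  contracts rather than incidental behavior.
* Ridge is solved in closed form on the z-scored design
  ($(Z^\top Z + \lambda I)^{-1} Z^\top y_c$); z-scoring statistics are
  computed once on the full data and reused inside CV folds, mirroring
  the stated order z-score-then-fit.
* Missing values propagate as NA (a never-walking fly has no speed),
  never as zeros.
* Seeds: every stochastic function takes an explicit seed, restores
  the caller's RNG state, and identical seeds give bit-identical
  output — the reproducibility contract the tests assert.

## Problem sizes in the test-suite

The suite exercises a 25-arena, 60 s, 15 fps rendered video (tracker
fidelity below 0.5 px RMSE), a 15 s optomotor recovery at 90 fps,
ICC recovery averaged over five seeded 200-fly cohorts per true-ICC
level (a single draw at that size has sampling sd ≈ 0.035, so the
replicate mean is the meaningful test of the ±0.05 accuracy claim),
and 100 seeded replicates for fixed-effect CI coverage. These sizes
were chosen to make sampling noise small relative to each tolerance
while keeping the suite quick to run.

## Known limitations

* One fly per ROI is assumed; identity across ROIs is positional.
* The legacy .TXT/.DAT export is versioned (`flyIndiv-dat-1`) and
  documented, not asserted byte-compatible with earlier Buridan
  analysis software, whose exact dialect is not specified.
* Video I/O is by in-memory arrays or PNG frame sequences; containered
  video (AVI) should be unpacked to frames with external tooling
  before tracking.
* The Y-maze arena is located and scaled (centroid, arm length) but
  arm-choice statistics are not part of the parameter suite.
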