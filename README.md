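# flyIndiv

Video tracking and individuality statistics for fly behavior across
environmental contexts.

Individual *Drosophila* differ consistently in how much they walk, how
fast, how strongly they fixate a visual target (Buridan's paradigm: a
fly walking between two inaccessible opposite stripes), and how much
they avoid the open center of an arena. `flyIndiv` implements the full
chain needed to measure whether those individual differences persist
when the environment changes — temperature, illumination, arena shape,
or even the switch from walking to tethered flight:

* **Walking tracker** — background model (per-pixel maximum of first
  and last frame), per-ROI background subtraction and thresholding,
  centroid extraction with nearest-previous identity persistence and
  hold-on-loss, automatic ROI detection for single platforms, 5×5
  Buridan arrays and Y-maze arrays, Brown–Conrady lens undistortion,
  mm conversion, and the 0.8 mm/frame walking-threshold filter.
* **Flight tracker** — dual-scale Gaussian segmentation of a tethered
  fly silhouette, body axis from the moment ellipse, head-end
  disambiguation by quadrant pixel sums (the head half has the smaller
  pixel mass), wing-based flight-stop detection, heading unwrapping.
* **Behavioral parameters** — percent time walked, walking speed,
  axial vector strength (mean resultant length
  R = |mean(exp(i·θ))| with angles doubled so opposite headings count
  as one axis), signed/absolute angular velocity, centrophobicity
  (time beyond 80% of the arena radius; uniform baseline
  1 − 0.8² = 0.36), pause counts, median axial heading, occupancy
  heatmaps capped at the 95% count quantile, non-mover exclusion.
* **Individuality statistics** — cross-context Pearson correlation;
  within-group percentile ranks (0–100) and absolute rank differences;
  ridge regression of rank change on binary context-change predictors
  (z-scored design, five-fold CV over a 10⁻⁶–10⁶ log-λ grid, 1000×
  joint bootstrap for SEs and p-values); hierarchical mixed models
  (context fixed effects + fly random intercept, REML) with
  ICC = between-fly / total variance as repeatability, and fly-level
  bootstrap CIs for the ICC.
* **Synthetic data** — seeded simulators for cohort trait tables with
  a known ICC, two-state correlated random walks in circular arenas,
  tethered-flight heading series, and rendered arena/close-up videos
  with frame-exact ground truth, so every stage is testable without
  recorded data.

## Worked example

Simulate one fly walking in a Buridan arena, apply the walking filter,
and compute its behavioral profile:

```r
library(flyIndiv)

prof <- latentFlyProfile("fly01", baseSpeed = 12, activity = 0.7,
                         stripeAttraction = 0.6, edgeBias = 0.4)
walk <- simulateWalk(prof, contextModifier("buridan"),
                     arenaRadius = 24.5, duration = 120, rate = 15,
                     seed = 42)
filt <- walkingFilter(walk$trajectory, tau = 0.8)
computeProfile(filt, "fly01", "buridan", rate = 15, arenaRadius = 24.5)
#> BehaviorProfile: fly fly01, context buridan (walk)
#> percent_time_walked       walking_speed     vector_strength    angular_velocity
#>             42.9127             17.0729              0.2541             26.0102
#>     centrophobicity
#>              0.9422
```

The fly walked during 42.9% of frame transitions at 17.1 mm/s while
moving; its movement directions align modestly with the stripe axis
(axial vector strength 0.25 of a possible 1), and it spent 94% of its
time in the outer ring beyond 80% of the arena radius (strong
thigmotaxis, consistent with its `edgeBias`).

Individuality across contexts on a simulated 300-fly cohort — two
contexts that differ only in temperature (ranks preserved, group mean
shifted) and one rank-disrupting arena change:

```r
ctxs <- list(contextModifier("cool", temperature = 25),
             contextModifier("hot",  temperature = 32),
             contextModifier("ymaze", arena = 1, rankDisruption = 1))
vc  <- varianceComponents(1, 1, fixedEffects = c(temperature = 0.5))
tab <- simulateCohort(300, ctxs, vc, seed = 42)

fit <- fitTraitLMM(tab, "trait")
pearsonAcrossContexts(tab, "trait", "cool", "hot")$r    # 0.488
pearsonAcrossContexts(tab, "trait", "cool", "ymaze")$r  # 0.055
fit$icc                                                 # 0.179
```

The temperature shift moves the group mean by 3.5 trait units yet
leaves the individual ranking almost intact (r ≈ 0.49, the generating
ICC of 0.5), while the rank-disrupting arena change destroys it
(r ≈ 0.06). The mixed-model ICC over **all three** contexts drops to
0.18: repeatability measures only the individual component shared
across every context, so a single disruptive context dilutes it —
exactly the dissociation between group-level and individual-level
effects the statistics are designed to expose.

A command-line wrapper over the same functions lives at
`inst/scripts/flyindiv.R`
(`simulate` / `track-walk` / `track-flight` / `params` / `stats`).

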