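Package: flyIndiv
Title: Tracking and Cross-Context Individuality Statistics for Fly Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Video tracking and behavioral quantification for single
    Drosophila walking in Buridan-type and Y-maze arenas and for tethered
    flying flies, together with the statistics used to quantify behavioral
    individuality across environmental contexts. Includes a synthetic-data
    layer that renders arena videos with known ground-truth trajectories
    and simulates cohorts of flies with individual-specific latent traits;
    centroid tracking with background subtraction, identity persistence
    and hold-on-loss; heading tracking by ellipse fit with head-end
    disambiguation; a behavioral parameter suite (percent time walked,
    walking speed, vector strength, angular velocity, centrophobicity,
    pause counts, median axial heading); and individuality statistics
    (cross-context Pearson correlation, percentile-rank differences,
    cross-validated ridge regression with bootstrap inference, and
    hierarchical mixed models with intraclass-correlation repeatability).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    lme4,
    yaml,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
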