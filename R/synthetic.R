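# Synthetic-data layer: simulated cohorts, walking trajectories, flight
# heading series and rendered arena videos with known ground truth.
# The walk model is a two-state correlated random walk with wall
# reflection; it is a declared test fixture for the tracking and
# statistics layers, not a claim about fly locomotion.

# Evaluate expr under a fixed RNG seed without clobbering the caller's
# RNG stream.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Latent behavioral profile of one simulated fly
#'
#' Stable, fly-specific factors that the simulator holds fixed across
#' contexts: the individual component of behavior.
#'
#' @param flyId identifier.
#' @param baseSpeed walking speed while in the walking state, mm/s (> 0).
#' @param activity fraction of time in the walking state, in [0, 1].
#' @param stripeAttraction dimensionless steering weight (>= 0) pulling
#'   the movement direction toward the nearer of the two opposite
#'   stimulus bearings (the stripe axis).
#' @param edgeBias dimensionless steering weight (>= 0) pulling movement
#'   outward toward the arena wall (thigmotaxis).
#' @param turnNoise per-step direction noise, degrees (sd).
#' @return A validated list of class `LatentFlyProfile`.
#' @export
latentFlyProfile <- function(flyId = "fly1", baseSpeed = 10, activity = 0.5,
                             stripeAttraction = 0, edgeBias = 0,
                             turnNoise = 20) {
  stopifnot(is.finite(baseSpeed), baseSpeed > 0,
            is.finite(activity), activity >= 0, activity <= 1,
            is.finite(stripeAttraction), stripeAttraction >= 0,
            is.finite(edgeBias), edgeBias >= 0,
            is.finite(turnNoise), turnNoise >= 0)
  structure(list(flyId = as.character(flyId), baseSpeed = baseSpeed,
                 activity = activity, stripeAttraction = stripeAttraction,
                 edgeBias = edgeBias, turnNoise = turnNoise),
            class = "LatentFlyProfile")
}

#' Environmental context and its effect on the simulated fly
#'
#' Factor levels follow the numeric coding used throughout the
#' statistics layer: day 1-3, temperature in degrees C, 0-2 stripes,
#' light off (0) / on (1), round arena (0) / Y-maze (1), modality walk
#' or flight.
#'
#' @param contextId identifier.
#' @param day,temperature,nStripes,light,arena,modality factor levels.
#' @param speedScale multiplicative effect on walking speed (> 0).
#' @param activityShift additive shift of the walking-state fraction.
#' @param attractionScale multiplicative effect on stripe attraction
#'   (>= 0; 0 emulates a dark or stripe-free arena).
#' @param rankDisruption fraction in [0, 1] of the between-fly variance
#'   replaced by fresh noise in this context; 0 preserves individual
#'   ranks perfectly, 1 destroys them.
#' @return A validated list of class `ContextModifier`.
#' @export
contextModifier <- function(contextId, day = 1, temperature = 25,
                            nStripes = 2, light = 1, arena = 0,
                            modality = "walk", speedScale = 1,
                            activityShift = 0, attractionScale = 1,
                            rankDisruption = 0) {
  stopifnot(speedScale > 0, attractionScale >= 0,
            rankDisruption >= 0, rankDisruption <= 1,
            modality %in% c("walk", "flight"))
  structure(list(contextId = as.character(contextId), day = day,
                 temperature = temperature, nStripes = nStripes,
                 light = light, arena = arena, modality = modality,
                 speedScale = speedScale, activityShift = activityShift,
                 attractionScale = attractionScale,
                 rankDisruption = rankDisruption),
            class = "ContextModifier")
}

#' Variance components of the simulated cohort
#'
#' The generating model of [simulateCohort()] mirrors the structure the
#' mixed model assumes: a fly-specific random intercept (between-fly
#' variance), additive context fixed effects, and residual within-fly
#' noise. The implied repeatability is
#' ICC = sigma2Between / (sigma2Between + sigma2Within).
#'
#' @param sigma2Between between-fly variance (>= 0), trait units squared.
#' @param sigma2Within residual within-fly variance (> 0).
#' @param fixedEffects named numeric: slope per unit of the numeric
#'   factor codes; names among day, temperature, stripes, light, arena.
#' @return A validated list of class `VarianceComponents`.
#' @export
varianceComponents <- function(sigma2Between, sigma2Within,
                               fixedEffects = numeric(0)) {
  if (!is.finite(sigma2Within) || sigma2Within <= 0)
    stop("sigma2Within must be finite and > 0")
  if (!is.finite(sigma2Between) || sigma2Between < 0)
    stop("sigma2Between must be finite and >= 0")
  ok <- c("day", "temperature", "stripes", "light", "arena")
  if (length(fixedEffects) && !all(names(fixedEffects) %in% ok))
    stop("fixedEffects names must be among: ", paste(ok, collapse = ", "))
  structure(list(sigma2Between = sigma2Between,
                 sigma2Within = sigma2Within, fixedEffects = fixedEffects),
            class = "VarianceComponents")
}

#' Simulate a cohort trait table with known individuality structure
#'
#' Generates a long-format behavior table (one row per fly x context):
#' value = grand mean + fly intercept + sum(fixed effects x factor
#' codes) + residual. Per context, `rankDisruption` d replaces the fly
#' intercept by sqrt(1-d) * intercept + sqrt(d) * fresh noise of the
#' same variance, so marginal variances are preserved while the
#' cross-context correlation of the individual component scales with
#' sqrt((1-dA)(1-dB)).
#'
#' @param nFlies number of flies (>= 2).
#' @param contexts list of [contextModifier()] objects (>= 1).
#' @param components a [varianceComponents()] object.
#' @param seed integer RNG seed; equal seeds give identical tables.
#' @param grandMean trait grand mean.
#' @param trait trait name recorded in the table.
#' @return data.frame with columns fly, context, day, temperature,
#'   stripes, light, arena, modality, trait, value.
#' @examples
#' cm <- list(contextModifier("a"), contextModifier("b", temperature = 32))
#' vc <- varianceComponents(1, 1)
#' tab <- simulateCohort(50, cm, vc, seed = 1)
#' head(tab)
#' @export
simulateCohort <- function(nFlies, contexts, components, seed,
                           grandMean = 0, trait = "trait") {
  stopifnot(is.numeric(nFlies), nFlies >= 2)
  if (!length(contexts)) stop("at least one context required")
  if (inherits(contexts, "ContextModifier")) contexts <- list(contexts)
  stopifnot(inherits(components, "VarianceComponents"))
  nFlies <- as.integer(nFlies)
  withSeed(seed, {
    b <- stats::rnorm(nFlies, 0, sqrt(components$sigma2Between))
    rows <- lapply(contexts, function(cx) {
      d <- cx$rankDisruption
      bc <- sqrt(1 - d) * b +
        sqrt(d) * stats::rnorm(nFlies, 0, sqrt(components$sigma2Between))
      codes <- c(day = cx$day, temperature = cx$temperature,
                 stripes = cx$nStripes, light = cx$light, arena = cx$arena)
      fe <- components$fixedEffects
      shift <- if (length(fe)) sum(fe * codes[names(fe)]) else 0
      val <- grandMean + bc + shift +
        stats::rnorm(nFlies, 0, sqrt(components$sigma2Within))
      data.frame(fly = sprintf("fly%03d", seq_len(nFlies)),
                 context = cx$contextId, day = cx$day,
                 temperature = cx$temperature, stripes = cx$nStripes,
                 light = cx$light, arena = cx$arena,
                 modality = cx$modality, trait = trait, value = val,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a walking trajectory in a circular arena
#'
#' Two-state (walk/pause) correlated random walk. While walking, the
#' step length is baseSpeed x speedScale / rate and the direction is the
#' previous direction plus Gaussian turn noise, an axial pull toward the
#' nearer of the two opposite stripe bearings, and an outward pull
#' toward the wall scaled by relative radius. Positions are reflected at
#' the wall so every point lies inside the arena.
#'
#' @param profile a [latentFlyProfile()].
#' @param modifier a [contextModifier()].
#' @param arenaRadius arena radius, mm (> 0).
#' @param duration recording length, s.
#' @param rate frame rate, frames/s (> 0); duration x rate >= 2.
#' @param seed integer RNG seed.
#' @param stripeAxis bearing of the stripe axis, degrees (stripes sit at
#'   `stripeAxis` and `stripeAxis + 180`).
#' @param start starting position, mm (default centre).
#' @param meanPauseBout mean pause-bout duration, s, used to set the
#'   two-state switching rates.
#' @return list with `trajectory` (a [Trajectory-class]), `state`
#'   (character per frame, "walk"/"pause") and `direction` (degrees per
#'   frame): the ground truth for tracker and parameter tests.
#' @export
simulateWalk <- function(profile, modifier, arenaRadius, duration, rate,
                         seed, stripeAxis = 0, start = c(0, 0),
                         meanPauseBout = 1) {
  stopifnot(inherits(profile, "LatentFlyProfile"),
            inherits(modifier, "ContextModifier"), arenaRadius > 0)
  if (rate <= 0) stop("rate must be > 0")
  n <- floor(duration * rate)
  if (n < 2) stop("duration x rate must give at least 2 frames")
  act <- min(1, max(0, profile$activity + modifier$activityShift))
  step <- profile$baseSpeed * modifier$speedScale / rate
  kA <- min(1, profile$stripeAttraction * modifier$attractionScale)
  kE <- min(1, profile$edgeBias)
  # two-state Markov chain with stationary walking fraction = act
  pWake <- if (act <= 0) 0 else min(1, 1 / (meanPauseBout * rate))
  pStop <- if (act >= 1) 0 else if (act <= 0) 1 else
    min(1, pWake * (1 - act) / act)
  withSeed(seed, {
    x <- y <- dir <- numeric(n)
    state <- character(n)
    x[1] <- start[1]; y[1] <- start[2]
    dir[1] <- stats::runif(1, 0, 360)
    walking <- stats::runif(1) < act
    state[1] <- if (walking) "walk" else "pause"
    turn <- stats::rnorm(n, 0, profile$turnNoise)
    flips <- stats::runif(n)
    for (i in 2:n) {
      walking <- if (walking) flips[i] >= pStop else flips[i] < pWake
      state[i] <- if (walking) "walk" else "pause"
      if (!walking) {
        x[i] <- x[i - 1]; y[i] <- y[i - 1]; dir[i] <- dir[i - 1]
        next
      }
      d <- dir[i - 1]
      # axial pull: error folded to [-90, 90)
      eA <- ((stripeAxis - d + 90) %% 180) - 90
      r0 <- sqrt(x[i - 1]^2 + y[i - 1]^2)
      eE <- if (r0 > 0) {
        wrapDiff(rad2deg(atan2(y[i - 1], x[i - 1])) - d) * (r0 / arenaRadius)
      } else 0
      d <- d + kA * eA + kE * eE + turn[i]
      nx <- x[i - 1] + step * cos(deg2rad(d))
      ny <- y[i - 1] + step * sin(deg2rad(d))
      r <- sqrt(nx^2 + ny^2)
      if (r > arenaRadius) {
        # reflect the position radially and the velocity across the wall
        # tangent
        phi <- atan2(ny, nx)
        rr <- max(2 * arenaRadius - r, 0)
        nx <- rr * cos(phi); ny <- rr * sin(phi)
        d <- 2 * (rad2deg(phi) + 90) - d
      }
      x[i] <- nx; y[i] <- ny; dir[i] <- wrap360(d)
    }
    tr <- trajectory(time = (seq_len(n) - 1) / rate, x = x, y = y)
    list(trajectory = tr, state = state, direction = dir)
  })
}

#' Simulate a tethered-flight heading series
#'
#' In `"fixation"` mode the heading fluctuates around a preferred
#' direction (mean-reverting wrapped noise), emulating a fly that keeps
#' an arbitrary heading for the whole flight. In `"optomotor"` mode the
#' heading drifts at a constant rotation rate, emulating the response to
#' a rotating stripe pattern. Pause bouts (flying = FALSE, heading held)
#' occur as a two-state process.
#'
#' @param profile a [latentFlyProfile()]; `turnNoise` sets the heading
#'   noise sd in degrees.
#' @param modifier a [contextModifier()].
#' @param duration length, s (> 0); duration x rate >= 2.
#' @param rate sampling rate, samples/s.
#' @param seed integer RNG seed.
#' @param mode "fixation" or "optomotor".
#' @param preferredHeading degrees; drawn uniformly if NULL.
#' @param rotationRate optomotor drift, degrees/s (sign = direction).
#' @param pausePerSec probability per second of entering a pause bout.
#' @param meanPauseBout mean pause-bout duration, s.
#' @param reversion mean-reversion gain toward the preferred heading per
#'   sample, in (0, 1].
#' @return A [HeadingSeries-class].
#' @export
simulateFlightHeadings <- function(profile, modifier, duration, rate, seed,
                                   mode = c("fixation", "optomotor"),
                                   preferredHeading = NULL,
                                   rotationRate = 120, pausePerSec = 0,
                                   meanPauseBout = 1, reversion = 0.2) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be > 0")
  n <- floor(duration * rate)
  if (n < 2) stop("duration x rate must give at least 2 samples")
  withSeed(seed, {
    mu <- if (is.null(preferredHeading)) stats::runif(1, 0, 360)
          else preferredHeading
    noise <- stats::rnorm(n, 0, profile$turnNoise)
    h <- numeric(n)
    if (mode == "optomotor") {
      h <- mu + rotationRate * (seq_len(n) - 1) / rate + noise
    } else {
      h[1] <- mu + noise[1]
      for (i in 2:n)
        h[i] <- h[i - 1] + reversion * wrapDiff(mu - h[i - 1]) + noise[i]
    }
    pIn <- min(1, pausePerSec / rate)
    pOut <- min(1, 1 / (meanPauseBout * rate))
    flying <- logical(n)
    flying[1] <- TRUE
    u <- stats::runif(n)
    for (i in 2:n)
      flying[i] <- if (flying[i - 1]) u[i] >= pIn else u[i] < pOut
    # hold: carry the last heading through pause bouts
    for (i in 2:n) if (!flying[i]) h[i] <- h[i - 1]
    hw <- wrap360(h)
    headingSeries(time = (seq_len(n) - 1) / rate, heading = hw,
                  flying = flying)
  })
}

# alpha coverage of an axis-aligned (after rotation) fly body at local
# coords (u along axis toward head, v across). headNarrow < 1 renders a
# pear: a wide abdomen lobe behind the centre and a narrower head lobe
# in front (head pixel mass smaller than the abdomen's, as in a real
# silhouette); headNarrow = 1 renders a plain symmetric ellipse.
# Anti-aliased: values in [0, 1].
flyBodyAlpha <- function(u, v, halfLength, halfWidth, headNarrow = 0.46) {
  aa <- function(d, w) pmin(1, pmax(0, (1 - d) * w + 0.5))
  if (headNarrow >= 1) {
    d <- sqrt((u / halfLength)^2 + (v / halfWidth)^2)
    return(aa(d, halfWidth))
  }
  lobe <- 0.6 * halfLength
  off <- 0.4 * halfLength
  dAbd <- sqrt(((u + off) / lobe)^2 + (v / halfWidth)^2)
  wHead <- headNarrow * halfWidth
  dHead <- sqrt(((u - off) / lobe)^2 + (v / wHead)^2)
  pmax(aa(dAbd, halfWidth), aa(dHead, wHead))
}

#' Render an arena video with known ground truth
#'
#' Draws bright arena disks on a dark surround and, per frame, one dark
#' anti-aliased fly ellipse per ROI at the ground-truth position,
#' oriented along the movement direction, with optional additive
#' Gaussian pixel noise. Emulates flies filmed from below against a
#' near-infrared backlight.
#'
#' @param trajectories list of [Trajectory-class] (mm, arena
#'   coordinates), one per ROI, all of equal length; trajectory `i` is
#'   drawn in the `i`-th ROI of `layout`.
#' @param layout an [ArenaLayout-class].
#' @param width,height frame size, pixels.
#' @param bodyLength,bodyWidth fly silhouette axes, pixels.
#' @param arenaIntensity,flyIntensity,bgIntensity gray levels (0-255).
#' @param noiseSd additive Gaussian noise sd, gray levels.
#' @param seed RNG seed for the noise.
#' @param hideFrames optional list (one element per trajectory) of frame
#'   indices on which that fly is not drawn (simulated detection loss).
#' @param asFunction if TRUE, return a generator `function(i)` yielding
#'   frame `i` (for long videos) instead of a 3-D array.
#' @return numeric array `height x width x nFrames` on the 0-255 scale
#'   (or a generator with attribute `nFrames`), with attribute
#'   `groundTruthPx`: data.frame (frame, roi, x_px, y_px).
#' @export
renderArenaFrames <- function(trajectories, layout, width, height,
                              bodyLength = 7, bodyWidth = 3.2,
                              arenaIntensity = 200, flyIntensity = 20,
                              bgIntensity = 30, noiseSd = 0, seed = 1,
                              hideFrames = NULL, asFunction = FALSE) {
  if (inherits(trajectories, "Trajectory")) trajectories <- list(trajectories)
  r <- rois(layout)
  if (length(trajectories) != nrow(r))
    stop(sprintf("got %d trajectories but layout has %d roi(s)",
                 length(trajectories), nrow(r)))
  n <- nFrames(trajectories[[1]])
  if (!all(vapply(trajectories, nFrames, 1L) == n))
    stop("all trajectories must have equal length")
  # static background: bright disks on dark surround
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  bg <- matrix(bgIntensity, height, width)
  for (k in seq_len(nrow(r)))
    bg[(xs - r$cx_px[k])^2 + (ys - r$cy_px[k])^2 <= r$radius_px[k]^2] <-
      arenaIntensity
  # ground-truth pixel positions (arena mm -> image px; image y is down)
  gt <- do.call(rbind, lapply(seq_len(nrow(r)), function(k) {
    tr <- trajectories[[k]]
    data.frame(frame = seq_len(n), roi = r$id[k],
               x_px = r$cx_px[k] + tr@x / r$mm_per_px[k],
               y_px = r$cy_px[k] - tr@y / r$mm_per_px[k])
  }))
  dirs <- lapply(trajectories, function(tr) {
    dx <- c(0, diff(tr@x)); dy <- c(0, diff(tr@y))
    a <- atan2(dy, dx)  # mathematical angle (arena coords, y up)
    a[dx == 0 & dy == 0] <- NA
    # carry last moving direction; default 0
    for (i in seq_along(a)) if (is.na(a[i])) a[i] <- if (i > 1) a[i - 1] else 0
    a
  })
  halfL <- bodyLength / 2; halfW <- bodyWidth / 2
  pad <- ceiling(halfL + 2)
  noise <- NULL
  if (noiseSd > 0 && !asFunction)
    noise <- withSeed(seed, stats::rnorm(height * width * n, 0, noiseSd))
  gtk <- split(gt, gt$roi)[as.character(r$id)]
  drawFrame <- function(i, noiseVec = NULL) {
    fr <- bg
    for (k in seq_len(nrow(r))) {
      if (!is.null(hideFrames) && i %in% hideFrames[[k]]) next
      cx <- gtk[[k]]$x_px[i]; cy <- gtk[[k]]$y_px[i]
      th <- dirs[[k]][i]
      x0 <- max(1L, floor(cx - pad)); x1 <- min(width, ceiling(cx + pad))
      y0 <- max(1L, floor(cy - pad)); y1 <- min(height, ceiling(cy + pad))
      if (x0 > x1 || y0 > y1) next
      lx <- x0:x1; ly <- y0:y1
      dx <- matrix(rep(lx - cx, each = length(ly)), length(ly))
      dy <- matrix(rep(ly - cy, length(lx)), length(ly))
      # projection onto the heading vector, which in image coords (y
      # down) is (cos th, -sin th) for a mathematical angle th
      u <- dx * cos(th) - dy * sin(th)
      v <- dx * sin(th) + dy * cos(th)
      a <- flyBodyAlpha(u, v, halfL, halfW, headNarrow = 1)
      fr[ly, lx] <- fr[ly, lx] * (1 - a) + flyIntensity * a
    }
    if (!is.null(noiseVec))
      fr <- matrix(pmin(255, pmax(0, fr + noiseVec)), height, width)
    fr
  }
  if (asFunction) {
    gen <- function(i) {
      nv <- if (noiseSd > 0)
        withSeed(seed + i, stats::rnorm(height * width, 0, noiseSd))
      else NULL
      drawFrame(i, nv)
    }
    attr(gen, "nFrames") <- n
    attr(gen, "groundTruthPx") <- gt
    return(gen)
  }
  out <- array(0, c(height, width, n))
  for (i in seq_len(n)) {
    nv <- if (!is.null(noise))
      noise[((i - 1) * height * width + 1):(i * height * width)] else NULL
    out[, , i] <- drawFrame(i, nv)
  }
  attr(out, "groundTruthPx") <- gt
  out
}

#' Render close-up frames of a tethered fly at given headings
#'
#' Draws a dark egg-shaped fly silhouette (head end narrower than the
#' abdomen) centred in the frame on a bright background, rotated to each
#' heading; optionally adds wing triangles flaring laterally from the
#' abdomen on non-flying frames (wings become visible when the fly
#' stops) and Gaussian pixel noise.
#'
#' @param headings numeric degrees per frame (counter-clockwise from
#'   image +x, i.e. the direction the head points).
#' @param size frame side length, pixels.
#' @param bodyLength,bodyWidth silhouette axes, pixels.
#' @param flying logical per frame; wings drawn where FALSE.
#' @param flyIntensity,bgIntensity gray levels.
#' @param noiseSd additive Gaussian noise sd, gray levels.
#' @param seed RNG seed for the noise.
#' @return numeric array `size x size x length(headings)`, 0-255 scale.
#' @export
renderFlightFrames <- function(headings, size = 96, bodyLength = 60,
                               bodyWidth = 22,
                               flying = rep(TRUE, length(headings)),
                               flyIntensity = 25, bgIntensity = 220,
                               noiseSd = 0, seed = 1) {
  n <- length(headings)
  c0 <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size) - c0, each = size), size, size)
  ys <- matrix(rep(seq_len(size) - c0, size), size, size)
  halfL <- bodyLength / 2; halfW <- bodyWidth / 2
  noise <- if (noiseSd > 0)
    withSeed(seed, stats::rnorm(size * size * n, 0, noiseSd)) else NULL
  out <- array(bgIntensity, c(size, size, n))
  for (i in seq_len(n)) {
    th <- deg2rad(headings[i])
    # rotate so +u points along the heading; image y is down, so a CCW
    # mathematical angle maps to (cos, -sin) in image rows
    u <- xs * cos(th) - ys * sin(th)
    v <- xs * sin(th) + ys * cos(th)
    a <- flyBodyAlpha(u, v, halfL, halfW)
    if (!flying[i]) {
      # wings: two thin strokes flaring laterally over the abdomen;
      # thin enough that a strong blur removes them from the body mask
      su <- -0.10 * halfL; sv <- 0.15 * halfW
      eu <- -1.40 * halfL; ev <- 2.80 * halfW
      vv <- abs(v)
      len2 <- (eu - su)^2 + (ev - sv)^2
      tt <- pmin(1, pmax(0, ((u - su) * (eu - su) + (vv - sv) * (ev - sv)) /
                              len2))
      d <- sqrt((u - (su + tt * (eu - su)))^2 +
                  (vv - (sv + tt * (ev - sv)))^2)
      a <- pmax(a, pmin(1, pmax(0, 2 - d)))
    }
    fr <- bgIntensity * (1 - a) + flyIntensity * a
    if (!is.null(noise))
      fr <- pmin(255, pmax(0, fr +
        noise[((i - 1) * size * size + 1):(i * size * size)]))
    out[, , i] <- fr
  }
  out
}
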