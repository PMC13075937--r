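# Behavioral parameter suite: exploration (% time walked, walking
# speed, pause counts), attention (vector strength, angular velocity,
# median axial heading), anxiety (centrophobicity), occupancy heatmaps
# and non-mover exclusion.

#' Percent of time walked
#'
#' Fraction of frame transitions on which the walking filter advanced
#' the position: 100 x (updated frames after the first) / (frames - 1).
#'
#' @param filtered a [FilteredTrajectory-class] with >= 2 frames.
#' @return percent in [0, 100].
#' @export
percentTimeWalked <- function(filtered) {
  stopifnot(is(filtered, "FilteredTrajectory"))
  n <- length(filtered@time)
  if (n < 2) stop("need at least 2 frames")
  100 * sum(filtered@updated[-1]) / (n - 1)
}

#' Mean walking speed
#'
#' Mean of step length x frame rate over updated frames only: the speed
#' while walking, not diluted by pauses. With no updated step the value
#' is undefined and NA is returned.
#'
#' @param filtered a [FilteredTrajectory-class].
#' @param rate frame rate, frames/s.
#' @return mm/s, or NA if the fly never walked.
#' @export
walkingSpeed <- function(filtered, rate) {
  stopifnot(is(filtered, "FilteredTrajectory"))
  upd <- which(filtered@updated)
  upd <- upd[upd > 1]
  if (!length(upd)) return(NA_real_)
  # displacement from the previous anchor position
  anchors <- c(1L, upd)
  steps <- sqrt(diff(filtered@x[anchors])^2 + diff(filtered@y[anchors])^2)
  mean(steps) * rate
}

#' Mean resultant vector length (vector strength)
#'
#' Length of the mean unit vector of the angles: 1 for perfectly
#' concentrated, 0 for uniform directions. With `axial = TRUE` the
#' angles are doubled before averaging so that opposite directions count
#' as the same axis (the two stripes sit 180 degrees apart).
#'
#' @param angles degrees (>= 1 value).
#' @param axial double the angles first?
#' @return value in [0, 1].
#' @export
vectorStrength <- function(angles, axial = FALSE) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("no angles supplied")
  a <- deg2rad(if (axial) 2 * angles else angles)
  min(1, sqrt(mean(cos(a))^2 + mean(sin(a))^2))
}

#' Angular velocity from a direction series
#'
#' Successive differences are mapped to the shortest signed arc
#' (-180, 180]; signed mode returns the mean difference x rate (turning
#' bias), absolute mode the mean absolute difference x rate (total
#' turning).
#'
#' @param directions degrees per frame (>= 2 samples).
#' @param rate frames/s.
#' @param mode "signed" or "absolute".
#' @return degrees/s.
#' @export
angularVelocity <- function(directions, rate, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  directions <- directions[!is.na(directions)]
  if (length(directions) < 2) stop("need at least 2 direction samples")
  d <- wrapDiff(diff(directions))
  if (mode == "absolute") mean(abs(d)) * rate else mean(d) * rate
}

# circular median of angles (degrees, on the full circle): the data
# point minimizing the summed absolute wrapped distance; exact ties are
# combined by circular mean of the minimizers
circularMedian <- function(a) {
  dev <- vapply(a, function(m) sum(abs(wrapDiff(a - m))), 0)
  best <- which(dev <= min(dev) + 1e-9)
  if (length(best) == 1L) return(wrap360(a[best]))
  b <- deg2rad(a[best])
  wrap360(rad2deg(atan2(mean(sin(b)), mean(cos(b)))))
}

#' Median axial heading
#'
#' Headings are folded mod 180, doubled, reduced by the circular median,
#' and halved back: the median orientation axis, in [0, 180).
#'
#' @param headings degrees (>= 1 value).
#' @return degrees in [0, 180).
#' @export
medianHeadingAxial <- function(headings) {
  headings <- headings[!is.na(headings)]
  if (!length(headings)) stop("no headings supplied")
  (circularMedian(2 * (headings %% 180)) / 2) %% 180
}

#' Centrophobicity (edge-time fraction)
#'
#' The center region is the disk around the arena center with a radius
#' of `centerFraction` (default 80%) of the arena radius;
#' centrophobicity is the fraction of frames spent outside it, in the
#' edge ring. Under uniform occupancy the expected value is
#' 1 - centerFraction^2 (0.36 at the default).
#'
#' @param traj a [Trajectory-class] (arena coordinates, mm).
#' @param arenaRadius arena radius, mm (> 0).
#' @param centerFraction radius fraction defining the center region.
#' @return fraction in [0, 1].
#' @export
centrophobicity <- function(traj, arenaRadius, centerFraction = 0.8) {
  stopifnot(is(traj, "Trajectory"), arenaRadius > 0)
  n <- length(traj@time)
  if (!n) stop("empty trajectory")
  r <- sqrt(traj@x^2 + traj@y^2)
  mean(r > centerFraction * arenaRadius)
}

#' Count flight pauses
#'
#' Number of maximal runs of `flying = FALSE` lasting at least
#' `minDuration` seconds.
#'
#' @param series a [HeadingSeries-class].
#' @param minDuration minimum bout duration, s (>= 0).
#' @return non-negative integer.
#' @export
countPauses <- function(series, minDuration = 0.2) {
  stopifnot(is(series, "HeadingSeries"), minDuration >= 0)
  r <- rle(!series@flying)
  if (!any(r$values)) return(0L)
  dt <- if (length(series@time) > 1) stats::median(diff(series@time)) else 1
  sum(r$values & r$lengths * dt >= minDuration)
}

#' Occupancy heatmap with a 95%-quantile color ceiling
#'
#' 2-D histogram of positions over the arena bounding square. The
#' maximum color value is set to the 95% quantile of the nonzero bin
#' counts, so a few heavily occupied bins do not wash out the rest of
#' the map.
#'
#' @param traj a [Trajectory-class].
#' @param bins number of bins per axis (>= 2).
#' @param arenaRadius half-width of the binned square, mm; defaults to
#'   the largest absolute coordinate.
#' @param ceilingQuantile quantile of the nonzero counts used as the
#'   color ceiling.
#' @return list with `counts` (bins x bins matrix), `ceiling` (numeric),
#'   and `breaks` (bin edges, mm).
#' @export
occupancyHeatmap <- function(traj, bins = 25, arenaRadius = NULL,
                             ceilingQuantile = 0.95) {
  stopifnot(is(traj, "Trajectory"), bins >= 2)
  if (is.null(arenaRadius))
    arenaRadius <- max(abs(c(traj@x, traj@y)), 1e-9)
  br <- seq(-arenaRadius, arenaRadius, length.out = bins + 1)
  ix <- pmin(bins, pmax(1, findInterval(traj@x, br, rightmost.closed = TRUE)))
  iy <- pmin(bins, pmax(1, findInterval(traj@y, br, rightmost.closed = TRUE)))
  counts <- matrix(0, bins, bins)
  for (i in seq_along(ix))
    counts[iy[i], ix[i]] <- counts[iy[i], ix[i]] + 1
  nz <- counts[counts > 0]
  list(counts = counts,
       ceiling = as.numeric(stats::quantile(nz, ceilingQuantile)),
       breaks = br)
}

# movement directions (degrees) of updated steps, measured between
# consecutive anchor positions
stepDirections <- function(filtered) {
  upd <- which(filtered@updated)
  if (length(upd) < 2) return(numeric(0))
  dx <- diff(filtered@x[upd]); dy <- diff(filtered@y[upd])
  wrap360(rad2deg(atan2(dy, dx)))
}

#' Compute the behavioral profile of one fly in one context
#'
#' Walking profiles (from a [FilteredTrajectory-class]):
#' percent_time_walked, walking_speed, vector_strength (axial, over the
#' movement directions of updated steps), angular_velocity (signed, over
#' the same directions) and centrophobicity. Flight profiles (from a
#' [HeadingSeries-class]): n_pauses, absolute_angular_velocity,
#' vector_strength, angular_velocity (both over headings) and
#' median_heading_axial. Undefined values (e.g. the speed of a fly that
#' never walked) are NA, never zero.
#'
#' @param input a [FilteredTrajectory-class] (walking) or
#'   [HeadingSeries-class] (flight).
#' @param flyId,contextId identifiers.
#' @param rate frame rate, frames/s.
#' @param arenaRadius arena radius, mm (walking only).
#' @param attentionAngles for walking, "steps" (default) uses the
#'   movement directions of updated steps for the attention parameters;
#'   "bearing" uses the positional bearing from the arena center.
#' @param pauseMinDuration minimum pause duration, s (flight only).
#' @return A [BehaviorProfile-class].
#' @export
computeProfile <- function(input, flyId, contextId, rate,
                           arenaRadius = NULL,
                           attentionAngles = c("steps", "bearing"),
                           pauseMinDuration = 0.2) {
  attentionAngles <- match.arg(attentionAngles)
  if (is(input, "FilteredTrajectory")) {
    moved <- any(input@updated[-1])
    ang <- if (attentionAngles == "steps") stepDirections(input)
           else wrap360(rad2deg(atan2(input@y, input@x)))
    p <- c(
      percent_time_walked = percentTimeWalked(input),
      walking_speed = walkingSpeed(input, rate),
      vector_strength = if (length(ang)) vectorStrength(ang, axial = TRUE)
                        else NA_real_,
      angular_velocity = if (length(ang) >= 2)
        angularVelocity(ang, rate, "signed") else NA_real_,
      centrophobicity = if (is.null(arenaRadius)) NA_real_
                        else centrophobicity(input, arenaRadius))
    mod <- "walk"
  } else if (is(input, "HeadingSeries")) {
    moved <- any(input@flying)
    h <- input@heading
    p <- c(
      n_pauses = as.numeric(countPauses(input, pauseMinDuration)),
      absolute_angular_velocity = angularVelocity(h, rate, "absolute"),
      vector_strength = vectorStrength(h, axial = FALSE),
      angular_velocity = angularVelocity(h, rate, "signed"),
      median_heading_axial = medianHeadingAxial(h))
    mod <- "flight"
  } else {
    stop("input must be a FilteredTrajectory or a HeadingSeries")
  }
  new("BehaviorProfile", flyId = as.character(flyId),
      contextId = as.character(contextId), modality = mod, parameters = p,
      moved = moved)
}

#' Exclude flies that did not move
#'
#' Walking profiles with no updated frame after the first (percent time
#' walked 0) and flight profiles with no flying frame are moved to the
#' excluded set, mirroring the exclusion of non-movers from analysis.
#'
#' @param profiles list of [BehaviorProfile-class].
#' @return list with `kept` and `excluded` profile lists.
#' @export
excludeNonmovers <- function(profiles) {
  isMover <- vapply(profiles, function(p) isTRUE(p@moved), TRUE)
  list(kept = profiles[isMover], excluded = profiles[!isMover])
}

#' Write behavior profiles as a wide CSV
#'
#' One row per profile: fly, context, modality, then one column per
#' parameter (the union over profiles; missing parameters are NA).
#'
#' @param profiles list of [BehaviorProfile-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  allNames <- unique(unlist(lapply(profiles, function(p) names(p@parameters))))
  rows <- lapply(profiles, function(p) {
    v <- stats::setNames(rep(NA_real_, length(allNames)), allNames)
    v[names(p@parameters)] <- p@parameters
    cbind(data.frame(fly = p@flyId, context = p@contextId,
                     modality = p@modality, stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
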