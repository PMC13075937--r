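# Behavioral parameter suite: circular statistics, exploration and
# anxiety measures, heatmaps, profiles and non-mover exclusion.

test_that("percent time walked counts updated transitions", {
  allWalk <- walkingFilter(stepTrajectory(rep(1, 10)), 0.8)
  expect_equal(percentTimeWalked(allWalk), 100)
  # sub-threshold jitter around the anchor never updates
  still <- walkingFilter(stepTrajectory(rep(c(0.5, -0.5), 5)), 0.8)
  expect_equal(percentTimeWalked(still), 0)
  # 30 updated of 61 frames -> 50%
  f2 <- walkingFilter(stepTrajectory(rep(c(1, 0), 30)), 0.8)
  expect_equal(length(f2@time), 61)
  expect_equal(sum(f2@updated[-1]), 30)
  expect_equal(percentTimeWalked(f2), 50)
  expect_error(percentTimeWalked(walkingFilter(
    trajectory(0, 0, 0), 0.8)))
})

test_that("walking speed averages over walking frames only", {
  f <- walkingFilter(stepTrajectory(rep(1, 10), rate = 20), 0.8)
  expect_equal(walkingSpeed(f, 20), 20)
  mixed <- walkingFilter(stepTrajectory(rep(c(1, 2), 5), rate = 10), 0.8)
  expect_equal(walkingSpeed(mixed, 10), 15)
  still <- walkingFilter(stepTrajectory(rep(0, 5)), 0.8)
  expect_true(is.na(walkingSpeed(still, 10)))
})

test_that("vector strength matches the complex-sum oracle and axial
           doubling", {
  expect_equal(vectorStrength(rep(123, 7)), 1)
  # direct oracle: |mean(exp(i*a))|
  oracle <- function(a) Mod(mean(exp(1i * a * pi / 180)))
  expect_equal(vectorStrength(c(0, 90)), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(vectorStrength(c(0, 90)), oracle(c(0, 90)))
  set.seed(1)
  a <- runif(50, 0, 360)
  expect_equal(vectorStrength(a), oracle(a), tolerance = 1e-12)
  expect_equal(vectorStrength(c(10, 190), axial = TRUE), 1)
  expect_lt(vectorStrength(c(10, 190), axial = FALSE), 1e-9)
  expect_error(vectorStrength(numeric(0)))
})

test_that("vector strength is rotation invariant; axial version ignores
           180-degree flips", {
  set.seed(2)
  a <- runif(40, 0, 360)
  for (phi in c(13, 117, 301))
    expect_equal(vectorStrength(a + phi), vectorStrength(a),
                 tolerance = 1e-12)
  flips <- sample(c(0, 180), 40, replace = TRUE)
  expect_equal(vectorStrength(a + flips, axial = TRUE),
               vectorStrength(a, axial = TRUE), tolerance = 1e-12)
})

test_that("angular velocity uses shortest-arc differences in both
           modes", {
  expect_equal(angularVelocity(rep(50, 10), 10, "signed"), 0)
  expect_equal(angularVelocity(rep(50, 10), 10, "absolute"), 0)
  alt <- cumsum(c(0, rep(c(10, -10), 10)))
  expect_equal(angularVelocity(alt, 10, "signed"), 0)
  expect_equal(angularVelocity(alt, 10, "absolute"), 100)
  mono <- (1.3333333 * (0:89)) %% 360  # wraps, but unwraps to a line
  expect_equal(angularVelocity(mono, 90, "signed"), 120, tolerance = 1e-4)
  expect_equal(angularVelocity(mono, 90, "absolute"), 120, tolerance = 1e-4)
  expect_error(angularVelocity(5, 10))
})

test_that("median axial heading folds, doubles and halves correctly", {
  expect_equal(medianHeadingAxial(rep(170, 5)), 170)
  expect_equal(medianHeadingAxial(c(10, 190)), 10)
  expect_equal(medianHeadingAxial(c(80, 100)), 90)
  # circular median oracle on doubled angles for an odd sample
  h <- c(10, 20, 30, 150, 170)
  doubled <- (2 * (h %% 180)) %% 360
  dev <- vapply(doubled, function(m)
    sum(abs(wrapDiff180(doubled - m))), 0)
  expect_equal(medianHeadingAxial(h),
               (doubled[which.min(dev)] / 2) %% 180)
  expect_error(medianHeadingAxial(numeric(0)))
})

test_that("centrophobicity is the edge-ring time fraction with the 80%
           boundary", {
  wall <- trajectory(0:9 / 10, rep(19.9, 10), rep(0, 10))
  expect_equal(centrophobicity(wall, 20), 1)
  centre <- trajectory(0:9 / 10, rep(0, 10), rep(0, 10))
  expect_equal(centrophobicity(centre, 20), 0)
  # uniform occupancy: analytic area ratio 1 - 0.8^2 = 0.36
  set.seed(3)
  n <- 40000
  r <- 20 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  unif <- trajectory(seq_len(n) / 15, r * cos(th), r * sin(th))
  expect_lt(abs(centrophobicity(unif, 20) - 0.36), 0.01)
  # boundary: a point at f x R is "edge" exactly when f > 0.8
  fr <- seq(0.70, 0.90, by = 0.01)
  edge <- vapply(fr, function(f)
    centrophobicity(trajectory(0, 20 * f, 0), 20), 0)
  expect_equal(max(fr[edge == 0]), 0.80)
  expect_equal(min(fr[edge == 1]), 0.81)
})

test_that("centrophobicity grows with the simulator's edge bias", {
  vals <- vapply(c(0, 0.3, 0.8), function(k) {
    w <- simulateWalk(latentFlyProfile(activity = 1, edgeBias = k,
                                       turnNoise = 30),
                      contextModifier("c"), arenaRadius = 20,
                      duration = 120, rate = 15, seed = 42)
    centrophobicity(w$trajectory, 20)
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("pause counting respects the minimum duration", {
  mk <- function(flying) headingSeries(seq_along(flying) / 10,
                                       rep(0, length(flying)),
                                       flying = flying)
  expect_equal(countPauses(mk(rep(TRUE, 50)), 0.5), 0L)
  two <- rep(TRUE, 60); two[11:20] <- FALSE; two[41:50] <- FALSE
  expect_equal(countPauses(mk(two), 0.5), 2L)  # two 1 s bouts at 10 Hz
  short <- rep(TRUE, 30); short[10] <- FALSE   # 0.1 s bout
  expect_equal(countPauses(mk(short), 0.5), 0L)
})

test_that("heatmap ceiling equals the 95% quantile of nonzero counts", {
  # constructed histogram: bin k holds k points (k = 1..100)
  bins <- 10
  xs <- ys <- cnt <- c()
  k <- 0
  for (bx in 1:bins) for (by in 1:bins) {
    k <- k + 1
    if (k > 100) break
    xs <- c(xs, rep(-20 + (bx - 0.5) * 4, k))
    ys <- c(ys, rep(-20 + (by - 0.5) * 4, k))
  }
  tr <- trajectory(seq_along(xs) / 15, xs, ys)
  hm <- occupancyHeatmap(tr, bins = bins, arenaRadius = 20)
  expect_equal(sort(hm$counts[hm$counts > 0]), as.numeric(1:100))
  expect_equal(hm$ceiling, unname(quantile(1:100, 0.95)))
  # single occupied bin holds everything; empty bins are excluded
  one <- trajectory(1:50 / 15, rep(1, 50), rep(1, 50))
  h1 <- occupancyHeatmap(one, bins = 5, arenaRadius = 20)
  expect_equal(max(h1$counts), 50)
  expect_equal(sum(h1$counts), 50)
  expect_equal(h1$ceiling, 50)
})

test_that("profiles carry the modality parameter sets and flag
           non-movers", {
  w <- fixtureWalk(seed = 12, duration = 20)
  f <- walkingFilter(w$trajectory)
  pw <- computeProfile(f, "f1", "ctx", rate = 15, arenaRadius = 18)
  expect_s4_class(pw, "BehaviorProfile")
  expect_named(profileParameters(pw),
               c("percent_time_walked", "walking_speed", "vector_strength",
                 "angular_velocity", "centrophobicity"))
  # stationary walker: zero percent, missing speed and attention
  still <- walkingFilter(stepTrajectory(rep(0, 20)), 0.8)
  ps <- computeProfile(still, "f2", "ctx", rate = 15, arenaRadius = 18)
  expect_equal(unname(profileParameters(ps)["percent_time_walked"]), 0)
  expect_true(is.na(profileParameters(ps)["walking_speed"]))
  expect_true(is.na(profileParameters(ps)["vector_strength"]))
  # strongly attracted walker fixates the stripe axis
  wa <- simulateWalk(latentFlyProfile(activity = 1, stripeAttraction = 3,
                                      turnNoise = 10),
                     contextModifier("c"), arenaRadius = 20,
                     duration = 60, rate = 15, seed = 10)
  pa <- computeProfile(walkingFilter(wa$trajectory), "f3", "ctx",
                       rate = 15, arenaRadius = 20)
  expect_gt(profileParameters(pa)["vector_strength"], 0.8)
  # constant-heading flight
  hs <- headingSeries(0:99 / 90, rep(77, 100))
  pf <- computeProfile(hs, "f4", "ctx", rate = 90)
  expect_named(profileParameters(pf),
               c("n_pauses", "absolute_angular_velocity", "vector_strength",
                 "angular_velocity", "median_heading_axial"))
  expect_equal(unname(profileParameters(pf)["vector_strength"]), 1)
  expect_equal(unname(profileParameters(pf)["angular_velocity"]), 0)
  # exclusion
  neverFlew <- headingSeries(0:9 / 90, rep(0, 10),
                             flying = rep(FALSE, 10))
  pn <- computeProfile(neverFlew, "f5", "ctx", rate = 90)
  sp <- excludeNonmovers(list(pw, ps, pa, pf, pn))
  expect_equal(length(sp$kept), 3)
  expect_equal(length(sp$excluded), 2)
  expect_equal(vapply(sp$excluded, function(p) p@flyId, ""), c("f2", "f5"))
})

test_that("profiles are pure functions of their input", {
  w <- fixtureWalk(seed = 14, duration = 10)
  f <- walkingFilter(w$trajectory)
  p1 <- computeProfile(f, "a", "c", rate = 15, arenaRadius = 18)
  p2 <- computeProfile(f, "a", "c", rate = 15, arenaRadius = 18)
  expect_identical(profileParameters(p1), profileParameters(p2))
})

test_that("profile tables are written wide with one column per
           parameter", {
  w <- fixtureWalk(seed = 15, duration = 5)
  p <- computeProfile(walkingFilter(w$trajectory), "a", "c", 15, 18)
  path <- tempfile(fileext = ".csv")
  writeProfiles(list(p), path)
  d <- read.csv(path)
  expect_equal(d$fly, "a")
  expect_true(all(c("percent_time_walked", "centrophobicity") %in%
                    names(d)))
})
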