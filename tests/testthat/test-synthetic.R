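# Synthetic-data layer: determinism, generating-model moments, and the
# ground-truth contracts the downstream stages rely on.

test_that("cohort generator is deterministic and validates inputs", {
  ctxs <- fourContexts()
  vc <- varianceComponents(1, 1)
  t1 <- simulateCohort(20, ctxs, vc, seed = 5)
  t2 <- simulateCohort(20, ctxs, vc, seed = 5)
  expect_identical(t1, t2)
  t3 <- simulateCohort(20, ctxs, vc, seed = 6)
  expect_false(identical(t1$value, t3$value))
  expect_equal(nrow(t1), 20 * 4)
  expect_error(simulateCohort(1, ctxs, vc, seed = 1))
  expect_error(varianceComponents(1, 0))
  expect_error(varianceComponents(1, -1))
})

test_that("cohort variance decomposition matches configured components", {
  # direct oracle: within = mean per-fly variance across identical
  # contexts; between = var of fly means minus within/k
  ctxs <- lapply(1:4, function(i) contextModifier(paste0("c", i)))
  tab <- simulateCohort(1000, ctxs, varianceComponents(2, 1), seed = 11)
  m <- tapply(tab$value, tab$fly, mean)
  within <- mean(tapply(tab$value, tab$fly, var))
  between <- var(m) - within / 4
  expect_lt(abs(within - 1) / 1, 0.1)
  expect_lt(abs(between - 2) / 2, 0.1)
})

test_that("equal variance components give sample ICC near 0.5 and no
           individual component gives r near 0", {
  ctxs <- list(contextModifier("a"), contextModifier("b"))
  tab <- simulateCohort(200, ctxs, varianceComponents(1, 1), seed = 7)
  a <- tab$value[tab$context == "a"]; b <- tab$value[tab$context == "b"]
  expect_lt(abs(cor(a, b) - 0.5), 0.12)  # population r = ICC = 0.5
  tab0 <- simulateCohort(400, ctxs, varianceComponents(0, 1), seed = 8)
  a0 <- tab0$value[tab0$context == "a"]; b0 <- tab0$value[tab0$context == "b"]
  expect_lt(abs(cor(a0, b0)), 0.12)
})

test_that("fixed effects shift context means by slope times factor step", {
  ctxs <- list(contextModifier("lo", temperature = 25),
               contextModifier("hi", temperature = 32))
  tab <- simulateCohort(800, ctxs, varianceComponents(1, 1, c(temperature = 2)),
                        seed = 13)
  shift <- mean(tab$value[tab$context == "hi"]) -
    mean(tab$value[tab$context == "lo"])
  expect_lt(abs(shift - 2 * 7) / 14, 0.05)
})

test_that("walk simulator honors activity and stays inside the arena", {
  still <- simulateWalk(latentFlyProfile(activity = 0),
                        contextModifier("c"), arenaRadius = 20,
                        duration = 5, rate = 15, seed = 1)
  expect_true(all(still$trajectory@x == still$trajectory@x[1]))
  expect_true(all(still$trajectory@y == still$trajectory@y[1]))
  expect_true(all(still$state == "pause"))
  w <- fixtureWalk(seed = 2, duration = 30)
  r <- sqrt(w$trajectory@x^2 + w$trajectory@y^2)
  expect_true(all(r <= 18 + 1e-9))
  expect_identical(fixtureWalk(seed = 4)$trajectory,
                   fixtureWalk(seed = 4)$trajectory)
  expect_error(simulateWalk(latentFlyProfile(), contextModifier("c"),
                            arenaRadius = 20, duration = 5, rate = 0,
                            seed = 1))
})

test_that("unbiased walk occupancy approaches uniform over the disk", {
  # Monte-Carlo occupancy oracle: under uniform occupancy the fraction
  # beyond 80% of the radius is 1 - 0.8^2 = 0.36 and the fraction
  # inside half the radius is 0.25
  w <- simulateWalk(latentFlyProfile(baseSpeed = 25, activity = 1,
                                     stripeAttraction = 0, edgeBias = 0,
                                     turnNoise = 40),
                    contextModifier("c"), arenaRadius = 20,
                    duration = 1200, rate = 15, seed = 9)
  r <- sqrt(w$trajectory@x^2 + w$trajectory@y^2) / 20
  expect_lt(abs(mean(r > 0.8) - 0.36), 0.08)
  expect_lt(abs(mean(r < 0.5) - 0.25), 0.08)
})

test_that("stripe attraction concentrates movement directions axially", {
  w <- simulateWalk(latentFlyProfile(activity = 1, stripeAttraction = 3,
                                     turnNoise = 10),
                    contextModifier("c"), arenaRadius = 20,
                    duration = 60, rate = 15, seed = 10)
  walkDirs <- w$direction[w$state == "walk"]
  expect_gt(vectorStrength(walkDirs, axial = TRUE), 0.9)
})

test_that("flight heading simulator covers fixation, optomotor and pauses", {
  p0 <- latentFlyProfile(turnNoise = 0)
  hs <- simulateFlightHeadings(p0, contextModifier("c", modality = "flight"),
                               duration = 2, rate = 90, seed = 1,
                               preferredHeading = 90)
  expect_true(all(hs@heading == 90))
  expect_equal(vectorStrength(hs@heading), 1)
  om <- simulateFlightHeadings(p0, contextModifier("c", modality = "flight"),
                               duration = 5, rate = 90, seed = 2,
                               mode = "optomotor", rotationRate = 120,
                               preferredHeading = 0)
  slope <- mean(diff(unwrapHeadings(om))) * 90
  expect_equal(slope, 120, tolerance = 1e-9)
  expect_equal(countPauses(hs, 0), 0L)
  wp <- simulateFlightHeadings(latentFlyProfile(turnNoise = 5),
                               contextModifier("c"), duration = 60,
                               rate = 90, seed = 3, pausePerSec = 0.2)
  expect_gt(sum(!wp@flying), 0)
  expect_error(simulateFlightHeadings(p0, contextModifier("c"),
                                      duration = -1, rate = 90, seed = 1))
})

test_that("renderer keeps frames and ground truth in one-to-one
           correspondence", {
  lay <- singleArenaLayout()
  w <- fixtureWalk(seed = 5, duration = 3)
  fr <- renderArenaFrames(list(w$trajectory), lay, width = 120,
                          height = 120, noiseSd = 0)
  gt <- attr(fr, "groundTruthPx")
  expect_equal(dim(fr)[3], nFrames(w$trajectory))
  expect_equal(nrow(gt), nFrames(w$trajectory))
  still <- simulateWalk(latentFlyProfile(activity = 0),
                        contextModifier("c"), arenaRadius = 18,
                        duration = 1, rate = 15, seed = 1)
  fs <- renderArenaFrames(list(still$trajectory), lay, width = 120,
                          height = 120, noiseSd = 0)
  for (i in 2:dim(fs)[3]) expect_identical(fs[, , i], fs[, , 1])
  # generator and array forms agree
  gen <- renderArenaFrames(list(w$trajectory), lay, width = 120,
                           height = 120, noiseSd = 0, asFunction = TRUE)
  expect_equal(gen(7), fr[, , 7])
  expect_error(renderArenaFrames(list(w$trajectory, w$trajectory), lay,
                                 width = 120, height = 120))
})
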