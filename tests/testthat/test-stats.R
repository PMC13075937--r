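# Individuality statistics: correlations, ranks, ridge GLM, mixed
# models and their bootstrap machinery.

test_that("cross-context Pearson correlation handles the degenerate and
           generated cases", {
  ctxs <- list(contextModifier("a"), contextModifier("b"))
  tab <- simulateCohort(10, ctxs, varianceComponents(1, 1), seed = 1)
  # identical values: r = 1; negated: r = -1
  tid <- tab; tid$value[tid$context == "b"] <- tid$value[tid$context == "a"]
  expect_equal(pearsonAcrossContexts(tid, "trait", "a", "b")$r, 1)
  tng <- tab; tng$value[tng$context == "b"] <- -tng$value[tng$context == "a"]
  expect_equal(pearsonAcrossContexts(tng, "trait", "a", "b")$r, -1)
  # rank-preserving cohort: population r = ICC = 0.75
  big <- simulateCohort(200, ctxs, varianceComponents(3, 1), seed = 2)
  res <- pearsonAcrossContexts(big, "trait", "a", "b")
  expect_lt(abs(res$r - 0.75), 0.1)
  expect_equal(res$n, 200)
  # zero variance: missing r, not an error
  tz <- tab; tz$value[tz$context == "a"] <- 5
  expect_true(is.na(pearsonAcrossContexts(tz, "trait", "a", "b")$r))
  # too few pairs
  small <- simulateCohort(2, ctxs, varianceComponents(1, 1), seed = 3)
  expect_error(pearsonAcrossContexts(small, "trait", "a", "b"), "pairs")
})

test_that("group comparison reports normality and the paired t-test
           without switching", {
  set.seed(4)
  a <- rnorm(30)
  g <- groupComparison(a, a + 2 + rnorm(30, 0, 0.3))
  expect_lt(abs(g$mean_diff - 2), 0.3)
  expect_lt(g$t_p, 1e-6)
  expect_true(is.finite(g$shapiro_p))
  same <- groupComparison(a, a)
  expect_true(is.na(same$t))
  expect_match(same$note, "identical")
  expect_error(groupComparison(1:2, 2:3))
})

test_that("percentile ranks scale 0-100 with average ties and monotone
           invariance", {
  expect_equal(unname(toPercentileRanks(c(5, 2, 9))), c(50, 0, 100))
  expect_equal(unname(toPercentileRanks(rep(7, 4))), rep(50, 4))
  expect_equal(unname(toPercentileRanks(c(1, 2, 2, 4))), c(0, 50, 50, 100))
  set.seed(5)
  v <- rnorm(20)
  expect_equal(toPercentileRanks(exp(3 * v)), toPercentileRanks(v))
  expect_error(toPercentileRanks(c(NA, NA, 1)))
})

test_that("rank change is symmetric, zero for preserved ranks and near
           100/3 for independent contexts", {
  ctxs <- list(contextModifier("a"), contextModifier("b"),
               contextModifier("z", rankDisruption = 1))
  tab <- simulateCohort(500, ctxs, varianceComponents(1, 1e-6), seed = 6)
  # near-noiseless rank-preserving contexts: all |delta| ~ 0
  expect_lt(max(rankChange(tab, "trait", "a", "b")), 2)
  expect_equal(rankChange(tab, "trait", "a", "z"),
               rankChange(tab, "trait", "z", "a"))
  # independent contexts: E|U - V| = 1/3 for iid uniforms
  tabI <- simulateCohort(500, ctxs, varianceComponents(1, 1), seed = 7)
  expect_lt(abs(mean(rankChange(tabI, "trait", "a", "z")) - 100 / 3), 4)
  # n = 2 rank reversal
  t2 <- simulateCohort(2, ctxs[1:2], varianceComponents(1, 1), seed = 8)
  t2$value[t2$context == "b"] <- -t2$value[t2$context == "a"]
  expect_equal(unname(rankChange(t2, "trait", "a", "b")), c(100, 100))
})

test_that("the change design codes exactly the factors that differ", {
  ctxs <- list(contextModifier("base", day = 1, temperature = 23, light = 1),
               contextModifier("retest", day = 1, temperature = 23, light = 1),
               contextModifier("hotdark", day = 1, temperature = 32, light = 0),
               contextModifier("fly", day = 2, temperature = 23,
                               light = 1, modality = "flight"))
  tab <- simulateCohort(10, ctxs, varianceComponents(1, 1), seed = 9)
  d <- buildChangeDesign(tab, "trait", list(c("base", "retest"),
                                            c("base", "hotdark"),
                                            c("base", "fly")))
  expect_equal(colnames(d$X), c("time", "temperature", "vision", "arena",
                                "behavioral_state"))
  expect_equal(unname(d$X[1, ]), c(0, 0, 0, 0, 0))       # same-context retest
  expect_equal(unname(d$X[11, ]), c(0, 1, 1, 0, 0))      # 32C dark vs 23C light
  expect_equal(unname(d$X[21, ]), c(1, 0, 0, 0, 1))      # walk vs flight
  expect_equal(length(d$y), 30)
  expect_error(buildChangeDesign(tab, "trait", list(c("base", "base"))))
})

test_that("ridge matches OLS as lambda -> 0 and shrinks to the mean as
           lambda -> Inf", {
  set.seed(10)
  X <- matrix(rnorm(200), 50, 4)
  y <- drop(X %*% c(1, -2, 0, 3)) + rnorm(50)
  fit0 <- fitRidgeCV(X, y, lambdaGrid = 1e-8, seed = 1)
  ols <- coef(lm(y ~ scale(X)))
  expect_lt(max(abs(fit0$coefficients - ols[-1])), 1e-6)
  expect_equal(fit0$intercept, mean(y))
  fitInf <- fitRidgeCV(X, y, lambdaGrid = 1e12, seed = 1)
  expect_lt(max(abs(fitInf$coefficients)), 1e-8)
  expect_equal(fitInf$intercept, mean(y))
})

test_that("ridge coefficients shrink monotonically and duplicate
           predictors share their coefficient", {
  set.seed(11)
  X <- matrix(rnorm(150), 50, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(50)
  grid <- 10^seq(-6, 6, length.out = 25)
  norms <- vapply(grid, function(lam)
    sqrt(sum(fitRidgeCV(X, y, lambdaGrid = lam, seed = 1)$coefficients^2)),
    0)
  expect_true(all(diff(norms) <= 1e-9))
  Xd <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  fd <- fitRidgeCV(Xd, y, lambdaGrid = 10, seed = 1)
  expect_equal(fd$coefficients[["a"]], fd$coefficients[["b"]],
               tolerance = 1e-10)
})

test_that("cross-validation selects lambda from the grid and is
           deterministic in the seed", {
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3)
  y <- drop(X %*% c(1, 0.5, -0.5)) + rnorm(100, 0, 2)
  grid <- 10^seq(-6, 6, length.out = 25)
  f1 <- fitRidgeCV(X, y, grid, seed = 3)
  f2 <- fitRidgeCV(X, y, grid, seed = 3)
  expect_identical(f1, f2)
  expect_true(f1$lambda %in% grid)
  expect_equal(length(f1$cvMse), 25)
  expect_warning(fitRidgeCV(cbind(X, k = rep(1, 100)), y, grid, seed = 1),
                 "constant")
})

test_that("ridge solution agrees with an independent implementation", {
  # MASS::lm.ridge re-standardizes internally with an n-divisor sd, so
  # on an already z-scored design its penalty lambda' corresponds to
  # lambda * n / (n - 1) of the unscaled objective
  set.seed(14)
  n <- 60
  X <- matrix(rnorm(3 * n), n, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n)
  for (lam in c(0.1, 7, 500)) {
    mine <- fitRidgeCV(X, y, lambdaGrid = lam, seed = 1)$coefficients
    ref <- coef(MASS::lm.ridge(y ~ scale(X), lambda = lam * n / (n - 1)))[-1]
    expect_lt(max(abs(mine - ref)), 1e-10)
  }
})

test_that("ridge bootstrap recovers effect presence and absence", {
  set.seed(13)
  n <- 120
  X <- matrix(rnorm(3 * n), n, 3,
              dimnames = list(NULL, c("strong", "null", "weak")))
  y <- drop(X %*% c(2, 0, 0.8)) + rnorm(n)
  fit <- fitRidgeCV(X, y, seed = 2)
  bt <- bootstrapRidge(X, y, fit = fit, B = 200, seed = 5)
  expect_lt(bt$p[["strong"]], 0.01)
  expect_gt(bt$p[["null"]], 0.05)
  expect_lt(abs(bt$mean[["null"]]), 0.2)
  expect_identical(bt, bootstrapRidge(X, y, fit = fit, B = 200, seed = 5))
})

test_that("the mixed model recovers variance components, ICC and fixed
           effects", {
  ctxs <- fourContexts()
  tab <- simulateCohort(200, ctxs, varianceComponents(1, 1), seed = 20)
  f <- fitTraitLMM(tab, "trait")
  expect_lt(abs(f$icc - 0.5), 0.07)
  expect_false(f$singular)
  expect_equal(f$icc, f$sigma2Between / (f$sigma2Between + f$sigma2Within))
  # generating slope recovered within its CI
  tabS <- simulateCohort(300, ctxs,
                         varianceComponents(1, 1, c(temperature = 2)),
                         seed = 21)
  fs <- fitTraitLMM(tabS, "trait")
  row <- fs$fixed[fs$fixed$term == "temperature", ]
  expect_lt(row$ci_lo, 2)
  expect_gt(row$ci_hi, 2)
  # no replication: rejected
  one <- simulateCohort(10, ctxs[1], varianceComponents(1, 1), seed = 22)
  expect_error(fitTraitLMM(one, "trait"), "observations")
})

test_that("a cohort without a between-fly component yields a flagged
           near-zero ICC", {
  ctxs <- fourContexts()
  tab <- simulateCohort(60, ctxs, varianceComponents(0, 1), seed = 23)
  f <- fitTraitLMM(tab, "trait")
  expect_lt(f$icc, 0.05)
  expect_true(is.finite(f$icc))
  ci <- bootstrapICC(tab, "trait", B = 20, seed = 24)
  expect_lt(ci$ci[1], 0.02)  # lower bound pinned near 0
})

test_that("the ICC bootstrap is deterministic and brackets the
           generating value", {
  ctxs <- fourContexts()
  tab <- simulateCohort(80, ctxs, varianceComponents(1, 1), seed = 25)
  c1 <- bootstrapICC(tab, "trait", B = 40, seed = 26)
  c2 <- bootstrapICC(tab, "trait", B = 40, seed = 26)
  expect_identical(c1, c2)
  expect_lt(c1$ci[1], 0.5)
  expect_gt(c1$ci[2], 0.5)
  expect_false(c1$unreliable)
})
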