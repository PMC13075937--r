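# Individuality statistics: cross-context Pearson consistency, paired
# group tests, percentile ranks and rank differences, the
# rank-difference ridge GLM with bootstrap inference, and hierarchical
# mixed models with ICC repeatability.

# canonical context factor columns of a behavior table
.factorCols <- c("day", "temperature", "stripes", "light", "arena",
                 "modality")

checkBehaviorTable <- function(table) {
  need <- c("fly", "context", .factorCols, "trait", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("behavior table lacks columns: ", paste(miss, collapse = ", "))
  invisible(table)
}

traitValues <- function(table, trait, context) {
  s <- table[table$trait == trait & table$context == context, ]
  stats::setNames(s$value, s$fly)
}

#' Pearson correlation of a trait between two contexts
#'
#' Correlates per-fly trait values across two contexts over flies
#' measured in both; the p-value comes from the t transform with n - 2
#' degrees of freedom, two-sided.
#'
#' @param table long-format behavior table (see [simulateCohort()]).
#' @param trait trait name.
#' @param contextA,contextB context ids.
#' @return list with `r`, `p`, `n`. With zero variance in either
#'   context, `r` and `p` are NA (undefined, reported as missing).
#' @export
pearsonAcrossContexts <- function(table, trait, contextA, contextB) {
  checkBehaviorTable(table)
  a <- traitValues(table, trait, contextA)
  b <- traitValues(table, trait, contextB)
  flies <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(flies) < 3)
    stop(sprintf("only %d complete pairs; need at least 3", length(flies)))
  a <- a[flies]; b <- b[flies]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(flies)))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(flies))
}

#' Normality check plus paired t-test for two matched samples
#'
#' Shapiro-Wilk on the paired differences, then a two-sided paired
#' t-test. The normality result is reported alongside the test, never
#' used to switch tests silently.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return list with `shapiro_w`, `shapiro_p`, `t`, `t_p`, `mean_diff`
#'   (mean of b - a), `n`, and `note` when the t statistic is undefined
#'   (all differences identical).
#' @export
groupComparison <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- b - a
  if (stats::sd(d) == 0)
    return(list(shapiro_w = NA_real_, shapiro_p = NA_real_, t = NA_real_,
                t_p = NA_real_, mean_diff = mean(d), n = length(d),
                note = "all paired differences identical; t undefined"))
  sw <- stats::shapiro.test(d)
  tt <- stats::t.test(b, a, paired = TRUE)
  list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       t = unname(tt$statistic), t_p = tt$p.value,
       mean_diff = unname(tt$estimate), n = length(d), note = NULL)
}

#' Convert values to within-group percentile ranks (0-100)
#'
#' Average ranks for ties, rescaled as (rank - 1) / (n - 1) x 100, so
#' the smallest value maps to 0 and the largest to 100. Invariant under
#' any strictly monotone transform of the values.
#'
#' @param values numeric; NAs stay NA.
#' @return numeric in [0, 100], same length and names as `values`.
#' @export
toPercentileRanks <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  out[ok] <- (rank(values[ok], ties.method = "average") - 1) / (n - 1) * 100
  names(out) <- names(values)
  out
}

#' Per-fly absolute rank difference between two contexts
#'
#' Both contexts are percentile-ranked over the flies present in both
#' (flies missing in one context are omitted with a message), and the
#' absolute rank difference is returned per fly. Symmetric in the two
#' contexts.
#'
#' @inheritParams pearsonAcrossContexts
#' @return named numeric, |delta rank| in [0, 100] per fly.
#' @export
rankChange <- function(table, trait, contextA, contextB) {
  checkBehaviorTable(table)
  a <- traitValues(table, trait, contextA)
  b <- traitValues(table, trait, contextB)
  flies <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  dropped <- setdiff(union(names(a), names(b)), flies)
  if (length(dropped))
    message(sprintf("rankChange: omitting %d fly(ies) missing in one context",
                    length(dropped)))
  if (length(flies) < 2) stop("need at least 2 flies present in both contexts")
  abs(toPercentileRanks(a[flies]) - toPercentileRanks(b[flies]))
}

#' Build the rank-change design matrix for the ridge GLM
#'
#' One row per fly per context pair. Predictors are binary
#' changed/unchanged codes: `time` (day differs), `temperature`,
#' `vision` (stripe count or illumination differs), `arena` and
#' `behavioral_state` (walking vs flight). The response is the per-fly
#' absolute percentile-rank difference between the two contexts.
#'
#' @param table long-format behavior table.
#' @param trait trait name.
#' @param pairs list of length-2 character vectors of context ids; a
#'   pair must either differ in at least one factor or be a labeled
#'   same-context retest (two distinct context ids with identical
#'   factors).
#' @return list with `X` (n x 5 binary matrix) and `y` (response).
#' @export
buildChangeDesign <- function(table, trait, pairs) {
  checkBehaviorTable(table)
  ctx <- unique(table[, c("context", .factorCols)])
  rownames(ctx) <- ctx$context
  rows <- lapply(pairs, function(pr) {
    if (pr[1] == pr[2])
      stop(sprintf("pair (%s, %s): a context cannot be paired with itself",
                   pr[1], pr[2]))
    A <- ctx[pr[1], ]; B <- ctx[pr[2], ]
    if (any(is.na(A$context)) || any(is.na(B$context)))
      stop("unknown context id in pair")
    x <- c(time = as.numeric(A$day != B$day),
           temperature = as.numeric(A$temperature != B$temperature),
           vision = as.numeric(A$stripes != B$stripes | A$light != B$light),
           arena = as.numeric(A$arena != B$arena),
           behavioral_state = as.numeric(A$modality != B$modality))
    y <- rankChange(table, trait, pr[1], pr[2])
    list(X = matrix(rep(x, length(y)), ncol = 5, byrow = TRUE,
                    dimnames = list(names(y), names(x))), y = y)
  })
  list(X = do.call(rbind, lapply(rows, `[[`, "X")),
       y = unlist(lapply(rows, `[[`, "y")))
}

# closed-form ridge on a centred/standardized design: unpenalized
# intercept = mean(y); coefficients on the z-scored scale
ridgeSolve <- function(Z, yc, lambda) {
  p <- ncol(Z)
  solve(crossprod(Z) + diag(lambda, p), crossprod(Z, yc))
}

#' Ridge regression with seeded k-fold cross-validation
#'
#' Predictors are z-scored on the full data (statistics reused inside
#' the CV folds); for each lambda on the grid the k-fold CV mean squared
#' error is computed with a seeded fold assignment; the final model is
#' refit on all data at the MSE-minimizing lambda. The intercept is
#' unpenalized. Constant predictor columns (z-score undefined) are
#' dropped with a warning.
#'
#' @param X numeric design matrix (rows >= folds).
#' @param y response vector.
#' @param lambdaGrid penalty grid; default 25 log-spaced points over
#'   1e-6 to 1e6.
#' @param folds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @return list of class `RidgeFit`: `lambda` (the selected value),
#'   `coefficients` (z-scored scale), `intercept`, `cvMse` (per grid
#'   point), `lambdaGrid`, `center`/`scale` (z-scoring statistics) and
#'   `dropped` (names of removed constant columns).
#' @export
fitRidgeCV <- function(X, y, lambdaGrid = 10^seq(-6, 6, length.out = 25),
                       folds = 5, seed = 1) {
  X <- as.matrix(X)
  if (!length(lambdaGrid)) stop("lambda grid is empty")
  if (nrow(X) < folds) stop("need at least as many rows as folds")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant predictor column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!ncol(X)) stop("no non-constant predictors left")
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  n <- nrow(Z)
  foldId <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  cvMse <- vapply(lambdaGrid, function(lam) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- foldId != f
      mu <- mean(y[tr])
      b <- ridgeSolve(Z[tr, , drop = FALSE], y[tr] - mu, lam)
      pred <- mu + Z[!tr, , drop = FALSE] %*% b
      mean((y[!tr] - pred)^2)
    }, 0)
    mean(errs)
  }, 0)
  lambda <- lambdaGrid[which.min(cvMse)]
  mu <- mean(y)
  beta <- drop(ridgeSolve(Z, y - mu, lambda))
  structure(list(lambda = lambda, coefficients = beta, intercept = mu,
                 cvMse = cvMse, lambdaGrid = lambdaGrid, center = ctr,
                 scale = sds, dropped = dropped, foldSeed = seed),
            class = "RidgeFit")
}

#' Bootstrap inference for ridge coefficients
#'
#' Rows of (X, y) are resampled with replacement jointly and the ridge
#' model is refit at the fixed selected lambda; the bootstrap standard
#' deviation of each coefficient is its SE, and the two-sided p-value is
#' the normal tail of (full-data coefficient) / SE (large-B reference
#' for the bootstrap t statistic). Degenerate resamples (a constant
#' column) are redrawn, up to 10 x B attempts.
#'
#' @param X,y as in [fitRidgeCV()].
#' @param fit a `RidgeFit` from [fitRidgeCV()]; refit from (X, y) if
#'   NULL.
#' @param B bootstrap iterations (>= 2).
#' @param seed integer seed; identical seeds give identical results.
#' @return list with per-coefficient `mean`, `se`, `p`, the full-data
#'   `coefficients`, `interceptSe`, `B` and `redraws`.
#' @export
bootstrapRidge <- function(X, y, fit = NULL, B = 1000, seed = 1) {
  stopifnot(B >= 2)
  X <- as.matrix(X)
  if (is.null(fit)) fit <- fitRidgeCV(X, y, seed = seed)
  keep <- setdiff(colnames(X) %||% paste0("x", seq_len(ncol(X))),
                  fit$dropped)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- X[, keep, drop = FALSE]
  Z <- scale(X, center = fit$center, scale = fit$scale)
  n <- nrow(Z)
  p <- ncol(Z)
  withSeed(seed, {
    bco <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(Z)))
    bint <- numeric(B)
    redraws <- 0L
    maxDraws <- 10L * B
    b <- 1L
    while (b <= B) {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(apply(Z[idx, , drop = FALSE], 2, stats::sd) == 0)) {
        redraws <- redraws + 1L
        if (redraws > maxDraws)
          stop("too many degenerate bootstrap resamples")
        next
      }
      mu <- mean(y[idx])
      bco[b, ] <- ridgeSolve(Z[idx, , drop = FALSE], y[idx] - mu,
                             fit$lambda)
      bint[b] <- mu
      b <- b + 1L
    }
    se <- apply(bco, 2, stats::sd)
    pv <- 2 * stats::pnorm(-abs(fit$coefficients / se))
    list(mean = colMeans(bco), se = se, p = pv,
         coefficients = fit$coefficients, interceptSe = stats::sd(bint),
         B = B, redraws = redraws)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hierarchical linear mixed model with ICC repeatability
#'
#' Fits value ~ context fixed effects + (1 | fly) by REML (lme4),
#' including each numeric context factor (day, temperature, stripes,
#' light, arena) that varies in the data. Variance is partitioned into
#' between-fly (random intercept) and within-fly (residual) components;
#' the intraclass correlation coefficient ICC = between / (between +
#' within) quantifies repeatability across contexts. Fixed effects are
#' reported with Wald 95% confidence intervals. Singular fits
#' (between-fly variance estimated at 0) are reported with a
#' singularity flag, not an error.
#'
#' @param table long-format behavior table.
#' @param trait trait name.
#' @return list of class `LMMFit`: `fixed` (data.frame term, estimate,
#'   se, ci_lo, ci_hi), `sigma2Between`, `sigma2Within`, `icc`,
#'   `singular`, `nFlies`, `nObs` and the fitted `model`.
#' @export
fitTraitLMM <- function(table, trait) {
  checkBehaviorTable(table)
  d <- table[table$trait == trait & !is.na(table$value), ]
  obsPerFly <- table(d$fly)
  if (sum(obsPerFly >= 2) < 2)
    stop("need at least 2 flies with at least 2 observations each")
  varying <- .factorCols[vapply(.factorCols, function(f)
    length(unique(d[[f]])) > 1, TRUE)]
  varying <- setdiff(varying, "modality")  # modality enters as 0/1 state
  if ("modality" %in% names(d) && length(unique(d$modality)) > 1) {
    d$state <- as.numeric(d$modality == "flight")
    varying <- c(varying, "state")
  }
  if (length(varying) > 1) {
    # with few contexts the factor codes can be collinear; keep an
    # independent subset so lme4 need not drop columns itself
    M <- cbind(1, as.matrix(d[, varying]))
    piv <- qr(M)$pivot[seq_len(qr(M)$rank)]
    varying <- varying[sort(piv[piv > 1]) - 1L]
  }
  rhs <- if (length(varying)) paste(varying, collapse = " + ") else "1"
  fm <- stats::as.formula(paste("value ~", rhs, "+ (1 | fly)"))
  fit <- lme4::lmer(fm, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vc$vcov[vc$grp == "fly"]
  s2w <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  fixed <- data.frame(term = names(fe), estimate = unname(fe),
                      se = unname(se), ci_lo = unname(fe - z * se),
                      ci_hi = unname(fe + z * se),
                      stringsAsFactors = FALSE)
  structure(list(fixed = fixed, sigma2Between = s2b, sigma2Within = s2w,
                 icc = s2b / (s2b + s2w),
                 singular = lme4::isSingular(fit), nFlies = length(obsPerFly),
                 nObs = nrow(d), model = fit),
            class = "LMMFit")
}

#' Bootstrap confidence interval for the ICC
#'
#' Flies are resampled with replacement keeping each resampled fly's
#' full set of context observations (duplicates relabeled as distinct
#' flies), the mixed model is refit, and the 2.5/97.5 percentiles of the
#' bootstrap ICC distribution form the 95% CI.
#'
#' @inheritParams fitTraitLMM
#' @param B bootstrap iterations.
#' @param seed integer seed; identical seeds give identical CIs.
#' @return list with `icc`, `ci` (length 2), `B`, `failed` (refits that
#'   errored) and `unreliable` (TRUE when more than 10% of refits
#'   failed).
#' @export
bootstrapICC <- function(table, trait, B = 1000, seed = 1) {
  checkBehaviorTable(table)
  full <- fitTraitLMM(table, trait)
  d <- table[table$trait == trait & !is.na(table$value), ]
  flies <- unique(d$fly)
  byFly <- split(d, d$fly)
  withSeed(seed, {
    iccs <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      pick <- sample(flies, length(flies), replace = TRUE)
      boot <- do.call(rbind, lapply(seq_along(pick), function(j) {
        dd <- byFly[[pick[j]]]
        dd$fly <- sprintf("boot%04d", j)  # relabel duplicates
        dd
      }))
      iccs[b] <- tryCatch(fitTraitLMM(boot, trait)$icc,
                          error = function(e) NA_real_)
    }
    failed <- sum(is.na(iccs))
    ci <- stats::quantile(iccs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    list(icc = full$icc, ci = ci, B = B, failed = failed,
         unreliable = failed > 0.1 * B)
  })
}
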