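# Logit transform, main-effects fit, Type III SS, residual diagnostics.

test_that("logit transform and its inverse behave as defined", {
  expect_equal(logitTransform(0.5), 0)
  expect_equal(logitTransform(0.65), log(13 / 7), tolerance = 1e-12)
  expect_equal(logitTransform(0.65), 0.61904, tolerance = 1e-5)
  # antisymmetry
  for (p in c(0.01, 0.3, 0.77)) {
    expect_equal(logitTransform(p) + logitTransform(1 - p), 0, tolerance = 1e-12)
    expect_equal(invLogitTransform(logitTransform(p)), p, tolerance = 1e-12)
  }
  # strictly increasing
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(logitTransform(ps)) > 0))
  expect_error(logitTransform(0), "strictly inside")
  expect_error(logitTransform(1), "strictly inside")
})

test_that("a balanced one-factor fit reproduces level means", {
  tab <- data.frame(g = rep(c("a", "b"), each = 4),
                    y = c(1, 2, 3, 2, 5, 6, 7, 6))
  fit <- fitMainEffects(tab, "y", "g")
  expect_equal(unname(fitted(fit@lmfit)), rep(c(2, 6), each = 4),
               tolerance = 1e-12)
  expect_equal(residualDf(fit), 6L)
  # constant response: all SS vanish
  tab$y <- 1
  fit0 <- fitMainEffects(tab, "y", "g")
  at <- type3Anova(fit0)
  expect_equal(at$SumSq[1], 0, tolerance = 1e-12)
  expect_equal(residualSS(fit0), 0, tolerance = 1e-12)
})

test_that("numeric factor levels are treated as categorical", {
  g <- factorLevels(replicates = 1)
  tab <- generateResultsTable(g, effectSpec("F1", 0.6, noiseSd = 0.01), seed = 2)
  fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
  expect_true(all(vapply(fit@data[fit@factors], is.factor, logical(1))))
  # Nt contributes 3 df (4 discrete levels), not 1 (a slope)
  at <- type3Anova(fit)
  expect_equal(at$Df[at$Source == "Nt"], 3)
})

test_that("noise-free injected effects are recovered exactly", {
  off <- list(Ly = c(`1` = 0.03, `2` = 0.02, `3` = -0.05),
              Dp = c(`0.2` = 0.01, `0.5` = 0.01, `0.8` = -0.02))
  g <- factorLevels(replicates = 2)
  tab <- generateResultsTable(g, effectSpec("F1", 0.6, factorEffects = off),
                              seed = 1)
  fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
  for (f in names(off)) {
    m <- lsMeans(fit, f)
    expect_equal(m$mean - 0.6, unname(off[[f]][m$level]), tolerance = 1e-9)
  }
  expect_lt(residualSS(fit), 1e-18)
})

test_that("Type III SS agree with the independent implementation in car", {
  # 100 random small unbalanced tables
  set.seed(31)
  for (i in 1:100) {
    k <- sample(2:3, 1)
    levs <- lapply(seq_len(k), function(j) seq_len(sample(2:4, 1)))
    n <- sample(30:60, 1)
    tab <- data.frame(lapply(levs, function(l) factor(sample(l, n, TRUE))))
    names(tab) <- paste0("f", seq_len(k))
    # guard against empty levels in the random draw
    tab[] <- lapply(tab, droplevels)
    if (any(vapply(tab, nlevels, integer(1)) < 2)) next
    tab$y <- rnorm(n)
    fit <- fitMainEffects(tab, "y", names(tab)[seq_len(k)])
    mine <- type3Anova(fit)
    ref <- car::Anova(fit@lmfit, type = 3)
    for (f in fit@factors) {
      expect_equal(mine$SumSq[mine$Source == f],
                   ref[f, "Sum Sq"], tolerance = 1e-8)
      expect_equal(mine$Df[mine$Source == f], ref[f, "Df"])
    }
    expect_equal(mine$SumSq[mine$Source == "Residual"],
                 ref["Residuals", "Sum Sq"], tolerance = 1e-8)
  }
})

test_that("balanced designs make Type III, Type I and between-group SS equal", {
  set.seed(5)
  tab <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v")),
                     rep = 1:5)
  tab$y <- rnorm(nrow(tab)) + ifelse(tab$a == "x", 0.5, -0.5)
  fit <- fitMainEffects(tab, "y", c("a", "b"))
  t3 <- type3Anova(fit)
  t1 <- anova(fit@lmfit)  # sequential (Type I)
  for (f in c("a", "b")) {
    expect_equal(t3$SumSq[t3$Source == f], t1[f, "Sum Sq"], tolerance = 1e-10)
    # hand-computed between-group SS
    grand <- mean(tab$y)
    bg <- sum(tapply(tab$y, tab[[f]], function(v) length(v) * (mean(v) - grand)^2))
    expect_equal(t3$SumSq[t3$Source == f], bg, tolerance = 1e-10)
  }
})

test_that("unbalanced factor SS need not add up to the total SS", {
  set.seed(6)
  g <- factorLevels(replicates = 3)
  tab <- generateResultsTable(g, effectSpec("F1", 0.6, noiseSd = 0.05), seed = 6)
  tab <- tab[-sample(nrow(tab), 40), ]  # unbalance by deletion
  fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
  at <- type3Anova(fit)
  comp <- sum(at$SumSq[seq_len(5)]) + at$SumSq[at$Source == "Residual"]
  expect_false(isTRUE(all.equal(comp, at$SumSq[at$Source == "Total (corrected)"],
                                tolerance = 1e-10)))
})

test_that("F p-values decrease monotonically in F at fixed df", {
  fs <- c(0.5, 1, 2, 5, 10, 50)
  ps <- pf(fs, 3, 100, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  at <- anovaTableFromComponents(c("a", "b"), ss = c(1, 10), df = c(2, 2),
                                 ssRes = 50, dfRes = 100)
  expect_gt(at$p[1], at$p[2])
})

test_that("residual diagnostics bundle the standard assumption checks", {
  g <- factorLevels(replicates = 3)
  tab <- generateResultsTable(g, effectSpec("F1", 0.6, noiseSd = 0.01), seed = 3)
  fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
  d <- residualDiagnostics(fit)
  expect_lt(abs(sum(d$residuals)), 1e-9)
  expect_length(d$predicted, nrow(tab))
  expect_equal(nrow(d$qq), nrow(tab))
  expect_true(!is.unsorted(d$qq$sample))
  expect_s3_class(d$shapiro, "htest")
  expect_gt(d$shapiro$p.value, 0.001)  # Gaussian noise: no rejection expected
  expect_true(is.data.frame(d$levene))
})

test_that("Shapiro-Wilk p-values are uniform under the null", {
  # Monte-Carlo calibration: n = 500 Gaussian residuals, 200 repetitions
  set.seed(11)
  ps <- vapply(1:200, function(i) shapiro.test(rnorm(500))$p.value, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the Levene check detects heteroscedasticity", {
  # sd doubling across one factor's levels, n = 300, 100 repetitions
  set.seed(12)
  hits <- vapply(1:100, function(i) {
    tab <- data.frame(g = factor(rep(c("a", "b", "c"), each = 100)))
    tab$y <- rnorm(300, sd = rep(c(1, 2, 4), each = 100))
    fit <- fitMainEffects(tab, "y", "g")
    d <- suppressWarnings(residualDiagnostics(fit))
    d$levene[1, "Pr(>F)"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 90)
})
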