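# LS means, Fisher LSD contrasts, homogeneous-group letters.

test_that("balanced one-factor LS means equal arithmetic cell means", {
  set.seed(21)
  tab <- data.frame(g = factor(rep(c("a", "b", "c"), each = 6)),
                    y = rnorm(18))
  fit <- fitMainEffects(tab, "y", "g")
  m <- lsMeans(fit, "g")
  expect_equal(m$mean, as.numeric(tapply(tab$y, tab$g, mean)), tolerance = 1e-12)
  # interval half-width identity
  tq <- qt(0.975, residualDf(fit))
  expect_equal((m$upper - m$lower) / 2, tq * m$se, tolerance = 1e-9)
  # balanced SE of a difference: sqrt(2 MS_res / n_per_level)
  ctr <- lsdContrasts(fit, "g")
  msRes <- residualSS(fit) / residualDf(fit)
  expect_equal(ctr$se, rep(sqrt(2 * msRes / 6), 3), tolerance = 1e-12)
  expect_error(lsMeans(fit, "nope"), "unknown factor")
})

test_that("noise-free LS means reproduce baseline plus injected offsets", {
  off <- c(`0` = -0.02, `5` = 0.01, `10` = 0.03, `20` = -0.02)
  g <- factorLevels(replicates = 2)
  tab <- generateResultsTable(
    g, effectSpec("F1", 0.63, factorEffects = list(Nb = off)), seed = 1)
  fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
  m <- lsMeans(fit, "Nb")
  expect_equal(m$mean, 0.63 + unname(off[m$level]), tolerance = 1e-9)
})

test_that("LS means agree with the reference grid implementation", {
  skip_if_not_installed("emmeans")
  set.seed(22)
  g <- factorLevels(replicates = 2)
  tab <- generateResultsTable(g, effectSpec("F1", 0.6, noiseSd = 0.05), seed = 22)
  tab <- tab[-sample(nrow(tab), 50), ]  # unbalanced on purpose
  fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
  m <- lsMeans(fit, "Nt")
  em <- as.data.frame(emmeans::emmeans(fit@lmfit, "Nt"))
  expect_equal(m$mean, em$emmean, tolerance = 1e-10)
  expect_equal(m$se, em$SE, tolerance = 1e-10)
  expect_equal(m$lower, em$lower.CL, tolerance = 1e-10)
})

test_that("LSD contrasts flag pairs beyond the least significant difference", {
  set.seed(42)
  tab <- data.frame(g = factor(rep(c("a", "b", "c"), each = 10)),
                    y = rnorm(30) + rep(c(0, 0, 2), each = 10))
  fit <- fitMainEffects(tab, "y", "g")
  ctr <- lsdContrasts(fit, "g", alpha = 0.05)
  expect_equal(nrow(ctr), 3L)
  expect_identical(ctr$significant, abs(ctr$difference) > ctr$lsd)
  # the separated level differs from both others; a-b does not
  sigPairs <- ctr[ctr$significant, ]
  expect_setequal(paste(sigPairs$level1, sigPairs$level2),
                  c("a c", "b c"))
  # symmetry in the pair: difference flips sign, significance unchanged
  expect_equal(ctr$difference[1],
               sum(lsMeans(fit, "g")$mean * c(1, -1, 0)), tolerance = 1e-12)
  expect_error(lsdContrasts(fit, "g", alpha = 1.5), "alpha")
})

test_that("identical LS means are never significantly different", {
  tab <- data.frame(g = factor(rep(c("a", "b"), each = 5)),
                    y = rep(c(1, 2, 3, 4, 5), 2))
  fit <- fitMainEffects(tab, "y", "g")
  ctr <- lsdContrasts(fit, "g", alpha = 0.2)
  expect_equal(ctr$difference, 0, tolerance = 1e-12)
  expect_false(ctr$significant)
})

test_that("homogeneous-group letters follow the significance matrix", {
  mkMeans <- function(levels, means) data.frame(factor = "f", level = levels,
                                                mean = means, se = 0.1,
                                                lower = means - 1, upper = means + 1)
  mkCtr <- function(pairs) do.call(rbind, lapply(pairs, function(p) {
    data.frame(level1 = p[[1]], level2 = p[[2]], difference = 0, se = 1,
               lsd = 1, significant = p[[3]])
  }))
  # all pairs significant: one letter each
  m <- mkMeans(c("x", "y", "z"), c(1, 2, 3))
  ctr <- mkCtr(list(list("x", "y", TRUE), list("x", "z", TRUE),
                    list("y", "z", TRUE)))
  g <- homogeneousGroups(m, ctr)
  expect_identical(g$groups, c("a", "b", "c"))

  # no pair significant: a single shared letter
  ctr0 <- mkCtr(list(list("x", "y", FALSE), list("x", "z", FALSE),
                     list("y", "z", FALSE)))
  expect_identical(unique(homogeneousGroups(m, ctr0)$groups), "a")

  # only the extremes differ: a / ab / b overlap
  ctr1 <- mkCtr(list(list("x", "y", FALSE), list("x", "z", TRUE),
                     list("y", "z", FALSE)))
  g1 <- homogeneousGroups(m, ctr1)
  expect_identical(g1$groups, c("a", "ab", "b"))

  # lettering respects the biconditional: shared letter <=> non-significant
  shared <- function(g, a, b) {
    la <- strsplit(g$groups[g$level == a], "")[[1]]
    lb <- strsplit(g$groups[g$level == b], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  expect_true(shared(g1, "x", "y"))
  expect_false(shared(g1, "x", "z"))

  # missing pair is an error
  expect_error(homogeneousGroups(m, ctr1[-1, ]), "cover all")
})

test_that("the four-level pattern with one non-adjacent separation letters correctly", {
  # ascending means 0, 20, 5, 10 with 10 vs 0 and 10 vs 20 significant
  m <- data.frame(factor = "Nb", level = c("0", "20", "5", "10"),
                  mean = c(0.6197, 0.6211, 0.6296, 0.6390), se = 0.004,
                  lower = 0, upper = 1)
  ctr <- data.frame(level1 = c("0", "0", "0", "20", "20", "5"),
                    level2 = c("20", "5", "10", "5", "10", "10"),
                    difference = 0, se = 1, lsd = 1,
                    significant = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  g <- homogeneousGroups(m, ctr)
  expect_identical(g$level, c("0", "20", "5", "10"))
  expect_identical(g$groups, c("a", "a", "ab", "b"))
})

test_that("rangeTest joins means, letters and contrasts", {
  set.seed(24)
  g <- factorLevels(replicates = 2)
  tab <- generateResultsTable(
    g, effectSpec("F1", 0.6,
                  factorEffects = list(Ly = c(`1` = 0.03, `2` = 0.02, `3` = -0.05)),
                  noiseSd = 0.01), seed = 24)
  fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
  rt <- rangeTest(fit, "Ly")
  expect_true(all(c("means", "contrasts") %in% names(rt)))
  expect_true("groups" %in% names(rt$means))
  # the depressed level 3 separates from 1 and 2
  ctr <- rt$contrasts
  expect_true(all(ctr$significant[ctr$level1 == "1" & ctr$level2 == "3" |
                                    ctr$level1 == "2" & ctr$level2 == "3"]))
})
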