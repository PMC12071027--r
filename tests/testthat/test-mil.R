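# The MinMax multiple-instance classifier.

test_that("patch scoring is a shared-weight per-patch map", {
  model <- randomModel()
  set.seed(1)
  bag <- matrix(rnorm(20 * 8), 20, 8)
  S <- scorePatches(model, bag)
  expect_equal(dim(S), c(20L, 3L))

  # permutation equivariance: kernel width 1 => same weights per patch
  perm <- sample(20)
  expect_equal(scorePatches(model, bag[perm, ]), S[perm, ], tolerance = 1e-12)

  # identical patches get identical score rows
  bag2 <- rbind(bag, bag[3, ])
  S2 <- scorePatches(model, bag2)
  expect_equal(S2[21, ], S2[3, ], tolerance = 1e-15)

  # all-zero weights and biases => all scores zero
  z <- model
  z@convW <- lapply(z@convW, function(W) W * 0)
  z@convB <- lapply(z@convB, function(b) b * 0)
  expect_true(all(scorePatches(z, bag) == 0))

  expect_error(scorePatches(model, matrix(0, 5, 4)), "dimension")
})

test_that("minmax selection matches the full-sort oracle", {
  expect_equal(as.numeric(minmaxSelect(c(0.9, 0.1, 0.5, 0.7), Nt = 2, Nb = 1)),
               c(0.9, 0.7, 0.1))
  # Nb = 0: only the maxima, no negative evidence
  expect_equal(as.numeric(minmaxSelect(c(3, 1, 2), Nt = 2, Nb = 0)), c(3, 2))
  # all-tied scores
  expect_equal(as.numeric(minmaxSelect(rep(0.4, 4), Nt = 2, Nb = 2)),
               rep(0.4, 4))
  # ties resolve to the lower patch index
  sel <- minmaxSelect(c(1, 2, 2, 0), Nt = 1, Nb = 1)
  expect_identical(attr(sel, "indices"), c(2L, 4L))
  expect_error(minmaxSelect(c(1, 2), Nt = 2, Nb = 1), "too small")

  # 1,000 random vectors against the brute-force sort oracle
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    s <- rnorm(n)
    Nt <- sample.int(min(n, 10), 1)
    Nb <- sample.int(n - Nt + 1L, 1) - 1L
    got <- as.numeric(minmaxSelect(s, Nt, Nb))
    want <- c(sort(s, decreasing = TRUE)[seq_len(Nt)],
              sort(s)[seq_len(Nb)])
    expect_identical(got, want)
  }
})

test_that("bag prediction is a probability and depends only on selections", {
  model <- randomModel()
  set.seed(2)
  bag <- matrix(rnorm(30 * 8), 30, 8)
  p <- predictBag(model, bag)
  expect_length(p, 3)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)

  # the prediction depends on the bag only through the selected patches:
  # restricting the bag to exactly those patches reproduces it (their top
  # and bottom scores are unchanged by removing the unselected middle)
  S <- scorePatches(model, bag)
  sel <- sort(unique(unlist(lapply(1:3, function(k) {
    attr(minmaxSelect(S[, k], 3, 2), "indices")
  }))))
  expect_equal(predictBag(model, bag[sel, , drop = FALSE]), p, tolerance = 1e-12)

  # permutation invariance
  expect_equal(predictBag(model, bag[sample(30), ]), p, tolerance = 1e-12)

  # symmetric all-zero parameters give the uniform prediction
  z <- model
  z@convW <- lapply(z@convW, function(W) W * 0)
  z@convB <- lapply(z@convB, function(b) b * 0)
  z@mlpW <- lapply(z@mlpW, function(W) W * 0)
  z@mlpB <- lapply(z@mlpB, function(b) b * 0)
  expect_equal(unname(predictBag(z, bag)), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("attention maps are consistent with selection and per-bag", {
  model <- randomModel()
  set.seed(3)
  bag <- matrix(rnorm(25 * 8), 25, 8)
  for (k in 1:3) {
    a <- attentionMap(model, bag, k)
    expect_length(a, 25)
    sel <- minmaxSelect(a, Nt = 1, Nb = 0)
    expect_equal(which.max(a), attr(sel, "indices")[1], ignore_attr = TRUE)
  }
  # no cross-bag coupling: same bag, same scores, other bags irrelevant
  expect_identical(attentionMap(model, bag, 1), attentionMap(model, bag, 1))
  expect_error(attentionMap(model, bag, 4), "classIdx")

  d <- generateBagDataset(1, nPatches = 6, featureDim = 8, seed = 4)
  camTab <- exportAttentionMaps(model, d)
  expect_equal(nrow(camTab), 3 * 6 * 3)  # bags x patches x classes
  expect_named(camTab, c("bag_id", "patch_index", "class", "score"))
})

test_that("unselected patches receive an exactly-zero loss gradient", {
  model <- randomModel(featureDim = 8, Nt = 3, Nb = 2)
  set.seed(6)
  bag <- matrix(rnorm(20 * 8), 20, 8)
  g <- milanova:::.bagGradients(model, bag, 2L)
  S <- scorePatches(model, bag)
  sel <- milanova:::.selectBag(S, 3L, 2L)

  for (k in 1:3) {
    unselected <- setdiff(seq_len(20), sel$idx[sel$class == k])
    # analytic gradient is exactly zero there
    expect_true(all(g$dScores[unselected, k] == 0))
    # finite differences on the head loss agree: perturbing an unselected
    # score does not change the loss at all
    base <- milanova:::.lossFromScores(model, S, 2L)
    for (i in unselected[1:3]) {
      S2 <- S
      S2[i, k] <- S2[i, k] + 1e-5
      expect_identical(milanova:::.lossFromScores(model, S2, 2L), base)
    }
  }
  # while a selected score does move the loss, matching the analytic value
  i1 <- sel$idx[1]
  S3 <- S
  S3[i1, 1] <- S3[i1, 1] + 1e-6
  fd <- (milanova:::.lossFromScores(model, S3, 2L) -
           milanova:::.lossFromScores(model, S, 2L)) / 1e-6
  expect_equal(fd, g$dScores[i1, 1], tolerance = 1e-4)
})

test_that("analytic parameter gradients match finite differences", {
  model <- randomModel(featureDim = 6, Nt = 2, Nb = 1, convWidths = c(5L, 3L))
  set.seed(7)
  bag <- matrix(rnorm(12 * 6), 12, 6)
  g <- milanova:::.bagGradients(model, bag, 3L)
  eps <- 1e-6
  lossAt <- function(m) milanova:::.bagGradients(m, bag, 3L)$loss
  for (l in seq_along(model@convW)) {
    m2 <- model
    m2@convW[[l]][1, 2] <- m2@convW[[l]][1, 2] + eps
    expect_equal((lossAt(m2) - g$loss) / eps, g$dConvW[[l]][1, 2],
                 tolerance = 1e-4)
  }
  for (l in seq_along(model@mlpW)) {
    m2 <- model
    m2@mlpW[[l]][2, 1] <- m2@mlpW[[l]][2, 1] + eps
    expect_equal((lossAt(m2) - g$loss) / eps, g$dMlpW[[l]][2, 1],
                 tolerance = 1e-4)
  }
})

test_that("training is seeded-reproducible and learns separable data", {
  tr <- separableTrainSet()
  ev <- separableEvalSet()
  cfg <- fastConfig()
  m1 <- trainMIL(tr, cfg)
  m2 <- trainMIL(tr, cfg)
  expect_identical(m1@convW, m2@convW)
  expect_identical(m1@mlpW, m2@mlpW)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_length(trainingHistory(m1), cfg@epochs)

  res <- evaluateModel(m1, ev)
  expect_gt(res$F1, 0.9)
  expect_gt(res$AUC, 0.9)
})

test_that("weight decay shrinks the trained parameter norm", {
  tr <- separableTrainSet(nPerClass = 8)
  cfg0 <- fastConfig(weightDecay = 0, epochs = 10L)
  cfg1 <- fastConfig(weightDecay = 0.1, epochs = 10L)
  n0 <- weightNorm(trainMIL(tr, cfg0))
  n1 <- weightNorm(trainMIL(tr, cfg1))
  expect_lt(n1, n0)
})

test_that("training validates its inputs", {
  d <- generateBagDataset(2, nPatches = 4, featureDim = 8, seed = 1)
  cfg <- milConfig(Nt = 3, Nb = 2, convWidths = c(6L, 3L))
  expect_error(trainMIL(d, cfg), "too small")
  oneClass <- d[bagLabels(d) == "benign"]
  expect_error(trainMIL(oneClass, milConfig(Nt = 2, Nb = 1,
                                            convWidths = c(6L, 3L))),
               "2 classes")
  expect_error(milConfig(dropout = 1), "dropout")
  expect_error(milConfig(Nt = 0), "Nt")
})

test_that("model checkpoints round-trip", {
  model <- randomModel()
  path <- withr::local_tempfile(fileext = ".rds")
  saveMILModel(model, path)
  m2 <- readMILModel(path)
  expect_identical(m2@convW, model@convW)
  expect_identical(m2@config@seed, model@config@seed)
})
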