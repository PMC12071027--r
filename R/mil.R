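# The MinMax multiple-instance classifier.
#
# Architecture, per bag of patch embeddings X (n_patches x d):
#   1. a stack of shared-weight one-dimensional convolutions (kernel width 1
#      along the patch axis, so each patch is mapped independently by the
#      same weights) producing one attention score per class per patch;
#   2. a MinMax layer keeping, per class, the Nt highest and Nb lowest
#      scores — top instances plus negative evidence;
#   3. an MLP head on the concatenated selections, softmax over classes.
# During training, gradients flow only through the selected patches: the
# selection is a subsetting operation, so unselected scores receive an
# exactly-zero gradient.

# ---- initialization ---------------------------------------------------------

.heInit <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

.initMILModel <- function(config, featureDim) {
  widths <- c(featureDim, config@convWidths)
  convW <- convB <- vector("list", length(config@convWidths))
  for (l in seq_along(config@convWidths)) {
    convW[[l]] <- .heInit(widths[l], widths[l + 1L])
    convB[[l]] <- numeric(widths[l + 1L])
  }
  zin <- config@nClasses * (config@Nt + config@Nb)
  mwidths <- c(zin, config@mlpWidths, config@nClasses)
  mlpW <- mlpB <- vector("list", length(mwidths) - 1L)
  for (l in seq_len(length(mwidths) - 1L)) {
    mlpW[[l]] <- .heInit(mwidths[l], mwidths[l + 1L])
    mlpB[[l]] <- numeric(mwidths[l + 1L])
  }
  new("MILModel", convW = convW, convB = convB, mlpW = mlpW, mlpB = mlpB,
      config = config, history = numeric())
}

# ---- forward pieces ---------------------------------------------------------

.addBias <- function(A, b) sweep(A, 2L, b, `+`)

# Conv-stack forward; returns per-layer pre-activations for backprop.
.convForward <- function(convW, convB, X) {
  L <- length(convW)
  acts <- vector("list", L)
  H <- X
  inputs <- vector("list", L)
  for (l in seq_len(L)) {
    inputs[[l]] <- H
    A <- .addBias(H %*% convW[[l]], convB[[l]])
    acts[[l]] <- A
    H <- if (l < L) pmax(A, 0) else A   # no nonlinearity after the score layer
  }
  list(scores = H, acts = acts, inputs = inputs)
}

.softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

#' Per-patch per-class attention scores
#'
#' Applies the shared-weight one-dimensional convolution stack to every
#' patch of a bag independently (kernel width 1 along the patch axis), so
#' the map is permutation-equivariant: permuting the patch rows permutes
#' the score rows identically.
#'
#' @param model a trained (or initialized) [MILModel-class].
#' @param bag numeric matrix `n_patches x feature_dim`.
#' @return Numeric matrix `n_patches x nClasses` of attention scores.
#' @seealso [minmaxSelect()], [attentionMap()]
#' @export
scorePatches <- function(model, bag) {
  stopifnot(is(model, "MILModel"))
  if (!is.matrix(bag)) bag <- as.matrix(bag)
  if (ncol(bag) != nrow(model@convW[[1L]])) {
    stop(sprintf("bag feature dimension (%d) does not match model input (%d)",
                 ncol(bag), nrow(model@convW[[1L]])), call. = FALSE)
  }
  if (!all(is.finite(bag))) stop("bag contains non-finite features", call. = FALSE)
  .convForward(model@convW, model@convB, bag)$scores
}

#' MinMax instance selection
#'
#' Keeps the `Nt` largest scores in descending order followed by the `Nb`
#' smallest in ascending order — the top instances plus negative evidence.
#' Ties are broken toward the lower patch index. The selected patch indices
#' are attached as attribute `"indices"`.
#'
#' @param scores numeric vector of per-patch scores for one class.
#' @param Nt number of top instances (>= 1).
#' @param Nb number of bottom instances (>= 0); `Nb = 0` disables negative
#'   evidence.
#' @return Numeric vector of length `Nt + Nb` with attribute `"indices"`.
#' @examples
#' minmaxSelect(c(0.9, 0.1, 0.5, 0.7), Nt = 2, Nb = 1)  # 0.9 0.7 0.1
#' @export
minmaxSelect <- function(scores, Nt, Nb) {
  Nt <- .checkCount(Nt, "Nt", 1L)
  Nb <- .checkCount(Nb, "Nb", 0L)
  n <- length(scores)
  if (n < Nt + Nb) {
    stop(sprintf("bag too small: %d patches but Nt + Nb = %d", n, Nt + Nb),
         call. = FALSE)
  }
  idx <- seq_len(n)
  topIdx <- idx[order(-scores, idx)][seq_len(Nt)]
  botIdx <- if (Nb > 0) idx[order(scores, idx)][seq_len(Nb)] else integer()
  sel <- c(topIdx, botIdx)
  structure(scores[sel], indices = sel)
}

# Selected-score vector for a whole bag: per-class MinMax outputs
# concatenated class-major. Returns value vector plus (index, class) pairs.
.selectBag <- function(scores, Nt, Nb) {
  K <- ncol(scores)
  per <- Nt + Nb
  z <- numeric(K * per)
  idx <- integer(K * per)
  for (k in seq_len(K)) {
    s <- minmaxSelect(scores[, k], Nt, Nb)
    pos <- (k - 1L) * per + seq_len(per)
    z[pos] <- s
    idx[pos] <- attr(s, "indices")
  }
  list(z = z, idx = idx, class = rep(seq_len(K), each = per))
}

# MLP forward. dropMasks NULL at inference; at training, a list of
# inverted-dropout masks for the hidden layers.
.mlpForward <- function(mlpW, mlpB, z, dropMasks = NULL) {
  L <- length(mlpW)
  acts <- vector("list", L)
  inputs <- vector("list", L)
  h <- z
  for (l in seq_len(L)) {
    inputs[[l]] <- h
    a <- drop(h %*% mlpW[[l]]) + mlpB[[l]]
    acts[[l]] <- a
    if (l < L) {
      h <- pmax(a, 0)
      if (!is.null(dropMasks)) h <- h * dropMasks[[l]]
    } else {
      h <- a
    }
  }
  list(logits = h, acts = acts, inputs = inputs)
}

#' Predict class probabilities for one bag
#'
#' Full forward pass: attention scores, per-class MinMax selection,
#' concatenation (class-major, length `nClasses * (Nt + Nb)`), MLP head and
#' softmax. The output is a nonnegative probability vector summing to 1.
#' Because only the selected score multiset enters the head, duplicating
#' every patch of a bag leaves the prediction unchanged.
#'
#' @param model a [MILModel-class].
#' @param bag numeric matrix `n_patches x feature_dim`.
#' @return Named probability vector over the classes.
#' @export
predictBag <- function(model, bag) {
  scores <- scorePatches(model, bag)
  cfg <- model@config
  sel <- .selectBag(scores, cfg@Nt, cfg@Nb)
  out <- .mlpForward(model@mlpW, model@mlpB, sel$z)
  p <- .softmax(out$logits)
  names(p) <- if (cfg@nClasses == 3L) .CLASS_NAMES else
    sprintf("class_%d", seq_len(cfg@nClasses))
  p
}

#' Predict class probabilities for every bag in a set
#'
#' @param model a [MILModel-class].
#' @param bagset a [FeatureBagSet-class].
#' @return Matrix `n_bags x nClasses` of probabilities, rownames = bag ids.
#' @export
predictBagSet <- function(model, bagset) {
  stopifnot(is(bagset, "FeatureBagSet"))
  P <- t(vapply(bags(bagset), function(b) predictBag(model, b),
                numeric(model@config@nClasses)))
  rownames(P) <- bagIds(bagset)
  P
}

#' Per-patch attention map for one class
#'
#' Returns the attention scores of every patch for the requested class —
#' the per-patch quantity a class activation map renders over the slide.
#' The computation is per-bag only (no cross-bag coupling), and the
#' highest-scoring patch is exactly the one [minmaxSelect()] ranks first.
#'
#' @param model a [MILModel-class].
#' @param bag numeric matrix `n_patches x feature_dim`.
#' @param classIdx class index in `1..nClasses`.
#' @return Numeric vector of length `n_patches`, named by patch index.
#' @export
attentionMap <- function(model, bag, classIdx) {
  stopifnot(is(model, "MILModel"))
  K <- model@config@nClasses
  if (!is.numeric(classIdx) || length(classIdx) != 1L ||
      classIdx != round(classIdx) || classIdx < 1 || classIdx > K) {
    stop(sprintf("classIdx must be an integer in 1..%d", K), call. = FALSE)
  }
  s <- scorePatches(model, bag)[, classIdx]
  names(s) <- seq_along(s)
  s
}

#' Export attention maps as a plain table
#'
#' @param model a [MILModel-class].
#' @param bagset a [FeatureBagSet-class].
#' @param file optional CSV path; when given the table is also written.
#' @return `data.frame(bag_id, patch_index, class, score)`, invisibly when
#'   `file` is given.
#' @export
exportAttentionMaps <- function(model, bagset, file = NULL) {
  stopifnot(is(bagset, "FeatureBagSet"))
  K <- model@config@nClasses
  classNames <- if (K == 3L) .CLASS_NAMES else sprintf("class_%d", seq_len(K))
  out <- do.call(rbind, lapply(seq_along(bagset@bags), function(i) {
    S <- scorePatches(model, bagset@bags[[i]])
    data.frame(bag_id = bagset@bagIds[i],
               patch_index = rep(seq_len(nrow(S)), K),
               class = rep(classNames, each = nrow(S)),
               score = as.vector(S))
  }))
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# ---- loss and gradients -----------------------------------------------------

.l2Penalty <- function(model) {
  wd <- model@config@weightDecay
  if (wd == 0) return(0)
  0.5 * wd * (sum(vapply(model@convW, function(W) sum(W^2), numeric(1))) +
              sum(vapply(model@mlpW, function(W) sum(W^2), numeric(1))))
}

# Head loss as a function of the attention-score matrix directly. Used by
# the finite-difference check that unselected patches get zero gradient.
.lossFromScores <- function(model, scores, label, dropMasks = NULL) {
  cfg <- model@config
  sel <- .selectBag(scores, cfg@Nt, cfg@Nb)
  out <- .mlpForward(model@mlpW, model@mlpB, sel$z, dropMasks)
  p <- .softmax(out$logits)
  -log(max(p[label], .Machine$double.xmin))
}

# Analytic gradient of the per-bag cross-entropy loss. Returns gradients for
# every parameter plus dScores (the gradient w.r.t. the attention-score
# matrix — exactly zero outside the MinMax selection).
.bagGradients <- function(model, bag, label, dropMasks = NULL) {
  cfg <- model@config
  fw <- .convForward(model@convW, model@convB, bag)
  sel <- .selectBag(fw$scores, cfg@Nt, cfg@Nb)
  out <- .mlpForward(model@mlpW, model@mlpB, sel$z, dropMasks)
  p <- .softmax(out$logits)
  loss <- -log(max(p[label], .Machine$double.xmin))

  K <- cfg@nClasses
  dlogits <- p
  dlogits[label] <- dlogits[label] - 1

  Lm <- length(model@mlpW)
  dMlpW <- vector("list", Lm)
  dMlpB <- vector("list", Lm)
  delta <- dlogits
  for (l in rev(seq_len(Lm))) {
    dMlpW[[l]] <- outer(out$inputs[[l]], delta)
    dMlpB[[l]] <- delta
    if (l > 1L) {
      delta <- drop(model@mlpW[[l]] %*% delta)
      if (!is.null(dropMasks)) delta <- delta * dropMasks[[l - 1L]]
      delta <- delta * (out$acts[[l - 1L]] > 0)
    }
  }
  # dMlpB[[1]] holds the delta at the first MLP layer
  dz <- drop(model@mlpW[[1L]] %*% dMlpB[[1L]])

  # scatter the selected-score gradient back onto the score matrix;
  # unselected entries stay exactly zero (selection blocks the gradient)
  dScores <- matrix(0, nrow(fw$scores), K)
  for (j in seq_along(sel$idx)) {
    dScores[sel$idx[j], sel$class[j]] <- dScores[sel$idx[j], sel$class[j]] + dz[j]
  }

  Lc <- length(model@convW)
  dConvW <- vector("list", Lc)
  dConvB <- vector("list", Lc)
  dH <- dScores
  for (l in rev(seq_len(Lc))) {
    dA <- if (l == Lc) dH else dH * (fw$acts[[l]] > 0)
    dConvW[[l]] <- crossprod(fw$inputs[[l]], dA)
    dConvB[[l]] <- colSums(dA)
    if (l > 1L) dH <- dA %*% t(model@convW[[l]])
  }

  list(loss = loss, dConvW = dConvW, dConvB = dConvB,
       dMlpW = dMlpW, dMlpB = dMlpB, dScores = dScores)
}

# ---- training ---------------------------------------------------------------

.zeroLike <- function(params) lapply(params, function(p) p * 0)

.adamStep <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Train the MinMax multiple-instance classifier
#'
#' Minimizes cross-entropy plus an L2 weight-decay penalty
#' (`0.5 * weightDecay * sum(weights^2)`, biases excluded) with Adam,
#' processing bags in shuffled mini-batches. Inverted dropout with the
#' configured rate is applied to every MLP hidden layer during training
#' only. Backpropagation reaches only the MinMax-selected patches: the
#' gradient of the loss with respect to any unselected patch's score is
#' exactly zero. Training is bit-reproducible for a fixed seed.
#'
#' @param bagset a [FeatureBagSet-class] with at least 2 classes present;
#'   every bag must have at least `Nt + Nb` patches.
#' @param config a [MILConfig-class].
#' @param verbose print per-epoch loss.
#' @return A [MILModel-class] whose `history` has one mean loss per epoch.
#' @examples
#' d <- generateBagDataset(4, nPatches = 30, featureDim = 16,
#'                         signalStrength = 5, seed = 1)
#' cfg <- milConfig(Nt = 3, Nb = 2, Ly = 1, convWidths = c(16L, 3L),
#'                  epochs = 3L, seed = 1L)
#' m <- trainMIL(d, cfg)
#' @export
trainMIL <- function(bagset, config, verbose = FALSE) {
  stopifnot(is(bagset, "FeatureBagSet"), is(config, "MILConfig"))
  if (length(bagset) == 0L) stop("empty dataset", call. = FALSE)
  labs <- droplevels(bagLabels(bagset))
  if (nlevels(labs) < 2L) {
    stop("training requires at least 2 classes present", call. = FALSE)
  }
  need <- config@Nt + config@Nb
  sizes <- vapply(bags(bagset), nrow, integer(1))
  if (any(sizes < need)) {
    stop(sprintf("bag(s) too small for MinMax selection: min %d patches but Nt + Nb = %d",
                 min(sizes), need), call. = FALSE)
  }
  y <- as.integer(bagLabels(bagset))
  X <- bags(bagset)
  nH <- length(config@mlpWidths)

  withSeed(config@seed, {
    model <- .initMILModel(config, ncol(X[[1L]]))
    mC <- .zeroLike(model@convW); vC <- .zeroLike(model@convW)
    mCb <- .zeroLike(model@convB); vCb <- .zeroLike(model@convB)
    mM <- .zeroLike(model@mlpW); vM <- .zeroLike(model@mlpW)
    mMb <- .zeroLike(model@mlpB); vMb <- .zeroLike(model@mlpB)
    t <- 0L
    history <- numeric(config@epochs)
    wd <- config@weightDecay
    keep <- 1 - config@dropout

    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(length(X))
      epochLoss <- 0
      batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      for (batch in batches) {
        gC <- .zeroLike(model@convW); gCb <- .zeroLike(model@convB)
        gM <- .zeroLike(model@mlpW); gMb <- .zeroLike(model@mlpB)
        for (i in batch) {
          masks <- if (config@dropout > 0 && nH > 0) {
            lapply(config@mlpWidths, function(w) {
              (stats::runif(w) >= config@dropout) / keep
            })
          } else NULL
          g <- .bagGradients(model, X[[i]], y[i], masks)
          epochLoss <- epochLoss + g$loss
          for (l in seq_along(gC)) {
            gC[[l]] <- gC[[l]] + g$dConvW[[l]]
            gCb[[l]] <- gCb[[l]] + g$dConvB[[l]]
          }
          for (l in seq_along(gM)) {
            gM[[l]] <- gM[[l]] + g$dMlpW[[l]]
            gMb[[l]] <- gMb[[l]] + g$dMlpB[[l]]
          }
        }
        nb <- length(batch)
        t <- t + 1L
        for (l in seq_along(gC)) {
          g1 <- gC[[l]] / nb + wd * model@convW[[l]]
          st <- .adamStep(model@convW[[l]], g1, mC[[l]], vC[[l]], config@learningRate, t)
          model@convW[[l]] <- st$p; mC[[l]] <- st$m; vC[[l]] <- st$v
          st <- .adamStep(model@convB[[l]], gCb[[l]] / nb, mCb[[l]], vCb[[l]],
                          config@learningRate, t)
          model@convB[[l]] <- st$p; mCb[[l]] <- st$m; vCb[[l]] <- st$v
        }
        for (l in seq_along(gM)) {
          g1 <- gM[[l]] / nb + wd * model@mlpW[[l]]
          st <- .adamStep(model@mlpW[[l]], g1, mM[[l]], vM[[l]], config@learningRate, t)
          model@mlpW[[l]] <- st$p; mM[[l]] <- st$m; vM[[l]] <- st$v
          st <- .adamStep(model@mlpB[[l]], gMb[[l]] / nb, mMb[[l]], vMb[[l]],
                          config@learningRate, t)
          model@mlpB[[l]] <- st$p; mMb[[l]] <- st$m; vMb[[l]] <- st$v
        }
      }
      history[epoch] <- epochLoss / length(X) + .l2Penalty(model)
      if (verbose) message(sprintf("epoch %d: loss %.4f", epoch, history[epoch]))
    }
    model@history <- history
    validObject(model)
    model
  })
}

#' Total L2 norm of a model's weight matrices
#'
#' @param model a [MILModel-class].
#' @return Single numeric, `sqrt(sum of squared weights)` (biases excluded).
#' @export
weightNorm <- function(model) {
  stopifnot(is(model, "MILModel"))
  sqrt(sum(vapply(model@convW, function(W) sum(W^2), numeric(1))) +
       sum(vapply(model@mlpW, function(W) sum(W^2), numeric(1))))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores all parameters, the configuration and the training
#' seed.
#'
#' @param model a [MILModel-class].
#' @param path file path.
#' @return `saveMILModel` returns `path` invisibly; `readMILModel` the model.
#' @export
saveMILModel <- function(model, path) {
  stopifnot(is(model, "MILModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveMILModel
#' @export
readMILModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "MILModel")) stop("file does not contain a MILModel", call. = FALSE)
  validObject(model)
  model
}
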