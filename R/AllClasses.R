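#' @import methods
NULL

#' Set of labeled patch-feature bags
#'
#' Container for a multiple-instance-learning dataset: one bag per slide,
#' each bag a numeric matrix of per-patch feature vectors (rows = patches,
#' columns = features), with a single class label per bag. Bags may differ
#' in patch count but must share the feature dimension.
#'
#' @slot bags list of numeric matrices, one per bag (`n_patches x feature_dim`).
#' @slot labels factor of bag-level class labels, same length as `bags`.
#' @slot bagIds character vector of unique bag identifiers.
#'
#' @seealso [generateBagDataset()] to simulate such a set, [trainMIL()] to
#'   fit the classifier on one.
#' @export
setClass("FeatureBagSet",
  representation(bags = "list", labels = "factor", bagIds = "character"))

setValidity("FeatureBagSet", function(object) {
  msgs <- character()
  n <- length(object@bags)
  if (length(object@labels) != n) msgs <- c(msgs, "labels length must equal number of bags")
  if (length(object@bagIds) != n) msgs <- c(msgs, "bagIds length must equal number of bags")
  if (anyDuplicated(object@bagIds)) msgs <- c(msgs, "bagIds must be unique")
  if (n > 0) {
    if (!all(vapply(object@bags, is.matrix, logical(1)))) {
      msgs <- c(msgs, "every bag must be a numeric matrix")
    } else {
      dims <- vapply(object@bags, ncol, integer(1))
      if (length(unique(dims)) > 1L) {
        msgs <- c(msgs, "all bags must share the same feature dimension")
      }
      if (any(vapply(object@bags, nrow, integer(1)) < 1L)) {
        msgs <- c(msgs, "every bag must contain at least one patch")
      }
      if (!all(vapply(object@bags, function(b) all(is.finite(b)), logical(1)))) {
        msgs <- c(msgs, "bag features must be finite")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureBagSet
#'
#' @param bags list of numeric matrices (`n_patches x feature_dim`).
#' @param labels factor (or vector coercible to factor) of bag labels.
#' @param bagIds optional character identifiers; defaults to `bag_1 ...`.
#' @return A [FeatureBagSet-class] object.
#' @export
FeatureBagSet <- function(bags, labels, bagIds = NULL) {
  if (is.null(bagIds)) bagIds <- sprintf("bag_%d", seq_along(bags))
  new("FeatureBagSet", bags = bags, labels = as.factor(labels),
      bagIds = as.character(bagIds))
}

#' @describeIn FeatureBagSet number of bags.
#' @param x,object a `FeatureBagSet`.
#' @export
setMethod("length", "FeatureBagSet", function(x) length(x@bags))

#' Accessors for FeatureBagSet
#'
#' `bags()` returns the list of patch-feature matrices, `bagLabels()` the
#' factor of class labels, `bagIds()` the identifiers and `featureDim()` the
#' shared feature dimension.
#'
#' @param x a [FeatureBagSet-class].
#' @return See individual descriptions.
#' @name FeatureBagSet-accessors
NULL

#' @rdname FeatureBagSet-accessors
#' @export
bags <- function(x) {
  stopifnot(is(x, "FeatureBagSet"))
  x@bags
}

#' @rdname FeatureBagSet-accessors
#' @export
bagLabels <- function(x) {
  stopifnot(is(x, "FeatureBagSet"))
  x@labels
}

#' @rdname FeatureBagSet-accessors
#' @export
bagIds <- function(x) {
  stopifnot(is(x, "FeatureBagSet"))
  x@bagIds
}

#' @rdname FeatureBagSet-accessors
#' @export
featureDim <- function(x) {
  stopifnot(is(x, "FeatureBagSet"))
  if (length(x@bags) == 0L) return(NA_integer_)
  ncol(x@bags[[1L]])
}

#' @describeIn FeatureBagSet subset bags by index, id or logical vector.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "FeatureBagSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@bagIds)
  new("FeatureBagSet", bags = x@bags[i], labels = droplevels(x@labels[i]),
      bagIds = x@bagIds[i])
})

setMethod("show", "FeatureBagSet", function(object) {
  cat(sprintf("FeatureBagSet with %d bags (feature dim %s)\n",
              length(object), featureDim(object)))
  if (length(object)) {
    np <- vapply(object@bags, nrow, integer(1))
    cat(sprintf("  patches per bag: %d-%d\n", min(np), max(np)))
    tab <- table(object@labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' Configuration of the MinMax multiple-instance classifier
#'
#' Holds every architecture and training factor of the model: the widths of
#' the shared-weight one-dimensional convolution stack that produces one
#' attention score per class per patch, the MinMax selection sizes (`Nt` top
#' instances, `Nb` bottom "negative evidence" instances), the MLP head
#' widths, dropout rate, weight decay, and optimizer settings.
#'
#' @slot nClasses integer, number of slide classes (3 for
#'   benign/atypical/malignant).
#' @slot convWidths integer vector of conv-stack output widths, last entry
#'   equal to `nClasses`.
#' @slot Nt integer >= 1, number of top-scoring instances kept per class.
#' @slot Nb integer >= 0, number of bottom-scoring instances kept per class.
#' @slot mlpWidths integer vector of MLP hidden-layer widths.
#' @slot dropout numeric in `[0, 1)`, dropout rate on every MLP hidden layer.
#' @slot weightDecay numeric >= 0, L2 penalty coefficient on weights.
#' @slot learningRate,epochs,batchSize,seed optimizer settings.
#' @seealso [milConfig()]
#' @export
setClass("MILConfig",
  representation(nClasses = "integer", convWidths = "integer",
                 Nt = "integer", Nb = "integer", mlpWidths = "integer",
                 dropout = "numeric", weightDecay = "numeric",
                 learningRate = "numeric", epochs = "integer",
                 batchSize = "integer", seed = "integer"))

setValidity("MILConfig", function(object) {
  msgs <- character()
  if (object@nClasses < 2L) msgs <- c(msgs, "nClasses must be >= 2")
  if (length(object@convWidths) < 1L ||
      object@convWidths[length(object@convWidths)] != object@nClasses) {
    msgs <- c(msgs, "convWidths must end in nClasses (one score per class)")
  }
  if (object@Nt < 1L) msgs <- c(msgs, "Nt must be >= 1")
  if (object@Nb < 0L) msgs <- c(msgs, "Nb must be >= 0")
  if (object@dropout < 0 || object@dropout >= 1) msgs <- c(msgs, "dropout must be in [0, 1)")
  if (object@weightDecay < 0) msgs <- c(msgs, "weightDecay must be >= 0")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be >= 1")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})

# MLP widths indexed by the number-of-hidden-layers factor level.
.LY_WIDTHS <- list(`1` = 64L, `2` = c(128L, 64L), `3` = c(256L, 128L, 64L))

#' Build a model configuration
#'
#' The MLP head can be specified either through the discrete `Ly` level
#' (1, 2 or 3 hidden layers with widths 64 / 128,64 / 256,128,64) or
#' explicitly through `mlpWidths`.
#'
#' @param Nt,Nb MinMax selection sizes (top instances, bottom instances).
#' @param Ly hidden-layer level in `1:3`; ignored when `mlpWidths` is given.
#' @param mlpWidths explicit integer vector of hidden widths.
#' @param dropout dropout rate applied to every MLP hidden layer.
#' @param weightDecay L2 penalty coefficient.
#' @param convWidths conv-stack widths; the default five-layer stack
#'   `256, 128, 64, 32, nClasses` tapers a 768-dimensional patch embedding
#'   down to one attention score per class.
#' @param nClasses number of slide classes.
#' @param learningRate,epochs,batchSize,seed optimizer settings.
#' @return A validated [MILConfig-class] object.
#' @examples
#' milConfig(Nt = 10, Nb = 5, Ly = 2, dropout = 0.2, weightDecay = 0.1)
#' @export
milConfig <- function(Nt = 10L, Nb = 5L, Ly = 2L, mlpWidths = NULL,
                      dropout = 0.2, weightDecay = 0,
                      convWidths = c(256L, 128L, 64L, 32L, 3L),
                      nClasses = 3L, learningRate = 1e-3, epochs = 30L,
                      batchSize = 8L, seed = 1L) {
  nClasses <- .checkCount(nClasses, "nClasses", 2L)
  if (is.null(mlpWidths)) {
    Ly <- as.character(.checkCount(Ly, "Ly", 1L))
    if (!Ly %in% names(.LY_WIDTHS)) stop("'Ly' must be 1, 2 or 3", call. = FALSE)
    mlpWidths <- .LY_WIDTHS[[Ly]]
  }
  convWidths <- as.integer(convWidths)
  convWidths[length(convWidths)] <- nClasses
  new("MILConfig", nClasses = nClasses, convWidths = convWidths,
      Nt = .checkCount(Nt, "Nt", 1L), Nb = .checkCount(Nb, "Nb", 0L),
      mlpWidths = as.integer(mlpWidths),
      dropout = .checkFraction(dropout, "dropout"),
      weightDecay = .checkPositive(weightDecay, "weightDecay", strict = FALSE),
      learningRate = .checkPositive(learningRate, "learningRate"),
      epochs = .checkCount(epochs, "epochs", 1L),
      batchSize = .checkCount(batchSize, "batchSize", 1L),
      seed = as.integer(seed))
}

setMethod("show", "MILConfig", function(object) {
  cat("MILConfig\n")
  cat(sprintf("  conv stack: %s\n", paste(object@convWidths, collapse = " -> ")))
  cat(sprintf("  MinMax: Nt=%d top, Nb=%d bottom per class\n", object@Nt, object@Nb))
  cat(sprintf("  MLP hidden: %s | dropout %.2f | weight decay %.3g\n",
              paste(object@mlpWidths, collapse = ","), object@dropout,
              object@weightDecay))
  cat(sprintf("  Adam lr=%g, epochs=%d, batch=%d, seed=%d\n",
              object@learningRate, object@epochs, object@batchSize, object@seed))
})

#' Trained MinMax multiple-instance classifier
#'
#' @slot convW,convB lists of conv-stack weight matrices and bias vectors.
#' @slot mlpW,mlpB lists of MLP weight matrices and bias vectors.
#' @slot config the [MILConfig-class] used for training.
#' @slot history numeric vector of mean training loss per epoch.
#' @seealso [trainMIL()], [scorePatches()], [predictBag()]
#' @export
setClass("MILModel",
  representation(convW = "list", convB = "list", mlpW = "list",
                 mlpB = "list", config = "MILConfig", history = "numeric"))

setValidity("MILModel", function(object) {
  cfg <- object@config
  msgs <- character()
  if (length(object@convW) != length(cfg@convWidths)) {
    msgs <- c(msgs, "conv parameter count must match configured widths")
  }
  for (l in seq_along(object@convW)) {
    if (ncol(object@convW[[l]]) != cfg@convWidths[l]) {
      msgs <- c(msgs, sprintf("conv layer %d width mismatch", l))
    }
    if (length(object@convB[[l]]) != cfg@convWidths[l]) {
      msgs <- c(msgs, sprintf("conv layer %d bias length mismatch", l))
    }
  }
  nmlp <- length(cfg@mlpWidths) + 1L
  if (length(object@mlpW) != nmlp) msgs <- c(msgs, "MLP parameter count mismatch")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MILModel configuration accessor.
#' @param object,x a `MILModel`.
#' @export
milConfigOf <- function(x) {
  stopifnot(is(x, "MILModel"))
  x@config
}

#' @describeIn MILModel training-loss history (one value per epoch).
#' @export
trainingHistory <- function(x) {
  stopifnot(is(x, "MILModel"))
  x@history
}

setMethod("show", "MILModel", function(object) {
  cfg <- object@config
  cat(sprintf("MILModel: conv %d -> %s, MinMax(Nt=%d, Nb=%d), MLP %s -> %d\n",
              nrow(object@convW[[1L]]),
              paste(cfg@convWidths, collapse = " -> "),
              cfg@Nt, cfg@Nb,
              paste(cfg@mlpWidths, collapse = ","), cfg@nClasses))
  if (length(object@history)) {
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(object@history), object@history[length(object@history)]))
  }
})

#' Main-effects least-squares fit of a factorial results table
#'
#' Wraps the sum-to-zero-coded linear model underlying the Type III ANOVA
#' and the LS-means/LSD machinery. Factor levels are always treated as
#' categorical, even when numerically labeled.
#'
#' @slot lmfit the underlying `lm` object (sum-to-zero contrasts).
#' @slot data the model data frame with factor-coerced columns.
#' @slot response name of the response column.
#' @slot factors character vector of factor column names.
#' @seealso [fitMainEffects()], [type3Anova()], [lsMeans()]
#' @export
setClass("MainEffectsFit",
  representation(lmfit = "lm", data = "data.frame", response = "character",
                 factors = "character"))

setValidity("MainEffectsFit", function(object) {
  msgs <- character()
  res <- stats::residuals(object@lmfit)
  if (abs(sum(res)) > 1e-9 * max(1, sum(abs(res)))) {
    msgs <- c(msgs, "residuals must sum to zero (intercept model)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MainEffectsFit residual degrees of freedom,
#'   `n - 1 - sum(levels - 1)`.
#' @param object,x a `MainEffectsFit`.
#' @export
residualDf <- function(x) {
  stopifnot(is(x, "MainEffectsFit"))
  stats::df.residual(x@lmfit)
}

#' @describeIn MainEffectsFit residual sum of squares.
#' @export
residualSS <- function(x) {
  stopifnot(is(x, "MainEffectsFit"))
  sum(stats::residuals(x@lmfit)^2)
}

#' @describeIn MainEffectsFit total (corrected) sum of squares.
#' @export
totalSS <- function(x) {
  stopifnot(is(x, "MainEffectsFit"))
  y <- x@data[[x@response]]
  sum((y - mean(y))^2)
}

setMethod("show", "MainEffectsFit", function(object) {
  cat(sprintf("MainEffectsFit: %s ~ %s (sum-to-zero coding)\n",
              object@response, paste(object@factors, collapse = " + ")))
  cat(sprintf("  n = %d, residual df = %d, residual SS = %.6g\n",
              nrow(object@data), residualDf(object), residualSS(object)))
})
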