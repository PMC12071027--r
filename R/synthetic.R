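# Synthetic data: class-conditional feature bags and factorial results
# tables with known injected effects, so every downstream stage can be
# exercised and calibrated without any real whole-slide images.

.CLASS_NAMES <- c("benign", "atypical", "malignant")

# Mutually orthogonal unit prototype directions, one per class, derived
# deterministically from the seed via QR of a seeded Gaussian matrix.
.classPrototypes <- function(featureDim, nClasses, seed) {
  if (featureDim < nClasses) {
    stop("featureDim must be >= nClasses for orthogonal prototypes", call. = FALSE)
  }
  withSeed(seed + 7919L, {
    M <- matrix(stats::rnorm(featureDim * nClasses), featureDim, nClasses)
    Q <- qr.Q(qr(M))
    # fix sign so the decomposition is unique
    sweep(Q, 2, sign(Q[1L, ]) + (Q[1L, ] == 0), `*`)
  })
}

#' Generate a labeled synthetic bag dataset
#'
#' Emulates the multiple-instance structure of patch-embedded whole-slide
#' images: each bag holds `nPatches` patch feature vectors of dimension
#' `featureDim`; a minority fraction (`signalFraction`) of patches carry the
#' bag's class signal, the rest are background. Background patches are drawn
#' i.i.d. Gaussian `(0, noiseSd^2 I)`; signal patches additionally shift by
#' `signalStrength` along the bag class's prototype direction. Prototypes
#' are fixed orthonormal vectors derived deterministically from the seed, so
#' classes are guaranteed separable at high `signalStrength` and the whole
#' dataset is bit-reproducible.
#'
#' @param nBagsPerClass number of bags per class (classes are balanced).
#' @param nPatches patches per bag.
#' @param featureDim patch embedding dimension; the default 768 matches a
#'   ViT-base patch embedding.
#' @param signalFraction fraction of patches per bag carrying class signal,
#'   in `[0, 1]`. Exactly `round(signalFraction * nPatches)` patches per bag
#'   are signal patches.
#' @param signalStrength non-negative shift along the class prototype.
#' @param noiseSd positive background standard deviation.
#' @param seed integer seed; identical seed and arguments give bit-identical
#'   output.
#' @param nClasses number of classes (default 3:
#'   benign/atypical/malignant).
#' @param prototypeSeed seed for the class prototype directions; defaults
#'   to `seed`. Distinct datasets from the same population (e.g. a
#'   training and a held-out evaluation set) must share `prototypeSeed`
#'   while differing in `seed`, otherwise their classes occupy unrelated
#'   directions.
#' @return A [FeatureBagSet-class] with `nClasses * nBagsPerClass` bags.
#' @examples
#' d <- generateBagDataset(2, nPatches = 30, featureDim = 16,
#'                         signalStrength = 5, seed = 1)
#' d
#' @export
generateBagDataset <- function(nBagsPerClass, nPatches = 100L,
                               featureDim = 768L, signalFraction = 0.2,
                               signalStrength = 5, noiseSd = 1, seed = 1L,
                               nClasses = 3L, prototypeSeed = seed) {
  nBagsPerClass <- .checkCount(nBagsPerClass, "nBagsPerClass")
  nPatches <- .checkCount(nPatches, "nPatches")
  featureDim <- .checkCount(featureDim, "featureDim")
  nClasses <- .checkCount(nClasses, "nClasses", 2L)
  signalFraction <- .checkFraction(signalFraction, "signalFraction")
  signalStrength <- .checkPositive(signalStrength, "signalStrength", strict = FALSE)
  noiseSd <- .checkPositive(noiseSd, "noiseSd")

  proto <- .classPrototypes(featureDim, nClasses, prototypeSeed)
  nSignal <- round(signalFraction * nPatches)
  classNames <- if (nClasses == 3L) .CLASS_NAMES else sprintf("class_%d", seq_len(nClasses))

  withSeed(seed, {
    bagList <- vector("list", nClasses * nBagsPerClass)
    labs <- character(length(bagList))
    k <- 0L
    for (cls in seq_len(nClasses)) {
      for (b in seq_len(nBagsPerClass)) {
        k <- k + 1L
        X <- matrix(stats::rnorm(nPatches * featureDim, sd = noiseSd),
                    nPatches, featureDim)
        if (nSignal > 0) {
          shift <- signalStrength * proto[, cls]
          X[seq_len(nSignal), ] <- X[seq_len(nSignal), , drop = FALSE] +
            matrix(shift, nSignal, featureDim, byrow = TRUE)
        }
        # randomize which rows are signal so position carries no information
        X <- X[sample.int(nPatches), , drop = FALSE]
        bagList[[k]] <- X
        labs[k] <- classNames[cls]
      }
    }
    FeatureBagSet(bagList, factor(labs, levels = classNames),
                  sprintf("bag_%03d_%s", seq_along(bagList), labs))
  })
}

#' Default factor grid of the sensitivity study
#'
#' The five studied factors and their levels: weight decay
#' `Wd in {0.0, 0.1}`, MLP depth `Ly in {1, 2, 3}`, dropout
#' `Dp in {0.2, 0.5, 0.8}`, top instances `Nt in {5, 10, 20, 40}` and
#' bottom instances (negative evidence) `Nb in {0, 5, 10, 20}`.
#'
#' @param Wd,Ly,Dp,Nt,Nb level vectors (overridable).
#' @param replicates replicate runs per factor cell, >= 1.
#' @return A named list of levels with class `"factorLevels"`.
#' @examples
#' g <- factorLevels()
#' prod(lengths(g[setdiff(names(g), "replicates")])) # 288 cells
#' @export
factorLevels <- function(Wd = c(0.0, 0.1), Ly = c(1L, 2L, 3L),
                         Dp = c(0.2, 0.5, 0.8), Nt = c(5L, 10L, 20L, 40L),
                         Nb = c(0L, 5L, 10L, 20L), replicates = 1L) {
  g <- list(Wd = Wd, Ly = Ly, Dp = Dp, Nt = Nt, Nb = Nb,
            replicates = .checkCount(replicates, "replicates"))
  if (any(lengths(g[1:5]) < 1L)) stop("every factor needs at least one level", call. = FALSE)
  class(g) <- "factorLevels"
  g
}

#' @export
print.factorLevels <- function(x, ...) {
  cat("Factor grid:\n")
  for (f in c("Wd", "Ly", "Dp", "Nt", "Nb")) {
    cat(sprintf("  %s: %s\n", f, paste(x[[f]], collapse = ", ")))
  }
  cat(sprintf("  replicates: %d (%d cells, %d runs)\n", x$replicates,
              prod(lengths(x[1:5])), prod(lengths(x[1:5])) * x$replicates))
  invisible(x)
}

# All factor cells in a fixed, reproducible order.
.gridCells <- function(grid) {
  expand.grid(Nb = grid$Nb, Nt = grid$Nt, Dp = grid$Dp, Ly = grid$Ly,
              Wd = grid$Wd, KEEP.OUT.ATTRS = FALSE)[, c("Wd", "Ly", "Dp", "Nt", "Nb")]
}

#' Specify ground-truth effects for a synthetic results table
#'
#' Defines an additive model for one response column: response =
#' `baseline` + per-factor level offset + Gaussian noise. Offsets within
#' each factor must sum to zero across its levels so the injected effect is
#' identifiable. Optional outlier rows are overwritten (not perturbed)
#' after generation, mimicking gross training failures rather than noise
#' tail events.
#'
#' @param response name of the response column this spec generates.
#' @param baseline scalar baseline response.
#' @param factorEffects named list; each element a named numeric vector of
#'   per-level offsets for one factor (names = level labels), summing to 0.
#' @param noiseSd positive Gaussian noise standard deviation (may be 0).
#' @param outlierRows optional `data.frame(row, value)` of rows to overwrite.
#' @return A list with class `"effectSpec"`.
#' @examples
#' effectSpec("F1", baseline = 0.6,
#'            factorEffects = list(Dp = c(`0.2` = 0.02, `0.5` = 0.01, `0.8` = -0.03)),
#'            noiseSd = 0.01)
#' @export
effectSpec <- function(response, baseline, factorEffects = list(),
                       noiseSd = 0, outlierRows = NULL) {
  stopifnot(is.character(response), length(response) == 1L)
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline)) {
    stop("'baseline' must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(noiseSd) || noiseSd < 0) stop("'noiseSd' must be >= 0", call. = FALSE)
  for (f in names(factorEffects)) {
    off <- factorEffects[[f]]
    if (is.null(names(off))) {
      stop(sprintf("offsets for factor '%s' must be named by level", f), call. = FALSE)
    }
    if (abs(sum(off)) > 1e-8) {
      stop(sprintf("offsets for factor '%s' must sum to zero", f), call. = FALSE)
    }
  }
  if (!is.null(outlierRows)) {
    stopifnot(is.data.frame(outlierRows), all(c("row", "value") %in% names(outlierRows)))
  }
  structure(list(response = response, baseline = baseline,
                 factorEffects = factorEffects, noiseSd = noiseSd,
                 outlierRows = outlierRows),
            class = "effectSpec")
}

#' Generate a synthetic factorial results table
#'
#' Builds one row per (factor cell x replicate) with factor columns first
#' (`Wd, Ly, Dp, Nt, Nb, replicate`) followed by one response column per
#' effect spec — the layout a factorial hyperparameter study records, with
#' known ground truth for recovery tests.
#'
#' @param grid a [factorLevels()] grid (its `replicates` is used).
#' @param effects one [effectSpec()] or a list of them (one per response).
#' @param seed integer seed.
#' @return A `data.frame` results table.
#' @examples
#' g <- factorLevels(replicates = 3)
#' eff <- effectSpec("F1", 0.6, noiseSd = 0.01)
#' nrow(generateResultsTable(g, eff, seed = 1)) # 864
#' @export
generateResultsTable <- function(grid, effects, seed = 1L) {
  stopifnot(inherits(grid, "factorLevels"))
  if (inherits(effects, "effectSpec")) effects <- list(effects)
  stopifnot(length(effects) >= 1L,
            all(vapply(effects, inherits, logical(1), "effectSpec")))

  cells <- .gridCells(grid)
  reps <- grid$replicates
  tab <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE]
  tab$replicate <- rep(seq_len(reps), nrow(cells))
  rownames(tab) <- NULL
  n <- nrow(tab)

  withSeed(seed, {
    for (eff in effects) {
      y <- rep(eff$baseline, n)
      for (f in names(eff$factorEffects)) {
        if (!f %in% names(cells)) {
          stop(sprintf("effect factor '%s' is not in the grid", f), call. = FALSE)
        }
        off <- eff$factorEffects[[f]]
        idx <- match(as.character(tab[[f]]), names(off))
        if (anyNA(idx)) {
          stop(sprintf("offsets for factor '%s' are missing some grid levels", f),
               call. = FALSE)
        }
        y <- y + off[idx]
      }
      if (eff$noiseSd > 0) y <- y + stats::rnorm(n, sd = eff$noiseSd)
      if (!is.null(eff$outlierRows)) {
        if (any(eff$outlierRows$row < 1 | eff$outlierRows$row > n)) {
          stop("outlier row index out of range", call. = FALSE)
        }
        y[eff$outlierRows$row] <- eff$outlierRows$value
      }
      tab[[eff$response]] <- unname(y)
    }
  })
  tab
}
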