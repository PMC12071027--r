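# Evaluation metrics and the factorial experiment runner.

#' Macro-averaged F1 score
#'
#' Per-class F1 is the harmonic mean of precision and recall,
#' `2PR/(P + R)`; the macro score averages per-class F1 unweighted over all
#' classes, so minority classes count as much as majority ones. A class
#' with no true positives (including one absent from both truth and
#' prediction) contributes 0.
#'
#' @param truth integer vector of true labels in `0..nClasses-1` (or a
#'   factor, converted positionally).
#' @param predicted integer vector of predicted labels, same coding.
#' @param nClasses number of classes averaged over (default 3).
#' @return Single numeric in `[0, 1]`.
#' @examples
#' macroF1(c(0, 0, 1, 2), c(0, 1, 1, 2))  # (2/3 + 2/3 + 1)/3
#' @export
macroF1 <- function(truth, predicted, nClasses = 3L) {
  truth <- .asClassIndex(truth)
  predicted <- .asClassIndex(predicted)
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length", call. = FALSE)
  }
  f1 <- vapply(seq_len(nClasses) - 1L, function(cls) {
    tp <- sum(truth == cls & predicted == cls)
    fp <- sum(truth != cls & predicted == cls)
    fn <- sum(truth == cls & predicted != cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

.asClassIndex <- function(x) {
  if (is.factor(x)) as.integer(x) - 1L else as.integer(x)
}

#' One-vs-rest ROC AUC, macro-averaged
#'
#' For each class, the ROC AUC of that class against the rest using the
#' class's score column (midrank handling of ties), then the unweighted
#' mean across classes. 1 means perfect ranking; 0.5 is chance level.
#'
#' @param truth integer vector of true labels in `0..nClasses-1` (or a
#'   factor).
#' @param scores numeric matrix, one row per sample, one column per class.
#' @return Single numeric in `[0, 1]`.
#' @export
ovrAUC <- function(truth, scores) {
  truth <- .asClassIndex(truth)
  scores <- as.matrix(scores)
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (nrow(scores) != length(truth)) {
    stop("scores must have one row per sample", call. = FALSE)
  }
  nClasses <- ncol(scores)
  aucs <- vapply(seq_len(nClasses), function(k) {
    pos <- truth == (k - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L) {
      stop(sprintf("class %d absent from truth: per-class AUC undefined", k - 1L),
           call. = FALSE)
    }
    if (n0 == 0L) {
      stop(sprintf("class %d is the only class present: per-class AUC undefined",
                   k - 1L), call. = FALSE)
    }
    r <- rank(scores[, k])           # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs)
}

#' Evaluate a trained model on a bag set
#'
#' @param model a [MILModel-class].
#' @param bagset a [FeatureBagSet-class].
#' @return List with `F1` (macro F1 of argmax predictions), `AUC`
#'   (one-vs-rest macro AUC of the probability matrix) and the probability
#'   matrix itself.
#' @export
evaluateModel <- function(model, bagset) {
  P <- predictBagSet(model, bagset)
  truth <- as.integer(bagLabels(bagset)) - 1L
  pred <- max.col(P, ties.method = "first") - 1L
  list(F1 = macroF1(truth, pred, nClasses = ncol(P)),
       AUC = ovrAUC(truth, P), probabilities = P)
}

#' Run the full factorial hyperparameter experiment
#'
#' Trains one model per factor cell and replicate on `trainBags`, evaluates
#' on `evalBags`, and collects one row per run with the factor columns
#' first (`Wd, Ly, Dp, Nt, Nb, replicate`) followed by the responses
#' `F1`, `AUC` and `T` (wall-clock training seconds). Replicate `r` of cell
#' `c` trains with a seed derived deterministically from
#' `(seed, c, r)`, so rerunning with the same master seed reproduces the
#' `F1` and `AUC` columns exactly (`T` is hardware-dependent and excluded
#' from the determinism contract). Cells whose `Nt + Nb` exceeds the
#' smallest bag are recorded as failed and skipped; the run continues.
#'
#' @param grid a [factorLevels()] grid.
#' @param trainBags,evalBags [FeatureBagSet-class] objects.
#' @param baseConfig a [MILConfig-class] supplying every setting the grid
#'   does not vary (conv widths, learning rate, epochs, batch size).
#' @param seed master seed.
#' @param verbose print a line per run.
#' @return `data.frame` results table; failed cells (if any) are attached
#'   as attribute `"failures"`.
#' @export
runFactorial <- function(grid, trainBags, evalBags, baseConfig = milConfig(),
                         seed = 1L, verbose = FALSE) {
  stopifnot(inherits(grid, "factorLevels"),
            is(trainBags, "FeatureBagSet"), is(evalBags, "FeatureBagSet"),
            is(baseConfig, "MILConfig"))
  cells <- .gridCells(grid)
  reps <- grid$replicates
  minBag <- min(vapply(bags(trainBags), nrow, integer(1)),
                vapply(bags(evalBags), nrow, integer(1)))
  rows <- vector("list", nrow(cells) * reps)
  failures <- list()
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    if (cell$Nt + cell$Nb > minBag) {
      failures[[length(failures) + 1L]] <-
        cbind(cell, reason = sprintf("Nt + Nb = %d exceeds smallest bag (%d patches)",
                                     cell$Nt + cell$Nb, minBag))
      next
    }
    for (r in seq_len(reps)) {
      cfg <- milConfig(Nt = cell$Nt, Nb = cell$Nb, Ly = cell$Ly,
                       dropout = cell$Dp, weightDecay = cell$Wd,
                       convWidths = baseConfig@convWidths,
                       nClasses = baseConfig@nClasses,
                       learningRate = baseConfig@learningRate,
                       epochs = baseConfig@epochs,
                       batchSize = baseConfig@batchSize,
                       seed = deriveSeed(seed, ci, r))
      elapsed <- system.time(model <- trainMIL(trainBags, cfg))[["elapsed"]]
      ev <- evaluateModel(model, evalBags)
      k <- k + 1L
      rows[[k]] <- data.frame(Wd = cell$Wd, Ly = cell$Ly, Dp = cell$Dp,
                              Nt = cell$Nt, Nb = cell$Nb, replicate = r,
                              F1 = ev$F1, AUC = ev$AUC, T = elapsed)
      if (verbose) {
        message(sprintf("cell %d/%d rep %d: F1=%.3f AUC=%.3f T=%.1fs",
                        ci, nrow(cells), r, ev$F1, ev$AUC, elapsed))
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (length(failures)) attr(out, "failures") <- do.call(rbind, failures)
  out
}
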