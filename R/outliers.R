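# Outlier screening of the factorial results table: studentized values
# (with and without deletion), MAD-based modified Z-scores, Grubbs' test,
# and the hard metric thresholds that define the analysis set.

#' Studentized values (z-scores)
#'
#' Without deletion, `z_i = (x_i - mean(x)) / sd(x)` with the sample
#' (n-1 denominator) standard deviation. With deletion, the mean and
#' standard deviation for observation `i` are computed excluding it, which
#' makes the score far more sensitive to a single gross outlier.
#'
#' @param values numeric vector, `n >= 2` (`n >= 3` with deletion).
#' @param deletion logical; exclude each observation from its own
#'   mean/sd.
#' @return Numeric vector of z-scores.
#' @examples
#' zScores(c(1, 2, 3))                      # -1 0 1
#' zScores(c(1, 2, 3, 4, 100), deletion = TRUE)[5]  # ~75.5
#' @export
zScores <- function(values, deletion = FALSE) {
  x <- as.numeric(values)
  n <- length(x)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  if (n < if (deletion) 3L else 2L) {
    stop(sprintf("need at least %d observations", if (deletion) 3L else 2L),
         call. = FALSE)
  }
  if (!deletion) {
    s <- stats::sd(x)
    if (s == 0) stop("constant sample: standard deviation is zero", call. = FALSE)
    return((x - mean(x)) / s)
  }
  vapply(seq_len(n), function(i) {
    xi <- x[-i]
    s <- stats::sd(xi)
    if (s == 0) stop("constant sample after deletion: standard deviation is zero",
                     call. = FALSE)
    (x[i] - mean(xi)) / s
  }, numeric(1))
}

#' MAD-based modified Z-scores
#'
#' `M_i = 0.6745 (x_i - median(x)) / MAD` with
#' `MAD = median(|x_i - median(x)|)` (unscaled). The median absolute
#' deviation is far less sensitive to extreme values than the standard
#' deviation, so these scores also expose outliers masked in ordinary
#' z-scores.
#'
#' @param values numeric vector.
#' @return Numeric vector of modified Z-scores.
#' @examples
#' modifiedZScores(c(1, 2, 3, 4, 100))[5]  # 0.6745 * 97 = 65.4265
#' @export
modifiedZScores <- function(values) {
  x <- as.numeric(values)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {
    stop(paste("MAD is zero (more than half the values are identical);",
               "modified Z-scores are undefined for this sample"), call. = FALSE)
  }
  0.6745 * (x - med) / mad0
}

#' Grubbs' test for a single outlier
#'
#' Tests whether the most extreme value of a univariate sample deviates
#' from a common normal population. The statistic is built from the largest
#' absolute studentized value (no deletion),
#' `t_max = max |x_i - mean| / sd`, mapped to a Student-t scale via
#' `T^2 = n (n-2) t_max^2 / ((n-1)^2 - n t_max^2)`, with an approximate
#' two-sided p-value `min(1, 2n * P(t_{n-2} > T))`. A small p-value flags
#' the most extreme point as an outlier; ties in `|z|` flag the lower
#' index.
#'
#' @param values numeric vector, `n >= 3`, non-constant.
#' @param alpha significance level for flagging (default 0.05).
#' @return A list of class `"grubbsResult"` with elements `tMax` (largest
#'   absolute studentized value), `statistic` (the t-scale statistic `T`),
#'   `n`, `pValue`, `flaggedIndex` (`NA` when not significant) and
#'   `extremeIndex` (the most extreme point regardless of significance).
#' @examples
#' grubbsTest(c(1, 2, 3, 4, 10))   # tMax ~1.697, not significant at 0.05
#' grubbsTest(c(0, 0.01, -0.01, 50))$flaggedIndex  # 4
#' @export
grubbsTest <- function(values, alpha = 0.05) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L) stop("Grubbs' test needs at least 3 observations", call. = FALSE)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("constant sample: Grubbs' test undefined", call. = FALSE)
  z <- (x - mean(x)) / s
  extremeIndex <- which.max(abs(z))     # ties resolve to the lower index
  tMax <- abs(z[extremeIndex])
  denom <- (n - 1)^2 - n * tMax^2
  if (denom <= .Machine$double.eps) {
    stat <- Inf
    p <- 0
  } else {
    stat <- sqrt(n * (n - 2) * tMax^2 / denom)
    p <- min(1, 2 * n * stats::pt(stat, df = n - 2, lower.tail = FALSE))
  }
  structure(list(tMax = tMax, statistic = stat, n = n, pValue = p,
                 alpha = alpha,
                 flaggedIndex = if (p < alpha) extremeIndex else NA_integer_,
                 extremeIndex = extremeIndex),
            class = "grubbsResult")
}

#' @export
print.grubbsResult <- function(x, ...) {
  cat("Grubbs' test for one outlier\n")
  cat(sprintf("  n = %d, t_max = %.4f, T = %.4f, p = %.4g\n",
              x$n, x$tMax, x$statistic, x$pValue))
  if (is.na(x$flaggedIndex)) {
    cat(sprintf("  no outlier at alpha = %g (extreme point: index %d)\n",
                x$alpha, x$extremeIndex))
  } else {
    cat(sprintf("  index %d flagged as outlier at alpha = %g\n",
                x$flaggedIndex, x$alpha))
  }
  invisible(x)
}

#' Screen a results table on hard metric thresholds
#'
#' Removes runs whose discrimination or classification quality falls below
#' the acceptability floor: by default `AUC < 0.65` (barely above the 0.5
#' chance level) or `F1 < 0.45` (imbalanced precision/recall in at least
#' one of three classes). The two criteria combine with OR by default (each
#' metric's criterion suffices on its own); `combine = "and"` requires
#' both. The audit report lists every removed row with its z-score,
#' modified Z-score and Grubbs flag on both metrics, so either reading of
#' the screen stays auditable.
#'
#' @param table results table with `AUC` and `F1` columns.
#' @param aucMin,f1Min thresholds (defaults 0.65 and 0.45).
#' @param combine `"or"` (default) or `"and"`.
#' @return A list of class `"screenResult"`: `table` (filtered), `report`
#'   (`data.frame(row, metric, value, z, modified_z, grubbs_flag, reason)`),
#'   `nBefore`, `nAfter`. Screening is idempotent: screening a screened
#'   table removes nothing.
#' @export
screenResults <- function(table, aucMin = 0.65, f1Min = 0.45,
                          combine = c("or", "and")) {
  combine <- match.arg(combine)
  if (!all(c("AUC", "F1") %in% names(table))) {
    stop("results table must contain 'AUC' and 'F1' columns", call. = FALSE)
  }
  lowAuc <- table$AUC < aucMin
  lowF1 <- table$F1 < f1Min
  drop <- if (combine == "or") lowAuc | lowF1 else lowAuc & lowF1

  stats_ <- lapply(c(AUC = "AUC", F1 = "F1"), function(m) {
    v <- table[[m]]
    z <- tryCatch(zScores(v), error = function(e) rep(NA_real_, length(v)))
    mz <- tryCatch(modifiedZScores(v), error = function(e) rep(NA_real_, length(v)))
    g <- tryCatch(grubbsTest(v)$flaggedIndex, error = function(e) NA_integer_)
    list(z = z, mz = mz, grubbs = g)
  })

  report <- do.call(rbind, lapply(which(drop), function(i) {
    do.call(rbind, lapply(c("AUC", "F1"), function(m) {
      below <- if (m == "AUC") lowAuc[i] else lowF1[i]
      thr <- if (m == "AUC") aucMin else f1Min
      data.frame(row = i, metric = m, value = table[[m]][i],
                 z = stats_[[m]]$z[i], modified_z = stats_[[m]]$mz[i],
                 grubbs_flag = identical(i, as.integer(stats_[[m]]$grubbs)),
                 reason = if (below) sprintf("%s < %g", m, thr) else "")
    }))
  }))
  if (is.null(report)) {
    report <- data.frame(row = integer(), metric = character(),
                         value = numeric(), z = numeric(),
                         modified_z = numeric(), grubbs_flag = logical(),
                         reason = character())
  }
  structure(list(table = table[!drop, , drop = FALSE], report = report,
                 nBefore = nrow(table), nAfter = sum(!drop),
                 aucMin = aucMin, f1Min = f1Min, combine = combine),
            class = "screenResult")
}

#' @export
print.screenResult <- function(x, ...) {
  cat(sprintf("Outlier screen (AUC < %g %s F1 < %g): %d -> %d rows (%d removed)\n",
              x$aucMin, toupper(x$combine), x$f1Min, x$nBefore, x$nAfter,
              x$nBefore - x$nAfter))
  invisible(x)
}

#' Write the screening audit report
#'
#' @param screen a `"screenResult"` from [screenResults()].
#' @param file CSV path; a trailing summary line records `n_before` and
#'   `n_after`.
#' @return `file`, invisibly.
#' @export
writeScreenReport <- function(screen, file) {
  stopifnot(inherits(screen, "screenResult"))
  utils::write.csv(screen$report, file, row.names = FALSE)
  cat(sprintf("# n_before=%d n_after=%d\n", screen$nBefore, screen$nAfter),
      file = file, append = TRUE)
  invisible(file)
}
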