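# Multiple range tests: least-squares means, Fisher LSD pairwise
# contrasts, and homogeneous-group lettering.

# Coefficient covariance straight from the QR factorization; avoids the
# "essentially perfect fit" noise of summary.lm() on zero-residual fits.
.fitVcov <- function(lmfit) {
  R <- qr.R(lmfit$qr)
  cov <- chol2inv(R)
  dimnames(cov) <- list(colnames(R), colnames(R))
  s2 <- sum(stats::residuals(lmfit)^2) / stats::df.residual(lmfit)
  s2 * cov
}

# Equal-weight LS-mean contrast vectors (rows of the model matrix averaged
# over all combinations of the other factors) for every level of `factor`.
.lsMeanContrasts <- function(fit, factor) {
  if (!factor %in% fit@factors) {
    stop(sprintf("unknown factor '%s'", factor), call. = FALSE)
  }
  levs <- lapply(fit@data[fit@factors], levels)
  grid <- expand.grid(levs, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (f in fit@factors) grid[[f]] <- base::factor(grid[[f]], levels = levs[[f]])
  form <- stats::delete.response(stats::terms(fit@lmfit))
  X <- stats::model.matrix(form, grid,
    contrasts.arg = stats::setNames(replicate(length(fit@factors), "contr.sum",
                                              simplify = FALSE), fit@factors))
  lapply(levs[[factor]], function(l) {
    colMeans(X[grid[[factor]] == l, , drop = FALSE])
  })
}

#' Least-squares means with standard errors and confidence limits
#'
#' The LS mean of a level is the model prediction at that level averaged
#' with equal weight over all levels of the other factors (not weighted by
#' observed cell frequencies), so unbalanced cells do not distort level
#' comparisons. Standard errors come from the fit's residual variance
#' through the averaging contrast, and the `level` confidence limits use
#' the t quantile at the residual degrees of freedom.
#'
#' @param fit a [MainEffectsFit-class].
#' @param factor name of the factor.
#' @param level confidence level (default 0.95).
#' @return `data.frame(factor, level, mean, se, lower, upper)`.
#' @export
lsMeans <- function(fit, factor, level = 0.95) {
  stopifnot(is(fit, "MainEffectsFit"))
  contrasts <- .lsMeanContrasts(fit, factor)
  beta <- stats::coef(fit@lmfit)
  V <- .fitVcov(fit@lmfit)
  dfRes <- stats::df.residual(fit@lmfit)
  tq <- stats::qt(1 - (1 - level) / 2, dfRes)
  rows <- lapply(seq_along(contrasts), function(i) {
    cvec <- contrasts[[i]]
    m <- sum(cvec * beta)
    se <- sqrt(drop(cvec %*% V %*% cvec))
    data.frame(factor = factor, level = levels(fit@data[[factor]])[i],
               mean = m, se = se, lower = m - tq * se, upper = m + tq * se)
  })
  do.call(rbind, rows)
}

#' Fisher LSD pairwise contrasts
#'
#' All unordered level pairs of one factor, compared by the least
#' significant difference: a pair differs significantly when the absolute
#' difference of its LS means exceeds
#' `LSD = t(1 - alpha/2, df_residual) * SE(difference)`. No multiplicity
#' correction is applied — the per-pair `alpha` risk is the definition of
#' the LSD procedure.
#'
#' @param fit a [MainEffectsFit-class].
#' @param factor name of the factor (>= 2 levels).
#' @param alpha per-pair significance level (default 0.05).
#' @return `data.frame(level1, level2, difference, se, lsd, significant)`
#'   with `difference = LSmean(level1) - LSmean(level2)`.
#' @export
lsdContrasts <- function(fit, factor, alpha = 0.05) {
  stopifnot(is(fit, "MainEffectsFit"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  contrasts <- .lsMeanContrasts(fit, factor)
  levs <- levels(fit@data[[factor]])
  beta <- stats::coef(fit@lmfit)
  V <- .fitVcov(fit@lmfit)
  dfRes <- stats::df.residual(fit@lmfit)
  tq <- stats::qt(1 - alpha / 2, dfRes)
  pairs <- utils::combn(seq_along(levs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- contrasts[[a]] - contrasts[[b]]
    diff <- sum(d * beta)
    se <- sqrt(drop(d %*% V %*% d))
    lsd <- tq * se
    data.frame(level1 = levs[a], level2 = levs[b], difference = diff,
               se = se, lsd = lsd, significant = abs(diff) > lsd)
  })
  do.call(rbind, rows)
}

#' Homogeneous-group letters
#'
#' Assigns the usual compact letter display: levels are sorted by LS mean
#' and each maximal run of consecutive levels containing no significant
#' internal pair shares a letter, so two levels share at least one letter
#' exactly when their pairwise difference is not significant.
#'
#' @param means output of [lsMeans()] for one factor.
#' @param contrasts output of [lsdContrasts()] for the same factor; must
#'   cover all pairs.
#' @return `data.frame(level, mean, groups)` sorted by ascending mean.
#' @examples
#' g <- factorLevels(replicates = 2)
#' tab <- generateResultsTable(g,
#'   effectSpec("F1", 0.6,
#'              factorEffects = list(Ly = c(`1` = 0.03, `2` = 0.02, `3` = -0.05)),
#'              noiseSd = 0.01), seed = 1)
#' fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
#' homogeneousGroups(lsMeans(fit, "Ly"), lsdContrasts(fit, "Ly"))
#' @export
homogeneousGroups <- function(means, contrasts) {
  stopifnot(is.data.frame(means), is.data.frame(contrasts))
  levs <- means$level[order(means$mean)]
  k <- length(levs)
  sig <- matrix(FALSE, k, k, dimnames = list(levs, levs))
  seen <- matrix(FALSE, k, k, dimnames = list(levs, levs))
  for (j in seq_len(nrow(contrasts))) {
    a <- as.character(contrasts$level1[j]); b <- as.character(contrasts$level2[j])
    if (!a %in% levs || !b %in% levs) {
      stop("contrast set refers to unknown levels", call. = FALSE)
    }
    sig[a, b] <- sig[b, a] <- contrasts$significant[j]
    seen[a, b] <- seen[b, a] <- TRUE
  }
  if (k > 1 && !all(seen[upper.tri(seen)])) {
    stop("contrast set does not cover all level pairs", call. = FALSE)
  }
  # maximal runs of consecutive (mean-ordered) levels with no significant
  # internal pair
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  maximal <- Filter(function(iv) {
    !any(vapply(intervals, function(other) {
      !identical(other, iv) && other[1] <= iv[1] && other[2] >= iv[2]
    }, logical(1)))
  }, unique(intervals))
  letterFor <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(maximal, function(iv) iv[1] <= i && i <= iv[2],
                               logical(1)))], collapse = "")
  }, character(1))
  data.frame(level = levs, mean = sort(means$mean), groups = letterFor)
}

#' Full multiple-range report for one factor
#'
#' Convenience wrapper combining [lsMeans()], [lsdContrasts()] and
#' [homogeneousGroups()].
#'
#' @param fit a [MainEffectsFit-class].
#' @param factor factor name.
#' @param alpha per-pair significance level.
#' @return List with `means` (LS means joined with group letters) and
#'   `contrasts`.
#' @export
rangeTest <- function(fit, factor, alpha = 0.05) {
  m <- lsMeans(fit, factor, level = 1 - alpha)
  ctr <- lsdContrasts(fit, factor, alpha = alpha)
  grp <- homogeneousGroups(m, ctr)
  m$groups <- grp$groups[match(m$level, grp$level)]
  list(means = m, contrasts = ctr)
}
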