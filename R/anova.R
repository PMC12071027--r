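# Main-effects ANOVA engine: logit transform, sum-to-zero-coded linear
# model, Type III sums of squares, and residual diagnostics.

#' Logit transformation
#'
#' `logit(p) = ln(p / (1 - p))` maps a proportion in (0, 1) to the whole
#' real line. Bounded responses such as AUC cluster near their bounds,
#' skewing residuals; analyzing them on the logit scale restores symmetry
#' and stabilizes variance.
#'
#' @param p numeric vector strictly inside (0, 1).
#' @return `ln(p / (1 - p))`.
#' @examples
#' logitTransform(0.5)    # 0
#' logitTransform(0.65)   # 0.61904
#' @export
logitTransform <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit is defined only for values strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logitTransform
#' @param x real-valued vector.
#' @return `invLogitTransform` returns `1 / (1 + exp(-x))`.
#' @export
invLogitTransform <- function(x) stats::plogis(x)

#' Fit an additive main-effects model
#'
#' Least-squares fit of a response on additive factor effects with
#' sum-to-zero (effects) coding and no interactions. Factor columns are
#' always treated as categorical, even when their level labels are
#' numeric: the studied levels are discrete design points, not a
#' continuous covariate.
#'
#' @param table results table (`data.frame`).
#' @param response name of the response column.
#' @param factors character vector of factor column names; each must have
#'   at least 2 observed levels.
#' @param transform optional transform applied to the response before
#'   fitting: `"identity"` (default) or `"logit"`.
#' @return A [MainEffectsFit-class].
#' @examples
#' g <- factorLevels(replicates = 2)
#' tab <- generateResultsTable(g, effectSpec("F1", 0.6, noiseSd = 0.01), seed = 1)
#' fit <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
#' residualDf(fit)
#' @export
fitMainEffects <- function(table, response, factors,
                           transform = c("identity", "logit")) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(table))
  missing <- setdiff(c(response, factors), names(table))
  if (length(missing)) {
    stop(sprintf("column(s) not in table: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df <- table[, c(response, factors), drop = FALSE]
  if (transform == "logit") df[[response]] <- logitTransform(df[[response]])
  for (f in factors) {
    # preserve declared levels of factor input so empty levels are caught
    fac <- if (is.factor(df[[f]])) df[[f]] else factor(df[[f]])
    if (nlevels(droplevels(fac)) < 2L) {
      stop(sprintf("factor '%s' has fewer than 2 observed levels", f),
           call. = FALSE)
    }
    empties <- setdiff(levels(fac), levels(droplevels(fac)))
    if (length(empties)) {
      stop(sprintf("factor '%s' has empty level(s): %s", f,
                   paste(empties, collapse = ", ")), call. = FALSE)
    }
    df[[f]] <- fac
  }
  modelDf <- 1L + sum(vapply(df[factors], nlevels, integer(1)) - 1L)
  if (nrow(df) <= modelDf) {
    stop("not enough observations for the model degrees of freedom", call. = FALSE)
  }
  form <- stats::as.formula(paste(response, "~", paste(factors, collapse = " + ")))
  contr <- stats::setNames(replicate(length(factors), "contr.sum", simplify = FALSE),
                           factors)
  lmfit <- stats::lm(form, data = df, contrasts = contr)
  if (anyNA(stats::coef(lmfit))) {
    stop("rank-deficient design after encoding; check for confounded levels",
         call. = FALSE)
  }
  new("MainEffectsFit", lmfit = lmfit, data = df, response = response,
      factors = factors)
}

# Shared assembly of an ANOVA table from per-source components; both the
# fitted Type III route and the printed-components route go through this,
# so MS = SS/df, F = MS/MS_res and p = P(F > F_obs) are computed in one
# place.
.assembleAnovaTable <- function(sources, ss, df, ssRes, dfRes, ssTotal = NULL,
                                dfTotal = NULL) {
  msRes <- ssRes / dfRes
  ms <- ss / df
  f <- ms / msRes
  p <- stats::pf(f, df, dfRes, lower.tail = FALSE)
  out <- data.frame(
    Source = c(sources, "Residual", "Total (corrected)"),
    SumSq = c(ss, ssRes, if (is.null(ssTotal)) NA_real_ else ssTotal),
    Df = c(df, dfRes, if (is.null(dfTotal)) NA_integer_ else dfTotal),
    MeanSq = c(ms, msRes, NA_real_),
    F = c(f, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_))
  rownames(out) <- NULL
  class(out) <- c("anovaTable", "data.frame")
  out
}

#' Type III sums of squares ANOVA
#'
#' For each factor, the Type III sum of squares is the increase in residual
#' sum of squares when that factor's effects are dropped from the full
#' main-effects model while all other factors are retained — the factor's
#' contribution isolated from the others, well-defined under sum-to-zero
#' coding and appropriate for unbalanced designs (after outlier removal
#' the factorial is no longer balanced, and the per-factor SS need not add
#' up to the total SS). `MS = SS/df`, `F = MS/MS_residual`, and p-values
#' come from the F distribution with `(df_factor, df_residual)` degrees of
#' freedom.
#'
#' @param fit a [MainEffectsFit-class].
#' @return A `data.frame` (class `"anovaTable"`) with columns
#'   `Source, SumSq, Df, MeanSq, F, p` and rows for every factor, the
#'   residual and the corrected total.
#' @examples
#' g <- factorLevels(replicates = 2)
#' tab <- generateResultsTable(g,
#'   effectSpec("F1", 0.6,
#'              factorEffects = list(Dp = c(`0.2` = 0.02, `0.5` = 0.01, `0.8` = -0.03)),
#'              noiseSd = 0.01), seed = 1)
#' type3Anova(fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb")))
#' @export
type3Anova <- function(fit) {
  stopifnot(is(fit, "MainEffectsFit"))
  full <- fit@lmfit
  rssFull <- sum(stats::residuals(full)^2)
  contrAll <- stats::setNames(replicate(length(fit@factors), "contr.sum",
                                        simplify = FALSE), fit@factors)
  ss <- df <- numeric(length(fit@factors))
  for (i in seq_along(fit@factors)) {
    others <- fit@factors[-i]
    form <- stats::as.formula(paste(fit@response, "~",
      if (length(others)) paste(others, collapse = " + ") else "1"))
    red <- stats::lm(form, data = fit@data,
                     contrasts = if (length(others)) contrAll[others] else NULL)
    ss[i] <- sum(stats::residuals(red)^2) - rssFull
    df[i] <- nlevels(fit@data[[fit@factors[i]]]) - 1L
  }
  y <- fit@data[[fit@response]]
  .assembleAnovaTable(fit@factors, pmax(ss, 0), df,
                      rssFull, stats::df.residual(full),
                      ssTotal = sum((y - mean(y))^2),
                      dfTotal = length(y) - 1L)
}

#' Assemble an ANOVA table from known components
#'
#' Computes the derivable cells (`MS = SS/df`, `F = MS/MS_residual`, and
#' F-distribution p-values) from per-source sums of squares and degrees of
#' freedom — the arithmetic that turns published SS/df components into a
#' complete table.
#'
#' @param sources character vector of factor names.
#' @param ss,df per-source sums of squares and degrees of freedom.
#' @param ssRes,dfRes residual sum of squares and degrees of freedom.
#' @param ssTotal,dfTotal optional corrected-total components.
#' @return Same layout as [type3Anova()].
#' @examples
#' anovaTableFromComponents("Ly", ss = 0.224158, df = 2,
#'                          ssRes = 2.99578, dfRes = 849)
#' @export
anovaTableFromComponents <- function(sources, ss, df, ssRes, dfRes,
                                     ssTotal = NULL, dfTotal = NULL) {
  stopifnot(length(sources) == length(ss), length(ss) == length(df),
            all(ss >= 0), all(df >= 1), ssRes >= 0, dfRes >= 1)
  .assembleAnovaTable(sources, ss, df, ssRes, dfRes, ssTotal, dfTotal)
}

#' @export
print.anovaTable <- function(x, ...) {
  cat("Type III Sums of Squares\n")
  y <- x
  y$p <- format.pval(y$p, digits = 4, eps = 1e-4)
  print.data.frame(format(y, digits = 6), row.names = FALSE)
  invisible(x)
}

#' Residual diagnostics for a main-effects fit
#'
#' Bundles the standard ANOVA-assumption checks: (predicted, residual)
#' pairs for the homoscedasticity scatter, theoretical-vs-ordered residual
#' quantile pairs for the Q-Q plot, the Shapiro-Wilk normality test on the
#' residuals, and the median-centred Levene test of variance homogeneity
#' across design cells.
#'
#' @param fit a [MainEffectsFit-class].
#' @return A list of class `"residualDiagnostics"`: `predicted`,
#'   `residuals`, `qq` (`data.frame(theoretical, sample)`), `shapiro`
#'   (`htest` or `NULL` with a warning when n is outside 3..5000), and
#'   `levene` (`data.frame` from [car::leveneTest()]).
#' @export
residualDiagnostics <- function(fit) {
  stopifnot(is(fit, "MainEffectsFit"))
  res <- unname(stats::residuals(fit@lmfit))
  pred <- unname(stats::fitted(fit@lmfit))
  n <- length(res)
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
                   sample = sort(res))
  shapiro <- if (n >= 3 && n <= 5000) {
    stats::shapiro.test(res)
  } else {
    warning("Shapiro-Wilk omitted: sample size outside 3..5000")
    NULL
  }
  cellFactor <- interaction(fit@data[fit@factors], drop = TRUE)
  levene <- if (nlevels(cellFactor) >= 2 && n > nlevels(cellFactor)) {
    car::leveneTest(res, group = cellFactor, center = stats::median)
  } else {
    warning("Levene test omitted: not enough cells or replicates")
    NULL
  }
  structure(list(predicted = pred, residuals = res, qq = qq,
                 shapiro = shapiro, levene = levene),
            class = "residualDiagnostics")
}

#' @export
print.residualDiagnostics <- function(x, ...) {
  cat(sprintf("Residual diagnostics (n = %d)\n", length(x$residuals)))
  if (!is.null(x$shapiro)) {
    cat(sprintf("  Shapiro-Wilk: W = %.4f, p = %.4g\n",
                x$shapiro$statistic, x$shapiro$p.value))
  }
  if (!is.null(x$levene)) {
    cat(sprintf("  Levene (median-centred): F = %.4f, p = %.4g\n",
                x$levene[1, "F value"], x$levene[1, "Pr(>F)"]))
  }
  invisible(x)
}
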