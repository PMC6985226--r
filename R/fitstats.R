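#' Root mean square error of approximation
#'
#' `sqrt(max(0, (T - df) / (df * (N - 1))))`. The `N - 1` denominator
#' reproduces conventional printed values; the `N` convention is available
#' via `nConvention`.
#'
#' @param T chi-square statistic.
#' @param df model degrees of freedom (> 0).
#' @param N sample size (> 1).
#' @param nConvention `"N-1"` (default) or `"N"`.
#' @return RMSEA point estimate.
#' @export
rmsea <- function(T, df, N, nConvention = c("N-1", "N")) {
  nConvention <- match.arg(nConvention)
  if (df <= 0) stop("RMSEA is undefined for df = 0")
  if (N <= 1) stop("RMSEA requires N > 1")
  n <- if (nConvention == "N-1") N - 1 else N
  sqrt(max(0, (T - df) / (df * n)))
}

#' Noncentral confidence interval for RMSEA
#'
#' Bounds are `sqrt(lambda / (df * (N - 1)))` where the noncentrality
#' `lambda` solves the noncentral chi-square tail equations
#' `P(chisq_df(lambda_lo) >= T) = (1 + coverage) / 2` and
#' `P(chisq_df(lambda_hi) >= T) = (1 - coverage) / 2`, clipped at zero.
#'
#' @inheritParams rmsea
#' @param coverage interval coverage (default 0.90).
#' @return numeric `c(lo, hi)`.
#' @export
rmseaCI <- function(T, df, N, coverage = 0.90, nConvention = c("N-1", "N")) {
  nConvention <- match.arg(nConvention)
  if (df <= 0) stop("RMSEA CI is undefined for df = 0")
  n <- if (nConvention == "N-1") N - 1 else N
  lambdaRoot <- function(prob) {
    ## solve pchisq(T, df, ncp = lambda) = prob in lambda (decreasing)
    f <- function(l) pchisq(T, df, ncp = l) - prob
    if (f(0) < 0) return(0)  # even lambda = 0 puts too little mass below T
    hi <- max(2 * (T - df), T, 1)
    tries <- 0L
    while (f(hi) > 0 && tries < 60L) { hi <- hi * 2; tries <- tries + 1L }
    if (f(hi) > 0) {
      warning("noncentrality root not bracketed; using expanded bracket endpoint")
      return(hi)
    }
    uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  lo <- lambdaRoot((1 + coverage) / 2)
  hi <- lambdaRoot((1 - coverage) / 2)
  c(lo = sqrt(max(0, lo) / (df * n)), hi = sqrt(max(0, hi) / (df * n)))
}

#' Comparative fit index
#'
#' `1 - max(T - df, 0) / max(T_base - df_base, T - df, 0)` against the
#' independence baseline (free means and variances, zero covariances)
#' fitted to the same data; returns 1 when both noncentralities truncate
#' to zero.
#'
#' @param T,df model statistic and degrees of freedom.
#' @param Tbase,dfBase baseline statistic and degrees of freedom.
#' @return CFI in `[0, 1]`.
#' @export
cfi <- function(T, df, Tbase, dfBase) {
  if (dfBase <= df) stop("baseline must be more restrictive than the model (dfBase > df)")
  num <- max(T - df, 0)
  den <- max(Tbase - dfBase, T - df, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' Satorra-Bentler scaled chi-square difference
#'
#' For model 0 nested in model 1 (more constrained, `df0 > df1`) with
#' scaling factors `c0`, `c1`:
#' `cd = (df0 * c0 - df1 * c1) / (df0 - df1)` and
#' `T_scaled = (T0 * c0 - T1 * c1) / cd`. With both scaling factors 1 this
#' reduces to the ordinary difference. A negative statistic (possible in the
#' scaled form) is returned with a warning flag rather than suppressed.
#'
#' @param T0,df0,c0 statistic, df and scaling factor of the constrained model.
#' @param T1,df1,c1 the less constrained model.
#' @return list `Tdiff`, `dfDiff`, `cd`, `p`, `warning` (character or NA).
#' @export
sbScaledDiff <- function(T0, df0, c0 = 1, T1, df1, c1 = 1) {
  if (df0 <= df1) stop("model 0 must be nested in model 1 (df0 > df1)")
  dfDiff <- df0 - df1
  cd <- (df0 * c0 - df1 * c1) / dfDiff
  if (cd <= 0) stop("degenerate scaled-difference correction: cd <= 0")
  Tdiff <- (T0 * c0 - T1 * c1) / cd
  warn <- NA_character_
  if (Tdiff < 0) warn <- "negative scaled difference statistic"
  p <- if (Tdiff >= 0) pchisq(Tdiff, dfDiff, lower.tail = FALSE) else NA_real_
  list(Tdiff = Tdiff, dfDiff = dfDiff, cd = cd, p = p, warning = warn)
}

#' Fit statistics for a fitted model
#'
#' Assembles T, df, scaling factor, RMSEA with 90% noncentral CI and CFI
#' (against the independence baseline computed on the same panel during
#' fitting).
#'
#' @param fit a [SemFit-class].
#' @param coverage RMSEA interval coverage.
#' @return list of class `FitStatistics`: `T`, `df`, `c`, `rmsea`,
#'   `rmsea.ci` (lo, hi), `cfi`, `N`.
#' @export
fitStatistics <- function(fit, coverage = 0.90) {
  base <- fit@details$baseline
  out <- list(T = fit@T, df = fit@df, c = fit@scaling, N = fit@N)
  if (fit@df > 0) {
    out$rmsea <- rmsea(fit@T, fit@df, fit@N)
    out$rmsea.ci <- rmseaCI(fit@T, fit@df, fit@N, coverage)
  } else {
    out$rmsea <- 0
    out$rmsea.ci <- c(lo = 0, hi = 0)
  }
  out$cfi <- if (!is.null(base)) cfi(fit@T, fit@df, base$T, base$df) else NA_real_
  class(out) <- "FitStatistics"
  out
}

#' @export
print.FitStatistics <- function(x, ...) {
  cat(sprintf("T = %.3f, df = %g, c = %.3f, N = %d\n", x$T, x$df, x$c, x$N))
  cat(sprintf("RMSEA = %.3f (90%% CI: %.3f-%.3f), CFI = %.3f\n",
              x$rmsea, x$rmsea.ci[1], x$rmsea.ci[2], x$cfi))
  invisible(x)
}

#' Standardize a single coefficient
#'
#' `stdyx` multiplies by `SD(predictor)/SD(outcome)`; `stdy` (for binary
#' or dummy predictors) divides by `SD(outcome)` only.
#'
#' @param b raw coefficient.
#' @param sdOutcome model-implied outcome SD (> 0).
#' @param sdPredictor predictor SD (ignored for `stdy`).
#' @param style `"stdyx"` or `"stdy"`.
#' @return standardized coefficient.
#' @export
stdCoef <- function(b, sdOutcome, sdPredictor = NA_real_,
                    style = c("stdyx", "stdy")) {
  style <- match.arg(style)
  if (!is.finite(sdOutcome) || sdOutcome <= 0)
    stop("outcome SD must be positive")
  if (style == "stdyx") b * sdPredictor / sdOutcome else b / sdOutcome
}
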