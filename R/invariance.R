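## Measurement-model builders for the longitudinal one-factor model under
## effects-coding identification: per occasion the loadings sum to the
## number of items and the intercepts sum to zero, leaving latent means and
## variances free at every occasion. The intercept constraint is imposed per
## occasion while intercepts are occasion-specific (configural/weak); once
## intercepts are (partially) equal across occasions the occasion-1
## constraint identifies the remaining latent means through the invariant
## items, which keeps the degrees-of-freedom ladder exact
## (each cross-occasion equality of one loading or intercept over three
## occasions contributes 2 df; 12 items give 22).

.buildMeasurementSpec <- function(nItems = 12L, nOccasions = 3L,
                                  loadings = c("occasion", "shared"),
                                  intercepts = c("occasion", "shared", "partial"),
                                  freedItems = integer(),
                                  residualLagCov = TRUE,
                                  description = NULL) {
  loadings <- match.arg(loadings)
  intercepts <- match.arg(intercepts)
  if (nItems < 3) stop("under-identified measurement model: need at least 3 items")
  p <- nItems; noc <- nOccasions
  obs <- panelColumnNames(p, noc)
  lat <- paste0("eta", seq_len(noc))
  b <- .newSpecBuilder(obs, lat)
  col <- function(j, t) (t - 1L) * p + j

  ## loadings with per-occasion sum-to-p constraint; item p is dependent
  for (t in seq_len(noc)) {
    labs <- character(p - 1)
    for (j in seq_len(p - 1)) {
      labs[j] <- if (loadings == "shared") sprintf("lam_%d", j) else sprintf("lam_%d_%d", j, t)
      .bPar(b, "Lambda", col(j, t), t, labs[j], start = 1)
    }
    .bDep(b, "Lambda", col(p, t), t, const = p, labels = labs, coefs = rep(-1, p - 1))
  }

  ## intercepts
  if (intercepts == "occasion") {
    for (t in seq_len(noc)) {
      labs <- sprintf("tau_%d_%d", seq_len(p - 1), t)
      for (j in seq_len(p - 1)) .bPar(b, "Tau", col(j, t), 1, labs[j], start = 0)
      .bDep(b, "Tau", col(p, t), 1, const = 0, labels = labs, coefs = rep(-1, p - 1))
    }
  } else if (intercepts == "shared") {
    labs <- sprintf("tau_%d", seq_len(p - 1))
    for (t in seq_len(noc)) {
      for (j in seq_len(p - 1)) .bPar(b, "Tau", col(j, t), 1, labs[j], start = 0)
      .bDep(b, "Tau", col(p, t), 1, const = 0, labels = labs, coefs = rep(-1, p - 1))
    }
  } else {
    freedItems <- sort(unique(as.integer(freedItems)))
    if (length(freedItems) >= p)
      stop("at least one intercept must remain invariant")
    inv <- setdiff(seq_len(p), freedItems)
    dep <- max(inv)
    invFree <- setdiff(inv, dep)
    ## occasion-1 constraint only: tau_dep = -(sum invariant free + sum freed at t1)
    depLabs <- c(sprintf("tau_%d", invFree), sprintf("tau_%d_1", freedItems))
    for (j in invFree)
      for (t in seq_len(noc)) .bPar(b, "Tau", col(j, t), 1, sprintf("tau_%d", j), start = 0)
    for (f in freedItems)
      for (t in seq_len(noc)) .bPar(b, "Tau", col(f, t), 1, sprintf("tau_%d_%d", f, t), start = 0)
    for (t in seq_len(noc))
      .bDep(b, "Tau", col(dep, t), 1, const = 0, labels = depLabs,
            coefs = rep(-1, length(depLabs)))
  }

  ## residual variances, and same-item covariances across occasions
  for (t in seq_len(noc))
    for (j in seq_len(p))
      .bPar(b, "Theta", col(j, t), col(j, t), sprintf("thd_%d_%d", j, t), start = 0.4)
  if (residualLagCov && noc > 1) {
    for (j in seq_len(p))
      for (t1 in seq_len(noc - 1)) for (t2 in (t1 + 1):noc)
        .bPar(b, "Theta", col(j, t2), col(j, t1),
              sprintf("thc_%d_%d_%d", j, t1, t2), start = 0.05)
  }

  ## latent moments: free means/variances at all occasions, free covariances
  for (t in seq_len(noc)) {
    .bPar(b, "Alpha", t, 1, sprintf("lmean_%d", t), start = 2.5)
    .bPar(b, "Psi", t, t, sprintf("lvar_%d", t), start = 0.5)
  }
  if (noc > 1)
    for (t1 in seq_len(noc - 1)) for (t2 in (t1 + 1):noc)
      .bPar(b, "Psi", t2, t1, sprintf("lcov_%d_%d", t1, t2), start = 0.2)

  .bSpec(b, meta = list(
    description = description %||%
      sprintf("one-factor longitudinal measurement model (%s loadings, %s intercepts)",
              loadings, intercepts),
    geometry = list(nItems = p, nOccasions = noc, basis = NULL),
    measurement = list(loadings = loadings, intercepts = intercepts,
                       freedItems = freedItems, residualLagCov = residualLagCov)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the measurement-invariance model ladder
#'
#' Returns the ordered configural / weak / strong specifications for a
#' one-factor scale measured at several occasions under effects coding:
#' configural frees loadings and intercepts per occasion, weak equates
#' loadings across occasions, strong additionally equates intercepts.
#' Latent means and variances stay free at every occasion.
#'
#' @param nItems number of items (>= 3).
#' @param nOccasions number of occasions.
#' @param residualLagCov free same-item residual covariances across
#'   occasions (standard longitudinal practice; default TRUE).
#' @return named list of [ModelSpec-class]: `configural`, `weak`, `strong`.
#' @export
buildLadder <- function(nItems = 12L, nOccasions = 3L, residualLagCov = TRUE) {
  list(
    configural = .buildMeasurementSpec(nItems, nOccasions, "occasion", "occasion",
                                       residualLagCov = residualLagCov,
                                       description = "configural invariance"),
    weak = .buildMeasurementSpec(nItems, nOccasions, "shared", "occasion",
                                 residualLagCov = residualLagCov,
                                 description = "weak invariance (equal loadings)"),
    strong = .buildMeasurementSpec(nItems, nOccasions, "shared", "shared",
                                   residualLagCov = residualLagCov,
                                   description = "strong invariance (equal loadings and intercepts)")
  )
}

#' Partial strong invariance specification
#'
#' Strong-invariance model with the intercepts of `freedItems` estimated
#' per occasion (loadings stay invariant). At least one intercept must
#' remain invariant.
#'
#' @inheritParams buildLadder
#' @param freedItems integer item indices freed across occasions.
#' @return a [ModelSpec-class].
#' @export
partialStrongSpec <- function(freedItems, nItems = 12L, nOccasions = 3L,
                              residualLagCov = TRUE) {
  .buildMeasurementSpec(nItems, nOccasions, "shared", "partial",
                        freedItems = freedItems,
                        residualLagCov = residualLagCov,
                        description = sprintf("partial strong invariance (freed: %s)",
                                              paste(freedItems, collapse = ", ")))
}

## Transfer estimates between specs: read each new label's value from the
## built matrices of the previous fit at the label's exclusive cell,
## matching cells by observed/latent variable names (the two specs need not
## share dimensions).
.embedTheta <- function(newSpec, oldSpec, oldTheta) {
  oldMats <- .buildMats(oldSpec, oldTheta)
  rowSpace <- c(Lambda = "obs", Tau = "obs", Theta = "obs",
                B = "lat", Alpha = "lat", Psi = "lat")
  colSpace <- c(Lambda = "lat", Tau = "one", Theta = "obs",
                B = "lat", Alpha = "one", Psi = "lat")
  nms <- function(spec, space) switch(space, obs = spec@obsNames,
                                      lat = spec@latNames, one = NULL)
  theta <- newSpec@start
  asn <- newSpec@assign
  cellCount <- table(paste(asn$mat, asn$idx))
  for (k in seq_along(newSpec@labels)) {
    rows <- which(asn$lab == k & abs(asn$coef - 1) < 1e-12)
    for (r in rows) {
      if (cellCount[[paste(asn$mat[r], asn$idx[r])]] != 1L) next
      mat <- asn$mat[r]
      nr <- nrow(newSpec@mats[[mat]])
      i <- (asn$idx[r] - 1L) %% nr + 1L
      j <- (asn$idx[r] - 1L) %/% nr + 1L
      rNew <- nms(newSpec, rowSpace[[mat]]); cNew <- nms(newSpec, colSpace[[mat]])
      oi <- if (is.null(rNew)) i else match(rNew[i], nms(oldSpec, rowSpace[[mat]]))
      oj <- if (is.null(cNew)) j else match(cNew[j], nms(oldSpec, colSpace[[mat]]))
      if (is.na(oi) || is.na(oj)) next
      theta[k] <- oldMats[[mat]][oi, oj]
      break
    }
  }
  theta
}

#' Rules for the invariance decision
#'
#' A level is accepted when the CFI decrease relative to the previous
#' accepted level does not exceed `deltaCfiMax` and (if
#' `useRmseaCIOverlap`) the new RMSEA lies inside the previous level's 90%
#' CI. The scaled chi-square difference is computed and reported but is not
#' decisive.
#'
#' @param deltaCfiMax maximal tolerated CFI decrease (default 0.01).
#' @param useRmseaCIOverlap require the new RMSEA inside the previous CI.
#' @param alpha significance level annotated on the difference tests.
#' @return list of rules.
#' @export
invarianceRules <- function(deltaCfiMax = 0.01, useRmseaCIOverlap = TRUE,
                            alpha = 0.05) {
  list(deltaCfiMax = deltaCfiMax, useRmseaCIOverlap = useRmseaCIOverlap,
       alpha = alpha)
}

.ruleDecision <- function(prevStats, newStats, rules) {
  dCfi <- prevStats$cfi - newStats$cfi
  inCI <- newStats$rmsea >= prevStats$rmsea.ci[1] - 1e-12 &&
    newStats$rmsea <= prevStats$rmsea.ci[2] + 1e-12
  accept <- dCfi <= rules$deltaCfiMax && (!rules$useRmseaCIOverlap || inCI)
  fired <- if (accept) {
    "accept: deltaCFI within bound and RMSEA within previous CI"
  } else if (dCfi > rules$deltaCfiMax && rules$useRmseaCIOverlap && !inCI) {
    "reject: deltaCFI exceeded and RMSEA outside previous CI"
  } else if (dCfi > rules$deltaCfiMax) {
    "reject: deltaCFI exceeded"
  } else {
    "reject: RMSEA outside previous CI"
  }
  list(accept = accept, deltaCfi = dCfi, rmseaInPrevCI = inCI, rule = fired)
}

#' Run the measurement-invariance ladder
#'
#' Fits configural, weak and strong models in sequence, applying the
#' acceptance rules between consecutive levels; on strong-level rejection a
#' greedy modification-index-driven partial search frees intercepts until
#' the rules pass (or no acceptable partial model exists).
#'
#' @param panel an [ItemPanel-class].
#' @param rules see [invarianceRules()].
#' @param residualLagCov passed to the builders.
#' @param robust compute sandwich scaling factors and use them in the
#'   difference tests (slower; plain ML otherwise).
#' @param seed integer, recorded and used for optimizer restarts.
#' @return an `InvarianceReport` list: per-level `FitStatistics`,
#'   comparison table, decisions, freed-intercept list, final accepted
#'   specification and fits.
#' @export
runLadder <- function(panel, rules = invarianceRules(), residualLagCov = TRUE,
                      robust = FALSE, seed = 1L) {
  ladder <- buildLadder(nItems(panel), nOccasions(panel), residualLagCov)
  se <- if (robust) "robust" else "none"
  Y <- .panelData(panel, ladder$configural@obsNames)
  prep <- .fimlPrep(Y)
  sat <- .saturatedFit(prep)
  basel <- .baselineFit(prep)

  fits <- list(); stats <- list(); comparisons <- list(); decisions <- list()
  prevFit <- NULL
  aborted <- NULL
  for (lev in c("configural", "weak", "strong")) {
    startv <- if (!is.null(prevFit))
      .embedTheta(ladder[[lev]], prevFit@spec, prevFit@theta) else NULL
    fit <- fitML(ladder[[lev]], panel, start = startv, se = se, seed = seed,
                 satLoglik = sat$loglik, baseline = basel)
    fits[[lev]] <- fit
    stats[[lev]] <- fitStatistics(fit)
    if (!fit@converged) { aborted <- lev; break }
    if (!is.null(prevFit)) {
      sb <- sbScaledDiff(fit@T, fit@df, fit@scaling,
                         prevFit@T, prevFit@df, prevFit@scaling)
      dec <- .ruleDecision(stats[[length(stats) - 1L]], stats[[lev]], rules)
      comparisons[[paste(lev, "vs previous")]] <- c(sb, dec)
      decisions[[lev]] <- dec
      if (!dec$accept && lev == "weak") {
        ## the ladder cannot proceed past a rejected weak level
        aborted <- NULL
      }
    }
    prevFit <- fit
  }

  freed <- integer(); partialFit <- NULL; partialOK <- NA
  if (is.null(aborted) && !is.null(decisions$strong) && !decisions$strong$accept) {
    ps <- partialSearch(panel, fits$strong, stats$weak, rules,
                        residualLagCov = residualLagCov, seed = seed,
                        prep = prep, satLoglik = sat$loglik, baseline = basel,
                        robust = robust)
    freed <- ps$freedItems
    partialFit <- ps$fit
    partialOK <- ps$acceptable
    if (!is.null(ps$fit)) {
      fits$partial <- ps$fit
      stats$partial <- fitStatistics(ps$fit)
      sb <- sbScaledDiff(ps$fit@T, ps$fit@df, ps$fit@scaling,
                         fits$weak@T, fits$weak@df, fits$weak@scaling)
      comparisons[["partial vs weak"]] <- c(sb, ps$decision)
    }
  }

  finalLevel <- if (!is.null(aborted)) NA_character_
  else if (!is.null(decisions$strong) && decisions$strong$accept) "strong"
  else if (isTRUE(partialOK)) "partial"
  else if (!is.null(decisions$weak) && decisions$weak$accept) "weak"
  else "configural"

  out <- list(levels = stats, fits = fits, comparisons = comparisons,
              decisions = decisions, freedItems = freed,
              finalLevel = finalLevel, aborted = aborted,
              rules = rules, seed = seed,
              finalSpec = if (identical(finalLevel, "partial")) partialFit@spec
                          else if (!is.na(finalLevel)) fits[[finalLevel]]@spec else NULL)
  class(out) <- "InvarianceReport"
  out
}

#' @export
print.InvarianceReport <- function(x, ...) {
  cat("Measurement-invariance ladder\n")
  for (lev in names(x$levels)) {
    s <- x$levels[[lev]]
    cat(sprintf("  %-10s T = %8.2f  df = %4g  RMSEA = %.3f (%.3f-%.3f)  CFI = %.3f\n",
                lev, s$T, s$df, s$rmsea, s$rmsea.ci[1], s$rmsea.ci[2], s$cfi))
  }
  if (length(x$freedItems))
    cat("  freed intercepts (in order):", paste(x$freedItems, collapse = ", "), "\n")
  cat("  final level:", x$finalLevel, "\n")
  invisible(x)
}

#' Greedy partial-invariance search
#'
#' Starting from a rejected strong model, repeatedly frees the
#' cross-occasion intercept constraint with the largest modification index,
#' refits, and stops when the acceptance rules pass against the weak-level
#' statistics. At least one intercept always remains invariant; if the
#' floor is reached without acceptance the result is flagged as having no
#' acceptable partial model.
#'
#' @param panel an [ItemPanel-class].
#' @param strongFit the fitted (rejected) strong model.
#' @param weakStats `FitStatistics` of the weak model (reference level).
#' @param rules see [invarianceRules()].
#' @param residualLagCov,robust,seed as in [runLadder()].
#' @param prep,satLoglik,baseline optional precomputed internals.
#' @return list: `freedItems` (in freeing order), `fit`, `acceptable`,
#'   `decision`, `trace` (per-step MI tables).
#' @export
partialSearch <- function(panel, strongFit, weakStats, rules = invarianceRules(),
                          residualLagCov = TRUE, robust = FALSE, seed = 1L,
                          prep = NULL, satLoglik = NULL, baseline = NULL) {
  geom <- strongFit@spec@meta$geometry
  p <- geom$nItems
  if (is.null(prep)) prep <- .fimlPrep(.panelData(panel, strongFit@spec@obsNames))
  if (is.null(satLoglik)) satLoglik <- .saturatedFit(prep)$loglik
  if (is.null(baseline)) baseline <- .baselineFit(prep)
  se <- if (robust) "robust" else "none"
  freed <- integer()
  fit <- strongFit
  trace <- list()
  decision <- NULL
  repeat {
    inv <- setdiff(seq_len(p), freed)
    if (length(inv) <= 1L)
      return(list(freedItems = freed, fit = fit, acceptable = FALSE,
                  decision = decision, trace = trace,
                  message = "no acceptable partial model (invariant-intercept floor reached)"))
    cands <- setNames(lapply(inv, function(j)
      partialStrongSpec(sort(c(freed, j)), p, geom$nOccasions, residualLagCov)),
      paste0("item", inv))
    mi <- modificationIndices(fit, cands, prep = prep)
    trace[[length(trace) + 1L]] <- mi
    best <- mi$candidate[which.max(mi$mi)]
    j <- as.integer(sub("item", "", best))
    freed <- sort(c(freed, j))
    startv <- .embedTheta(cands[[best]], fit@spec, fit@theta)
    fit <- fitML(cands[[best]], panel, start = startv, se = se, seed = seed,
                 satLoglik = satLoglik, baseline = baseline)
    st <- fitStatistics(fit)
    decision <- .ruleDecision(weakStats, st, rules)
    if (decision$accept)
      return(list(freedItems = freed, fit = fit, acceptable = TRUE,
                  decision = decision, trace = trace))
  }
}

#' Standardized residual moments
#'
#' Difference between saturated (FIML-estimated) and model-implied moments,
#' residual covariances standardized by the implied standard deviations --
#' the "inspect the residuals" companion to the modification indices.
#'
#' @param fit a [SemFit-class].
#' @param panel the panel it was fitted to.
#' @return list with `meanResiduals` and `stdResidualCov`.
#' @export
residualMoments <- function(fit, panel) {
  prep <- .fimlPrep(.panelData(panel, fit@spec@obsNames))
  sat <- .saturatedFit(prep)
  imp <- impliedMoments(fit@spec, fit@theta)
  sdv <- sqrt(diag(imp$Sigma))
  list(meanResiduals = (sat$mu - imp$mu) / sdv,
       stdResidualCov = (sat$Sigma - imp$Sigma) / tcrossprod(sdv))
}
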