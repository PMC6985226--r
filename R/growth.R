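#' Growth-curve structure specification
#'
#' Describes the second-order growth factors placed on top of the occasion
#' factors: loadings of the intercept factor are all 1; the slope basis is
#' a fixed vector (default `c(0, 0.5, 1)`, i.e. occasions on a 0-1 span) or
#' a latent-basis pattern with fixed endpoints and free interior loadings.
#'
#' @param basis numeric slope loadings per occasion.
#' @param latentBasis if TRUE, interior basis entries are estimated and the
#'   two endpoints stay fixed.
#' @return list of class `GrowthSpec`.
#' @export
growthSpec <- function(basis = c(0, 0.5, 1), latentBasis = FALSE) {
  if (length(basis) < 2) stop("slope basis needs at least two occasions")
  nFixed <- if (latentBasis) 2L else length(basis)
  if (nFixed < 2) stop("identification requires at least two fixed basis values")
  structure(list(basis = basis, latentBasis = latentBasis), class = "GrowthSpec")
}

#' Build a second-order latent growth curve model
#'
#' Places intercept and slope factors on the occasion factors of an
#' accepted (partial-)strong measurement model: first-order latent
#' intercepts are fixed to 0 so the growth factors absorb the means under
#' effects coding; occasion disturbances are free and uncorrelated.
#' Time-invariant covariates (numeric, or factors dummy-coded against their
#' reference level) regress onto both growth factors; their own moments are
#' fixed at the sample values (exogenous conditioning). An optional
#' `predictor` slot (used by the voxel-wise stage) adds one more exogenous
#' variable regressed on the slope and/or intercept.
#'
#' @param miSpec accepted measurement model (shared loadings; shared or
#'   partial intercepts).
#' @param growth a [growthSpec()].
#' @param covariates character, covariate column names as produced by
#'   [covariateDesign()].
#' @param panel the [ItemPanel-class] supplying covariate sample moments
#'   (required when covariates or a predictor are present).
#' @param predictor optional name of an extra exogenous predictor column.
#' @param predictorTarget `"slope"`, `"intercept"` or `"both"`.
#' @return a [ModelSpec-class].
#' @export
buildLGCM <- function(miSpec, growth = growthSpec(), covariates = character(),
                      panel = NULL, predictor = NULL,
                      predictorTarget = c("slope", "intercept", "both")) {
  predictorTarget <- match.arg(predictorTarget)
  ms <- miSpec@meta$measurement
  geom <- miSpec@meta$geometry
  if (is.null(ms) || ms$loadings != "shared" || ms$intercepts == "occasion")
    stop("miSpec must be a (partial-)strong invariance measurement model")
  noc <- geom$nOccasions; p <- geom$nItems
  if (length(growth$basis) != noc) stop("basis length must match occasions")
  if (!growth$latentBasis && sum(!is.na(growth$basis)) < 2)
    stop("identification error: slope basis needs >= 2 fixed values")

  exo <- c(covariates, predictor)
  if (length(exo) && is.null(panel))
    stop("panel is required to fix exogenous covariate moments")

  obs <- c(panelColumnNames(p, noc), exo)
  lat <- c(paste0("eta", seq_len(noc)), "icept", "slope", exo)
  b <- .newSpecBuilder(obs, lat, exoNames = exo)
  col <- function(j, t) (t - 1L) * p + j

  ## measurement part: rebuild with the accepted invariance structure
  for (t in seq_len(noc)) {
    labs <- sprintf("lam_%d", seq_len(p - 1))
    for (j in seq_len(p - 1)) .bPar(b, "Lambda", col(j, t), t, labs[j], start = 1)
    .bDep(b, "Lambda", col(p, t), t, const = p, labels = labs, coefs = rep(-1, p - 1))
  }
  freed <- ms$freedItems
  if (ms$intercepts == "shared" || !length(freed)) {
    labs <- sprintf("tau_%d", seq_len(p - 1))
    for (t in seq_len(noc)) {
      for (j in seq_len(p - 1)) .bPar(b, "Tau", col(j, t), 1, labs[j], start = 0)
      .bDep(b, "Tau", col(p, t), 1, const = 0, labels = labs, coefs = rep(-1, p - 1))
    }
  } else {
    inv <- setdiff(seq_len(p), freed)
    dep <- max(inv)
    invFree <- setdiff(inv, dep)
    depLabs <- c(sprintf("tau_%d", invFree), sprintf("tau_%d_1", freed))
    for (j in invFree)
      for (t in seq_len(noc)) .bPar(b, "Tau", col(j, t), 1, sprintf("tau_%d", j), start = 0)
    for (f in freed)
      for (t in seq_len(noc)) .bPar(b, "Tau", col(f, t), 1, sprintf("tau_%d_%d", f, t), start = 0)
    for (t in seq_len(noc))
      .bDep(b, "Tau", col(dep, t), 1, const = 0, labels = depLabs,
            coefs = rep(-1, length(depLabs)))
  }
  for (t in seq_len(noc))
    for (j in seq_len(p))
      .bPar(b, "Theta", col(j, t), col(j, t), sprintf("thd_%d_%d", j, t), start = 0.4)
  if (ms$residualLagCov && noc > 1)
    for (j in seq_len(p))
      for (t1 in seq_len(noc - 1)) for (t2 in (t1 + 1):noc)
        .bPar(b, "Theta", col(j, t2), col(j, t1),
              sprintf("thc_%d_%d_%d", j, t1, t2), start = 0.05)

  ## growth structure: eta_t = icept + basis_t * slope + disturbance
  iI <- noc + 1L; iS <- noc + 2L
  for (t in seq_len(noc)) {
    .bFix(b, "B", t, iI, 1)
    if (growth$latentBasis && t > 1 && t < noc) {
      .bPar(b, "B", t, iS, sprintf("basis_%d", t), start = growth$basis[t])
    } else {
      .bFix(b, "B", t, iS, growth$basis[t])
    }
    .bPar(b, "Psi", t, t, sprintf("dist_%d", t), start = 0.1)
    ## Alpha for eta_t fixed at 0 (absorbed by the growth factors)
  }
  .bPar(b, "Alpha", iI, 1, "gmean_icept", start = 2.5)
  .bPar(b, "Alpha", iS, 1, "gmean_slope", start = -0.2)
  .bPar(b, "Psi", iI, iI, "gvar_icept", start = 0.5)
  .bPar(b, "Psi", iS, iS, "gvar_slope", start = 0.1)
  .bPar(b, "Psi", iS, iI, "gcov_is", start = -0.05)

  ## exogenous block: identity measurement, moments fixed at sample values
  if (length(exo)) {
    X <- .panelData(panel, exo)
    if (anyNA(X)) stop("exogenous covariates must be complete")
    mx <- colMeans(X)
    Sx <- crossprod(sweep(X, 2L, mx)) / nrow(X)  # ML (1/N) convention
    for (k in seq_along(exo)) {
      io <- p * noc + k; il <- noc + 2L + k
      .bFix(b, "Lambda", io, il, 1)
      .bFix(b, "Alpha", il, 1, mx[k])
      for (k2 in seq_len(k)) .bFix(b, "Psi", il, noc + 2L + k2, Sx[k, k2])
      targets <- if (!is.null(predictor) && exo[k] == predictor) {
        switch(predictorTarget, slope = iS, intercept = iI, both = c(iI, iS))
      } else c(iI, iS)
      for (tg in targets)
        .bPar(b, "B", tg, il,
              sprintf("b_%s_%s", exo[k], if (tg == iI) "icept" else "slope"),
              start = 0)
    }
  }

  .bSpec(b, meta = list(
    description = sprintf("second-order LGCM (%s basis%s)",
                          if (growth$latentBasis) "latent" else "fixed",
                          if (length(exo)) sprintf(", %d exogenous predictors", length(exo)) else ""),
    geometry = list(nItems = p, nOccasions = noc, basis = growth$basis),
    measurement = ms, growth = growth,
    covariates = covariates, predictor = predictor,
    predictorTarget = if (!is.null(predictor)) predictorTarget else NULL
  ))
}

#' Estimate a second-order growth model
#'
#' FIML estimation of a [buildLGCM()] specification with a summary of the
#' growth parameters: intercept/slope means and variances,
#' intercept-slope correlation, occasion disturbances, and covariate paths
#' (raw, `stdyx`, and `stdy` for binary/dummy covariates).
#'
#' @param spec a [ModelSpec-class] from [buildLGCM()].
#' @param panel an [ItemPanel-class].
#' @param ... passed to [fitML()].
#' @return list of class `GrowthEstimates`: `fit` ([SemFit-class]),
#'   `growth` (data.frame), `correlation`, `covariatePaths` (data.frame),
#'   `heywood` flag.
#' @export
estimateGrowth <- function(spec, panel, ...) {
  fit <- fitML(spec, panel, ...)
  if (!fit@converged)
    return(structure(list(fit = fit, growth = NULL, correlation = NA,
                          covariatePaths = NULL,
                          heywood = "heywood" %in% fit@flags),
                     class = "GrowthEstimates"))
  th <- fit@theta
  se <- sqrt(pmax(diag(fit@vcov), 0))
  names(se) <- names(th)
  pick <- function(lab) c(est = unname(th[lab]), se = unname(se[lab]))
  growthTab <- data.frame(
    parameter = c("intercept mean", "intercept variance",
                  "slope mean", "slope variance", "intercept-slope covariance"),
    estimate = c(th["gmean_icept"], th["gvar_icept"],
                 th["gmean_slope"], th["gvar_slope"], th["gcov_is"]),
    se = c(se["gmean_icept"], se["gvar_icept"],
           se["gmean_slope"], se["gvar_slope"], se["gcov_is"]),
    row.names = NULL)
  corIS <- unname(th["gcov_is"] / sqrt(max(th["gvar_icept"], 0) * max(th["gvar_slope"], 0)))
  covPaths <- NULL
  covs <- c(spec@meta$covariates, spec@meta$predictor)
  if (length(covs)) {
    std <- tryCatch(standardizedSolution(fit), error = function(e) NULL)
    if (!is.null(std)) {
      covPaths <- std[std$matrix == "B" & std$predictor %in% covs,
                      c("outcome", "predictor", "label", "raw", "stdyx", "stdy")]
    } else {
      ## degenerate implied variance (e.g. Heywood slope): report raw paths
      labs <- grep("^b_", names(th), value = TRUE)
      covPaths <- data.frame(
        outcome = sub(".*_(icept|slope)$", "\\1", labs),
        predictor = sub("^b_(.*)_(icept|slope)$", "\\1", labs),
        label = labs, raw = unname(th[labs]),
        stdyx = NA_real_, stdy = NA_real_, stringsAsFactors = FALSE)
    }
    rownames(covPaths) <- NULL
  }
  structure(list(fit = fit, growth = growthTab, correlation = corIS,
                 covariatePaths = covPaths,
                 heywood = "heywood" %in% fit@flags),
            class = "GrowthEstimates")
}

#' @export
print.GrowthEstimates <- function(x, ...) {
  if (is.null(x$growth)) {
    cat("GrowthEstimates: model did not converge\n")
    return(invisible(x))
  }
  cat("Second-order growth model estimates\n")
  print(transform(x$growth, estimate = round(estimate, 4), se = round(se, 4)),
        row.names = FALSE)
  cat(sprintf("intercept-slope correlation: %.3f\n", x$correlation))
  if (!is.null(x$covariatePaths) && nrow(x$covariatePaths)) {
    cat("covariate paths (raw / stdyx / stdy):\n")
    print(transform(x$covariatePaths, raw = round(raw, 4),
                    stdyx = round(stdyx, 4), stdy = round(stdy, 4)),
          row.names = FALSE)
  }
  if (isTRUE(x$heywood)) cat("note: Heywood case flagged\n")
  invisible(x)
}

#' Write growth estimates as TSV
#'
#' Two tables in one file: growth parameters, then covariate paths with
#' raw and standardized (stdyx/stdy) coefficients.
#'
#' @param est a `GrowthEstimates`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGrowthTSV <- function(est, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# growth parameters", con)
  utils::write.table(est$growth, con, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(est$covariatePaths) && nrow(est$covariatePaths)) {
    writeLines("# covariate paths", con)
    utils::write.table(est$covariatePaths, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
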