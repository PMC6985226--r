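## Objective/gradient factory. Caches the most recent evaluation so nlminb's
## paired objective/gradient calls at the same theta cost one pass.
.makeObjective <- function(spec, prep) {
  ix <- .specIndex(spec)
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  evalPoint <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return(invisible(NULL))
    mats <- .buildMats(spec, theta, ix)
    imp <- tryCatch(.impliedFromMats(mats, spec), error = function(e) NULL)
    if (is.null(imp)) {
      cache$theta <- theta; cache$ll <- -Inf; cache$g <- numeric(ix$q)
      return(invisible(NULL))
    }
    core <- .fimlCore(imp$mu, imp$Sigma, prep, grad = TRUE)
    cache$theta <- theta
    if (!core$ok) {
      cache$ll <- -Inf; cache$g <- numeric(ix$q)
    } else {
      cache$ll <- core$ll
      cache$g <- .chainGrad(imp, core$V, core$gmu, spec, ix)
    }
    invisible(NULL)
  }
  list(
    obj = function(theta) { evalPoint(theta); if (is.finite(cache$ll)) -cache$ll else 1e10 },
    gr = function(theta) { evalPoint(theta); -cache$g },
    loglik = function(theta) { evalPoint(theta); cache$ll },
    grad = function(theta) { evalPoint(theta); cache$g },
    ix = ix
  )
}

## Data-driven refinement of builder starting values, keyed off the label
## naming conventions used by the ladder/growth builders. Unknown labels
## keep the builder's start.
.refineStart <- function(spec, prep) {
  start <- spec@start
  labs <- spec@labels
  p <- prep$p
  nj <- numeric(p); sj <- numeric(p); ssj <- numeric(p)
  for (pt in prep$patterns) {
    nj[pt$obs] <- nj[pt$obs] + pt$n
    sj[pt$obs] <- sj[pt$obs] + pt$Sx
    ssj[pt$obs] <- ssj[pt$obs] + diag(pt$Sxx)
  }
  mj <- sj / pmax(nj, 1)
  vj <- pmax(ssj / pmax(nj, 1) - mj^2, 1e-3)
  names(mj) <- names(vj) <- spec@obsNames
  g <- spec@meta$geometry
  if (is.null(g)) return(start)
  nit <- g$nItems; noc <- g$nOccasions
  col <- function(j, t) (t - 1L) * nit + j
  occMean <- vapply(seq_len(noc), function(t) mean(mj[col(seq_len(nit), t)]), 0)
  occVar <- vapply(seq_len(noc), function(t) mean(vj[col(seq_len(nit), t)]), 0)
  basis <- g$basis
  for (k in seq_along(labs)) {
    f <- strsplit(labs[k], "_", fixed = TRUE)[[1L]]
    start[k] <- switch(f[1L],
      thd = 0.5 * vj[col(as.integer(f[2L]), as.integer(f[3L]))],
      tau = {
        j <- as.integer(f[2L])
        t <- if (length(f) >= 3L) as.integer(f[3L]) else 1L
        mj[col(j, t)] - occMean[t]
      },
      lmean = occMean[as.integer(f[2L])],
      lvar = 0.45 * occVar[as.integer(f[2L])],
      lcov = 0.35 * sqrt(occVar[as.integer(f[2L])] * occVar[as.integer(f[3L])]),
      thc = 0.1 * sqrt(vj[col(as.integer(f[2L]), as.integer(f[3L]))] *
                         vj[col(as.integer(f[2L]), as.integer(f[4L]))]),
      gmean = if (f[2L] == "icept") occMean[1L] else
        (occMean[noc] - occMean[1L]) / max(basis[noc] - basis[1L], 0.5),
      gvar = if (f[2L] == "icept") 0.4 * occVar[1L] else 0.1 * occVar[1L],
      gcov = -0.05 * occVar[1L],
      dist = 0.15 * occVar[min(as.integer(f[2L]), noc)],
      start[k])
  }
  start
}

#' Fit a structural equation model by FIML
#'
#' Maximizes the full-information multivariate-normal likelihood over the
#' free parameters of `spec` with a quasi-Newton optimizer (analytic
#' gradients; variances unconstrained so Heywood cases remain representable
#' and are flagged rather than truncated). `T = 2 * (loglik_sat - loglik)`;
#' the saturated log-likelihood is obtained by EM over unstructured
#' `(mu, Sigma)` when responses are incomplete (closed form when complete).
#'
#' @param spec a [ModelSpec-class].
#' @param panel an [ItemPanel-class].
#' @param start optional numeric start vector (label order); default is the
#'   builder's start refined by observed moments.
#' @param se `"observed"` (inverse observed information), `"robust"`
#'   (sandwich from casewise scores; also computes the scaling factor `c`),
#'   or `"none"` (fast; replicate loops).
#' @param nRestarts jittered restarts attempted when the first optimization
#'   fails to converge.
#' @param maxIter,tol optimizer budget and relative tolerance.
#' @param seed integer seed for restart jitter (recorded in the result).
#' @param satLoglik optional precomputed saturated log-likelihood for this
#'   panel (reused across a model ladder).
#' @param baseline optional precomputed `.baselineFit` result.
#' @return a [SemFit-class] object.
#' @export
fitML <- function(spec, panel, start = NULL,
                  se = c("observed", "robust", "none"),
                  nRestarts = 3L, maxIter = 500L, tol = 1e-10,
                  seed = 1L, satLoglik = NULL, baseline = NULL) {
  se <- match.arg(se)
  if (dfModel(spec) < 0)
    stop("model is not identified: negative degrees of freedom")
  Y <- .panelData(panel, spec@obsNames)
  prep <- .fimlPrep(Y)
  engine <- .makeObjective(spec, prep)
  theta0 <- if (is.null(start)) .refineStart(spec, prep) else start
  runOnce <- function(th) {
    nlminb(th, engine$obj, engine$gr,
           control = list(iter.max = maxIter, eval.max = 4L * maxIter,
                          rel.tol = tol))
  }
  opt <- runOnce(theta0)
  attempts <- 1L
  ok <- function(o) is.finite(o$objective) && o$objective < 1e9 &&
    o$convergence %in% c(0L, 1L)
  if (!ok(opt) && nRestarts > 0L) {
    oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (r in seq_len(nRestarts)) {
      jit <- theta0 + rnorm(length(theta0), 0, 0.25 * (abs(theta0) + 0.1))
      o2 <- runOnce(jit)
      attempts <- attempts + 1L
      if (ok(o2) && o2$objective < opt$objective) opt <- o2
      if (ok(opt)) break
    }
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  }
  theta <- setNames(opt$par, spec@labels)
  ll <- -opt$objective
  converged <- ok(opt)
  flags <- character()
  if (!converged) flags <- c(flags, "nonconverged")

  if (is.null(satLoglik)) satLoglik <- .saturatedFit(prep)$loglik
  Tstat <- max(2 * (satLoglik - ll), 0)
  if (2 * (satLoglik - ll) < -1e-4) flags <- c(flags, "loglik_above_saturated")

  mats <- .buildMats(spec, theta)
  if (any(diag(mats$Theta) < -1e-8) || any(diag(mats$Psi) < -1e-8))
    flags <- c(flags, "heywood")

  q <- length(theta)
  vc <- matrix(NA_real_, q, q, dimnames = list(spec@labels, spec@labels))
  scaling <- 1
  details <- list(optimizer = opt[c("convergence", "iterations", "message")],
                  attempts = attempts, seed = seed, satLoglik = satLoglik)
  if (se != "none" && converged && q > 0) {
    info <- .numInfo(engine$grad, theta)
    vcObs <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(vcObs)) {
      flags <- c(flags, "singular_information")
    } else {
      vc <- vcObs
      dimnames(vc) <- list(spec@labels, spec@labels)
    }
    if (se == "robust" && !is.null(vcObs)) {
      rb <- tryCatch(.robustPieces(spec, prep, theta, Tstat, dfModel(spec)),
                     error = function(e) NULL)
      if (!is.null(rb)) {
        S <- rb$scores
        vc <- vcObs %*% crossprod(S) %*% vcObs
        dimnames(vc) <- list(spec@labels, spec@labels)
        scaling <- rb$c
        details$Gamma <- NULL
      } else {
        flags <- c(flags, "robust_failed")
      }
    }
  }
  if (is.null(baseline)) baseline <- .baselineFit(prep)
  details$baseline <- list(T = max(2 * (satLoglik - baseline$loglik), 0),
                           df = baseline$df)
  new("SemFit", spec = spec, theta = theta, vcov = vc, loglik = ll,
      loglikSaturated = satLoglik, T = Tstat, df = dfModel(spec),
      scaling = scaling, N = as.integer(prep$N), converged = converged,
      flags = flags, details = details)
}

## Observed information (negative Hessian of the log-likelihood) by central
## differences of the analytic gradient.
.numInfo <- function(gradFun, theta, h = NULL) {
  q <- length(theta)
  if (is.null(h)) h <- 1e-5 * (abs(theta) + 1e-2)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    H[, j] <- (gradFun(tp) - gradFun(tm)) / (2 * h[j])
  }
  -(H + t(H)) / 2
}

## Numeric Jacobian of the stacked moment vector (mu, vech Sigma) wrt theta.
.momentJacobian <- function(spec, theta, ix = .specIndex(spec)) {
  p <- length(spec@obsNames)
  stack <- function(th) {
    imp <- .impliedFromMats(.buildMats(spec, th, ix), spec)
    c(imp$mu, imp$Sigma[lower.tri(imp$Sigma, diag = TRUE)])
  }
  q <- length(theta)
  base <- stack(theta)
  J <- matrix(0, length(base), q)
  for (j in seq_len(q)) {
    h <- 1e-6 * (abs(theta[j]) + 1e-2)
    tp <- theta; tp[j] <- tp[j] + h
    J[, j] <- (stack(tp) - base) / h
  }
  J
}

## Casewise scores in moment space (mu, vech Sigma) at given (mu, Sigma):
## N x (p + p(p+1)/2) matrix. Off-diagonal covariance scores carry the
## duplication factor.
.casewiseMomentScores <- function(mu, Sigma, prep) {
  p <- prep$p
  vechIdx <- matrix(0L, p, p)
  vechIdx[lower.tri(vechIdx, diag = TRUE)] <- seq_len(p * (p + 1) / 2)
  vechIdx[upper.tri(vechIdx)] <- t(vechIdx)[upper.tri(vechIdx)]
  G <- matrix(0, prep$N, p + p * (p + 1) / 2)
  for (pt in prep$patterns) {
    o <- pt$obs; pk <- length(o)
    Sinv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
    R <- sweep(pt$X, 2L, mu[o])
    W <- R %*% Sinv
    G[pt$rows, o] <- W
    for (a in seq_len(pk)) for (b in seq_len(a)) {
      cidx <- p + vechIdx[o[a], o[b]]
      if (a == b) {
        G[pt$rows, cidx] <- 0.5 * (W[, a]^2 - Sinv[a, a])
      } else {
        G[pt$rows, cidx] <- W[, a] * W[, b] - Sinv[a, b]
      }
    }
  }
  G
}

## Sandwich scores and Satorra-Bentler-style scaling factor c.
## c = tr(U Gamma) / df with U = V - V Delta (Delta' V Delta)^-1 Delta' V,
## V the per-observation normal-theory information in moment space at the
## model-implied moments, and Gamma = V^-1 Omega V^-1 with Omega the
## casewise moment-score covariance.
.robustPieces <- function(spec, prep, theta, Tstat, df) {
  ix <- .specIndex(spec)
  imp <- .impliedFromMats(.buildMats(spec, theta, ix), spec)
  p <- prep$p
  G <- .casewiseMomentScores(imp$mu, imp$Sigma, prep)
  J <- .momentJacobian(spec, theta, ix)
  scores <- G %*% J
  cfac <- NA_real_
  if (df > 0) {
    etaGrad <- function(mu, Sigma) {
      core <- .fimlCore(mu, Sigma, prep, grad = TRUE)
      Vg <- core$V
      vech <- Vg[lower.tri(Vg, diag = TRUE)]
      dup <- row(Vg)[lower.tri(Vg, diag = TRUE)] != col(Vg)[lower.tri(Vg, diag = TRUE)]
      vech[dup] <- 2 * vech[dup]
      c(core$gmu, vech)
    }
    nEta <- p + p * (p + 1) / 2
    A <- matrix(0, nEta, nEta)
    hmu <- 1e-4; hs <- 1e-4
    base <- list(mu = imp$mu, Sigma = imp$Sigma)
    k <- 0L
    for (i in seq_len(p)) {
      k <- k + 1L
      mup <- base$mu; mup[i] <- mup[i] + hmu
      mum <- base$mu; mum[i] <- mum[i] - hmu
      A[, k] <- -(etaGrad(mup, base$Sigma) - etaGrad(mum, base$Sigma)) / (2 * hmu)
    }
    for (jj in seq_len(p)) for (ii in jj:p) {
      k <- k + 1L
      Sp <- base$Sigma; Sm <- base$Sigma
      Sp[ii, jj] <- Sp[ii, jj] + hs; Sp[jj, ii] <- Sp[ii, jj]
      Sm[ii, jj] <- Sm[ii, jj] - hs; Sm[jj, ii] <- Sm[ii, jj]
      A[, k] <- -(etaGrad(base$mu, Sp) - etaGrad(base$mu, Sm)) / (2 * hs)
    }
    A <- (A + t(A)) / 2
    V <- A / prep$N
    Omega <- crossprod(G) / prep$N
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (!is.null(Vi)) {
      Gamma <- Vi %*% Omega %*% Vi
      VD <- V %*% J
      Minner <- tryCatch(solve(crossprod(J, VD)), error = function(e) NULL)
      if (!is.null(Minner)) {
        U <- V - VD %*% Minner %*% t(VD)
        cfac <- sum(U * t(Gamma)) / df
      }
    }
  }
  if (!is.finite(cfac) || cfac <= 0) cfac <- 1
  list(scores = scores, c = cfac)
}

#' @rdname SemFit-class
#' @export
setMethod("estimates", "SemFit", function(object) {
  se <- sqrt(pmax(diag(object@vcov), 0))
  data.frame(label = object@spec@labels,
             estimate = as.numeric(object@theta),
             se = as.numeric(se),
             z = as.numeric(object@theta) / as.numeric(se),
             row.names = NULL)
})

#' @rdname dfModel
#' @export
setMethod("dfModel", "SemFit", function(object) object@df)

setMethod("show", "SemFit", function(object) {
  cat(sprintf("SemFit: %d free parameters, N = %d\n",
              length(object@theta), object@N))
  cat(sprintf("  loglik = %.3f, T = %.3f, df = %g, scaling c = %.3f\n",
              object@loglik, object@T, object@df, object@scaling))
  cat(sprintf("  converged: %s%s\n", object@converged,
              if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ", "), "]") else ""))
  invisible(object)
})

#' Standardized solution
#'
#' Standardizes loadings and regression paths using model-implied variances:
#' `stdyx` multiplies each coefficient by `SD(predictor) / SD(outcome)`;
#' `stdy` divides by `SD(outcome)` only (the convention recommended for
#' binary dummy predictors). Latent standard deviations come from the
#' implied latent covariance `(I-B)^-1 Psi (I-B)^-T`.
#'
#' @param fit a converged [SemFit-class].
#' @return data.frame with one row per free loading/path/intercept-relevant
#'   cell: matrix, outcome, predictor, label, raw estimate, `stdyx`, `stdy`.
#' @export
standardizedSolution <- function(fit) {
  if (!fit@converged) stop("fit did not converge; refusing to standardize")
  spec <- fit@spec
  imp <- impliedMoments(spec, fit@theta)
  latCov <- imp$A %*% imp$mats$Psi %*% t(imp$A)
  sdLat <- sqrt(pmax(diag(latCov), 0))
  sdObs <- sqrt(pmax(diag(imp$Sigma), 0))
  names(sdLat) <- spec@latNames
  rows <- list()
  asn <- spec@assign
  seen <- character()
  for (r in seq_len(nrow(asn))) {
    mat <- asn$mat[r]
    if (!mat %in% c("Lambda", "B")) next
    if (abs(asn$coef[r] - 1) > 1e-12) next  # dependent cells reported via their own labels
    key <- paste(mat, asn$idx[r])
    if (key %in% seen) next
    seen <- c(seen, key)
    nr <- nrow(spec@mats[[mat]])
    i <- (asn$idx[r] - 1L) %% nr + 1L
    j <- (asn$idx[r] - 1L) %/% nr + 1L
    raw <- imp$mats[[mat]][i, j]
    if (mat == "Lambda") {
      sdy <- sdObs[i]; sdx <- sdLat[j]
      outcome <- spec@obsNames[i]; predictor <- spec@latNames[j]
    } else {
      sdy <- sdLat[i]; sdx <- sdLat[j]
      outcome <- spec@latNames[i]; predictor <- spec@latNames[j]
    }
    if (sdy <= 0) stop("zero model-implied variance for outcome ", outcome)
    rows[[length(rows) + 1L]] <- data.frame(
      matrix = mat, outcome = outcome, predictor = predictor,
      label = spec@labels[asn$lab[r]], raw = raw,
      stdyx = raw * sdx / sdy, stdy = raw / sdy,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Serialize a fit to JSON
#'
#' @param fit a [SemFit-class].
#' @param path output path.
#' @param extra optional named list merged into the report (e.g. resolved
#'   run configuration).
#' @return `path`, invisibly.
#' @export
writeFitJSON <- function(fit, path, extra = list()) {
  est <- estimates(fit)
  out <- c(list(
    estimates = est,
    loglik = fit@loglik, loglikSaturated = fit@loglikSaturated,
    T = fit@T, df = fit@df, scaling = fit@scaling, N = fit@N,
    converged = fit@converged, flags = fit@flags
  ), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
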