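## Expected (normal-theory) information in moment space (mu, vech Sigma)
## accumulated over missingness patterns: means block n * Sigma_oo^-1,
## covariance block n/2 * (S_ac S_bd + S_ad S_bc) in the duplicated (vech,
## off-diagonals doubled) parameterization, zero cross block. Verified in
## tests against central differences of the analytic moment gradient.
.etaInfo <- function(mu, Sigma, prep, hmu = NULL, hs = NULL) {
  p <- prep$p
  nv <- p * (p + 1) / 2
  vechIdx <- matrix(0L, p, p)
  vechIdx[lower.tri(vechIdx, diag = TRUE)] <- seq_len(nv)
  vechIdx[upper.tri(vechIdx)] <- t(vechIdx)[upper.tri(vechIdx)]
  low <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  A <- matrix(0, p + nv, p + nv)
  for (pt in prep$patterns) {
    o <- pt$obs; n <- pt$n
    Sinv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
    A[o, o] <- A[o, o] + n * Sinv
    pk <- length(o)
    lk <- which(lower.tri(diag(pk), diag = TRUE), arr.ind = TRUE)
    va <- lk[, 1]; vb <- lk[, 2]
    w <- ifelse(va == vb, 1 / sqrt(2), sqrt(2))
    block <- 0.5 * n * (Sinv[va, va, drop = FALSE] * Sinv[vb, vb, drop = FALSE] +
                          Sinv[va, vb, drop = FALSE] * Sinv[vb, va, drop = FALSE]) *
      tcrossprod(w)
    gidx <- p + vechIdx[cbind(o[va], o[vb])]
    A[gidx, gidx] <- A[gidx, gidx] + block
  }
  A
}

#' Modification indices
#'
#' Univariate score tests for freeing constrained parameters: each
#' candidate is a relaxed [ModelSpec-class] into which the fitted estimates
#' are embedded; the index approximates the drop in the chi-square T if the
#' candidate's constraints were freed. The information is the expected
#' (Gauss-Newton) information `J' A J`, with `A` the moment-space
#' information at the fitted point (shared by all candidates) and `J` each
#' candidate's moment Jacobian.
#'
#' @param fit a converged [SemFit-class].
#' @param candidates named list of relaxed [ModelSpec-class] objects; labels
#'   absent from the fitted spec count as the freed block.
#' @param prep optional precomputed pattern statistics for the fitted panel
#'   (required if `fit` was produced outside this session's helpers);
#'   otherwise supply `panel`.
#' @param panel the [ItemPanel-class] the model was fitted to.
#' @return data.frame ranked by decreasing `mi`: `candidate`, `mi`,
#'   `dfAdded`, `ok` (FALSE when the candidate's information was singular;
#'   its `mi` is `NA`).
#' @export
modificationIndices <- function(fit, candidates, panel = NULL, prep = NULL) {
  if (!fit@converged) stop("fit did not converge; modification indices unavailable")
  if (is.null(prep)) {
    if (is.null(panel)) stop("supply either prep or panel")
    prep <- .fimlPrep(.panelData(panel, fit@spec@obsNames))
  }
  oldMats <- .buildMats(fit@spec, fit@theta)
  imp <- .impliedFromMats(oldMats, fit@spec)
  A <- .etaInfo(imp$mu, imp$Sigma, prep)
  out <- data.frame(candidate = names(candidates), mi = NA_real_,
                    dfAdded = NA_real_, ok = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    sp2 <- candidates[[i]]
    th2 <- .embedTheta(sp2, fit@spec, fit@theta)
    eng <- .makeObjective(sp2, prep)
    g <- eng$grad(th2)
    J <- .momentJacobian(sp2, th2)
    I2 <- crossprod(J, A %*% J)
    newIdx <- which(!(sp2@labels %in% fit@spec@labels))
    if (!length(newIdx)) next
    oldIdx <- setdiff(seq_along(sp2@labels), newIdx)
    res <- tryCatch({
      Schur <- I2[newIdx, newIdx, drop = FALSE] -
        I2[newIdx, oldIdx, drop = FALSE] %*%
        solve(I2[oldIdx, oldIdx, drop = FALSE], I2[oldIdx, newIdx, drop = FALSE])
      sn <- g[newIdx]
      drop(crossprod(sn, solve(Schur, sn)))
    }, error = function(e) NULL)
    out$dfAdded[i] <- length(sp2@labels) - length(fit@spec@labels)
    if (!is.null(res) && is.finite(res)) {
      out$mi[i] <- max(res, 0)
      out$ok[i] <- TRUE
    }
  }
  out[order(-ifelse(is.na(out$mi), -Inf, out$mi)), , drop = FALSE]
}

#' Intercept-release candidates for a (partial) strong model
#'
#' Builds one relaxed specification per currently invariant item, freeing
#' that item's intercepts across occasions.
#'
#' @param fit fitted strong or partial-strong model.
#' @return named list of [ModelSpec-class] candidates.
#' @export
interceptCandidates <- function(fit) {
  ms <- fit@spec@meta$measurement
  geom <- fit@spec@meta$geometry
  if (is.null(ms) || !ms$intercepts %in% c("shared", "partial"))
    stop("fit must be a strong or partial-strong measurement model")
  freed <- ms$freedItems
  inv <- setdiff(seq_len(geom$nItems), freed)
  if (length(inv) <= 1L) stop("invariant-intercept floor reached")
  setNames(lapply(inv, function(j)
    partialStrongSpec(sort(c(freed, j)), geom$nItems, geom$nOccasions,
                      ms$residualLagCov)),
    paste0("item", inv))
}
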