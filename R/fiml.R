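## Full-information ML machinery. Participants are grouped by missingness
## pattern; each pattern contributes through its sufficient statistics
## (n, sum x, sum xx'), which makes the objective cost independent of N.

.fimlPrep <- function(Y) {
  if (!nrow(Y)) stop("panel is empty")
  obsMask <- !is.na(Y)
  if (any(rowSums(obsMask) == 0))
    stop("each participant's observed subvector must be non-empty")
  key <- apply(obsMask, 1L, function(r) paste(which(r), collapse = ","))
  patterns <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    o <- which(obsMask[rows[1L], ])
    X <- Y[rows, o, drop = FALSE]
    patterns[[length(patterns) + 1L]] <- list(
      obs = o, n = length(rows), rows = rows,
      Sx = colSums(X), Sxx = crossprod(X), X = X)
  }
  list(patterns = patterns, N = nrow(Y), p = ncol(Y),
       complete = all(obsMask))
}

## log-likelihood (and optionally the full-moment-space gradient) of a
## multivariate-normal model (mu, Sigma) under the pattern prep.
## Returns ll = -Inf when any pattern submatrix is not positive definite
## (the optimizer treats that as a barrier).
.fimlCore <- function(mu, Sigma, prep, grad = FALSE) {
  ll <- 0
  p <- prep$p
  V <- if (grad) matrix(0, p, p) else NULL
  gmu <- if (grad) numeric(p) else NULL
  for (pt in prep$patterns) {
    o <- pt$obs; n <- pt$n; pk <- length(o)
    Sk <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(Sk), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf, ok = FALSE))
    logdet <- 2 * sum(log(diag(ch)))
    muk <- mu[o]
    T2 <- pt$Sxx - tcrossprod(pt$Sx, muk) - tcrossprod(muk, pt$Sx) +
      n * tcrossprod(muk)
    Sinv <- chol2inv(ch)
    quad <- sum(Sinv * T2)
    ll <- ll - 0.5 * (n * pk * log(2 * pi) + n * logdet + quad)
    if (grad) {
      G <- -0.5 * (n * Sinv - Sinv %*% T2 %*% Sinv)
      V[o, o] <- V[o, o] + G
      gmu[o] <- gmu[o] + as.vector(Sinv %*% (pt$Sx - n * muk))
    }
  }
  list(ll = ll, ok = TRUE, V = V, gmu = gmu)
}

## Chain rule from moment-space gradients (V = dL/dSigma full symmetric,
## gmu = dL/dmu) to the free-parameter vector via the spec's affine maps.
.chainGrad <- function(imp, V, gmu, spec, ix) {
  mats <- imp$mats; A <- imp$A; M <- imp$M
  m <- length(spec@latNames)
  Aalpha <- A %*% mats$Alpha
  F <- A %*% mats$Psi %*% t(A)
  full <- list()
  if (!is.null(ix$mats$Lambda))
    full$Lambda <- 2 * V %*% mats$Lambda %*% F + gmu %*% t(Aalpha)
  if (!is.null(ix$mats$Tau)) full$Tau <- matrix(gmu, ncol = 1)
  if (!is.null(ix$mats$Theta)) full$Theta <- V
  if (!is.null(ix$mats$Alpha)) full$Alpha <- crossprod(M, gmu)
  if (!is.null(ix$mats$Psi)) full$Psi <- crossprod(M, V) %*% M
  if (!is.null(ix$mats$B)) {
    D <- 2 * crossprod(mats$Lambda, V) %*% mats$Lambda %*% A %*% mats$Psi +
      crossprod(mats$Lambda, gmu) %*% t(mats$Alpha)
    full$B <- t(A) %*% D %*% t(A)
  }
  g <- numeric(ix$q)
  for (mat in names(ix$mats)) {
    e <- ix$mats[[mat]]
    g <- g + as.vector(crossprod(e$K, full[[mat]][e$uidx] * e$gmult))
  }
  g
}

#' FIML log-likelihood
#'
#' Casewise (full-information) multivariate-normal log-likelihood of an item
#' panel under a model specification: each participant contributes the log
#' density of their observed subvector under the corresponding marginal of
#' the implied moments.
#'
#' @param spec a [ModelSpec-class].
#' @param panel an [ItemPanel-class].
#' @param theta free-parameter vector (defaults to the spec's start values).
#' @return scalar log-likelihood; `-Inf` when an implied pattern submatrix
#'   is not positive definite.
#' @export
fimlLoglik <- function(spec, panel, theta = spec@start) {
  prep <- .fimlPrep(.panelData(panel, spec@obsNames))
  imp <- impliedMoments(spec, theta)
  .fimlCore(imp$mu, imp$Sigma, prep)$ll
}

## Saturated-model FIML log-likelihood via EM over (mu, Sigma).
## Complete data reduces to the closed form in one E-step.
.saturatedFit <- function(prep, tol = 1e-9, maxit = 2000L) {
  p <- prep$p; N <- prep$N
  ## available-case start
  sx <- numeric(p); nx <- numeric(p)
  for (pt in prep$patterns) { sx[pt$obs] <- sx[pt$obs] + pt$Sx; nx[pt$obs] <- nx[pt$obs] + pt$n }
  mu <- sx / pmax(nx, 1)
  Sxx <- matrix(0, p, p); nxx <- matrix(0, p, p)
  for (pt in prep$patterns) {
    Sxx[pt$obs, pt$obs] <- Sxx[pt$obs, pt$obs] + pt$Sxx
    nxx[pt$obs, pt$obs] <- nxx[pt$obs, pt$obs] + pt$n
  }
  Sigma <- Sxx / pmax(nxx, 1) - tcrossprod(mu)
  ## ensure positive definite start
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev))
    Sigma <- Sigma + diag(max(ev) * 1e-6 + 1e-8 - min(0, min(ev)), p)
  if (prep$complete) {
    res <- .fimlCore(mu, Sigma, prep)
    return(list(mu = mu, Sigma = Sigma, loglik = res$ll, iterations = 0L,
                converged = TRUE))
  }
  llOld <- -Inf
  for (it in seq_len(maxit)) {
    Tx <- numeric(p); Txx <- matrix(0, p, p)
    for (pt in prep$patterns) {
      o <- pt$obs; n <- pt$n
      mi <- setdiff(seq_len(p), o)
      if (!length(mi)) {
        Tx[o] <- Tx[o] + pt$Sx
        Txx[o, o] <- Txx[o, o] + pt$Sxx
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      Bk <- Sigma[mi, o, drop = FALSE] %*% solve(Soo)
      a <- mu[mi] - as.vector(Bk %*% mu[o])
      Ck <- Sigma[mi, mi, drop = FALSE] - Bk %*% Sigma[o, mi, drop = FALSE]
      BSx <- as.vector(Bk %*% pt$Sx)
      Exm <- n * a + BSx
      Tx[o] <- Tx[o] + pt$Sx
      Tx[mi] <- Tx[mi] + Exm
      Exmo <- a %*% t(pt$Sx) + Bk %*% pt$Sxx
      Txx[o, o] <- Txx[o, o] + pt$Sxx
      Txx[mi, o] <- Txx[mi, o] + Exmo
      Txx[o, mi] <- Txx[o, mi] + t(Exmo)
      Txx[mi, mi] <- Txx[mi, mi] + n * Ck + n * tcrossprod(a) +
        a %*% t(BSx) + BSx %*% t(a) + Bk %*% pt$Sxx %*% t(Bk)
    }
    mu <- Tx / N
    Sigma <- Txx / N - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- .fimlCore(mu, Sigma, prep)$ll
    if (is.finite(ll) && abs(ll - llOld) < tol * (abs(ll) + 1))
      return(list(mu = mu, Sigma = Sigma, loglik = ll, iterations = it,
                  converged = TRUE))
    llOld <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = llOld, iterations = maxit,
       converged = FALSE)
}

## Independence-baseline log-likelihood (free means and variances, all
## covariances zero). Under independence the casewise likelihood factorizes
## per variable, so per-variable univariate ML moments are exact FIML.
.baselineFit <- function(prep) {
  p <- prep$p
  nj <- numeric(p); sj <- numeric(p); ssj <- numeric(p)
  for (pt in prep$patterns) {
    nj[pt$obs] <- nj[pt$obs] + pt$n
    sj[pt$obs] <- sj[pt$obs] + pt$Sx
    ssj[pt$obs] <- ssj[pt$obs] + diag(pt$Sxx)
  }
  mj <- sj / nj
  vj <- ssj / nj - mj^2
  ll <- sum(-0.5 * nj * (log(2 * pi) + log(vj) + 1))
  list(loglik = ll, nFree = 2 * p,
       df = p * (p + 3) / 2 - 2 * p, mean = mj, var = vj)
}
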