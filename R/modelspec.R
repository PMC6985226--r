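## Internal builder for ModelSpec objects. Matrices start at zero; `fix()`
## writes constants, `par()` attaches a free parameter (creating the label on
## first use, shared on reuse), `dep()` adds affine terms for dependent
## (linearly constrained) cells. Symmetric matrices (Theta, Psi) are
## canonicalized to their lower triangle.

.symMats <- c("Theta", "Psi")

.newSpecBuilder <- function(obsNames, latNames, exoNames = character()) {
  p <- length(obsNames); m <- length(latNames)
  b <- new.env(parent = emptyenv())
  b$obsNames <- obsNames; b$latNames <- latNames; b$exoNames <- exoNames
  b$mats <- list(Lambda = matrix(0, p, m), Tau = matrix(0, p, 1),
                 Theta = matrix(0, p, p), B = matrix(0, m, m),
                 Alpha = matrix(0, m, 1), Psi = matrix(0, m, m))
  b$assign <- list()
  b$labels <- character(); b$start <- numeric()
  b
}

.cellIdx <- function(b, mat, i, j) {
  if (mat %in% .symMats && j > i) { tmp <- i; i <- j; j <- tmp }
  (j - 1L) * nrow(b$mats[[mat]]) + i
}

.bFix <- function(b, mat, i, j, value) {
  b$mats[[mat]][.cellIdx(b, mat, i, j)] <- value
  invisible(b)
}

.bLabel <- function(b, label, start) {
  k <- match(label, b$labels)
  if (is.na(k)) {
    b$labels <- c(b$labels, label)
    b$start <- c(b$start, start)
    k <- length(b$labels)
  }
  k
}

.bPar <- function(b, mat, i, j, label, start = 0, coef = 1) {
  k <- .bLabel(b, label, start)
  b$assign[[length(b$assign) + 1L]] <-
    list(mat = mat, idx = .cellIdx(b, mat, i, j), lab = k, coef = coef)
  invisible(b)
}

## dependent cell: value = const + sum(coef_l * theta_l); labels must exist.
.bDep <- function(b, mat, i, j, const, labels, coefs) {
  idx <- .cellIdx(b, mat, i, j)
  b$mats[[mat]][idx] <- b$mats[[mat]][idx] + const
  for (k in seq_along(labels)) {
    li <- match(labels[k], b$labels)
    if (is.na(li)) stop("dependent cell refers to unknown label ", labels[k])
    b$assign[[length(b$assign) + 1L]] <-
      list(mat = mat, idx = idx, lab = li, coef = coefs[k])
  }
  invisible(b)
}

.bSpec <- function(b, meta = list()) {
  asn <- if (length(b$assign)) {
    data.frame(mat = vapply(b$assign, `[[`, "", "mat"),
               idx = as.integer(vapply(b$assign, function(a) as.numeric(a$idx), 0)),
               lab = as.integer(vapply(b$assign, function(a) as.numeric(a$lab), 0)),
               coef = vapply(b$assign, `[[`, 0, "coef"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(mat = character(), idx = integer(), lab = integer(),
               coef = numeric(), stringsAsFactors = FALSE)
  }
  new("ModelSpec", obsNames = b$obsNames, latNames = b$latNames,
      mats = b$mats, assign = asn, labels = b$labels, start = b$start,
      exoNames = b$exoNames, meta = meta)
}

#' @rdname ModelSpec-class
#' @export
setMethod("freeParameters", "ModelSpec", function(object)
  setNames(object@start, object@labels))

#' @rdname dfModel
#' @export
setMethod("dfModel", "ModelSpec", function(object) {
  p <- length(object@obsNames)
  e <- length(object@exoNames)
  p * (p + 3) / 2 - length(object@labels) - e * (e + 3) / 2
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %d observed, %d latent, %d free parameters, df = %g\n",
              length(object@obsNames), length(object@latNames),
              length(object@labels), dfModel(object)))
  if (!is.null(object@meta$description)) cat(" ", object@meta$description, "\n")
  if (length(object@exoNames))
    cat("  exogenous (moments fixed at sample values):",
        paste(object@exoNames, collapse = ", "), "\n")
  invisible(object)
})

## Precompute fast indexing: per matrix a dense map K so that
## cells[uidx] = const[uidx] + K %*% theta, plus gradient multipliers that
## fold the symmetric mirroring (off-diagonal cells of Theta/Psi count twice).
.specIndex <- function(spec) {
  q <- length(spec@labels)
  out <- list()
  for (mat in unique(spec@assign$mat)) {
    rows <- spec@assign[spec@assign$mat == mat, , drop = FALSE]
    uidx <- sort(unique(rows$idx))
    K <- matrix(0, length(uidx), q)
    pos <- match(rows$idx, uidx)
    for (r in seq_len(nrow(rows)))
      K[pos[r], rows$lab[r]] <- K[pos[r], rows$lab[r]] + rows$coef[r]
    nr <- nrow(spec@mats[[mat]])
    ri <- (uidx - 1L) %% nr + 1L
    ci <- (uidx - 1L) %/% nr + 1L
    gmult <- if (mat %in% .symMats) ifelse(ri == ci, 1, 2) else rep(1, length(uidx))
    out[[mat]] <- list(uidx = uidx, K = K, gmult = gmult)
  }
  ## precomputed mirror indices for symmetrizing Theta/Psi on build
  upper <- lapply(setNames(.symMats, .symMats), function(mat) {
    M <- spec@mats[[mat]]
    ut <- which(upper.tri(M))
    nr <- nrow(M)
    ri <- (ut - 1L) %% nr + 1L
    ci <- (ut - 1L) %/% nr + 1L
    cbind(to = ut, from = (ri - 1L) * nr + ci)
  })
  list(mats = out, q = q, upper = upper)
}

## theta -> full numeric matrices (symmetric ones mirrored).
.buildMats <- function(spec, theta, ix = .specIndex(spec)) {
  mats <- spec@mats
  for (mat in names(ix$mats)) {
    e <- ix$mats[[mat]]
    mats[[mat]][e$uidx] <- mats[[mat]][e$uidx] + as.vector(e$K %*% theta)
  }
  for (mat in .symMats) {
    up <- ix$upper[[mat]]
    mats[[mat]][up[, "to"]] <- mats[[mat]][up[, "from"]]
  }
  mats
}

#' Model-implied moments
#'
#' Computes the implied covariance matrix and mean vector
#' `Sigma = Lambda (I-B)^-1 Psi (I-B)^-T Lambda' + Theta`,
#' `mu = Tau + Lambda (I-B)^-1 Alpha` at a given parameter vector.
#'
#' @param spec a [ModelSpec-class].
#' @param theta numeric free-parameter vector in `spec@labels` order
#'   (default: the spec's starting values).
#' @return list with `Sigma` (p x p, dimnamed) and `mu` (length p).
#' @export
impliedMoments <- function(spec, theta = spec@start) {
  mats <- .buildMats(spec, theta)
  .impliedFromMats(mats, spec)
}

.impliedFromMats <- function(mats, spec) {
  m <- length(spec@latNames)
  ImB <- diag(m) - mats$B
  A <- tryCatch(solve(ImB), error = function(e) NULL)
  if (is.null(A)) {
    dg <- abs(diag(qr.R(qr(ImB))))
    bad <- spec@latNames[which.min(dg)]
    stop("singular latent structure (I - B) around latent block '", bad, "'")
  }
  M <- mats$Lambda %*% A
  Sigma <- M %*% mats$Psi %*% t(M) + mats$Theta
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- as.vector(mats$Tau) + as.vector(M %*% mats$Alpha)
  dimnames(Sigma) <- list(spec@obsNames, spec@obsNames)
  names(mu) <- spec@obsNames
  list(Sigma = Sigma, mu = mu, A = A, M = M, mats = mats)
}
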