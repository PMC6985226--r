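## Shared fixtures: all synthetic, generated in code at test time.

## small panel config: scaled-down dropout profile, no covariates by default
smallConfig <- function(n = 300, drift = 0, seed = 1, covariates = FALSE, ...) {
  simConfig(n = n,
            occasionCounts = as.integer(c(n, round(0.78 * n), round(0.71 * n))),
            intermittentReturn = as.integer(round(0.05 * n)),
            driftMagnitude = drift, covariates = covariates, seed = seed, ...)
}

## tiny one-factor cross-sectional spec with explicit numeric structure:
## p indicators, loadings lam (free, marker = effects coding not used here),
## used for oracle arithmetic tests
toyFactorSpec <- function(lam = c(1, 0.8), psi = 1, theta = rep(0.5, length(lam)),
                          tau = rep(0, length(lam)), alpha = 0,
                          free = FALSE) {
  p <- length(lam)
  b <- longsem:::.newSpecBuilder(panelColumnNames(p, 1), "f")
  for (j in seq_len(p)) {
    if (free && j > 1) longsem:::.bPar(b, "Lambda", j, 1, paste0("l", j), start = lam[j])
    else longsem:::.bFix(b, "Lambda", j, 1, lam[j])
    if (free) longsem:::.bPar(b, "Theta", j, j, paste0("th", j), start = theta[j])
    else longsem:::.bFix(b, "Theta", j, j, theta[j])
    if (free) longsem:::.bPar(b, "Tau", j, 1, paste0("t", j), start = tau[j])
    else longsem:::.bFix(b, "Tau", j, 1, tau[j])
  }
  if (free) longsem:::.bPar(b, "Psi", 1, 1, "psi", start = psi)
  else longsem:::.bFix(b, "Psi", 1, 1, psi)
  ## alpha stays fixed even in free mode: with free intercepts a free latent
  ## mean would not be identified in this marker parameterization
  longsem:::.bFix(b, "Alpha", 1, 1, alpha)
  longsem:::.bSpec(b, meta = list(description = "toy factor"))
}

## direct multivariate-normal log density (independent oracle)
mvnLogLik <- function(Y, mu, Sigma) {
  sum(apply(Y, 1, function(y) {
    o <- !is.na(y)
    S <- Sigma[o, o, drop = FALSE]
    r <- y[o] - mu[o]
    -0.5 * (sum(o) * log(2 * pi) + determinant(S)$modulus +
              drop(r %*% solve(S) %*% r))
  }))
}

## breadth-first-search component labelling oracle (independent of the
## union-find implementation in the package)
bfsLabel <- function(binary, connectivity) {
  dm <- dim(binary)
  offs <- switch(connectivity,
                 faces = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                               c(0,0,1), c(0,0,-1)),
                 faces_edges = {
                   g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                   g[rowSums(abs(g)) %in% c(1, 2), , drop = FALSE]
                 },
                 faces_edges_corners = {
                   g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                   g[rowSums(abs(g)) > 0, , drop = FALSE]
                 })
  lab <- array(0L, dm)
  nxt <- 0L
  for (start in which(binary)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      cv <- arrayInd(v, dm)
      for (r in seq_len(nrow(offs))) {
        nb <- cv + offs[r, ]
        if (any(nb < 1) || any(nb > dm)) next
        ni <- (nb[3] - 1L) * dm[1] * dm[2] + (nb[2] - 1L) * dm[1] + nb[1]
        if (binary[ni] && lab[ni] == 0L) {
          lab[ni] <- nxt
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

## canonical form for comparing labelings up to label permutation
canonicalPartition <- function(lab) {
  idx <- which(lab > 0)
  split(idx, lab[idx]) |> lapply(sort) |> (\(x) x[order(vapply(x, min, 0))])() |>
    unname()
}
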