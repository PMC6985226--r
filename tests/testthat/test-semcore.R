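test_that("implied moments reproduce hand matrix algebra", {
  ## identity measurement: single indicator, loading 1, latent variance 1
  sp1 <- toyFactorSpec(lam = 1, psi = 1, theta = 0, tau = 0, alpha = 0)
  im1 <- impliedMoments(sp1)
  expect_equal(unname(im1$Sigma), matrix(1), tolerance = 1e-12)
  expect_equal(unname(im1$mu), 0)

  ## two indicators: Sigma = Lambda Psi Lambda' + Theta elementwise
  lam <- c(1, 0.8); psi <- 1.2; th <- c(0.3, 0.4); tau <- c(0.5, -0.2); al <- 0.3
  sp2 <- toyFactorSpec(lam, psi, th, tau, alpha = al)
  im2 <- impliedMoments(sp2)
  SigmaHand <- outer(lam, lam) * psi + diag(th)
  expect_equal(unname(im2$Sigma), SigmaHand, tolerance = 1e-12)
  expect_equal(unname(im2$mu), tau + lam * al, tolerance = 1e-12)
})

test_that("singular latent structure raises an informative error", {
  b <- longsem:::.newSpecBuilder(c("y1", "y2"), c("f1", "f2"))
  longsem:::.bFix(b, "Lambda", 1, 1, 1); longsem:::.bFix(b, "Lambda", 2, 2, 1)
  longsem:::.bFix(b, "Psi", 1, 1, 1); longsem:::.bFix(b, "Psi", 2, 2, 1)
  longsem:::.bFix(b, "B", 1, 2, 1); longsem:::.bFix(b, "B", 2, 1, 1)
  sp <- longsem:::.bSpec(b)
  expect_error(impliedMoments(sp), "singular latent structure")
})

test_that("FIML log-likelihood equals direct density evaluation", {
  cfg <- smallConfig(n = 60, seed = 3)
  panel <- genItemPanel(cfg)
  spec <- buildLadder(12, 3)$configural
  theta <- longsem:::.refineStart(spec, longsem:::.fimlPrep(responses(panel)))
  imp <- impliedMoments(spec, theta)
  expect_equal(fimlLoglik(spec, panel, theta),
               mvnLogLik(responses(panel), imp$mu, imp$Sigma),
               tolerance = 1e-8)

  ## complete data: FIML and complete-data ML agree to 1e-8
  Yc <- responses(panel)[complete.cases(responses(panel)), , drop = FALSE]
  pc <- ItemPanel(Yc, nItems = 12, nOccasions = 3)
  expect_equal(fimlLoglik(spec, pc, theta), mvnLogLik(Yc, imp$mu, imp$Sigma),
               tolerance = 1e-8)
})

test_that("single observation at its mean with unit variance gives -log(2*pi)/2", {
  sp <- toyFactorSpec(lam = 1, psi = 0, theta = 1, tau = 1.7, alpha = 0)
  pan <- ItemPanel(matrix(1.7, 1, 1), nItems = 1, nOccasions = 1)
  expect_equal(fimlLoglik(sp, pan), -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("missing occasions contribute their analytic marginal density", {
  lam <- c(1, 0.9, 1.1); psi <- 0.8; th <- c(0.5, 0.6, 0.4)
  sp <- toyFactorSpec(lam, psi, th, tau = c(0, 0.1, -0.1), alpha = 0.5)
  im <- impliedMoments(sp)
  set.seed(4)
  Y <- matrix(rnorm(15), 5, 3)
  Y[2, 3] <- NA; Y[4, 2:3] <- NA
  pan <- ItemPanel(Y, nItems = 3, nOccasions = 1)
  expect_equal(fimlLoglik(sp, pan), mvnLogLik(Y, im$mu, im$Sigma),
               tolerance = 1e-10)
})

test_that("saturated model reaches T = 0 on a complete panel", {
  set.seed(9)
  Y <- matrix(rnorm(50 * 2), 50, 2)
  pan <- ItemPanel(Y, nItems = 2, nOccasions = 1)
  ## saturated: identity loadings, free latent moments
  b <- longsem:::.newSpecBuilder(c("item1_t1", "item2_t1"), c("f1", "f2"))
  longsem:::.bFix(b, "Lambda", 1, 1, 1); longsem:::.bFix(b, "Lambda", 2, 2, 1)
  longsem:::.bPar(b, "Psi", 1, 1, "v1", start = 1)
  longsem:::.bPar(b, "Psi", 2, 2, "v2", start = 1)
  longsem:::.bPar(b, "Psi", 2, 1, "c12", start = 0)
  longsem:::.bPar(b, "Alpha", 1, 1, "m1", start = 0)
  longsem:::.bPar(b, "Alpha", 2, 1, "m2", start = 0)
  sp <- longsem:::.bSpec(b)
  fit <- fitML(sp, pan, se = "none")
  expect_true(fit@converged)
  expect_equal(fit@df, 0)
  expect_lt(abs(fit@T), 1e-6)
  ## and the implied moments equal the sample ML moments
  imp <- impliedMoments(fit@spec, fit@theta)
  expect_equal(unname(imp$mu), unname(colMeans(Y)), tolerance = 1e-5)
  expect_equal(unname(imp$Sigma), unname(crossprod(sweep(Y, 2, colMeans(Y))) / 50),
               tolerance = 1e-4)
})

test_that("three-indicator loadings are recovered within 3 SEs at N = 2000", {
  lamT <- c(1, 0.7, 1.3); psiT <- 0.9; thT <- c(0.4, 0.5, 0.3)
  set.seed(11)
  eta <- rnorm(2000, 0, sqrt(psiT))
  Y <- outer(eta, lamT) + matrix(rnorm(6000), 2000, 3) %*% diag(sqrt(thT))
  pan <- ItemPanel(Y, nItems = 3, nOccasions = 1)
  sp <- toyFactorSpec(lamT, psiT, thT, free = TRUE)
  fit <- fitML(sp, pan)
  expect_true(fit@converged)
  est <- estimates(fit)
  truth <- c(l2 = 0.7, l3 = 1.3, th1 = 0.4, th2 = 0.5, th3 = 0.3,
             t1 = 0, t2 = 0, t3 = 0, psi = 0.9)
  for (nm in names(truth)) {
    row <- est[est$label == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 3 * row$se)
  }
})

test_that("fitted log-likelihood matches multi-start brute-force optimization", {
  set.seed(21)
  cfg <- smallConfig(n = 120, seed = 21)
  panel <- genItemPanel(cfg)
  Y <- responses(panel)[, 1:4]  # occasion-1 block, small model
  Y <- Y[complete.cases(Y), ]
  pan <- ItemPanel(Y, nItems = 4, nOccasions = 1)
  sp <- toyFactorSpec(rep(1, 4), 0.6, rep(0.5, 4), free = TRUE)
  fit <- fitML(sp, pan, se = "none")
  ## brute force: finite-difference BFGS from several random starts,
  ## polished by Nelder-Mead (independent of the analytic-gradient path)
  obj <- function(th) {
    v <- -fimlLoglik(sp, pan, th)
    if (!is.finite(v)) 1e8 else v
  }
  best <- Inf
  set.seed(1)
  for (r in 1:5) {
    st <- sp@start + rnorm(length(sp@start), 0, 0.2)
    o <- optim(st, obj, method = "BFGS", control = list(maxit = 2000))
    o2 <- optim(o$par, obj, method = "Nelder-Mead",
                control = list(maxit = 20000, reltol = 1e-13))
    best <- min(best, o2$value)
  }
  expect_equal(fit@loglik, -best, tolerance = 1e-4)
})

test_that("nested models keep T ordered and effects-coding sums hold exactly", {
  cfg <- smallConfig(n = 250, seed = 13)
  panel <- genItemPanel(cfg)
  lad <- buildLadder(12, 3)
  fc <- fitML(lad$configural, panel, se = "none")
  fw <- fitML(lad$weak, panel, se = "none",
              start = longsem:::.embedTheta(lad$weak, fc@spec, fc@theta))
  fs <- fitML(lad$strong, panel, se = "none",
              start = longsem:::.embedTheta(lad$strong, fw@spec, fw@theta))
  expect_gte(fw@T, fc@T - 1e-6)
  expect_gte(fs@T, fw@T - 1e-6)
  for (fit in list(fc, fw, fs)) {
    mats <- longsem:::.buildMats(fit@spec, fit@theta)
    for (t in 1:3) {
      rows <- (t - 1) * 12 + 1:12
      expect_equal(sum(mats$Lambda[rows, t]), 12, tolerance = 1e-10)
      expect_equal(sum(mats$Tau[rows, 1]), 0, tolerance = 1e-10)
    }
  }
})

test_that("standardization follows the stdyx/stdy definitions", {
  expect_equal(stdCoef(1.0, sdOutcome = 2.0, style = "stdy"), 0.5)
  expect_equal(stdCoef(1.0, sdOutcome = 2.0, sdPredictor = 0.5, style = "stdyx"), 0.25)
  expect_error(stdCoef(1, 0), "positive")

  ## standardized loadings of a fitted toy model match covariance algebra
  set.seed(31)
  lamT <- c(1, 0.8, 1.1); psiT <- 1.1; thT <- c(0.3, 0.5, 0.4)
  eta <- rnorm(1500, 0, sqrt(psiT))
  Y <- outer(eta, lamT) + matrix(rnorm(4500), 1500, 3) %*% diag(sqrt(thT))
  pan <- ItemPanel(Y, nItems = 3, nOccasions = 1)
  fit <- fitML(toyFactorSpec(lamT, psiT, thT, free = TRUE), pan)
  std <- standardizedSolution(fit)
  mats <- longsem:::.buildMats(fit@spec, fit@theta)
  l2 <- mats$Lambda[2, 1]; psih <- mats$Psi[1, 1]; th2 <- mats$Theta[2, 2]
  expect_equal(std$stdyx[std$outcome == "item2_t1"],
               l2 * sqrt(psih) / sqrt(l2^2 * psih + th2), tolerance = 1e-8)
})

test_that("robust machinery returns a near-unit scaling factor on normal data", {
  set.seed(41)
  lamT <- c(1, 0.9, 1.2, 0.8); psiT <- 1; thT <- rep(0.5, 4)
  eta <- rnorm(600)
  Y <- outer(eta, lamT) + matrix(rnorm(2400), 600, 4) %*% diag(sqrt(thT))
  pan <- ItemPanel(Y, nItems = 4, nOccasions = 1)
  fit <- fitML(toyFactorSpec(lamT, psiT, thT, free = TRUE), pan, se = "robust")
  expect_true(fit@converged)
  expect_gt(fit@scaling, 0.75)
  expect_lt(fit@scaling, 1.35)
  ## sandwich and observed-information SEs are of comparable magnitude
  expect_true(all(is.finite(diag(fit@vcov))))
})
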