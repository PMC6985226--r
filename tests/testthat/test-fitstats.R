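test_that("rmsea reproduces reference chi-square inputs and truncates at zero", {
  ## printed model statistics with N = 1814, 3 decimals
  expect_equal(round(rmsea(1134.62, 534, 1814), 3), 0.025)
  expect_equal(round(rmsea(1673.23, 578, 1814), 3), 0.032)
  expect_equal(rmsea(90, 100, 500), 0)
  expect_error(rmsea(10, 0, 100), "df")
  expect_error(rmsea(10, 5, 1), "N")
})

test_that("rmsea is monotone in T and decreasing in N beyond df", {
  Ts <- seq(120, 400, by = 20)
  vals <- vapply(Ts, rmsea, 0, df = 100, N = 500)
  expect_true(all(diff(vals) > 0))
  Ns <- c(100, 200, 500, 1000, 5000)
  vals2 <- vapply(Ns, function(n) rmsea(200, 100, n), 0)
  expect_true(all(diff(vals2) < 0))
})

test_that("rmsea CI inverts the noncentral chi-square tails", {
  ci <- rmseaCI(1208.75, 556, 1814)
  expect_equal(round(unname(ci["hi"]), 3), 0.027)
  expect_lt(abs(ci["lo"] - 0.0235), 5e-4)
  ## T = df: lower bound collapses to zero
  expect_equal(unname(rmseaCI(10, 10, 100)["lo"]), 0)
  ## grid-search oracle on a small case
  ci2 <- rmseaCI(30, 10, 100, coverage = 0.90)
  grid <- seq(0, 200, by = 1e-4)
  loGrid <- grid[which.min(abs(pchisq(30, 10, ncp = grid) - 0.95))]
  hiGrid <- grid[which.min(abs(pchisq(30, 10, ncp = grid) - 0.05))]
  expect_equal(unname(ci2["lo"]), sqrt(loGrid / (10 * 99)), tolerance = 1e-4)
  expect_equal(unname(ci2["hi"]), sqrt(hiGrid / (10 * 99)), tolerance = 1e-4)
  ## interval shrinks as N grows with the same T/df
  wide <- rmseaCI(300, 100, 200)
  narrow <- rmseaCI(300, 100, 2000)
  expect_lt(narrow["hi"] - narrow["lo"], wide["hi"] - wide["lo"])
})

test_that("cfi follows its truncation rules", {
  expect_equal(cfi(90, 100, 1100, 120), 1)
  expect_equal(cfi(150, 100, 1100, 120), 1 - 50 / 980)
  expect_equal(round(cfi(150, 100, 1100, 120), 4), 0.949)
  expect_equal(cfi(500, 100, 500, 100 + 1e-9), 0)
  expect_error(cfi(100, 100, 200, 100), "baseline")
})

test_that("scaled chi-square difference matches hand arithmetic", {
  ## both scaling factors 1: plain difference
  r <- sbScaledDiff(100, 50, 1, 80, 45, 1)
  expect_equal(r$Tdiff, 20)
  expect_equal(r$dfDiff, 5)
  ## hand-computed scaled case
  r2 <- sbScaledDiff(100, 50, 1.2, 80, 45, 1.1)
  expect_equal(r2$cd, (50 * 1.2 - 45 * 1.1) / 5)
  expect_equal(r2$cd, 2.1, tolerance = 1e-12)
  expect_equal(round(r2$Tdiff, 3), round((100 * 1.2 - 80 * 1.1) / 2.1, 3))
  expect_equal(round(r2$Tdiff, 3), 15.238)
  ## negative statistic is reported with a warning flag, not suppressed
  r3 <- sbScaledDiff(80, 50, 1, 85, 45, 1)
  expect_lt(r3$Tdiff, 0)
  expect_match(r3$warning, "negative")
  ## non-positive correction is a degenerate-correction error
  expect_error(sbScaledDiff(50, 50, 0.5, 80, 45, 1.1), "degenerate")
  expect_error(sbScaledDiff(100, 40, 1, 80, 45, 1), "nested")
})

test_that("fitStatistics assembles indices consistent with the raw formulas", {
  cfg <- smallConfig(n = 200, seed = 17)
  panel <- genItemPanel(cfg)
  fit <- fitML(buildLadder(12, 3)$weak, panel, se = "none")
  st <- fitStatistics(fit)
  expect_equal(st$rmsea, rmsea(fit@T, fit@df, fit@N))
  expect_true(st$rmsea.ci["lo"] <= st$rmsea && st$rmsea <= st$rmsea.ci["hi"])
  expect_gte(st$cfi, 0); expect_lte(st$cfi, 1)
})

test_that("an intercept fixed at its unconstrained optimum has MI ~ 0", {
  set.seed(5)
  lamT <- c(1, 0.8, 1.2); psiT <- 1; thT <- rep(0.5, 3)
  eta <- rnorm(500)
  Y <- outer(eta, lamT) + matrix(rnorm(1500), 500, 3) %*% diag(sqrt(thT))
  pan <- ItemPanel(Y, nItems = 3, nOccasions = 1)
  specFree <- toyFactorSpec(lamT, psiT, thT, free = TRUE)
  fitFree <- fitML(specFree, pan, se = "none")
  l2hat <- longsem:::.buildMats(fitFree@spec, fitFree@theta)$Lambda[2, 1]
  ## same model with that loading fixed at its unconstrained optimum
  b <- longsem:::.newSpecBuilder(panelColumnNames(3, 1), "f")
  for (j in 1:3) {
    if (j == 2) longsem:::.bFix(b, "Lambda", j, 1, l2hat)
    else if (j == 3) longsem:::.bPar(b, "Lambda", j, 1, "l3", start = lamT[3])
    else longsem:::.bFix(b, "Lambda", j, 1, 1)
    longsem:::.bPar(b, "Theta", j, j, paste0("th", j), start = thT[j])
    longsem:::.bPar(b, "Tau", j, 1, paste0("t", j), start = 0)
  }
  longsem:::.bPar(b, "Psi", 1, 1, "psi", start = 1)
  longsem:::.bFix(b, "Alpha", 1, 1, 0)
  specCon <- longsem:::.bSpec(b)
  fitCon <- fitML(specCon, pan, se = "none")
  prep <- longsem:::.fimlPrep(Y)
  mi <- modificationIndices(fitCon, list(freeL2 = fitFree@spec), prep = prep)
  expect_true(mi$ok[1])
  expect_lt(mi$mi[1], 1e-3)
})

test_that("modification indices rank the drifted item first and track refit drops", {
  ## drifted intercept planted on one item of a 6-item scale
  cfg <- smallConfig(n = 600, seed = 23, drift = 0.35,
                     loadingsT1 = rep(c(0.5, 0.6, 0.7), 2),
                     driftItems = 3L)
  panel <- genItemPanel(cfg)
  strong <- longsem:::.buildMeasurementSpec(6, 3, "shared", "shared")
  fit <- fitML(strong, panel, se = "none")
  prep <- longsem:::.fimlPrep(responses(panel))
  cands <- interceptCandidates(fit)
  mi <- modificationIndices(fit, cands, prep = prep)
  expect_true(all(mi$ok))
  ## the drifted item ranks first
  expect_identical(mi$candidate[1], "item3")

  ## MI approximates the actual free-and-refit T drop within 15% for MI > 5
  sat <- longsem:::.saturatedFit(prep)$loglik
  for (i in seq_len(nrow(mi))) {
    if (mi$mi[i] <= 5) next
    sp2 <- cands[[mi$candidate[i]]]
    f2 <- fitML(sp2, panel, se = "none",
                start = longsem:::.embedTheta(sp2, fit@spec, fit@theta),
                satLoglik = sat)
    drop <- fit@T - f2@T
    expect_lt(abs(mi$mi[i] - drop) / drop, 0.15)
  }

  ## refit-ranking oracle: MI order equals actual T-drop order
  drops <- vapply(cands, function(sp2) {
    f2 <- fitML(sp2, panel, se = "none",
                start = longsem:::.embedTheta(sp2, fit@spec, fit@theta),
                satLoglik = sat)
    fit@T - f2@T
  }, 0)
  expect_identical(mi$candidate[1], names(which.max(drops)))

  ## at the (correctly specified) optimum of the freed model, MI ~ 0
  spFree <- cands[["item3"]]
  fitFree <- fitML(spFree, panel, se = "none",
                   start = longsem:::.embedTheta(spFree, fit@spec, fit@theta))
  cands2 <- interceptCandidates(fitFree)["item3" != names(interceptCandidates(fitFree))]
  mi2 <- modificationIndices(fitFree, cands2, prep = prep)
  ## remaining items are truly invariant: indices stay small (chi2_2 scale)
  expect_lt(max(mi2$mi, na.rm = TRUE), 12)
})

test_that("analytic expected moment information matches central differences", {
  numEtaInfo <- function(mu, Sigma, prep, hmu = 1e-5, hs = 1e-5) {
    p <- prep$p
    etaGrad <- function(m, S) {
      core <- longsem:::.fimlCore(m, S, prep, grad = TRUE)
      Vg <- core$V; low <- lower.tri(Vg, diag = TRUE)
      vech <- Vg[low]; offd <- (row(Vg) != col(Vg))[low]
      vech[offd] <- 2 * vech[offd]; c(core$gmu, vech)
    }
    nEta <- p + p * (p + 1) / 2; A <- matrix(0, nEta, nEta); k <- 0
    for (i in 1:p) {
      k <- k + 1; mp <- mu; mp[i] <- mp[i] + hmu; mm <- mu; mm[i] <- mm[i] - hmu
      A[, k] <- -(etaGrad(mp, Sigma) - etaGrad(mm, Sigma)) / (2 * hmu)
    }
    for (jj in 1:p) for (ii in jj:p) {
      k <- k + 1
      Sp <- Sigma; Sm <- Sigma
      Sp[ii, jj] <- Sp[ii, jj] + hs; Sp[jj, ii] <- Sp[ii, jj]
      Sm[ii, jj] <- Sm[ii, jj] - hs; Sm[jj, ii] <- Sm[ii, jj]
      A[, k] <- -(etaGrad(mu, Sp) - etaGrad(mu, Sm)) / (2 * hs)
    }
    (A + t(A)) / 2
  }
  set.seed(2)
  Y <- matrix(rnorm(300 * 4, 1), 300, 4)
  prep <- longsem:::.fimlPrep(Y)
  sat <- longsem:::.saturatedFit(prep)
  ## at the complete-data saturated point observed equals expected information
  Anum <- numEtaInfo(sat$mu, sat$Sigma, prep)
  Aan <- longsem:::.etaInfo(sat$mu, sat$Sigma, prep)
  expect_lt(max(abs(Anum - Aan)) / max(abs(Anum)), 1e-7)
})
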