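test_that("growth builder df bookkeeping: latent basis frees exactly one df", {
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  linSpec <- buildLGCM(mi, growthSpec(basis = c(0, 0.5, 1)))
  lbSpec <- buildLGCM(mi, growthSpec(basis = c(0, 0.5, 1), latentBasis = TRUE))
  expect_equal(dfModel(linSpec) - dfModel(lbSpec), 1)
  ## no covariates: structural regression block only carries the growth part
  expect_length(grep("^b_", linSpec@labels), 0)
  expect_error(growthSpec(basis = 0.5), "two occasions")
})

test_that("a nine-level site factor dummy-codes into eight columns", {
  cfg <- smallConfig(n = 120, seed = 51, covariates = TRUE)
  panel <- genItemPanel(cfg)
  X <- covariateDesign(panel)
  expect_length(grep("^site_", colnames(X)), 8)
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  spec <- buildLGCM(mi, growthSpec(), covariates = colnames(X), panel = panel)
  ## two paths (intercept, slope) per covariate column
  expect_length(grep("^b_site_", spec@labels), 16)
})

test_that("latent-basis model with the middle loading at its linear value nests exactly", {
  cfg <- smallConfig(n = 300, seed = 53)
  panel <- genItemPanel(cfg)
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  lin <- buildLGCM(mi, growthSpec(basis = c(0, 0.5, 1)))
  lb <- buildLGCM(mi, growthSpec(basis = c(0, 0.5, 1), latentBasis = TRUE))
  fLin <- fitML(lin, panel, se = "none")
  ## evaluate the latent-basis model at the embedded linear solution
  thLb <- longsem:::.embedTheta(lb, fLin@spec, fLin@theta)
  thLb[match("basis_2", lb@labels)] <- 0.5
  expect_equal(fimlLoglik(lb, panel, thLb), fLin@loglik, tolerance = 1e-6)
  ## and the free fit can only improve
  fLb <- fitML(lb, panel, se = "none", start = thLb)
  expect_gte(fLb@loglik, fLin@loglik - 1e-6)
})

test_that("implied occasion means follow the growth structure", {
  cfg <- smallConfig(n = 500, seed = 57)
  panel <- genItemPanel(cfg)
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  spec <- buildLGCM(mi, growthSpec())
  fit <- fitML(spec, panel, se = "none")
  imp <- impliedMoments(spec, fit@theta)
  latMeans <- drop(imp$A %*% longsem:::.buildMats(spec, fit@theta)$Alpha)
  gi <- fit@theta["gmean_icept"]; gs <- fit@theta["gmean_slope"]
  expect_equal(unname(latMeans[1:3]), unname(gi + c(0, 0.5, 1) * gs),
               tolerance = 1e-8)
})

test_that("growth parameters and a planted sex effect are recovered", {
  cfg <- smallConfig(n = 1200, seed = 59, covariates = TRUE)
  panel <- genItemPanel(cfg)
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  spec <- buildLGCM(mi, growthSpec(), covariates = c("sex", "depression"),
                    panel = panel)
  est <- estimateGrowth(spec, panel, seed = 1)
  expect_true(est$fit@converged)
  g <- est$growth
  ## means within 3 SEs of the generating values (conditional on covariates)
  gm <- g[g$parameter == "intercept mean", ]
  expect_lt(abs(gm$estimate - cfg$iceptMean), 3 * gm$se + 0.05)
  sm <- g[g$parameter == "slope mean", ]
  expect_lt(abs(sm$estimate - cfg$slopeMean), 3 * sm$se + 0.02)
  ## negative intercept-slope correlation of roughly the planted size
  expect_lt(est$correlation, 0.15)
  ## positive female intercept advantage, standardized stdy
  sexRow <- est$covariatePaths[est$covariatePaths$predictor == "sex" &
                                 est$covariatePaths$outcome == "icept", ]
  expect_gt(sexRow$raw, 0)
  expect_gt(sexRow$stdy, 0)
  ## stdy is raw / SD(outcome), so smaller in magnitude for SD > 1 outcomes
  expect_equal(sexRow$stdy, sexRow$raw / (sexRow$raw / sexRow$stdy))
})

test_that("no time trend yields a slope mean near zero", {
  cfg <- smallConfig(n = 800, seed = 61, slopeMean = 0)
  panel <- genItemPanel(cfg)
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  est <- estimateGrowth(buildLGCM(mi, growthSpec()), panel, seed = 1)
  sm <- est$growth[est$growth$parameter == "slope mean", ]
  expect_lt(abs(sm$estimate / sm$se), 2.6)
})

test_that("growth TSV serialization includes both tables", {
  cfg <- smallConfig(n = 400, seed = 63, covariates = TRUE)
  panel <- genItemPanel(cfg)
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  est <- estimateGrowth(buildLGCM(mi, growthSpec(), covariates = "sex",
                                  panel = panel), panel, seed = 1)
  f <- tempfile(fileext = ".tsv")
  writeGrowthTSV(est, f)
  txt <- readLines(f)
  expect_true(any(grepl("growth parameters", txt)))
  expect_true(any(grepl("covariate paths", txt)))
})
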