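test_that("ladder df accounting is exact under effects coding", {
  lad <- buildLadder(12, 3)
  dfs <- vapply(lad, dfModel, 0)
  expect_equal(unname(dfs["weak"] - dfs["configural"]), 22)
  expect_equal(unname(dfs["strong"] - dfs["weak"]), 22)
  ## closed form: each equality of one loading/intercept over 3 occasions
  ## adds 2 df, with one constraint absorbed per occasion by the coding
  expect_equal(unname(dfs["weak"] - dfs["configural"]), 2 * (12 - 1))
  ## partial model: freeing k intercepts across time removes 2k df
  for (k in 1:4) {
    sp <- partialStrongSpec(seq_len(k), 12, 3)
    expect_equal(dfModel(lad$strong) - dfModel(sp), 2 * k)
  }
  ## fitted-model df equals the analytic count (moments - free parameters)
  expect_equal(unname(dfs["configural"]), 36 * 39 / 2 - length(lad$configural@labels))
})

test_that("degenerate ladders are handled", {
  ## single occasion: weak coincides with configural (no cross-occasion ties)
  lad1 <- buildLadder(3, 1)
  expect_equal(dfModel(lad1$weak), dfModel(lad1$configural))
  expect_error(buildLadder(2, 3), "under-identified")
})

test_that("a vacuous rule accepts every level regardless of data", {
  cfg <- smallConfig(n = 150, drift = 0.8, seed = 29)
  panel <- genItemPanel(cfg)
  rep <- runLadder(panel, rules = invarianceRules(deltaCfiMax = 1.0,
                                                  useRmseaCIOverlap = FALSE))
  expect_identical(rep$finalLevel, "strong")
  expect_true(rep$decisions$weak$accept)
  expect_true(rep$decisions$strong$accept)
})

test_that("null drift accepts strong invariance; planted drifts are freed", {
  ## single-panel qualitative checks (replicate rates are exercised in the
  ## acceptance suite)
  cfg0 <- smallConfig(n = 600, drift = 0, seed = 37)
  rep0 <- runLadder(genItemPanel(cfg0))
  expect_identical(rep0$finalLevel, "strong")
  expect_length(rep0$freedItems, 0)

  cfg1 <- smallConfig(n = 900, drift = 0.5, seed = 38)
  rep1 <- runLadder(genItemPanel(cfg1))
  expect_false(rep1$decisions$strong$accept)
  expect_identical(rep1$finalLevel, "partial")
  ## freed set concentrates on the drifted items
  expect_gte(length(intersect(rep1$freedItems, cfg1$driftItems)), 3)
  ## df bookkeeping of the partial model matches the freed count
  expect_equal(rep1$fits$strong@df - rep1$fits$partial@df,
               2 * length(rep1$freedItems))
  ## T non-decreasing up the ladder
  expect_gte(rep1$fits$weak@T, rep1$fits$configural@T - 1e-6)
  expect_gte(rep1$fits$strong@T, rep1$fits$weak@T - 1e-6)
})

test_that("partial search respects the invariant-intercept floor", {
  ## 3-item scale with an unsatisfiable rule: search must stop at the floor
  cfg <- smallConfig(n = 200, drift = 0.6, seed = 41,
                     loadingsT1 = c(0.5, 0.6, 0.7), driftItems = c(1L, 2L))
  panel <- genItemPanel(cfg)
  strong <- longsem:::.buildMeasurementSpec(3, 3, "shared", "shared")
  fit <- fitML(strong, panel, se = "none")
  weakStats <- fitStatistics(fitML(
    longsem:::.buildMeasurementSpec(3, 3, "shared", "occasion"), panel, se = "none"))
  impossible <- invarianceRules(deltaCfiMax = -1, useRmseaCIOverlap = FALSE)
  res <- partialSearch(panel, fit, weakStats, impossible)
  expect_false(res$acceptable)
  expect_match(res$message, "floor")
  expect_lte(length(res$freedItems), 2)  # at least one intercept invariant
})

test_that("search output is reproducible for a fixed panel and seed", {
  cfg <- smallConfig(n = 500, drift = 0.5, seed = 43)
  panel <- genItemPanel(cfg)
  r1 <- runLadder(panel, seed = 2)
  r2 <- runLadder(panel, seed = 2)
  expect_identical(r1$freedItems, r2$freedItems)
  expect_equal(r1$levels$strong$T, r2$levels$strong$T)
})

test_that("reports serialize with per-level statistics and decisions", {
  cfg <- smallConfig(n = 200, seed = 47)
  rep <- runLadder(genItemPanel(cfg))
  expect_s3_class(rep, "InvarianceReport")
  expect_named(rep$levels, c("configural", "weak", "strong"))
  out <- capture.output(print(rep))
  expect_true(any(grepl("final level", out)))
})
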