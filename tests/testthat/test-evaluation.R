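# Robustness evaluation: dose moments, Delta-map, RI, DVH/cDVH, price.

test_that("scenario dose moments reproduce weighted mean and standard deviation", {
  D1 <- Matrix::Matrix(2, 1, 1, sparse = TRUE)
  D2 <- Matrix::Matrix(4, 1, 1, sparse = TRUE)
  st <- scenarioDoseStats(1, list(D1, D2), c(0.5, 0.5))
  expect_equal(st$expected, 3)
  expect_equal(st$stdev, 1)
  one <- scenarioDoseStats(1, list(D1), 1)
  expect_equal(one$expected, 2)
  expect_equal(one$stdev, 0)
  zero <- scenarioDoseStats(0, list(D1, D2), c(0.5, 0.5))
  expect_equal(zero$expected, 0)
  expect_equal(zero$stdev, 0)
  expect_error(scenarioDoseStats(1, list(D1, D2), c(0.7, 0.7)), "sum to 1")
})

test_that("the Delta-map hits its closed-form boundary cases", {
  pars <- robustnessParams(p = 78, c1 = 0.05, c2 = 0.05)
  mk <- function(E, S) list(expected = E, stdev = S)
  expect_equal(deltaMap(mk(78, 0), pars, TRUE), 0)
  expect_equal(deltaMap(mk(78 * 1.05, 0), pars, TRUE), 1)  # E = p(1 + c1)
  expect_equal(deltaMap(mk(78 * 1.03, 78 * 0.02), pars, TRUE),
               0.6^2 + 0.4^2)  # = 0.52
  expect_error(deltaMap(mk(78, 0), pars, FALSE), "empty CTV")
  expect_error(robustnessParams(p = 78, c1 = 0), "> 0")
})

test_that("the robustness index counts Delta < 1 strictly", {
  expect_equal(robustnessIndex(c(0.5, 2.0, 0.9, 1.0)), 0.5)
  expect_equal(robustnessIndex(rep(0.2, 7)), 1)
  expect_equal(robustnessIndex(c(1, 1.5, 3)), 0)
  expect_error(robustnessIndex(numeric()), "empty")

  # RI never increases when deviations or spreads grow
  pars <- robustnessParams(78, 0.05, 0.05)
  set.seed(6)
  E <- 78 + rnorm(200, 0, 3); S <- abs(rnorm(200, 0, 2))
  base <- robustnessIndex(deltaMap(list(expected = E, stdev = S), pars,
                                   rep(TRUE, 200)))
  worse <- robustnessIndex(deltaMap(
    list(expected = 78 + (E - 78) * 1.5, stdev = S * 1.5), pars,
    rep(TRUE, 200)))
  expect_lte(worse, base)
})

test_that("VxGy and DVH curves follow the closed-threshold definition", {
  d <- c(10, 50, 70, 90)
  mask <- rep(TRUE, 4)
  expect_equal(vx(d, mask, 60), 50)
  expect_equal(vx(rep(70, 5), rep(TRUE, 5), 60), 100)
  expect_equal(vx(d, mask, 0), 100)
  expect_error(vx(d, rep(FALSE, 4), 60), "empty")

  curve <- dvh(d, mask, bins = seq(0, 100, by = 5))
  expect_true(all(diff(curve$volume) <= 0))
  expect_true(all(curve$volume >= 0 & curve$volume <= 100))
  expect_equal(curve$volume[curve$dose == 60], 50)
})

test_that("the confidence-band DVH carries weighted moments of per-scenario volumes", {
  # 5 voxels, two scenarios engineered for V60 = 40% and 60%
  D1 <- Matrix::Matrix(diag(c(70, 70, 50, 50, 50)), sparse = TRUE)
  D2 <- Matrix::Matrix(diag(c(70, 70, 70, 50, 50)), sparse = TRUE)
  x <- rep(1, 5)
  masks <- list(all = array(TRUE, c(5, 1, 1)))
  tab <- cdvh(x, list(D1, D2), c(0.5, 0.5), masks, bins = c(0, 60), nominal = 1)
  at60 <- tab[tab$dose == 60, ]
  expect_equal(at60$expected, 50)
  expect_equal(at60$std, 10)
  expect_equal(at60$nominal, 40)
  # identical scenarios give a zero-width band equal to the nominal curve
  same <- cdvh(x, list(D1, D1), c(0.5, 0.5), masks, bins = c(0, 60), nominal = 1)
  expect_equal(same$std, c(0, 0))
  expect_equal(same$expected, same$nominal)
})

test_that("price of robustness composes the nominal-scenario VxGy metrics", {
  setup <- smallSetup()
  nomD <- setup$evalDijs[[nominalIndex(setup$evalSet)]]
  masks <- list(bladder = structureMask(setup$phantom, "bladder"),
                rectum = structureMask(setup$phantom, "rectum"))
  zero <- priceOfRobustness(rep(0, nBixels(nomD)), nomD, masks)
  expect_equal(zero$v40_rectum, 0)
  expect_equal(zero$v60_bladder, 0)

  x <- initialFluence(nomD, structureMask(setup$phantom, "CTV"), 78)
  pr <- priceOfRobustness(x, nomD, masks)
  d <- as.vector(doseMatrix(nomD) %*% x)
  expect_equal(pr$v40_rectum, vx(d, masks$rectum, 40))
  expect_equal(pr$v60_bladder, vx(d, masks$bladder, 60))
  expect_equal(pr$v60_bladder,
               100 * sum(d[as.vector(masks$bladder)] >= 60) /
                 sum(masks$bladder))  # brute-force count
  expect_error(priceOfRobustness(x, nomD, masks["rectum"]), "masks required")
})

test_that("plan evaluation refuses optimization scenario sets", {
  setup <- smallSetup()
  x <- initialFluence(doseCenter(setup$intervalModel),
                      structureMask(setup$phantom, "CTV"), 78)
  expect_error(
    evaluatePlan(x, setup$optDijs, setup$optSet, setup$phantom),
    "evaluation scenario grid")
  ev <- evaluatePlan(x, setup$evalDijs, setup$evalSet, setup$phantom,
                     model = "custom")
  expect_true(robustnessIndexOf(ev) >= 0 && robustnessIndexOf(ev) <= 1)
  expect_true(all(ev@stdev >= 0))
  # cDVH expected curve equals the weighted mean of per-scenario DVHs
  w <- scenarioWeights(setup$evalSet)
  bins <- ev@params$bins
  ctv <- structureMask(setup$phantom, "CTV")
  manual <- Reduce(`+`, lapply(seq_along(w), function(k) {
    d <- as.vector(doseMatrix(setup$evalDijs[[k]]) %*% x)
    w[k] * dvh(d, ctv, bins)$volume
  }))
  got <- ev@dvh[ev@dvh$structure == "CTV", ]
  expect_equal(got$expected, manual, tolerance = 1e-10)
})
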