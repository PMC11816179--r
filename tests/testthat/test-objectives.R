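# Bertoluzza metric, penalty functions, composite objectives and gradients.

test_that("Bertoluzza distance reproduces hand arithmetic and the metric axioms", {
  expect_equal(bertoluzzaDistance(c(5, 2), c(5, 2), 7), 0)
  expect_equal(bertoluzzaDistance(c(3, 1), c(1, 1), 13), 2)  # radii cancel
  expect_equal(bertoluzzaDistance(c(80, 4), c(78, 0), 10), sqrt(164))
  expect_error(bertoluzzaDistance(c(1, 1), c(0, 0), -1), "theta")

  set.seed(8)
  for (i in 1:25) {
    X <- c(rnorm(1), runif(1, 0, 3))
    Y <- c(rnorm(1), runif(1, 0, 3))
    Z <- c(rnorm(1), runif(1, 0, 3))
    th <- runif(1, 0.1, 20)
    expect_equal(bertoluzzaDistance(X, Y, th), bertoluzzaDistance(Y, X, th))
    expect_lte(bertoluzzaDistance(X, Z, th),
               bertoluzzaDistance(X, Y, th) + bertoluzzaDistance(Y, Z, th) + 1e-12)
    if (any(X != Y)) expect_gt(bertoluzzaDistance(X, Y, th), 0)
  }
})

test_that("the interval CTV objective matches hand arithmetic and its theta = 0 limit", {
  im <- unitIntervalModel(center = 80, radius = 1)
  ctv <- TRUE
  res <- fCtvInterval(1, im, ctv, p = 78, theta = 1)
  expect_equal(res$value, 5)  # (80-78)^2 + 1 * 1^2
  expect_equal(fCtvInterval(1, im, ctv, p = 78, theta = 0)$value, 4)
  # perfect plan: center = p, zero radius
  im0 <- unitIntervalModel(center = 78, radius = 0)
  expect_equal(fCtvInterval(1, im0, ctv, p = 78, theta = 10)$value, 0)
  expect_error(fCtvInterval(1, im, c(FALSE), p = 78, theta = 1), "empty CTV")
})

test_that("penalty functions follow the planning conventions", {
  expect_equal(penalty(c(30, 40), "SqOver", 39)$value, 0.5)  # mean(0, 1)
  expect_equal(penalty(c(78, 80, 90), "DoseMin", 78)$value, 0)
  expect_equal(penalty(c(76, 80), "SqDev", 78)$value, 4)
  expect_equal(penalty(c(70, 76), "DoseMax", 75)$value, 0.5)
  # MaxDVH satisfied: V81 = 3% <= 5% allowed
  d <- c(rep(82, 3), rep(70, 97))
  expect_equal(penalty(d, "MaxDVH", 81, vol = 0.05)$value, 0)
  # MaxDVH violated: only voxels between dref and the volume-fraction dose count
  d2 <- c(85, 84, 82, rep(70, 7))
  res <- penalty(d2, "MaxDVH", 81, vol = 0.2)  # allowed 2 of 10 above 81
  # the hottest voxel (above the 20%-volume dose of 84) is spared; the band
  # between dref = 81 and 84 is pushed down
  expect_equal(res$value, ((84 - 81)^2 + (82 - 81)^2) / 10)
  # vol = 0 reduces MaxDVH to the max-dose penalty
  expect_equal(penalty(d2, "MaxDVH", 81, vol = 0)$value,
               penalty(d2, "DoseMax", 81)$value)
  expect_error(penalty(1:3, "Banana", 5), "unknown penalty type")
})

test_that("composite modes collapse to their simple limits", {
  setup <- smallSetup()
  ph <- setup$phantom
  obj <- setup$objectives
  nomD <- setup$optDijs[[nominalIndex(setup$optSet)]]
  x <- initialFluence(doseCenter(setup$intervalModel),
                      structureMask(ph, "CTV"), 78)

  # all OAR weights zero: interval objective reduces to the CTV terms only
  objCtv <- obj
  objCtv$weight[objCtv$structure != "CTV"] <- 0
  objBert <- objCtv
  objBert$weight[objBert$structure == "CTV" & objBert$type != "SqDev"] <- 0
  fInt <- makeObjective("interval", ph, objBert, intervalModel = setup$intervalModel,
                        p = 78, theta = 10, omegaCtv = 1)
  fb <- fCtvInterval(x, setup$intervalModel, structureMask(ph, "CTV"),
                     p = 78, theta = 10, aggregate = "mean")
  expect_equal(fInt(x)$value, fb$value)
  expect_equal(fInt(x)$gradient, fb$gradient)

  # single-scenario minimax equals the nominal composite
  fMm1 <- makeObjective("minimax", ph, obj, scenarioDs = list(nomD), p = 78)
  fNom <- makeObjective("nominal", ph, obj, nominalD = nomD, p = 78)
  expect_equal(fMm1(x)$value, fNom(x)$value, tolerance = 1e-9)

  # ptv model requires a PTV mask
  noPtv <- voxelPhantom(voxelGridOf(ph),
                        ph@masks[setdiff(structureNames(ph), "PTV")])
  expect_error(makeObjective("ptv", noPtv, obj, nominalD = nomD), "PTV")
})

test_that("the smoothed minimax lies between the hard maximum and its log-sum-exp bound", {
  # 1-voxel phantom, two scenarios with composite values 3 and 7
  g <- voxelGrid(c(1, 1, 1), 1)
  ph <- voxelPhantom(g, list(body = array(TRUE, c(1, 1, 1)),
                             CTV = array(TRUE, c(1, 1, 1))))
  obj <- data.frame(structure = "CTV", type = "SqDev", dose = 0, volume = NA,
                    weight = 1, ptv_only = FALSE)
  Ds <- list(Matrix::Matrix(sqrt(3), 1, 1, sparse = TRUE),
             Matrix::Matrix(sqrt(7), 1, 1, sparse = TRUE))
  beta <- 1000
  fHard <- makeObjective("minimax", ph, obj, scenarioDs = Ds, hardMax = TRUE)
  fSoft <- makeObjective("minimax", ph, obj, scenarioDs = Ds, beta = beta)
  expect_equal(fHard(1)$value, 7)
  expect_gte(fSoft(1)$value, 7)
  expect_lte(fSoft(1)$value, 7 + log(2) / beta)
})

test_that("analytic gradients of all four composites match central differences", {
  setup <- smallSetup()
  nomD <- setup$optDijs[[nominalIndex(setup$optSet)]]
  m <- nBixels(nomD)
  x0 <- initialFluence(doseCenter(setup$intervalModel),
                       structureMask(setup$phantom, "CTV"), 78)
  set.seed(14)
  for (model in c("nominal", "ptv", "minimax", "interval")) {
    f <- makeObjective(model, setup$phantom, setup$objectives,
                       nominalD = nomD, scenarioDs = setup$optDijs,
                       intervalModel = setup$intervalModel, p = 78, theta = 10)
    for (i in 1:3) {
      x <- x0 * runif(m, 0.5, 1.5)
      g <- f(x)$gradient
      gn <- numericalGradient(f, x)
      expect_lt(sqrt(sum((g - gn)^2)) / max(sqrt(sum(g^2)), 1e-8), 1e-5)
    }
  }
})

test_that("the interval objective is non-decreasing in theta at fixed fluence", {
  setup <- smallSetup()
  x <- initialFluence(doseCenter(setup$intervalModel),
                      structureMask(setup$phantom, "CTV"), 78)
  vals <- vapply(c(0, 0.5, 1, 2, 5, 10, 20), function(th) {
    f <- makeObjective("interval", setup$phantom, setup$objectives,
                       intervalModel = setup$intervalModel, p = 78, theta = th)
    f(x)$value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-10))
})

test_that("upper-bound penalties dominate center-dose penalties (conservatism)", {
  setup <- smallSetup()
  x <- initialFluence(doseCenter(setup$intervalModel),
                      structureMask(setup$phantom, "CTV"), 78)
  iv <- doseInterval(x, setup$intervalModel)
  body <- which(as.vector(structureMask(setup$phantom, "body")))
  for (spec in list(list(type = "SqOver", dref = 39, vol = NA),
                    list(type = "DoseMax", dref = 60, vol = NA),
                    list(type = "MaxDVH", dref = 50, vol = 0.3))) {
    pUp <- penalty(iv$upper[body], spec$type, spec$dref, spec$vol)$value
    pCtr <- penalty(iv$center[body], spec$type, spec$dref, spec$vol)$value
    expect_gte(pUp, pCtr)
  }
})
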