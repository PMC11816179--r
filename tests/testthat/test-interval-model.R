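# Interval dose model: center, exact radius, SVD compression.

twoScenarioToy <- function() {
  # one voxel, one bixel; doses 2 and 4 Gy at x = 1
  list(Dks = list(Matrix::Matrix(2, 1, 1, sparse = TRUE),
                  Matrix::Matrix(4, 1, 1, sparse = TRUE)),
       w = c(0.5, 0.5))
}

test_that("center and radius reproduce the hand-worked two-scenario example", {
  toy <- twoScenarioToy()
  ctr <- buildCenter(toy$Dks, toy$w)
  expect_equal(as.numeric(ctr %*% 1), 3)       # weighted mean of 2 and 4
  expect_equal(radiusExact(1, toy$Dks, toy$w), 1)  # E[d^2]=10, (E d)^2=9
  # single scenario: center is that matrix, radius vanishes
  expect_equal(as.numeric(buildCenter(toy$Dks[1], 1) %*% 1), 2)
  expect_equal(radiusExact(1, toy$Dks[1], 1), 0)
  # zero fluence
  expect_equal(as.numeric(ctr %*% 0), 0)
})

test_that("radius is positively homogeneous and vanishes for identical scenarios", {
  rs <- randomScenarioMatrices(4, 60, 9, seed = 21)
  x <- runif(9)
  expect_equal(radiusExact(2 * x, rs$Dks, rs$w),
               2 * radiusExact(x, rs$Dks, rs$w))
  same <- list(rs$Dks[[1]], rs$Dks[[1]], rs$Dks[[1]])
  expect_equal(max(radiusExact(x, same, rep(1 / 3, 3))), 0)
  comp <- compressRadius(same, rep(1 / 3, 3))
  expect_equal(radiusRank(comp), 0)
  expect_equal(radiusFromCompressed(x, comp), numeric(60))
})

test_that("full-rank compression reproduces the exact radius; truncation only shrinks it", {
  rs <- randomScenarioMatrices(6, 80, 12, seed = 31)
  ctr <- buildCenter(rs$Dks, rs$w)
  full <- compressRadius(rs$Dks, rs$w, ctr, varianceThreshold = 1.0)
  expect_lte(radiusRank(full), length(rs$Dks))
  set.seed(32)
  for (i in 1:20) {
    x <- runif(12)
    re <- radiusExact(x, rs$Dks, rs$w, ctr)
    rc <- radiusFromCompressed(x, full)
    expect_lt(sqrt(sum((re - rc)^2)) / sqrt(sum(re^2)), 1e-10)
  }
  # squared radius decreases monotonically as modes are dropped
  x <- runif(12)
  rsqPrev <- radiusSqFromCompressed(x, full)
  for (k in rev(seq_len(radiusRank(full) - 1))) {
    trunc <- new("CompressedRadius", rank = as.integer(k), sv = full@sv[1:k],
                 modes = full@modes[1:k],
                 varianceExplained = sum(full@sv[1:k]^2) / full@totalVariance,
                 totalVariance = full@totalVariance, fullRank = full@fullRank,
                 dims = full@dims)
    rsq <- radiusSqFromCompressed(x, trunc)
    expect_true(all(rsq <= rsqPrev + 1e-12))
    rsqPrev <- rsq
  }
})

test_that("the retained variance honors the threshold and bounds the truncation error", {
  rs <- randomScenarioMatrices(8, 100, 10, seed = 41)
  comp <- compressRadius(rs$Dks, rs$w, varianceThreshold = 0.9)
  expect_gte(varianceExplained(comp), 0.9)
  expect_lte(radiusRank(comp), comp@fullRank)
  expect_error(compressRadius(rs$Dks, rs$w, varianceThreshold = 0), "threshold")
  expect_error(compressRadius(rs$Dks, rs$w, varianceThreshold = 1.5), "threshold")

  # dropped squared-radius mass matches the discarded singular-value tail
  # in expectation over isotropic fluences
  full <- compressRadius(rs$Dks, rs$w, varianceThreshold = 1.0)
  set.seed(42)
  dropped <- total <- 0
  for (i in 1:200) {
    x <- rnorm(10)
    rf <- radiusSqFromCompressed(x, full)
    rt <- radiusSqFromCompressed(x, comp)
    dropped <- dropped + sum(rf - rt)
    total <- total + sum(rf)
  }
  expect_lt(dropped / total, (1 - varianceExplained(comp)) * 2)
  expect_gte(dropped / total, 0)
})

test_that("the per-voxel covariance quadratic form equals the squared radius (small-instance oracle)", {
  rs <- randomScenarioMatrices(5, 40, 7, seed = 51)
  ctr <- buildCenter(rs$Dks, rs$w)
  set.seed(52)
  x <- runif(7)
  re <- radiusExact(x, rs$Dks, rs$w, ctr)
  dense <- lapply(rs$Dks, as.matrix)
  ctrDense <- as.matrix(ctr)
  for (i in 1:40) {
    COV <- matrix(0, 7, 7)
    for (k in 1:5) COV <- COV + rs$w[k] * tcrossprod(dense[[k]][i, ])
    Dri <- COV - tcrossprod(ctrDense[i, ])
    expect_equal(drop(t(x) %*% Dri %*% x), re[i]^2, tolerance = 1e-10)
  }
})

test_that("the assembled interval model exposes bounds and keeps rank <= K", {
  setup <- smallSetup()
  im <- setup$intervalModel
  expect_lte(radiusRank(im), nScenarios(setup$optSet))
  expect_gte(varianceExplained(im), 0.99)
  x <- initialFluence(doseCenter(im), structureMask(setup$phantom, "CTV"), 78)
  iv <- doseInterval(x, im)
  expect_true(all(iv$radius >= 0))
  expect_true(all(iv$upper >= iv$center - 1e-12))
  expect_true(all(iv$center >= iv$lower - 1e-12))
})
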