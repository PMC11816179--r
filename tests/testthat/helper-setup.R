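# Shared fixtures, memoized so the expensive end-to-end runs happen once per
# test session.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# coarse 30 x 30 single-slice setup with 3 beams: fast objective/gradient work
smallConfig <- function() {
  cfg <- defaultRunConfig(seed = 7)
  cfg$phantom$shape <- c(30, 30, 1)
  cfg$phantom$spacing <- c(6, 6, 6)
  cfg$beams$gantry_angles <- c(0, 120, 240)
  cfg$optimizer$maxit <- 200
  cfg
}

smallSetup <- function() .memo("small", planSetup(smallConfig()))

# the packaged default study conditions (60 x 60 single slice, 9 beams)
defaultSetup <- function() .memo("default", planSetup(defaultRunConfig()))

defaultComparison <- function() .memo("comparison",
  compareModels(setup = defaultSetup(), thetaSweep = 10))

intervalRunAtTheta <- function(theta) .memo(paste0("theta", theta),
  runPlanOnSetup(defaultSetup(), model = "interval", theta = theta))

# 1 x 1 sparse general matrix (dgCMatrix)
unitSparse <- function(v) Matrix::sparseMatrix(i = 1, j = 1, x = v,
                                               dims = c(1, 1))

# tiny 1-voxel interval model with prescribed center dose and radius at x = 1
unitIntervalModel <- function(center, radius) {
  ctr <- unitSparse(center)
  if (radius > 0) {
    comp <- new("CompressedRadius", rank = 1L, sv = radius,
                modes = list(unitSparse(1)),
                varianceExplained = 1, totalVariance = radius^2,
                fullRank = 1L, dims = c(1L, 1L))
  } else {
    comp <- new("CompressedRadius", rank = 0L, sv = numeric(), modes = list(),
                varianceExplained = 1, totalVariance = 0, fullRank = 0L,
                dims = c(1L, 1L))
  }
  new("IntervalDoseModel", center = ctr, radius = comp, deviations = list(),
      weights = 1, shifts = matrix(0, 1, 3))
}

# random sparse scenario matrices for small-instance oracles
randomScenarioMatrices <- function(K, n, m, seed) {
  set.seed(seed)
  Dks <- lapply(seq_len(K), function(k)
    as(Matrix::Matrix(matrix(runif(n * m), n, m) *
                        (matrix(runif(n * m), n, m) < 0.6), sparse = TRUE),
       "CsparseMatrix"))
  w <- runif(K)
  list(Dks = Dks, w = w / sum(w))
}
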