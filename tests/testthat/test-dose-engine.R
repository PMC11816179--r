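# Toy pencil-beam engine: kernel correctness, attenuation, shift handling.

# phantom whose body fills the whole grid (translation-invariant medium)
fullBodyPhantom <- function(n = 11, spacing = 3) {
  g <- voxelGrid(c(n, n, 1), spacing)
  body <- array(TRUE, dim = c(n, n, 1))
  ctv <- array(FALSE, dim = c(n, n, 1))
  mid <- ceiling(n / 2)
  ctv[(mid - 1):(mid + 1), (mid - 1):(mid + 1), 1] <- TRUE
  voxelPhantom(g, list(body = body, CTV = ctv))
}

test_that("with no attenuation the dose equals the lateral Gaussian kernel (dense oracle)", {
  ph <- fullBodyPhantom(11)
  bs <- beamSetup(gantryAngles = c(0, 90), bixelWidth = 3, mu = 0, penumbraSigma = 3)
  dij <- computeDij(ph, bs, sparsityFloor = 1e-4)
  D <- as.matrix(doseMatrix(dij))
  pos <- voxelCenters(ph)
  iso <- maskCentroid(ph, "CTV")

  for (j in seq_len(ncol(D))) {
    ang <- dij@bixels$angle[j] * pi / 180
    v <- c(cos(ang), sin(ang), 0)
    lat <- as.vector((pos - matrix(iso, nrow(pos), 3, byrow = TRUE)) %*% v) -
      dij@bixels$s[j]
    dense <- exp(-lat^2 / (2 * 3^2))
    dense[dense < 1e-4 * max(dense)] <- 0
    expect_equal(D[, j], dense, tolerance = 1e-12)
  }
  # central bixel: voxels on the ray get the kernel peak at every depth
  jc <- which(dij@bixels$angle == 0)[which.min(abs(dij@bixels$s[dij@bixels$angle == 0]))]
  onRay <- abs(pos[, 1] - iso[1] - dij@bixels$s[jc]) < 1e-9
  expect_gt(sum(onRay), 2)
  expect_true(all(abs(D[onRay, jc] - 1) < 1e-12))
})

test_that("attenuation decreases dose monotonically with depth along a ray", {
  ph <- fullBodyPhantom(11)
  bs <- beamSetup(gantryAngles = 0, bixelWidth = 3, mu = 0.02, penumbraSigma = 3)
  dij <- computeDij(ph, bs)
  D <- as.matrix(doseMatrix(dij))
  pos <- voxelCenters(ph)
  iso <- maskCentroid(ph, "CTV")
  jc <- which.min(abs(dij@bixels$s))
  onRay <- which(abs(pos[, 1] - iso[1] - dij@bixels$s[jc]) < 1e-9)
  # gantry 0 enters from anterior: dose decreases as y decreases
  ord <- onRay[order(pos[onRay, 2], decreasing = TRUE)]
  expect_gt(length(ord), 2)
  expect_true(all(diff(D[ord, jc]) < 0))
})

test_that("a patient shift equals a lookup translation on a translation-invariant phantom", {
  ph <- fullBodyPhantom(11, spacing = 3)
  bs <- beamSetup(gantryAngles = c(0, 90), mu = 0, penumbraSigma = 3)
  d0 <- as.matrix(doseMatrix(computeDij(ph, bs)))
  s <- c(3, 0, 0)  # one voxel in x
  d1 <- as.matrix(doseMatrix(computeDij(ph, bs, shift = s)))
  shp <- gridShape(ph)
  # D_shift[ix, iy] == D_0[ix + 1, iy] for interior voxels
  for (ix in 1:(shp[1] - 1)) for (iy in 1:shp[2]) {
    i <- ix + shp[1] * (iy - 1)
    expect_equal(d1[i, ], d0[i + 1, ], tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected", {
  ph <- fullBodyPhantom(11)
  bs <- beamSetup()
  empty <- array(FALSE, dim = gridShape(ph))
  expect_error(computeDij(ph, bs, target = empty), "empty fluence map")
  expect_error(computeDij(ph, bs, shift = c(NA, 0, 0)), "finite")
})

test_that("scenario Dij lists share the bixel layout and respect caching", {
  ph <- makeProstatePhantom(seed = 3)
  bs <- beamSetup(gantryAngles = c(0, 180))
  sc <- makeOptScenarios(setupErrorModel(c(5, 10, 5)))
  dijs <- computeScenarioDijs(ph, bs, sc)
  expect_length(dijs, 13)
  m <- vapply(dijs, nBixels, integer(1))
  expect_true(all(m == m[1]))
  # IS shifts leave a single-slice dose unchanged: identical to nominal
  nom <- nominalIndex(sc)
  zOnly <- which(scenarioShifts(sc)[, 3] != 0 &
                 rowSums(abs(scenarioShifts(sc)[, 1:2])) == 0)
  for (k in zOnly)
    expect_identical(doseMatrix(dijs[[k]]), doseMatrix(dijs[[nom]]))
  # in-plane shifts do change the dose
  xShift <- which(scenarioShifts(sc)[, 1] != 0)[1]
  expect_false(identical(doseMatrix(dijs[[xShift]]), doseMatrix(dijs[[nom]])))
})
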