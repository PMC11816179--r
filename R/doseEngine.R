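# Desk-scale pencil-beam dose engine.
#
# Parallel (non-divergent) beams; each bixel is an exponentially attenuated
# Gaussian pencil: dose_ij = exp(-mu * depth_i) * exp(-lateral_ij^2 /
# (2 sigma_pen^2)). Depth is the body path length upstream of the voxel along
# the beam axis; lateral is the perpendicular distance from the bixel ray.
# A rigid patient shift delta is realized exactly by translating the
# isocenter by -delta and recomputing. On single-slice grids (nz == 1) the
# bixels are z-invariant line pencils, so IS displacements leave the dose
# unchanged (infinite-cylinder idealization).

#' @importFrom Matrix sparseMatrix crossprod t colSums rowSums
NULL

# unit vectors of the beam frame for a gantry angle (degrees):
# u = beam direction (source -> isocenter), v = lateral in-plane, w = z
.beamFrame <- function(angleDeg) {
  a <- angleDeg * pi / 180
  list(u = c(sin(a), -cos(a), 0), v = c(cos(a), sin(a), 0), w = c(0, 0, 1))
}

# body path length upstream of every voxel along direction u (ray marching,
# nearest-voxel body lookup); independent of the isocenter for parallel beams
.rayDepth <- function(phantom, u, step = NULL) {
  grid <- voxelGridOf(phantom)
  sp <- grid@spacing; shp <- grid@shape
  if (is.null(step)) step <- min(sp[c(1, 2, if (shp[3] > 1L) 3)]) / 2
  pos <- voxelCenters(grid)
  body <- as.vector(structureMask(phantom, "body"))
  tmax <- sqrt(sum((shp * sp)^2))
  ts <- seq(step / 2, tmax, by = step)
  depth <- numeric(nrow(pos))
  for (t in ts) {
    q <- cbind(pos[, 1] - t * u[1], pos[, 2] - t * u[2], pos[, 3] - t * u[3])
    ii <- floor(sweep(q, 2, grid@origin, `-`) %*% diag(1 / sp)) + 1
    inside <- ii[, 1] >= 1 & ii[, 1] <= shp[1] &
              ii[, 2] >= 1 & ii[, 2] <= shp[2] &
              ii[, 3] >= 1 & ii[, 3] <= shp[3]
    lin <- ii[inside, 1] + shp[1] * (ii[inside, 2] - 1) +
           shp[1] * shp[2] * (ii[inside, 3] - 1)
    hit <- logical(nrow(pos))
    hit[inside] <- body[lin]
    depth <- depth + step * hit
  }
  depth
}

# bixel lattice covering the target projection plus 3 sigma_pen, per beam;
# laid out in the *nominal* beam frame so columns are scenario-invariant
.bixelLayout <- function(phantom, beams, iso, target) {
  pos <- voxelCenters(phantom)
  tm <- as.vector(target)
  if (!any(tm)) stop("empty fluence map: no bixel intersects the target projection")
  tpos <- pos[tm, , drop = FALSE]
  pad <- 3 * beams@penumbraSigma
  singleSlice <- gridShape(phantom)[3] == 1L
  out <- list()
  for (b in seq_along(beams@gantryAngles)) {
    fr <- .beamFrame(beams@gantryAngles[b])
    s <- (tpos - matrix(iso, nrow(tpos), 3, byrow = TRUE)) %*% fr$v
    sGrid <- seq(min(s) - pad, max(s) + pad, by = beams@bixelWidth)
    if (singleSlice) {
      out[[b]] <- data.frame(beam = b, angle = beams@gantryAngles[b],
                             s = sGrid, z = 0)
    } else {
      z <- (tpos - matrix(iso, nrow(tpos), 3, byrow = TRUE)) %*% fr$w
      zGrid <- seq(min(z) - pad, max(z) + pad, by = beams@bixelWidth)
      g <- expand.grid(s = sGrid, z = zGrid)
      out[[b]] <- data.frame(beam = b, angle = beams@gantryAngles[b],
                             s = g$s, z = g$z)
    }
  }
  do.call(rbind, out)
}

#' Compute a sparse dose-influence matrix for one scenario
#'
#' @param phantom a [VoxelPhantom-class] with a body mask.
#' @param beams a [beamSetup()].
#' @param shift rigid patient shift (mm triple); realized by translating the
#'   isocenter by \code{-shift}.
#' @param target structure name (or logical mask) whose projection defines the
#'   bixel lattice; defaults to PTV when present, else CTV. The lattice is
#'   always built at the nominal position so the columns are identical across
#'   scenarios.
#' @param sparsityFloor per-column relative floor; entries below
#'   \code{sparsityFloor * max(column)} are dropped.
#' @param depthCache optional environment memoizing per-beam depth vectors
#'   (depth is scenario-independent for parallel beams).
#' @return a [DoseInfluence-class].
#' @examples
#' ph <- makeProstatePhantom(seed = 1)
#' dij <- computeDij(ph, beamSetup(gantryAngles = c(0, 120, 240)))
#' dij
#' @export
computeDij <- function(phantom, beams, shift = c(0, 0, 0), target = NULL,
                       sparsityFloor = 1e-4, depthCache = NULL) {
  if (any(!is.finite(shift))) stop("shift must be finite")
  grid <- voxelGridOf(phantom)
  if (is.null(target))
    target <- if ("PTV" %in% structureNames(phantom)) "PTV" else "CTV"
  if (is.character(target)) target <- structureMask(phantom, target)
  iso <- beams@isocenter
  if (any(is.na(iso))) iso <- maskCentroid(phantom, "CTV")

  bixels <- .bixelLayout(phantom, beams, iso, target)
  pos <- voxelCenters(grid)
  n <- nrow(pos)
  singleSlice <- gridShape(phantom)[3] == 1L
  isoEff <- iso - shift
  s2 <- 2 * beams@penumbraSigma^2
  cutoff2 <- -s2 * log(sparsityFloor)  # lateral^2 beyond which the kernel is < floor

  triplets <- vector("list", length(beams@gantryAngles))
  for (b in seq_along(beams@gantryAngles)) {
    fr <- .beamFrame(beams@gantryAngles[b])
    dkey <- as.character(beams@gantryAngles[b])
    depth <- if (!is.null(depthCache) && !is.null(depthCache[[dkey]])) {
      depthCache[[dkey]]
    } else {
      d <- .rayDepth(phantom, fr$u)
      if (!is.null(depthCache)) depthCache[[dkey]] <- d
      d
    }
    atten <- exp(-beams@mu * depth)
    rel <- sweep(pos, 2, isoEff, `-`)
    sv <- as.vector(rel %*% fr$v)
    zv <- if (singleSlice) NULL else as.vector(rel %*% fr$w)
    cols <- which(bixels$beam == b)
    bx <- bixels[cols, , drop = FALSE]
    ii <- jj <- xx <- list()
    for (q in seq_len(nrow(bx))) {
      lat2 <- (sv - bx$s[q])^2
      if (!singleSlice) lat2 <- lat2 + (zv - bx$z[q])^2
      keep <- which(lat2 <= cutoff2)
      if (!length(keep)) next
      val <- atten[keep] * exp(-lat2[keep] / s2)
      ok <- val >= sparsityFloor * max(val)
      ii[[q]] <- keep[ok]; jj[[q]] <- rep(cols[q], sum(ok)); xx[[q]] <- val[ok]
    }
    triplets[[b]] <- list(i = unlist(ii), j = unlist(jj), x = unlist(xx))
  }
  D <- sparseMatrix(i = unlist(lapply(triplets, `[[`, "i")),
                    j = unlist(lapply(triplets, `[[`, "j")),
                    x = unlist(lapply(triplets, `[[`, "x")),
                    dims = c(n, nrow(bixels)))
  rownames(bixels) <- NULL
  new("DoseInfluence", D = as(D, "CsparseMatrix"), shift = as.numeric(shift),
      bixels = bixels)
}

#' Dose-influence matrices for every scenario of a set
#'
#' On single-slice phantoms, scenarios whose in-plane shift repeats reuse the
#' cached matrix (IS shifts do not change the dose there).
#'
#' @param phantom,beams,target,sparsityFloor as in [computeDij()].
#' @param scenarios a [ScenarioSet-class].
#' @return list of [DoseInfluence-class], one per scenario.
#' @export
computeScenarioDijs <- function(phantom, beams, scenarios, target = NULL,
                                sparsityFloor = 1e-4) {
  shifts <- scenarioShifts(scenarios)
  singleSlice <- gridShape(phantom)[3] == 1L
  key <- apply(shifts, 1, function(s)
    paste(signif(if (singleSlice) s[1:2] else s, 12), collapse = "/"))
  cache <- new.env(parent = emptyenv())
  depthCache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(shifts)), function(k) {
    if (!is.null(cache[[key[k]]])) return(cache[[key[k]]])
    dij <- computeDij(phantom, beams, shifts[k, ], target, sparsityFloor,
                      depthCache = depthCache)
    cache[[key[k]]] <- dij
    dij
  })
}
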