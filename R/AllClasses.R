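#' @import methods
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom stats dnorm optim quantile runif setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# ---------------------------------------------------------------------------
# VoxelGrid
# ---------------------------------------------------------------------------

#' Regular voxel grid
#'
#' A regular 3D voxel grid (a single-slice grid has \code{nz = 1}). Axis
#' convention: x = left-right (LR), y = anterior-posterior (AP, positive =
#' anterior), z = inferior-superior (IS). All geometric quantities are in mm.
#'
#' @slot shape integer triple (nx, ny, nz), all >= 1.
#' @slot spacing mm triple, all > 0.
#' @slot origin mm triple; position of the grid corner. Voxel (i, j, k) is
#'   centred at \code{origin + (c(i, j, k) - 0.5) * spacing}.
#'
#' @export
setClass("VoxelGrid",
  slots = c(shape = "integer", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be an integer triple with all entries >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be a positive mm triple")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite mm triple")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param shape integer triple (nx, ny, nz).
#' @param spacing voxel spacing in mm (scalar recycled, or triple).
#' @param origin grid corner in mm; defaults to centring the grid on 0.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- voxelGrid(c(60, 60, 1), 3)
#' nVoxels(g)
#' @export
voxelGrid <- function(shape, spacing = 3, origin = NULL) {
  shape <- as.integer(shape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(origin)) origin <- -shape * spacing / 2
  new("VoxelGrid", shape = shape, spacing = spacing,
      origin = as.numeric(origin))
}

# ---------------------------------------------------------------------------
# VoxelPhantom
# ---------------------------------------------------------------------------

#' Voxel phantom: a grid plus named structure masks
#'
#' Binary structure masks (logical arrays with the grid's dimensions) over a
#' [VoxelGrid-class]. Generated prostate-like phantoms carry the masks
#' \code{CTV}, \code{body}, \code{bladder}, \code{rectum} and the derived
#' \code{PTV}, \code{ring_0_20}, \code{ring_20_50}.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot masks named list of logical arrays; every mask must be contained in
#'   \code{body} when a body mask is present.
#'
#' @export
setClass("VoxelPhantom", slots = c(grid = "VoxelGrid", masks = "list"))

setValidity("VoxelPhantom", function(object) {
  msg <- character()
  shp <- object@grid@shape
  if (length(object@masks) && is.null(names(object@masks)))
    msg <- c(msg, "masks must be named")
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(shp)))
      msg <- c(msg, sprintf("mask '%s' must be a logical array with grid dimensions", nm))
  }
  if (!length(msg) && "body" %in% names(object@masks)) {
    body <- object@masks[["body"]]
    for (nm in setdiff(names(object@masks), "body"))
      if (any(object@masks[[nm]] & !body))
        msg <- c(msg, sprintf("mask '%s' extends outside the body", nm))
  }
  if (!length(msg) && "CTV" %in% names(object@masks) &&
      !any(object@masks[["CTV"]]))
    msg <- c(msg, "CTV empty")
  if (length(msg)) msg else TRUE
})

#' @rdname VoxelPhantom-class
#' @param grid a [VoxelGrid-class].
#' @param masks named list of logical arrays.
#' @export
voxelPhantom <- function(grid, masks) {
  masks <- lapply(masks, function(m) {
    m <- array(as.logical(m), dim = grid@shape)
    m
  })
  new("VoxelPhantom", grid = grid, masks = masks)
}

# ---------------------------------------------------------------------------
# BeamSetup
# ---------------------------------------------------------------------------

#' Beam and pencil-kernel configuration for the toy dose engine
#'
#' @slot gantryAngles gantry angles in degrees; 0 deg enters from anterior,
#'   angles increase clockwise when viewed from the feet.
#' @slot bixelWidth bixel (beamlet) lattice spacing in mm.
#' @slot isocenter mm triple, or \code{NA} to use the CTV centroid.
#' @slot mu linear attenuation coefficient per mm of body path.
#' @slot penumbraSigma lateral Gaussian pencil sigma in mm.
#'
#' @export
setClass("BeamSetup",
  slots = c(gantryAngles = "numeric", bixelWidth = "numeric",
            isocenter = "numeric", mu = "numeric", penumbraSigma = "numeric"))

setValidity("BeamSetup", function(object) {
  msg <- character()
  if (!length(object@gantryAngles)) msg <- c(msg, "at least one gantry angle required")
  if (object@bixelWidth <= 0) msg <- c(msg, "bixel width must be > 0")
  if (object@mu < 0) msg <- c(msg, "attenuation mu must be >= 0")
  if (object@penumbraSigma <= 0) msg <- c(msg, "penumbra sigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BeamSetup-class
#' @param gantryAngles,bixelWidth,isocenter,mu,penumbraSigma see slots.
#' @export
beamSetup <- function(gantryAngles = seq(0, 320, by = 40), bixelWidth = 5,
                      isocenter = NA_real_, mu = 0.005, penumbraSigma = 3) {
  new("BeamSetup", gantryAngles = as.numeric(gantryAngles),
      bixelWidth = as.numeric(bixelWidth),
      isocenter = as.numeric(isocenter), mu = as.numeric(mu),
      penumbraSigma = as.numeric(penumbraSigma))
}

# ---------------------------------------------------------------------------
# ScenarioSet
# ---------------------------------------------------------------------------

#' Set of rigid setup-error scenarios
#'
#' K rigid patient shifts with normalized probability weights. The
#' \code{purpose} tag ("optimization" or "evaluation") records which stage a
#' set was generated for; the evaluation routines refuse optimization sets.
#'
#' @slot shifts K x 3 matrix of shifts (dx, dy, dz) in mm.
#' @slot weights length-K nonnegative weights summing to 1.
#' @slot nominal index of the nominal (zero-shift) scenario.
#' @slot purpose character tag.
#' @slot sigma the (LR, AP, IS) standard deviations (mm) the set was built from.
#'
#' @export
setClass("ScenarioSet",
  slots = c(shifts = "matrix", weights = "numeric", nominal = "integer",
            purpose = "character", sigma = "numeric"))

setValidity("ScenarioSet", function(object) {
  msg <- character()
  K <- nrow(object@shifts)
  if (ncol(object@shifts) != 3L) msg <- c(msg, "shifts must be K x 3")
  if (length(object@weights) != K) msg <- c(msg, "one weight per scenario required")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (K && abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1 (within 1e-12)")
  if (length(object@nominal) != 1L || object@nominal < 1L || object@nominal > K)
    msg <- c(msg, "nominal index out of range")
  else if (any(object@shifts[object@nominal, ] != 0))
    msg <- c(msg, "nominal scenario must have zero shift")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# DoseInfluence
# ---------------------------------------------------------------------------

#' Sparse dose-influence matrix for one scenario
#'
#' Maps m bixel fluences to n voxel doses (Gy per unit fluence) for one rigid
#' shift scenario. Columns (bixels) are identical across the scenarios of one
#' plan; the bixel table records beam membership and lateral coordinates.
#'
#' @slot D sparse nonnegative n x m matrix (\code{dgCMatrix}).
#' @slot shift the patient shift (mm triple) the matrix was computed for.
#' @slot bixels data.frame with columns beam, angle, s (lateral mm), z (mm).
#'
#' @export
setClass("DoseInfluence",
  slots = c(D = "dgCMatrix", shift = "numeric", bixels = "data.frame"))

setValidity("DoseInfluence", function(object) {
  msg <- character()
  if (length(object@D@x) && min(object@D@x) < 0)
    msg <- c(msg, "dose-influence entries must be >= 0")
  if (nrow(object@bixels) != ncol(object@D))
    msg <- c(msg, "bixel table must have one row per column")
  if (length(object@shift) != 3L || any(!is.finite(object@shift)))
    msg <- c(msg, "shift must be a finite mm triple")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CompressedRadius / IntervalDoseModel
# ---------------------------------------------------------------------------

#' SVD-compressed radius representation
#'
#' Low-rank representation of the per-voxel dose-spread quadratic form. The
#' weighted deviation matrices \eqn{E_k = \sqrt{w_k}(D_k - D_c)} are decomposed
#' along the scenario axis; with orthonormal scenario loadings the squared
#' radius of any fluence x is \eqn{\sum_r \sigma_r^2 (\Phi_r x)_i^2}, exact
#' when all positive singular values are retained.
#'
#' @slot rank number of retained modes k (k <= K).
#' @slot sv retained singular values, descending.
#' @slot modes list of k sparse n x m mode matrices \eqn{\Phi_r}.
#' @slot varianceExplained fraction of total squared singular value retained.
#' @slot totalVariance sum of all squared singular values.
#' @slot fullRank number of positive singular values before truncation.
#' @slot dims (n, m) dimensions of the mode matrices.
#'
#' @export
setClass("CompressedRadius",
  slots = c(rank = "integer", sv = "numeric", modes = "list",
            varianceExplained = "numeric", totalVariance = "numeric",
            fullRank = "integer", dims = "integer"))

setValidity("CompressedRadius", function(object) {
  msg <- character()
  k <- object@rank
  if (length(object@sv) != k || length(object@modes) != k)
    msg <- c(msg, "rank, singular values and modes must agree")
  if (k && (any(diff(object@sv) > 1e-12) || any(object@sv <= 0)))
    msg <- c(msg, "singular values must be positive and descending")
  if (length(msg)) msg else TRUE
})

#' Interval dose-influence model
#'
#' Center matrix \eqn{D_c = \sum_k w_k D_k} plus the radius representation:
#' the exact weighted deviation matrices and/or their SVD-compressed form.
#'
#' @slot center sparse n x m center matrix.
#' @slot radius a [CompressedRadius-class].
#' @slot deviations list of K sparse weighted deviation matrices
#'   \eqn{\sqrt{w_k}(D_k - D_c)} (may be empty if dropped after compression).
#' @slot weights scenario weights.
#' @slot shifts K x 3 scenario shift matrix.
#'
#' @export
setClass("IntervalDoseModel",
  slots = c(center = "dgCMatrix", radius = "CompressedRadius",
            deviations = "list", weights = "numeric", shifts = "matrix"))

# ---------------------------------------------------------------------------
# PlanEvaluation
# ---------------------------------------------------------------------------

#' Robustness evaluation of one optimized plan
#'
#' @slot model plan model id ("nominal", "ptv", "minimax", "interval").
#' @slot theta Bertoluzza spread weight used (NA for non-interval models).
#' @slot fluence optimized bixel fluence vector.
#' @slot objective final objective value.
#' @slot expected per-voxel expected dose (Gy) over the evaluation grid.
#' @slot stdev per-voxel dose standard deviation (Gy).
#' @slot delta per-CTV-voxel Delta values.
#' @slot ri robustness index (fraction of CTV voxels with Delta < 1).
#' @slot dvh nominal/expected/std DVH table (long format).
#' @slot price list with V40Gy rectum and V60Gy bladder percentages at the
#'   nominal scenario.
#' @slot params evaluation parameters (p, c1, c2, bins).
#'
#' @export
setClass("PlanEvaluation",
  slots = c(model = "character", theta = "numeric", fluence = "numeric",
            objective = "numeric", expected = "numeric", stdev = "numeric",
            delta = "numeric", ri = "numeric", dvh = "data.frame",
            price = "list", params = "list"))
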