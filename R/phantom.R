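# Synthetic prostate-like phantoms, margin expansion and ring structures.

#' Anisotropic PTV margin specification
#'
#' Margins in mm per direction; the AP direction is asymmetric (anterior vs
#' posterior), the common prostate recipe being (7, 7-4, 7) mm: 7 mm LR,
#' 7 mm anterior, 4 mm posterior, 7 mm IS.
#'
#' @param lr left-right margin (mm).
#' @param anterior,posterior AP margins (mm).
#' @param is inferior-superior margin (mm).
#' @return list of class "MarginSpec".
#' @examples marginSpec()  # the (7, 7-4, 7) mm default
#' @export
marginSpec <- function(lr = 7, anterior = 7, posterior = 4, is = 7) {
  m <- list(lr = lr, anterior = anterior, posterior = posterior, is = is)
  if (any(unlist(m) < 0)) stop("margins must be >= 0")
  structure(m, class = "MarginSpec")
}

#' Default prostate phantom configuration
#'
#' A single-slice 60 x 60 grid at 3 mm spacing (180 x 180 mm axial slice)
#' holding an elliptical body contour, an ellipsoidal CTV, a bladder anterior
#' of the CTV and a rectum posterior of it. Centers/semi-axes in mm relative
#' to the grid center; \code{jitter} is the half-width (mm) of the uniform
#' seeded perturbation applied to the OAR centers (and +/-5% to their
#' semi-axes) so that different seeds emulate different patients.
#'
#' @param shape,spacing grid geometry.
#' @return configuration list accepted by [makeProstatePhantom()].
#' @export
defaultPhantomConfig <- function(shape = c(60, 60, 1), spacing = c(3, 3, 3)) {
  list(
    shape = shape, spacing = spacing,
    body    = list(center = c(0, 0, 0),   semiaxes = c(80, 72, Inf)),
    CTV     = list(center = c(0, -5, 0),  semiaxes = c(22, 20, 20)),
    bladder = list(center = c(0, 38, 0),  semiaxes = c(26, 20, 24)),
    rectum  = list(center = c(0, -40, 0), semiaxes = c(15, 12, 30)),
    jitter = 2
  )
}

# Ellipsoid membership on the voxel grid. Infinite semi-axes drop that axis
# (used for the body "cylinder" on single-slice grids and for all structures
# along z when nz == 1, where the phantom is treated as z-invariant).
.ellipsoidMask <- function(grid, center, semiaxes) {
  pos <- voxelCenters(grid)
  if (grid@shape[3] == 1L) semiaxes[3] <- Inf
  q <- rep(0, nrow(pos))
  for (a in 1:3) {
    if (is.finite(semiaxes[a])) {
      if (semiaxes[a] <= 0) return(array(FALSE, dim = grid@shape))
      q <- q + ((pos[, a] - center[a]) / semiaxes[a])^2
    }
  }
  array(q <= 1, dim = grid@shape)
}

#' Generate a synthetic prostate-like voxel phantom
#'
#' Builds the structure set (body, CTV, bladder, rectum), expands the CTV by
#' the PTV margins and derives the two normal-tissue rings (0-20 mm and
#' 20-50 mm from the ring anchor structure). Deterministic given (config,
#' seed); the seed drives only the patient-variability jitter of the OAR
#' geometry.
#'
#' @param config list from [defaultPhantomConfig()] (fields may be overridden).
#' @param seed integer seed.
#' @param margins a [marginSpec()] for the PTV expansion.
#' @param ringAnchor structure the rings are grown from ("CTV" or "PTV").
#' @return a [VoxelPhantom-class] with masks CTV, body, bladder, rectum, PTV,
#'   ring_0_20, ring_20_50.
#' @examples
#' ph <- makeProstatePhantom(seed = 42)
#' ph
#' @export
makeProstatePhantom <- function(config = defaultPhantomConfig(), seed = 42,
                                margins = marginSpec(), ringAnchor = "CTV") {
  grid <- voxelGrid(config$shape, config$spacing)
  jit <- if (is.null(config$jitter)) 0 else config$jitter

  rng <- local({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    list(centers = matrix(runif(6, -jit, jit), 2, 3),
         scales  = matrix(runif(6, 0.95, 1.05), 2, 3))
  })

  structs <- config[c("body", "CTV", "bladder", "rectum")]
  structs$bladder$center <- structs$bladder$center + rng$centers[1, ]
  structs$rectum$center  <- structs$rectum$center  + rng$centers[2, ]
  structs$bladder$semiaxes <- structs$bladder$semiaxes * rng$scales[1, ]
  structs$rectum$semiaxes  <- structs$rectum$semiaxes  * rng$scales[2, ]

  masks <- lapply(structs, function(s)
    .ellipsoidMask(grid, s$center, s$semiaxes))
  names(masks) <- names(structs)

  if (!any(masks$CTV)) stop("CTV empty")
  for (nm in c("CTV", "bladder", "rectum")) {
    if (!any(masks[[nm]])) stop(sprintf("structure '%s' is empty", nm))
    if (any(masks[[nm]] & !masks$body))
      stop(sprintf("structure '%s' extends outside the body contour", nm))
  }
  # extent check against the grid (body may be clipped by design, organs not)
  ext <- gridShape(grid) * voxelSpacing(grid) / 2
  for (nm in c("CTV", "bladder", "rectum")) {
    s <- structs[[nm]]
    hi <- abs(s$center) + ifelse(is.finite(s$semiaxes), s$semiaxes, 0)
    ax <- if (grid@shape[3] == 1L) 1:2 else 1:3
    if (any(hi[ax] > ext[ax]))
      stop(sprintf("structure '%s' extends outside the grid", nm))
  }
  if (any(masks$CTV & masks$bladder) || any(masks$CTV & masks$rectum))
    stop("CTV overlaps an organ at risk; adjust the phantom geometry")

  masks$PTV <- expandMargin(masks$CTV, margins, grid) & masks$body

  anchor <- if (identical(ringAnchor, "PTV")) masks$PTV else masks$CTV
  masks$ring_0_20  <- makeRing(anchor, 0, 20, grid, body = masks$body)
  masks$ring_20_50 <- makeRing(anchor, 20, 50, grid, body = masks$body)

  voxelPhantom(grid, masks)
}

#' Expand a mask by anisotropic, AP-asymmetric margins
#'
#' The expansion is the union, over source voxels, of an ellipsoid with
#' semi-axes (lr, anterior-or-posterior, is); the AP semi-axis is the anterior
#' margin for displacements with dy >= 0 and the posterior margin otherwise.
#' A zero margin in a direction permits no displacement along it. The result
#' is clipped to the grid.
#'
#' @param mask non-empty logical mask array.
#' @param margins a [marginSpec()].
#' @param grid the [VoxelGrid-class] the mask lives on.
#' @return logical mask array, a superset of \code{mask}.
#' @export
expandMargin <- function(mask, margins, grid) {
  if (!any(mask)) stop("mask is empty")
  sp <- voxelSpacing(grid)
  shp <- gridShape(grid)

  nOff <- floor(c(margins$lr, max(margins$anterior, margins$posterior),
                  margins$is) / sp)
  offs <- expand.grid(dx = -nOff[1]:nOff[1], dy = -nOff[2]:nOff[2],
                      dz = -nOff[3]:nOff[3])
  dmm <- sweep(as.matrix(offs), 2, sp, `*`)
  normalized <- function(d, m) {
    m <- rep_len(m, length(d))
    ifelse(m > 0, (d / m)^2, ifelse(d == 0, 0, Inf))
  }
  my <- ifelse(dmm[, 2] >= 0, margins$anterior, margins$posterior)
  q <- normalized(dmm[, 1], margins$lr) + normalized(dmm[, 2], my) +
       normalized(dmm[, 3], margins$is)
  offs <- offs[q <= 1, , drop = FALSE]

  out <- array(FALSE, dim = shp)
  src <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(offs))) {
    tgt <- sweep(src, 2, as.numeric(offs[r, ]), `+`)
    keep <- tgt[, 1] >= 1 & tgt[, 1] <= shp[1] &
            tgt[, 2] >= 1 & tgt[, 2] <= shp[2] &
            tgt[, 3] >= 1 & tgt[, 3] <= shp[3]
    out[tgt[keep, , drop = FALSE]] <- TRUE
  }
  out
}

#' Ring (shell) structure around a target
#'
#' Voxels outside the target whose Euclidean distance to the nearest target
#' voxel center lies in the half-open band [inner, outer) mm, intersected
#' with the body when given.
#'
#' @param target non-empty logical mask array.
#' @param inner,outer band limits in mm, 0 <= inner < outer.
#' @param grid the [VoxelGrid-class].
#' @param body optional body mask to intersect with.
#' @return logical mask array.
#' @export
makeRing <- function(target, inner, outer, grid, body = NULL) {
  if (inner < 0 || inner >= outer) stop("ring bands require 0 <= inner < outer")
  if (!any(target)) stop("target mask is empty")
  pos <- voxelCenters(grid)
  tpos <- pos[as.vector(target), , drop = FALSE]

  cand <- !as.vector(target)
  if (!is.null(body)) cand <- cand & as.vector(body)
  # bounding-box precull: candidates farther than outer from the target's
  # bounding box (per axis) cannot be in the band
  lo <- apply(tpos, 2, min) - outer
  hi <- apply(tpos, 2, max) + outer
  cand <- cand & pos[, 1] >= lo[1] & pos[, 1] <= hi[1] &
                 pos[, 2] >= lo[2] & pos[, 2] <= hi[2] &
                 pos[, 3] >= lo[3] & pos[, 3] <= hi[3]

  d2 <- rep(Inf, nrow(pos))
  idx <- which(cand)
  if (length(idx)) {
    cpos <- pos[idx, , drop = FALSE]
    # chunked nearest-target distance (brute force; desk-scale grids)
    step <- max(1L, floor(2e6 / nrow(tpos)))
    for (s in seq(1, length(idx), by = step)) {
      e <- min(s + step - 1, length(idx))
      block <- cpos[s:e, , drop = FALSE]
      dd <- outer(rowSums(block^2), rowSums(tpos^2), `+`) -
            2 * block %*% t(tpos)
      d2[idx[s:e]] <- pmax(apply(dd, 1, min), 0)
    }
  }
  d <- sqrt(d2)
  array(cand & d >= inner & d < outer, dim = gridShape(grid))
}
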