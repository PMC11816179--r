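# Plan evaluation under the evaluation scenario grid: per-voxel dose moments,
# Delta-map, robustness index, DVH / confidence-band DVH, price of robustness.

#' Robustness-evaluation parameters
#'
#' c1 and c2 are the tolerances (as fractions of the prescription) for the
#' mean-deviation and spread components of the per-voxel Delta score.
#'
#' @param p prescribed dose (Gy).
#' @param c1,c2 positive component weights, default 0.05.
#' @return list of class "RobustnessParams".
#' @export
robustnessParams <- function(p = 78, c1 = 0.05, c2 = 0.05) {
  if (p <= 0 || c1 <= 0 || c2 <= 0) stop("p, c1, c2 must be > 0")
  structure(list(p = p, c1 = c1, c2 = c2), class = "RobustnessParams")
}

#' Per-voxel dose moments over a scenario set
#'
#' Expected dose E = sum_k w_k D_k x and per-voxel standard deviation
#' sqrt(sum_k w_k (D_k x)^2 - E^2) (round-off clamped at 0).
#'
#' @param x fluence vector.
#' @param Dks list of scenario matrices (or [DoseInfluence-class]).
#' @param w scenario weights summing to 1.
#' @return list(expected, stdev), per-voxel Gy vectors.
#' @export
scenarioDoseStats <- function(x, Dks, w) {
  Dks <- .asDij(Dks)
  .checkWeights(w, length(Dks))
  doses <- lapply(Dks, function(D) as.vector(D %*% x))
  E <- numeric(length(doses[[1]]))
  M2 <- numeric(length(doses[[1]]))
  for (k in seq_along(doses)) {
    E <- E + w[k] * doses[[k]]
    M2 <- M2 + w[k] * doses[[k]]^2
  }
  list(expected = E, stdev = sqrt(pmax(M2 - E^2, 0)))
}

#' Per-CTV-voxel Delta map
#'
#' \eqn{\Delta_i = \left(\frac{E(d_i) - p}{c_1 p}\right)^2 +
#'   \left(\frac{std(d_i)}{c_2 p}\right)^2}. A voxel is robustly treated iff
#' \eqn{\Delta_i < 1} (strict).
#'
#' @param stats list(expected, stdev) from [scenarioDoseStats()].
#' @param params a [robustnessParams()].
#' @param ctv logical CTV mask, non-empty.
#' @return numeric vector of Delta values over the CTV voxels.
#' @export
deltaMap <- function(stats, params, ctv) {
  idx <- which(as.vector(ctv))
  if (!length(idx)) stop("empty CTV")
  ((stats$expected[idx] - params$p) / (params$c1 * params$p))^2 +
    (stats$stdev[idx] / (params$c2 * params$p))^2
}

#' Robustness index
#'
#' Fraction of CTV voxels with Delta strictly below 1.
#'
#' @param delta per-CTV-voxel Delta values.
#' @return RI in [0, 1].
#' @examples robustnessIndex(c(0.5, 2.0, 0.9, 1.0))  # 0.5
#' @export
robustnessIndex <- function(delta) {
  if (!length(delta)) stop("empty Delta map")
  mean(delta < 1)
}

#' Volume receiving at least a threshold dose
#'
#' VxGy as a percentage: 100 * |voxels in mask with dose >= threshold| /
#' |mask| (closed threshold, "x Gy or higher").
#'
#' @param d per-voxel dose vector (whole grid).
#' @param mask logical structure mask, non-empty.
#' @param threshold dose threshold (Gy).
#' @return percentage in [0, 100].
#' @export
vx <- function(d, mask, threshold) {
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("empty structure mask")
  100 * mean(d[idx] >= threshold)
}

#' Dose-volume histogram
#'
#' @param d per-voxel dose vector.
#' @param mask logical structure mask, non-empty.
#' @param bins dose bin edges (Gy); default 0 to 1.2 * max bin at 0.1 Gy.
#' @return data.frame(dose, volume) with volume in percent, monotone
#'   non-increasing in dose.
#' @export
dvh <- function(d, mask, bins = NULL) {
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("empty structure mask")
  if (is.null(bins)) bins <- seq(0, max(d[idx], 1) * 1.2, by = 0.1)
  vol <- vapply(bins, function(t) 100 * mean(d[idx] >= t), numeric(1))
  data.frame(dose = bins, volume = vol)
}

#' Confidence-band DVH over a scenario set
#'
#' Per dose bin, the expected value and standard deviation of the
#' per-scenario volume values under the scenario weights, plus the nominal
#' (zero-shift) curve.
#'
#' @param x fluence vector.
#' @param Dks list of evaluation scenario matrices.
#' @param w weights summing to 1.
#' @param masks named list of logical structure masks.
#' @param bins dose bin edges (Gy).
#' @param nominal index of the nominal scenario within \code{Dks}.
#' @return data.frame(structure, dose, nominal, expected, std).
#' @export
cdvh <- function(x, Dks, w, masks, bins, nominal = 1L) {
  Dks <- .asDij(Dks)
  .checkWeights(w, length(Dks))
  doses <- lapply(Dks, function(D) as.vector(D %*% x))
  out <- list()
  for (nm in names(masks)) {
    idx <- which(as.vector(masks[[nm]]))
    curves <- vapply(doses, function(d)
      vapply(bins, function(t) 100 * mean(d[idx] >= t), numeric(1)),
      numeric(length(bins)))
    curves <- matrix(curves, nrow = length(bins))
    E <- as.vector(curves %*% w)
    S <- sqrt(pmax(as.vector(curves^2 %*% w) - E^2, 0))
    out[[nm]] <- data.frame(structure = nm, dose = bins,
                            nominal = curves[, nominal], expected = E, std = S)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Price of robustness (nominal-scenario OAR metrics)
#'
#' V40Gy of the rectum and V60Gy of the bladder, computed on the
#' nominal-scenario (perfect positioning) dose.
#'
#' @param x fluence vector.
#' @param nominalD nominal dose-influence matrix.
#' @param masks named list with \code{bladder} and \code{rectum} masks.
#' @return list(v40_rectum, v60_bladder) in percent.
#' @export
priceOfRobustness <- function(x, nominalD, masks) {
  if (!all(c("bladder", "rectum") %in% names(masks)))
    stop("bladder and rectum masks required")
  D <- if (is(nominalD, "DoseInfluence")) nominalD@D else nominalD
  d <- as.vector(D %*% x)
  list(v40_rectum = vx(d, masks$rectum, 40),
       v60_bladder = vx(d, masks$bladder, 60))
}

#' Evaluate an optimized plan on the evaluation grid
#'
#' Runs the full robustness evaluation: scenario dose moments, Delta-map and
#' robustness index over the CTV, DVH/cDVH tables, and the
#' price-of-robustness metrics at the nominal scenario. Refuses scenario sets
#' not tagged "evaluation" (planning and evaluation scenario sets are kept
#' separate by construction).
#'
#' @param x optimized fluence.
#' @param evalDijs list of [DoseInfluence-class] for the evaluation grid.
#' @param evalSet the evaluation [ScenarioSet-class].
#' @param phantom a [VoxelPhantom-class].
#' @param params a [robustnessParams()].
#' @param model,theta,objective metadata recorded in the result.
#' @param structures structure names for the DVH tables.
#' @return a [PlanEvaluation-class].
#' @export
evaluatePlan <- function(x, evalDijs, evalSet, phantom,
                         params = robustnessParams(),
                         model = "custom", theta = NA_real_,
                         objective = NA_real_,
                         structures = c("CTV", "bladder", "rectum")) {
  if (!identical(scenarioPurpose(evalSet), "evaluation"))
    stop("plan evaluation requires the evaluation scenario grid, not the '",
         scenarioPurpose(evalSet), "' set")
  w <- scenarioWeights(evalSet)
  stats <- scenarioDoseStats(x, evalDijs, w)
  ctv <- structureMask(phantom, "CTV")
  delta <- deltaMap(stats, params, ctv)
  ri <- robustnessIndex(delta)
  bins <- seq(0, 1.2 * params$p, by = 0.1)
  masks <- lapply(structures, function(nm) structureMask(phantom, nm))
  names(masks) <- structures
  dvhTab <- cdvh(x, evalDijs, w, masks, bins, nominal = nominalIndex(evalSet))
  price <- priceOfRobustness(x, evalDijs[[nominalIndex(evalSet)]],
                             list(bladder = structureMask(phantom, "bladder"),
                                  rectum = structureMask(phantom, "rectum")))
  new("PlanEvaluation", model = model, theta = as.numeric(theta),
      fluence = as.numeric(x), objective = as.numeric(objective),
      expected = stats$expected, stdev = stats$stdev, delta = delta,
      ri = ri, dvh = dvhTab, price = price,
      params = list(p = params$p, c1 = params$c1, c2 = params$c2, bins = bins))
}
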