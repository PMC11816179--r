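# Bertoluzza interval metric, per-structure penalty functions, and the
# composite objectives (nominal / PTV / minimax / interval) with analytic
# gradients.

#' Bertoluzza distance between two intervals
#'
#' \eqn{\|\Delta_\theta(X, Y)\| = \sqrt{(x_c - y_c)^2 + \theta (x_r - y_r)^2}}
#' for intervals written as (center, radius). For theta > 0 this is a metric
#' on intervals: symmetric, zero iff both centers and radii coincide, and
#' satisfying the triangle inequality.
#'
#' @param x,y intervals as length-2 numerics c(center, radius).
#' @param theta spread weight, >= 0.
#' @return nonnegative distance.
#' @examples
#' bertoluzzaDistance(c(80, 4), c(78, 0), theta = 10)  # sqrt(164)
#' @export
bertoluzzaDistance <- function(x, y, theta) {
  if (theta < 0) stop("theta must be >= 0")
  sqrt((x[1] - y[1])^2 + theta * (x[2] - y[2])^2)
}

#' Interval CTV objective (Bertoluzza form)
#'
#' \eqn{F_{CTV}(x) = \sum_{i \in CTV} [(d_c(x))_i - p]^2 + \theta (d_r(x))_i^2}:
#' the squared Bertoluzza distance between each CTV voxel's dose interval and
#' the degenerate prescription interval [p, 0], summed (or averaged) over the
#' CTV.
#'
#' @param x fluence vector.
#' @param model an [IntervalDoseModel-class].
#' @param ctv logical CTV mask (array or vector), non-empty.
#' @param p prescribed dose (Gy).
#' @param theta spread weight >= 0.
#' @param aggregate "sum" (the plain formula) or "mean" (per-voxel average,
#'   as used inside the composite objective).
#' @return list(value, gradient) with the analytic gradient w.r.t. x.
#' @export
fCtvInterval <- function(x, model, ctv, p, theta, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (theta < 0) stop("theta must be >= 0")
  ctv <- as.vector(ctv)
  idx <- which(ctv)
  if (!length(idx)) stop("empty CTV")
  sc <- if (aggregate == "mean") 1 / length(idx) else 1

  ctr <- as.vector(model@center %*% x)
  res <- numeric(length(ctr))
  res[idx] <- ctr[idx] - p
  comp <- model@radius
  ys <- lapply(seq_len(comp@rank), function(r) as.vector(comp@modes[[r]] %*% x))
  rsqCtv <- 0
  if (comp@rank > 0L)
    for (r in seq_len(comp@rank)) rsqCtv <- rsqCtv + comp@sv[r]^2 * ys[[r]][idx]^2

  value <- sc * (sum(res[idx]^2) + theta * sum(rsqCtv))
  grad <- 2 * sc * as.vector(Matrix::crossprod(model@center, res))
  if (theta > 0 && comp@rank > 0L) {
    msk <- numeric(length(ctr)); msk[idx] <- 1
    for (r in seq_len(comp@rank))
      grad <- grad + 2 * sc * theta * comp@sv[r]^2 *
        as.vector(Matrix::crossprod(comp@modes[[r]], msk * ys[[r]]))
  }
  list(value = value, gradient = grad)
}

#' Per-structure penalty function
#'
#' Voxel-mean penalties in the treatment-planning convention:
#' \describe{
#'   \item{DoseMin}{mean(min(d - dref, 0)^2) — underdose below dref}
#'   \item{DoseMax / SqOver}{mean(max(d - dref, 0)^2) — overdose above dref}
#'   \item{SqDev}{mean((d - dref)^2)}
#'   \item{MaxDVH}{zero when the volume at dref is within the allowed
#'     fraction v; otherwise mean over the structure of max(d - dref, 0)^2
#'     restricted to voxels with dose between dref and the current dose at
#'     volume fraction v (v = 0 reduces to DoseMax).}
#' }
#'
#' @param d per-voxel dose for the structure's voxels (Gy).
#' @param type one of "DoseMin", "DoseMax", "SqDev", "SqOver", "MaxDVH".
#' @param dref reference dose (Gy).
#' @param vol volume fraction in [0, 1] (MaxDVH only).
#' @return list(value, gradient) with gradient w.r.t. d (already divided by
#'   the voxel count).
#' @export
penalty <- function(d, type, dref, vol = NA_real_) {
  N <- length(d)
  if (!N) stop("penalty on empty structure")
  dev <- switch(type,
    DoseMin = pmin(d - dref, 0),
    DoseMax = ,
    SqOver  = pmax(d - dref, 0),
    SqDev   = d - dref,
    MaxDVH  = {
      if (is.na(vol) || vol < 0 || vol > 1)
        stop("MaxDVH requires a volume fraction in [0, 1]")
      vref <- mean(d >= dref)
      if (vref <= vol) {
        numeric(N)
      } else {
        idxv <- ceiling(vol * N)
        dv <- if (idxv < 1) Inf else sort(d, decreasing = TRUE)[idxv]
        out <- pmax(d - dref, 0)
        out[d > dv] <- 0
        out
      }
    },
    stop(sprintf("unknown penalty type '%s'", type))
  )
  list(value = mean(dev^2), gradient = 2 * dev / N)
}

#' Prostate objective table
#'
#' The default set of planning objectives: CTV minimum dose, squared
#' deviation, DVH maximum and maximum dose at the prescription level; PTV
#' twins of the CTV objectives (used only by the margin-based model); a body
#' dose bath penalty; conformity rings; and bladder/rectum DVH maxima whose
#' volume fractions default to NA ("pulled" from a preliminary nominal
#' CTV-only plan, see [pullOarFractions()]).
#'
#' @param p prescribed dose (Gy), default 78.
#' @return data.frame(structure, type, dose, volume, weight, ptv_only).
#' @export
defaultObjectives <- function(p = 78) {
  data.frame(
    structure = c("CTV", "CTV", "CTV", "CTV",
                  "PTV", "PTV", "PTV",
                  "body", "ring_0_20", "ring_20_50", "bladder", "rectum"),
    type   = c("DoseMin", "SqDev", "MaxDVH", "DoseMax",
               "DoseMin", "MaxDVH", "DoseMax",
               "SqOver", "MaxDVH", "MaxDVH", "MaxDVH", "MaxDVH"),
    dose   = c(p, p, 81, 83.5, p, 81, 83.5, 39, 83.5, p, 60, 40),
    volume = c(NA, NA, 0.05, NA, NA, 0.05, NA, NA, 0, 0, NA, NA),
    weight = c(30, 0.01, 10, 100, 30, 10, 100, 10, 100, 100, 2, 2),
    ptv_only = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# evaluate the weighted penalty table on one dose vector; returns value and
# the per-voxel gradient accumulated over structures
.compositeOnDose <- function(d, objectives, masks) {
  value <- 0
  g <- numeric(length(d))
  for (r in seq_len(nrow(objectives))) {
    o <- objectives[r, ]
    idx <- masks[[o$structure]]
    pen <- penalty(d[idx], o$type, o$dose, o$volume)
    value <- value + o$weight * pen$value
    g[idx] <- g[idx] + o$weight * pen$gradient
  }
  list(value = value, gradient = g)
}

#' Composite plan objective with analytic gradient
#'
#' Builds the objective closure for one of the four plan models:
#' \describe{
#'   \item{nominal}{all terms on the nominal-scenario dose; PTV rows dropped.}
#'   \item{ptv}{all terms (including the PTV rows) on the nominal dose.}
#'   \item{minimax}{smoothed (log-sum-exp) maximum over the optimization
#'     scenarios of the nominal-form composite on each scenario dose;
#'     \code{beta} is the inverse smoothing temperature, and
#'     \code{hardMax = TRUE} evaluates the exact maximum instead.}
#'   \item{interval}{the Bertoluzza CTV term (weight \code{omegaCtv}) plus
#'     the penalty rows evaluated on the dose interval: OAR/body/ring rows on
#'     the upper bound \eqn{\bar d = center + radius}, the CTV minimum-dose
#'     row on the lower bound, CTV maximum/DVH rows on \eqn{\bar d}; the CTV
#'     SqDev row is subsumed by the Bertoluzza term.}
#' }
#'
#' @param model "nominal", "ptv", "minimax" or "interval".
#' @param phantom a [VoxelPhantom-class].
#' @param objectives objective table from [defaultObjectives()], with MaxDVH
#'   volume fractions resolved (no NA).
#' @param nominalD sparse nominal dose-influence matrix (nominal/ptv).
#' @param scenarioDs list of scenario matrices (minimax).
#' @param intervalModel an [IntervalDoseModel-class] (interval).
#' @param p prescribed dose (Gy).
#' @param theta Bertoluzza spread weight (interval).
#' @param omegaCtv weight of the Bertoluzza CTV term (interval).
#' @param beta minimax smoothing inverse temperature.
#' @param hardMax evaluate minimax as a hard maximum (no gradient smoothing).
#' @return function(x) -> list(value, gradient).
#' @export
makeObjective <- function(model = c("nominal", "ptv", "minimax", "interval"),
                          phantom, objectives,
                          nominalD = NULL, scenarioDs = NULL,
                          intervalModel = NULL,
                          p = 78, theta = 10, omegaCtv = 1, beta = 1000,
                          hardMax = FALSE) {
  model <- match.arg(model)
  if (model == "ptv" && !"PTV" %in% structureNames(phantom))
    stop("ptv model requires a PTV mask")
  keep <- if (model == "ptv") rep(TRUE, nrow(objectives)) else !objectives$ptv_only
  obj <- objectives[keep, , drop = FALSE]
  if (any(obj$type == "MaxDVH" & is.na(obj$volume)))
    stop("MaxDVH rows must have resolved volume fractions (see pullOarFractions)")
  masks <- lapply(unique(obj$structure), function(nm)
    which(as.vector(structureMask(phantom, nm))))
  names(masks) <- unique(obj$structure)
  for (nm in names(masks)) if (!length(masks[[nm]]))
    stop(sprintf("objective structure '%s' is empty", nm))

  if (model %in% c("nominal", "ptv")) {
    D <- if (is(nominalD, "DoseInfluence")) nominalD@D else nominalD
    return(function(x) {
      d <- as.vector(D %*% x)
      comp <- .compositeOnDose(d, obj, masks)
      list(value = comp$value,
           gradient = as.vector(Matrix::crossprod(D, comp$gradient)))
    })
  }

  if (model == "minimax") {
    Ds <- .asDij(scenarioDs)
    return(function(x) {
      evals <- lapply(Ds, function(D) {
        comp <- .compositeOnDose(as.vector(D %*% x), obj, masks)
        comp
      })
      f <- vapply(evals, `[[`, numeric(1), "value")
      if (hardMax) {
        kmax <- which.max(f)
        return(list(value = f[kmax],
                    gradient = as.vector(Matrix::crossprod(Ds[[kmax]],
                                                           evals[[kmax]]$gradient))))
      }
      fmax <- max(f)
      ex <- exp(beta * (f - fmax))
      value <- fmax + log(sum(ex)) / beta
      pk <- ex / sum(ex)
      g <- numeric(length(x))
      for (k in seq_along(Ds)) {
        if (pk[k] > 1e-14)
          g <- g + pk[k] * as.vector(Matrix::crossprod(Ds[[k]], evals[[k]]$gradient))
      }
      list(value = value, gradient = g)
    })
  }

  # interval model
  im <- intervalModel
  if (is.null(im)) stop("interval model requires an IntervalDoseModel")
  ctvIdx <- masks[["CTV"]]
  objNoSqDev <- obj[!(obj$structure == "CTV" & obj$type == "SqDev"), , drop = FALSE]
  lowerRows <- objNoSqDev$structure == "CTV" & objNoSqDev$type == "DoseMin"
  comp <- im@radius
  function(x) {
    ctr <- as.vector(im@center %*% x)
    ys <- lapply(seq_len(comp@rank), function(r)
      as.vector(comp@modes[[r]] %*% x))
    rsq <- numeric(length(ctr))
    if (comp@rank > 0L)
      for (r in seq_len(comp@rank)) rsq <- rsq + comp@sv[r]^2 * ys[[r]]^2
    rad <- sqrt(pmax(rsq, 0))
    upper <- ctr + rad
    lower <- ctr - rad

    nC <- length(ctvIdx)
    resC <- ctr[ctvIdx] - p
    value <- omegaCtv * (sum(resC^2) + theta * sum(rsq[ctvIdx])) / nC
    a <- numeric(length(ctr))          # coefficient on d(center)
    b <- numeric(length(ctr))          # coefficient on d(radius)
    a[ctvIdx] <- 2 * omegaCtv * resC / nC
    q <- numeric(length(ctr))          # coefficient on d(radius^2)
    q[ctvIdx] <- omegaCtv * theta / nC

    up <- .compositeOnDose(upper, objNoSqDev[!lowerRows, , drop = FALSE], masks)
    lo <- if (any(lowerRows))
      .compositeOnDose(lower, objNoSqDev[lowerRows, , drop = FALSE], masks)
    else list(value = 0, gradient = numeric(length(ctr)))
    value <- value + up$value + lo$value
    a <- a + up$gradient + lo$gradient
    b <- b + up$gradient - lo$gradient

    grad <- as.vector(Matrix::crossprod(im@center, a))
    if (comp@rank > 0L) {
      # d(radius)/dx via d(rsq)/dx / (2 r); subgradient 0 where r == 0
      binv <- ifelse(rad > 1e-12, b / (2 * pmax(rad, 1e-300)), 0)
      wvec <- 2 * (q + binv)
      for (r in seq_len(comp@rank))
        grad <- grad + comp@sv[r]^2 *
          as.vector(Matrix::crossprod(comp@modes[[r]], wvec * ys[[r]]))
    }
    list(value = value, gradient = grad)
  }
}
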