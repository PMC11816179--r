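# Interval dose-influence representation: center matrix, exact per-voxel
# radius, and its scenario-axis SVD compression.
#
# With scenario matrices D_k and weights w_k (sum 1), the per-voxel dose
# interval of a fluence x is [center, radius] with
#   center_i = (D_c x)_i,            D_c = sum_k w_k D_k
#   radius_i = sqrt(sum_k w_k ((D_k - D_c) x)_i^2)
# i.e. the mean and standard deviation of the scenario doses. Stacking the
# weighted deviations E_k = sqrt(w_k) (D_k - D_c) along the scenario axis and
# taking the SVD of that K x (n m) stack gives orthonormal scenario loadings
# u_r, singular values sigma_r and mode matrices Phi_r with
#   radius_i(x)^2 = sum_r sigma_r^2 (Phi_r x)_i^2,
# exact when all positive singular values are retained. The K x K Gram matrix
# of the stack is eigendecomposed instead of forming the dense stack.

.asDij <- function(Dks) lapply(Dks, function(d) if (is(d, "DoseInfluence")) d@D else d)

# general sparse double matrix (dgCMatrix), whatever special class arithmetic
# or user input produced
.asDgC <- function(M)
  as(as(as(as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix"), "dgCMatrix")

.checkWeights <- function(w, K) {
  if (length(w) != K) stop("one weight per scenario matrix required")
  if (abs(sum(w) - 1) > 1e-9) stop("scenario weights must sum to 1")
}

#' Center dose-influence matrix
#'
#' \eqn{D_c = \sum_k w_k D_k}: the center dose of a fluence x is the weighted
#' mean of its scenario doses.
#'
#' @param Dks list of sparse n x m matrices (or [DoseInfluence-class]).
#' @param w scenario weights summing to 1.
#' @return sparse n x m matrix.
#' @export
buildCenter <- function(Dks, w) {
  Dks <- .asDij(Dks)
  .checkWeights(w, length(Dks))
  dims <- lapply(Dks, dim)
  if (length(unique(dims)) != 1L) stop("scenario matrices have mismatched dimensions")
  Dc <- w[1] * Dks[[1]]
  for (k in seq_along(Dks)[-1]) Dc <- Dc + w[k] * Dks[[k]]
  .asDgC(Dc)
}

#' Exact per-voxel dose radius
#'
#' The standard deviation of the scenario doses of fluence x, computed in the
#' numerically stable deviation form
#' \eqn{\sqrt{\sum_k w_k ((D_k - D_c) x)_i^2}}. Round-off negatives are
#' clamped at 0.
#'
#' @param x nonnegative fluence vector.
#' @param Dks list of scenario matrices.
#' @param w weights summing to 1.
#' @param center optional precomputed center matrix.
#' @return per-voxel radius vector (Gy).
#' @export
radiusExact <- function(x, Dks, w, center = NULL) {
  Dks <- .asDij(Dks)
  .checkWeights(w, length(Dks))
  if (is.null(center)) center <- buildCenter(Dks, w)
  cx <- as.vector(center %*% x)
  rsq <- numeric(length(cx))
  for (k in seq_along(Dks))
    rsq <- rsq + w[k] * (as.vector(Dks[[k]] %*% x) - cx)^2
  sqrt(pmax(rsq, 0))
}

#' SVD-compress the radius representation
#'
#' Decomposes the weighted deviation stack along the scenario axis and keeps
#' the smallest number of modes whose cumulative squared singular value
#' reaches \code{varianceThreshold} (default 0.99).
#'
#' @param Dks list of K >= 2 scenario matrices.
#' @param w weights summing to 1.
#' @param center optional precomputed center matrix.
#' @param varianceThreshold fraction in (0, 1].
#' @return a [CompressedRadius-class].
#' @export
compressRadius <- function(Dks, w, center = NULL, varianceThreshold = 0.99) {
  if (!is.numeric(varianceThreshold) || varianceThreshold <= 0 ||
      varianceThreshold > 1)
    stop("variance threshold must lie in (0, 1]")
  Dks <- .asDij(Dks)
  K <- length(Dks)
  if (K < 2L) stop("at least two scenarios required for compression")
  .checkWeights(w, K)
  if (is.null(center)) center <- buildCenter(Dks, w)
  Eks <- lapply(seq_len(K), function(k)
    .asDgC(sqrt(w[k]) * (Dks[[k]] - center)))

  # K x K Gram matrix of the vectorized deviation stack
  G <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in a:K) {
    v <- sum(Eks[[a]] * Eks[[b]])
    G[a, b] <- v; G[b, a] <- v
  }
  eg <- eigen(G, symmetric = TRUE)
  # deviations that are pure round-off relative to the scenario matrices
  # themselves carry no variability: threshold against that scale
  refScale <- sum(vapply(seq_len(K), function(k)
    w[k] * sum(Dks[[k]]^2), numeric(1)))
  tolAbs <- max(1e-24 * refScale, .Machine$double.xmin)
  total <- sum(pmax(eg$values, 0))
  if (total <= tolAbs) {
    return(new("CompressedRadius", rank = 0L, sv = numeric(),
               modes = list(), varianceExplained = 1, totalVariance = 0,
               fullRank = 0L, dims = dim(Dks[[1]])))
  }
  pos <- which(eg$values > max(1e-12 * max(eg$values), tolAbs))
  fullRank <- length(pos)
  cumfrac <- cumsum(eg$values[pos]) / total
  k <- which(cumfrac >= varianceThreshold)[1]
  if (is.na(k)) k <- fullRank
  sv <- sqrt(eg$values[pos[seq_len(k)]])
  modes <- lapply(seq_len(k), function(r) {
    u <- eg$vectors[, pos[r]]
    M <- u[1] * Eks[[1]]
    for (j in 2:K) M <- M + u[j] * Eks[[j]]
    .asDgC(M / sv[r])
  })
  new("CompressedRadius", rank = as.integer(k), sv = sv, modes = modes,
      varianceExplained = cumfrac[k], totalVariance = total,
      fullRank = as.integer(fullRank), dims = dim(Dks[[1]]))
}

#' Per-voxel radius from the compressed representation
#'
#' \eqn{\sqrt{\sum_{r \le k} \sigma_r^2 (\Phi_r x)_i^2}} per voxel; a rank-0
#' compression gives zero radius.
#'
#' @param x fluence vector.
#' @param comp a [CompressedRadius-class].
#' @return per-voxel radius vector (Gy).
#' @export
radiusFromCompressed <- function(x, comp) {
  sqrt(radiusSqFromCompressed(x, comp))
}

#' @rdname radiusFromCompressed
#' @export
radiusSqFromCompressed <- function(x, comp) {
  if (comp@rank == 0L) return(numeric(comp@dims[1]))
  rsq <- numeric(nrow(comp@modes[[1]]))
  for (r in seq_len(comp@rank))
    rsq <- rsq + comp@sv[r]^2 * as.vector(comp@modes[[r]] %*% x)^2
  rsq
}

#' Build the full interval dose-influence model
#'
#' @param Dks list of scenario matrices (or [DoseInfluence-class] objects).
#' @param scenarios the [ScenarioSet-class] they were computed for (used for
#'   weights and metadata), or a numeric weight vector.
#' @param varianceThreshold SVD retention threshold, default 0.99.
#' @param keepDeviations keep the exact weighted deviation matrices in the
#'   model (needed for exact-radius queries afterwards).
#' @return an [IntervalDoseModel-class].
#' @examples
#' ph <- makeProstatePhantom(seed = 1)
#' sc <- makeOptScenarios(setupErrorModel(c(5, 10, 5)))
#' dijs <- computeScenarioDijs(ph, beamSetup(gantryAngles = c(0, 180)), sc)
#' m <- buildIntervalModel(dijs, sc)
#' m
#' @export
buildIntervalModel <- function(Dks, scenarios, varianceThreshold = 0.99,
                               keepDeviations = FALSE) {
  if (is(scenarios, "ScenarioSet")) {
    w <- scenarioWeights(scenarios)
    shifts <- scenarioShifts(scenarios)
  } else {
    w <- scenarios
    shifts <- matrix(NA_real_, length(w), 3)
  }
  mats <- .asDij(Dks)
  center <- buildCenter(mats, w)
  comp <- compressRadius(mats, w, center, varianceThreshold)
  devs <- if (keepDeviations) {
    lapply(seq_along(mats), function(k)
      .asDgC(sqrt(w[k]) * (mats[[k]] - center)))
  } else list()
  new("IntervalDoseModel", center = center, radius = comp,
      deviations = devs, weights = w, shifts = shifts)
}

#' Per-voxel dose interval of a fluence
#'
#' @param x fluence vector.
#' @param model an [IntervalDoseModel-class].
#' @return list with \code{center}, \code{radius}, \code{upper} (= center +
#'   radius) and \code{lower} (= center - radius), each a per-voxel Gy vector.
#' @export
doseInterval <- function(x, model) {
  ctr <- as.vector(model@center %*% x)
  r <- radiusFromCompressed(x, model@radius)
  list(center = ctr, radius = r, upper = ctr + r, lower = ctr - r)
}
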