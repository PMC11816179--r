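# Gaussian setup-error model and scenario-set generation.

#' Setup-error model
#'
#' Zero-mean uncorrelated 3D Gaussian setup errors with per-axis standard
#' deviations (mm) mapped to LR, AP, IS. The clinical default is
#' sigma = (5, 10, 5) mm.
#'
#' @param sigma length-3 positive numeric (mm).
#' @return list of class "SetupErrorModel".
#' @export
setupErrorModel <- function(sigma = c(5, 10, 5)) {
  sigma <- rep_len(as.numeric(sigma), 3L)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("all sigma must be > 0")
  structure(list(sigma = sigma), class = "SetupErrorModel")
}

#' Setup-error probability density
#'
#' Product of three univariate zero-mean normal densities:
#' \deqn{PDF(\delta) = \frac{1}{(2\pi)^{3/2}\sigma_x\sigma_y\sigma_z}
#'   \exp\left(-\frac{1}{2}\left(\frac{\delta_x^2}{\sigma_x^2} +
#'   \frac{\delta_y^2}{\sigma_y^2} + \frac{\delta_z^2}{\sigma_z^2}\right)\right)}
#'
#' @param delta shift triple (mm) or K x 3 matrix of shifts.
#' @param model a [setupErrorModel()].
#' @return density value(s).
#' @export
setupErrorPdf <- function(delta, model = setupErrorModel()) {
  d <- if (is.matrix(delta)) delta else matrix(delta, ncol = 3)
  s <- model$sigma
  dnorm(d[, 1], sd = s[1]) * dnorm(d[, 2], sd = s[2]) * dnorm(d[, 3], sd = s[3])
}

.scenarioSet <- function(shifts, model, purpose) {
  w <- setupErrorPdf(shifts, model)
  w <- w / sum(w)
  nom <- which(rowSums(abs(shifts)) == 0)
  new("ScenarioSet", shifts = shifts, weights = w, nominal = as.integer(nom[1]),
      purpose = purpose, sigma = model$sigma)
}

#' Optimization scenario set (13 scenarios)
#'
#' The nominal scenario plus, per axis, four single-axis shifts at
#' +/- 0.5 sigma and +/- 1.0 sigma (12 shifted scenarios in total). Weights
#' are proportional to the setup-error density, normalized to sum to 1.
#'
#' @param model a [setupErrorModel()].
#' @return a [ScenarioSet-class] tagged "optimization".
#' @export
makeOptScenarios <- function(model = setupErrorModel()) {
  shifts <- matrix(0, 1, 3)
  for (ax in 1:3) {
    for (f in c(-1, -0.5, 0.5, 1)) {
      row <- c(0, 0, 0)
      row[ax] <- f * model$sigma[ax]
      shifts <- rbind(shifts, row)
    }
  }
  dimnames(shifts) <- NULL
  .scenarioSet(shifts, model, "optimization")
}

#' Evaluation scenario grid (5 x 5 x 5)
#'
#' The Cartesian product of the per-axis offsets
#' \{-1.5, -0.75, 0, 0.75, 1.5\} sigma, centered on perfect positioning.
#' Weights proportional to the setup-error density, normalized.
#'
#' @param model a [setupErrorModel()].
#' @return a [ScenarioSet-class] tagged "evaluation" with 125 scenarios.
#' @export
makeEvalGrid <- function(model = setupErrorModel()) {
  lev <- c(-1.5, -0.75, 0, 0.75, 1.5)
  g <- expand.grid(x = lev * model$sigma[1], y = lev * model$sigma[2],
                   z = lev * model$sigma[3], KEEP.OUT.ATTRS = FALSE)
  .scenarioSet(unname(as.matrix(g)), model, "evaluation")
}

#' Export a scenario set as a data.frame / CSV
#' @param x a [ScenarioSet-class].
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame (dx, dy, dz, weight, is_nominal).
#' @export
scenarioTable <- function(x, file = NULL) {
  df <- data.frame(dx = x@shifts[, 1], dy = x@shifts[, 2], dz = x@shifts[, 3],
                   weight = x@weights,
                   is_nominal = seq_len(nrow(x@shifts)) == x@nominal)
  if (!is.null(file)) write.csv(df, file, row.names = FALSE)
  df
}
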