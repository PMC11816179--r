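# Bound-constrained fluence optimization (projected quasi-Newton via
# L-BFGS-B). Deterministic: fixed initialization, no randomized components.

#' Optimizer configuration
#'
#' @param maxit maximum iterations (default 500).
#' @param pgtol projected-gradient tolerance (relative to max(1, |f0|)).
#' @param factr L-BFGS-B relative function-reduction factor.
#' @return list of class "OptimizerConfig".
#' @export
optimizerConfig <- function(maxit = 500, pgtol = 1e-6, factr = 1e7) {
  if (maxit < 1) stop("max iterations must be >= 1")
  structure(list(maxit = maxit, pgtol = pgtol, factr = factr),
            class = "OptimizerConfig")
}

#' Optimize a fluence map
#'
#' Minimizes an objective closure (value + analytic gradient) over x >= 0.
#' If the initial point is already first-order stationary the initial point
#' is returned after a single evaluation.
#'
#' @param objective function(x) -> list(value, gradient).
#' @param x0 initial nonnegative fluence vector.
#' @param config an [optimizerConfig()].
#' @return list(x, value, trace, evaluations, converged); \code{trace} is the
#'   non-increasing sequence of accepted objective values.
#' @examples
#' # single voxel / single bixel with unit response, squared deviation to 5:
#' obj <- function(x) list(value = (x - 5)^2, gradient = 2 * (x - 5))
#' optimizeFluence(obj, 1)$x
#' @export
optimizeFluence <- function(objective, x0, config = optimizerConfig()) {
  x0 <- pmax(as.numeric(x0), 0)
  f0 <- objective(x0)
  if (!is.finite(f0$value)) stop("objective is not finite at the initial point")
  nEval <- 1L

  projGrad <- function(x, g) {
    pg <- g
    pg[x <= 0 & g > 0] <- 0
    pg
  }
  tol <- config$pgtol * max(1, abs(f0$value))
  if (max(abs(projGrad(x0, f0$gradient))) <= tol) {
    return(list(x = x0, value = f0$value, trace = f0$value,
                evaluations = nEval, converged = TRUE))
  }

  best <- f0$value
  trace <- f0$value
  fn <- function(x) {
    v <- objective(x)$value
    nEval <<- nEval + 1L
    if (is.finite(v) && v < best) {
      best <<- v
      trace <<- c(trace, v)
    }
    v
  }
  gr <- function(x) objective(x)$gradient

  res <- optim(x0, fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = config$maxit, factr = config$factr,
                              pgtol = 0))
  list(x = pmax(res$par, 0), value = res$value, trace = trace,
       evaluations = nEval, converged = res$convergence == 0)
}

#' Default uniform initial fluence
#'
#' Uniform fluence scaled so the mean CTV center dose equals the prescription.
#'
#' @param D dose matrix used for scaling (center or nominal matrix).
#' @param ctv logical CTV mask.
#' @param p prescribed dose (Gy).
#' @return fluence vector of length ncol(D).
#' @export
initialFluence <- function(D, ctv, p) {
  D <- if (is(D, "DoseInfluence")) D@D else D
  ones <- rep(1, ncol(D))
  dbar <- mean(as.vector(D %*% ones)[as.vector(ctv)])
  if (dbar <= 0) stop("CTV receives no dose from uniform fluence")
  ones * p / dbar
}
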