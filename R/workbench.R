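# Configuration-driven end-to-end planning runs and model comparison.

#' Default run configuration
#'
#' Aggregates the study defaults: the packaged prostate-like phantom, nine
#' equispaced beams (0..320 by 40 degrees), setup-error sigma = (5, 10, 5) mm,
#' prescription 78 Gy, PTV margins (7, 7-4, 7) mm, theta = 10, c1 = c2 =
#' 0.05, SVD variance threshold 0.99.
#'
#' @param seed integer seed (phantom jitter).
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 42) {
  list(
    phantom = defaultPhantomConfig(),
    beams = list(gantry_angles = seq(0, 320, by = 40), bixel_width = 5,
                 mu = 0.005, penumbra_sigma = 3),
    sigma = c(5, 10, 5),
    prescription = 78,
    margins = list(lr = 7, anterior = 7, posterior = 4, is = 7),
    model = "interval",
    theta = 10,
    omega_ctv = 1,
    c1 = 0.05, c2 = 0.05,
    svd_threshold = 0.99,
    beta = 1000,
    optimizer = list(maxit = 400, pgtol = 1e-6, factr = 1e7),
    oar_volume_fractions = NULL,   # NULL -> pulled from a nominal CTV-only plan
    seed = seed
  )
}

#' Validate a run configuration
#'
#' Structural and range checks applied before any computation.
#'
#' @param config configuration list.
#' @return the config, invisibly; errors on violation.
#' @export
validateRunConfig <- function(config) {
  req <- c("phantom", "beams", "sigma", "prescription", "margins", "model",
           "theta", "c1", "c2", "svd_threshold", "seed")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("config is missing fields: ", paste(missing, collapse = ", "))
  if (!config$model %in% c("nominal", "ptv", "minimax", "interval"))
    stop("model must be one of nominal, ptv, minimax, interval")
  if (length(config$sigma) != 3 || any(config$sigma <= 0))
    stop("sigma must be a positive mm triple")
  if (config$prescription <= 0) stop("prescription must be > 0")
  if (config$theta < 0) stop("theta must be >= 0")
  if (config$c1 <= 0 || config$c2 <= 0) stop("c1 and c2 must be > 0")
  if (config$svd_threshold <= 0 || config$svd_threshold > 1)
    stop("svd_threshold must lie in (0, 1]")
  if (any(unlist(config$margins) < 0)) stop("margins must be >= 0")
  invisible(config)
}

#' Read / write a run configuration as YAML
#' @param file path.
#' @param config configuration list.
#' @return \code{readRunConfig}: the validated config (defaults filled in).
#' @export
readRunConfig <- function(file) {
  user <- yaml::read_yaml(file)
  config <- utils::modifyList(defaultRunConfig(), user)
  validateRunConfig(config)
  config
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

#' Pull bladder/rectum DVH volume fractions from a nominal CTV-only plan
#'
#' Optimizes a preliminary nominal plan with only the CTV objectives and
#' returns the achieved V60Gy (bladder) and V40Gy (rectum) fractions at the
#' nominal scenario. These become the allowed volume fractions of the OAR
#' MaxDVH objectives, so each model is asked to not exceed what a plan that
#' ignores the OARs already achieves.
#'
#' @param setup a plan setup from [planSetup()].
#' @return list(bladder, rectum) fractions in [0, 1].
#' @export
pullOarFractions <- function(setup) {
  obj <- setup$objectives
  ctvOnly <- obj[obj$structure == "CTV", , drop = FALSE]
  f <- makeObjective("nominal", setup$phantom, ctvOnly,
                     nominalD = setup$optDijs[[nominalIndex(setup$optSet)]],
                     p = setup$config$prescription)
  x0 <- initialFluence(setup$optDijs[[nominalIndex(setup$optSet)]],
                       structureMask(setup$phantom, "CTV"),
                       setup$config$prescription)
  res <- optimizeFluence(f, x0, optimizerConfig(
    maxit = min(200, setup$config$optimizer$maxit)))
  d <- as.vector(doseMatrix(setup$optDijs[[nominalIndex(setup$optSet)]]) %*% res$x)
  list(bladder = vx(d, structureMask(setup$phantom, "bladder"), 60) / 100,
       rectum = vx(d, structureMask(setup$phantom, "rectum"), 40) / 100)
}

#' Prepare the shared inputs of a planning run
#'
#' Stages A and B of the planning loop: phantom generation, dose-influence
#' matrices for the 13-scenario optimization set and the 5x5x5 evaluation
#' grid, the interval dose model, and the resolved objective table.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param verbose print one line per stage.
#' @return list with phantom, beams, scenario sets, Dij lists, interval
#'   model, objective table, config.
#' @export
planSetup <- function(config = defaultRunConfig(), verbose = FALSE) {
  validateRunConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))
  margins <- do.call(marginSpec, config$margins)
  phantom <- makeProstatePhantom(config$phantom, seed = config$seed,
                                 margins = margins)
  beams <- beamSetup(gantryAngles = config$beams$gantry_angles,
                     bixelWidth = config$beams$bixel_width,
                     mu = config$beams$mu,
                     penumbraSigma = config$beams$penumbra_sigma)
  errModel <- setupErrorModel(config$sigma)
  optSet <- makeOptScenarios(errModel)
  evalSet <- makeEvalGrid(errModel)

  say("[A] dose-influence matrices: %d optimization + %d evaluation scenarios",
      nScenarios(optSet), nScenarios(evalSet))
  t0 <- Sys.time()
  optDijs <- computeScenarioDijs(phantom, beams, optSet)
  evalDijs <- computeScenarioDijs(phantom, beams, evalSet)
  say("[A] done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  say("[B] interval dose model (SVD threshold %.2f)", config$svd_threshold)
  t0 <- Sys.time()
  intervalModel <- buildIntervalModel(optDijs, optSet,
                                      varianceThreshold = config$svd_threshold)
  say("[B] done in %.1f s: rank %d, variance %.4f",
      as.numeric(Sys.time() - t0, units = "secs"),
      radiusRank(intervalModel), varianceExplained(intervalModel))

  setup <- list(config = config, phantom = phantom, beams = beams,
                optSet = optSet, evalSet = evalSet,
                optDijs = optDijs, evalDijs = evalDijs,
                intervalModel = intervalModel,
                objectives = defaultObjectives(config$prescription))

  fr <- config$oar_volume_fractions
  if (is.null(fr)) {
    say("[B] pulling OAR DVH volume fractions from a nominal CTV-only plan")
    fr <- pullOarFractions(setup)
  }
  obj <- setup$objectives
  obj$volume[obj$structure == "bladder"] <- fr$bladder
  obj$volume[obj$structure == "rectum"] <- fr$rectum
  setup$objectives <- obj
  setup$oarFractions <- fr
  setup
}

#' Optimize and evaluate one plan model on a prepared setup
#'
#' Stages C and D: fluence optimization for the selected model and
#' robustness evaluation on the 5x5x5 grid.
#'
#' @param setup from [planSetup()].
#' @param model "nominal", "ptv", "minimax" or "interval" (default: the
#'   config's model).
#' @param theta Bertoluzza spread weight (interval model).
#' @param verbose print stage lines.
#' @return list(evaluation = [PlanEvaluation-class], fluence, trace, value).
#' @export
runPlanOnSetup <- function(setup, model = NULL, theta = NULL, verbose = FALSE) {
  config <- setup$config
  if (is.null(model)) model <- config$model
  if (is.null(theta)) theta <- config$theta
  say <- function(...) if (verbose) message(sprintf(...))
  nomD <- setup$optDijs[[nominalIndex(setup$optSet)]]
  objective <- makeObjective(
    model, setup$phantom, setup$objectives,
    nominalD = nomD, scenarioDs = setup$optDijs,
    intervalModel = setup$intervalModel,
    p = config$prescription, theta = theta,
    omegaCtv = if (is.null(config$omega_ctv)) 1 else config$omega_ctv,
    beta = if (is.null(config$beta)) 1000 else config$beta)

  scaleD <- if (model == "interval") setup$intervalModel@center else doseMatrix(nomD)
  x0 <- initialFluence(scaleD, structureMask(setup$phantom, "CTV"),
                       config$prescription)
  say("[C] optimizing %s model%s", model,
      if (model == "interval") sprintf(" (theta = %g)", theta) else "")
  t0 <- Sys.time()
  oc <- optimizerConfig(maxit = config$optimizer$maxit,
                        pgtol = config$optimizer$pgtol,
                        factr = config$optimizer$factr)
  res <- optimizeFluence(objective, x0, oc)
  say("[C] done in %.1f s: objective %.4g after %d evaluations",
      as.numeric(Sys.time() - t0, units = "secs"), res$value, res$evaluations)

  say("[D] robustness evaluation on the %d-scenario grid", nScenarios(setup$evalSet))
  ev <- evaluatePlan(res$x, setup$evalDijs, setup$evalSet, setup$phantom,
                     robustnessParams(config$prescription, config$c1, config$c2),
                     model = model,
                     theta = if (model == "interval") theta else NA_real_,
                     objective = res$value)
  list(evaluation = ev, fluence = res$x, trace = res$trace, value = res$value)
}

#' Run one plan end-to-end from a configuration
#'
#' Executes phantom generation, scenario dose calculation, interval-model
#' construction, fluence optimization and robustness evaluation, optionally
#' writing the plan bundle to an output directory.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param outdir optional output directory for [writePlanBundle()].
#' @param verbose print one line per stage.
#' @return list(evaluation, fluence, trace, value, setup).
#' @export
runPlan <- function(config = defaultRunConfig(), outdir = NULL,
                    verbose = FALSE) {
  setup <- planSetup(config, verbose = verbose)
  run <- runPlanOnSetup(setup, verbose = verbose)
  run$setup <- setup
  if (!is.null(outdir)) writePlanBundle(run, outdir)
  run
}

#' Compare plan models on one setup
#'
#' Optimizes each requested model (the interval model once per theta in
#' \code{thetaSweep}) on a shared setup and tabulates robustness index and
#' price-of-robustness metrics — one row per (model, theta).
#'
#' @param config configuration list.
#' @param models at least two of "nominal", "ptv", "minimax", "interval".
#' @param thetaSweep theta values for the interval model.
#' @param setup optional precomputed [planSetup()] (overrides config).
#' @param verbose print stage lines.
#' @return list(table = data.frame(model, theta, objective, ri, v40_rectum,
#'   v60_bladder), runs = named list of run results).
#' @export
compareModels <- function(config = defaultRunConfig(),
                          models = c("nominal", "ptv", "minimax", "interval"),
                          thetaSweep = 10, setup = NULL, verbose = FALSE) {
  jobs <- list()
  for (m in models) {
    if (m == "interval") for (th in thetaSweep) jobs[[length(jobs) + 1]] <- list(model = m, theta = th)
    else jobs[[length(jobs) + 1]] <- list(model = m, theta = NA_real_)
  }
  if (length(jobs) < 2) stop("at least two model runs required for comparison")
  if (is.null(setup)) setup <- planSetup(config, verbose = verbose)

  runs <- list()
  rows <- list()
  for (j in jobs) {
    run <- runPlanOnSetup(setup, model = j$model, theta = j$theta,
                          verbose = verbose)
    ev <- run$evaluation
    id <- if (j$model == "interval") sprintf("interval_theta%g", j$theta) else j$model
    runs[[id]] <- run
    rows[[id]] <- data.frame(model = j$model, theta = j$theta,
                             objective = run$value, ri = robustnessIndexOf(ev),
                             v40_rectum = priceMetrics(ev)$v40_rectum,
                             v60_bladder = priceMetrics(ev)$v60_bladder)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       runs = runs, setup = setup)
}

#' Central-difference gradient check utility
#'
#' The default step is small enough that the piecewise-defined DVH objectives
#' are almost never probed across an active-set boundary.
#'
#' @param objective function(x) -> list(value, gradient) or plain value.
#' @param x point.
#' @param h relative step.
#' @return numeric gradient by central differences.
#' @export
numericalGradient <- function(objective, x, h = 1e-6) {
  val <- function(z) {
    v <- objective(z)
    if (is.list(v)) v$value else v
  }
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (val(xp) - val(xm)) / (2 * hi)
  }
  g
}
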