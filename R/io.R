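# Plain-text persistence: a plan/phantom "bundle" is a directory of
# MatrixMarket (sparse matrices), CSV (masks, tables, curves) and JSON
# (metadata, metrics) files, all round-tripping through the readers below.

#' @importFrom Matrix writeMM readMM
NULL

# tiny FNV-1a hash for provenance records; arithmetic kept in doubles below
# 2^53 (the xor touches only the low byte, the multiply is split)
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- bitwXor(h %% 256, b %% 256)
    h <- h - (h %% 256) + low
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536 * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Write / read a voxel phantom
#'
#' The phantom directory holds \code{grid.json} (shape, spacing, origin) and
#' one \code{mask_<name>.csv} voxel-index list per structure.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param dir directory path (created).
#' @return \code{readPhantom}: the reconstructed phantom.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- voxelGridOf(phantom)
  jsonlite::write_json(
    list(shape = grid@shape, spacing = grid@spacing, origin = grid@origin,
         structures = structureNames(phantom)),
    file.path(dir, "grid.json"), auto_unbox = FALSE, digits = NA)
  for (nm in structureNames(phantom)) {
    idx <- which(as.vector(structureMask(phantom, nm)))
    write.csv(data.frame(voxel = idx),
              file.path(dir, paste0("mask_", nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writePhantom
#' @param dir directory written by [writePhantom()].
#' @export
readPhantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  grid <- voxelGrid(meta$shape, meta$spacing, meta$origin)
  masks <- lapply(meta$structures, function(nm) {
    idx <- read.csv(file.path(dir, paste0("mask_", nm, ".csv")))$voxel
    m <- array(FALSE, dim = grid@shape)
    m[idx] <- TRUE
    m
  })
  names(masks) <- meta$structures
  voxelPhantom(grid, masks)
}

#' Write / read a dose-influence matrix
#'
#' MatrixMarket file for the sparse matrix plus a JSON sidecar (shift, bixel
#' table).
#'
#' @param dij a [DoseInfluence-class].
#' @param prefix path prefix; writes \code{<prefix>.mtx} and
#'   \code{<prefix>.json}.
#' @return \code{readDoseInfluence}: the reconstructed object.
#' @export
writeDoseInfluence <- function(dij, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dij@D, paste0(prefix, ".mtx"))
  jsonlite::write_json(list(shift = dij@shift, bixels = dij@bixels),
                       paste0(prefix, ".json"), auto_unbox = FALSE,
                       digits = NA, dataframe = "columns")
  invisible(prefix)
}

#' @rdname writeDoseInfluence
#' @export
readDoseInfluence <- function(prefix) {
  D <- as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new("DoseInfluence", D = as(D, "dgCMatrix"), shift = meta$shift,
      bixels = as.data.frame(meta$bixels))
}

#' Metrics of a plan evaluation as a flat list
#' @param ev a [PlanEvaluation-class].
#' @return named list suitable for JSON export.
#' @export
planMetrics <- function(ev) {
  list(model = ev@model, theta = ev@theta, objective = ev@objective,
       ri = ev@ri, v40_rectum = ev@price$v40_rectum,
       v60_bladder = ev@price$v60_bladder,
       p = ev@params$p, c1 = ev@params$c1, c2 = ev@params$c2)
}

#' Write a full plan bundle
#'
#' Writes fluence, optimization trace, Delta-map, DVH/cDVH table, metrics
#' JSON (with a config-hash provenance record) and the phantom into a
#' directory.
#'
#' @param run result of [runPlan()] / [runPlanOnSetup()] (with \code{setup}).
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writePlanBundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- run$evaluation
  write.csv(data.frame(bixel = seq_along(run$fluence), fluence = run$fluence),
            file.path(dir, "fluence.csv"), row.names = FALSE)
  write.csv(data.frame(iteration = seq_along(run$trace), objective = run$trace),
            file.path(dir, "trace.csv"), row.names = FALSE)
  write.csv(data.frame(ctv_voxel = seq_along(ev@delta), delta = ev@delta),
            file.path(dir, "delta_map.csv"), row.names = FALSE)
  write.csv(ev@dvh, file.path(dir, "dvh.csv"), row.names = FALSE)
  if (!is.null(run$setup)) {
    writePhantom(run$setup$phantom, file.path(dir, "phantom"))
    cfgJson <- jsonlite::toJSON(run$setup$config, auto_unbox = TRUE, digits = NA)
    provenance <- list(config_hash = .fnv1a(as.character(cfgJson)),
                       package = "intervalRT",
                       version = as.character(packageVersion("intervalRT")),
                       r_version = R.version.string)
  } else provenance <- NULL
  metrics <- list(model = ev@model, theta = ev@theta, objective = ev@objective,
                  ri = ev@ri, v40_rectum = ev@price$v40_rectum,
                  v60_bladder = ev@price$v60_bladder,
                  p = ev@params$p, c1 = ev@params$c1, c2 = ev@params$c2,
                  provenance = provenance)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read the metrics JSON of a plan bundle
#' @param dir bundle directory.
#' @return named list.
#' @export
readPlanMetrics <- function(dir) {
  jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE)
}
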