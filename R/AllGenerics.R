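# Generics, accessors and show methods.

#' Number of voxels in a grid or phantom
#' @param x a VoxelGrid or VoxelPhantom.
#' @return integer voxel count n = nx * ny * nz.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "VoxelGrid", function(x) prod(x@shape))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "VoxelPhantom", function(x) prod(x@grid@shape))

#' Grid accessors
#' @param x a VoxelGrid or VoxelPhantom.
#' @return \code{gridShape}: integer triple; \code{voxelSpacing}: mm triple;
#'   \code{voxelGridOf}: the VoxelGrid of a phantom.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname gridShape
#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)
#' @rdname gridShape
#' @export
setMethod("gridShape", "VoxelPhantom", function(x) x@grid@shape)

#' @rdname gridShape
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname gridShape
#' @export
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname gridShape
#' @export
setMethod("voxelSpacing", "VoxelPhantom", function(x) x@grid@spacing)

#' @rdname gridShape
#' @export
setGeneric("voxelGridOf", function(x) standardGeneric("voxelGridOf"))
#' @rdname gridShape
#' @export
setMethod("voxelGridOf", "VoxelPhantom", function(x) x@grid)

#' Voxel center coordinates
#'
#' @param x a VoxelGrid or VoxelPhantom.
#' @return n x 3 matrix of voxel-center positions (mm), rows in R array order
#'   (x index varies fastest), matching \code{as.vector()} of a mask array.
#' @export
setGeneric("voxelCenters", function(x) standardGeneric("voxelCenters"))

#' @rdname voxelCenters
#' @export
setMethod("voxelCenters", "VoxelGrid", function(x) {
  ax <- lapply(1:3, function(a)
    x@origin[a] + (seq_len(x@shape[a]) - 0.5) * x@spacing[a])
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
})

#' @rdname voxelCenters
#' @export
setMethod("voxelCenters", "VoxelPhantom", function(x) voxelCenters(x@grid))

#' Structure masks of a phantom
#'
#' @param x a VoxelPhantom.
#' @param name structure name.
#' @return \code{structureMask}: the logical mask array; \code{structureNames}:
#'   character vector; \code{maskCentroid}: mm triple of the mask centroid.
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))

#' @rdname structureMask
#' @export
setMethod("structureMask", "VoxelPhantom", function(x, name) {
  if (!name %in% names(x@masks))
    stop(sprintf("phantom has no structure '%s'", name))
  x@masks[[name]]
})

#' @rdname structureMask
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
#' @rdname structureMask
#' @export
setMethod("structureNames", "VoxelPhantom", function(x) names(x@masks))

#' @rdname structureMask
#' @export
setGeneric("maskCentroid", function(x, name) standardGeneric("maskCentroid"))
#' @rdname structureMask
#' @export
setMethod("maskCentroid", "VoxelPhantom", function(x, name) {
  m <- as.vector(structureMask(x, name))
  if (!any(m)) stop(sprintf("structure '%s' is empty", name))
  colMeans(voxelCenters(x)[m, , drop = FALSE])
})

#' Scenario-set accessors
#' @param x a ScenarioSet.
#' @return \code{scenarioShifts}: K x 3 mm matrix; \code{scenarioWeights}:
#'   normalized weights; \code{nScenarios}: K; \code{nominalIndex}: index of
#'   the zero-shift scenario; \code{scenarioPurpose}: tag.
#' @export
setGeneric("scenarioShifts", function(x) standardGeneric("scenarioShifts"))
#' @rdname scenarioShifts
#' @export
setMethod("scenarioShifts", "ScenarioSet", function(x) x@shifts)
#' @rdname scenarioShifts
#' @export
setGeneric("scenarioWeights", function(x) standardGeneric("scenarioWeights"))
#' @rdname scenarioShifts
#' @export
setMethod("scenarioWeights", "ScenarioSet", function(x) x@weights)
#' @rdname scenarioShifts
#' @export
setGeneric("nScenarios", function(x) standardGeneric("nScenarios"))
#' @rdname scenarioShifts
#' @export
setMethod("nScenarios", "ScenarioSet", function(x) nrow(x@shifts))
#' @rdname scenarioShifts
#' @export
setGeneric("nominalIndex", function(x) standardGeneric("nominalIndex"))
#' @rdname scenarioShifts
#' @export
setMethod("nominalIndex", "ScenarioSet", function(x) x@nominal)
#' @rdname scenarioShifts
#' @export
setGeneric("scenarioPurpose", function(x) standardGeneric("scenarioPurpose"))
#' @rdname scenarioShifts
#' @export
setMethod("scenarioPurpose", "ScenarioSet", function(x) x@purpose)

#' Dose-influence accessors
#' @param x a DoseInfluence or IntervalDoseModel.
#' @return \code{doseMatrix}: sparse n x m matrix; \code{nBixels}: m;
#'   \code{doseCenter}: center matrix of an interval model;
#'   \code{doseRadiusModel}: its CompressedRadius.
#' @export
setGeneric("doseMatrix", function(x) standardGeneric("doseMatrix"))
#' @rdname doseMatrix
#' @export
setMethod("doseMatrix", "DoseInfluence", function(x) x@D)
#' @rdname doseMatrix
#' @export
setGeneric("nBixels", function(x) standardGeneric("nBixels"))
#' @rdname doseMatrix
#' @export
setMethod("nBixels", "DoseInfluence", function(x) ncol(x@D))
#' @rdname doseMatrix
#' @export
setGeneric("doseCenter", function(x) standardGeneric("doseCenter"))
#' @rdname doseMatrix
#' @export
setMethod("doseCenter", "IntervalDoseModel", function(x) x@center)
#' @rdname doseMatrix
#' @export
setGeneric("doseRadiusModel", function(x) standardGeneric("doseRadiusModel"))
#' @rdname doseMatrix
#' @export
setMethod("doseRadiusModel", "IntervalDoseModel", function(x) x@radius)

#' Compressed-radius accessors
#' @param x a CompressedRadius or IntervalDoseModel.
#' @return \code{radiusRank}: retained mode count k; \code{singularValues}:
#'   retained singular values; \code{varianceExplained}: retained fraction of
#'   total squared singular value.
#' @export
setGeneric("radiusRank", function(x) standardGeneric("radiusRank"))
#' @rdname radiusRank
#' @export
setMethod("radiusRank", "CompressedRadius", function(x) x@rank)
#' @rdname radiusRank
#' @export
setMethod("radiusRank", "IntervalDoseModel", function(x) x@radius@rank)
#' @rdname radiusRank
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
#' @rdname radiusRank
#' @export
setMethod("singularValues", "CompressedRadius", function(x) x@sv)
#' @rdname radiusRank
#' @export
setMethod("singularValues", "IntervalDoseModel", function(x) x@radius@sv)
#' @rdname radiusRank
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @rdname radiusRank
#' @export
setMethod("varianceExplained", "CompressedRadius", function(x) x@varianceExplained)
#' @rdname radiusRank
#' @export
setMethod("varianceExplained", "IntervalDoseModel", function(x) x@radius@varianceExplained)

#' Plan-evaluation accessors
#' @param x a PlanEvaluation.
#' @return \code{robustnessIndexOf}: RI in [0, 1]; \code{deltaValues}:
#'   per-CTV-voxel Delta; \code{priceMetrics}: list (v40_rectum, v60_bladder);
#'   \code{dvhTable}: long-format DVH table.
#' @export
setGeneric("robustnessIndexOf", function(x) standardGeneric("robustnessIndexOf"))
#' @rdname robustnessIndexOf
#' @export
setMethod("robustnessIndexOf", "PlanEvaluation", function(x) x@ri)
#' @rdname robustnessIndexOf
#' @export
setGeneric("deltaValues", function(x) standardGeneric("deltaValues"))
#' @rdname robustnessIndexOf
#' @export
setMethod("deltaValues", "PlanEvaluation", function(x) x@delta)
#' @rdname robustnessIndexOf
#' @export
setGeneric("priceMetrics", function(x) standardGeneric("priceMetrics"))
#' @rdname robustnessIndexOf
#' @export
setMethod("priceMetrics", "PlanEvaluation", function(x) x@price)
#' @rdname robustnessIndexOf
#' @export
setGeneric("dvhTable", function(x) standardGeneric("dvhTable"))
#' @rdname robustnessIndexOf
#' @export
setMethod("dvhTable", "PlanEvaluation", function(x) x@dvh)

# -- show methods -----------------------------------------------------------

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s voxels at %s mm\n",
              paste(object@shape, collapse = "x"),
              paste(object@spacing, collapse = "x")))
})

setMethod("show", "VoxelPhantom", function(object) {
  cat(sprintf("VoxelPhantom %s voxels at %s mm\n",
              paste(object@grid@shape, collapse = "x"),
              paste(object@grid@spacing, collapse = "x")))
  for (nm in names(object@masks))
    cat(sprintf("  %-10s %d voxels\n", nm, sum(object@masks[[nm]])))
})

setMethod("show", "ScenarioSet", function(object) {
  cat(sprintf("ScenarioSet (%s): %d scenarios, sigma = (%s) mm\n",
              object@purpose, nrow(object@shifts),
              paste(object@sigma, collapse = ", ")))
})

setMethod("show", "DoseInfluence", function(object) {
  cat(sprintf("DoseInfluence %d voxels x %d bixels, %d nonzeros, shift (%s) mm\n",
              nrow(object@D), ncol(object@D), length(object@D@x),
              paste(object@shift, collapse = ", ")))
})

setMethod("show", "CompressedRadius", function(object) {
  cat(sprintf("CompressedRadius: rank %d of %d, variance explained %.4f\n",
              object@rank, object@fullRank, object@varianceExplained))
})

setMethod("show", "IntervalDoseModel", function(object) {
  cat(sprintf("IntervalDoseModel: center %d x %d, %d scenarios, radius rank %d (%.2f%% variance)\n",
              nrow(object@center), ncol(object@center), length(object@weights),
              object@radius@rank, 100 * object@radius@varianceExplained))
})

setMethod("show", "PlanEvaluation", function(object) {
  cat(sprintf("PlanEvaluation [%s%s]: RI = %.3f, V40Gy rectum = %.1f%%, V60Gy bladder = %.1f%%\n",
              object@model,
              if (is.finite(object@theta)) sprintf(", theta = %g", object@theta) else "",
              object@ri, object@price$v40_rectum, object@price$v60_bladder))
})
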