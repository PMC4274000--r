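#' Accessors for patchCT objects
#'
#' Small accessor generics for the S4 containers: view angles, detector bin
#' count, image side, pixel pitch, sinogram values, acquisition geometry,
#' patch counts, patch side, translation step, channel count, dictionary
#' atoms and solver-trace components.
#'
#' @param x,object a patchCT S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("nAngles", function(x) standardGeneric("nAngles"))
#' @rdname accessors
#' @export
setGeneric("detBins", function(x) standardGeneric("detBins"))
#' @rdname accessors
#' @export
setGeneric("imageSide", function(x) standardGeneric("imageSide"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("sinogramValues", function(x) standardGeneric("sinogramValues"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))
#' @rdname accessors
#' @export
setGeneric("patchSide", function(x) standardGeneric("patchSide"))
#' @rdname accessors
#' @export
setGeneric("stepSize", function(x) standardGeneric("stepSize"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("patchCorners", function(x) standardGeneric("patchCorners"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("patchCoefficients", function(x) standardGeneric("patchCoefficients"))
#' @rdname accessors
#' @export
setGeneric("solution", function(x) standardGeneric("solution"))

# ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("angles", "ProjectionGeometry", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("angles", "Sinogram", function(x) x@geometry@angles)
#' @rdname accessors
#' @export
setMethod("nAngles", "ProjectionGeometry", function(x) length(x@angles))
#' @rdname accessors
#' @export
setMethod("nAngles", "Sinogram", function(x) length(x@geometry@angles))
#' @rdname accessors
#' @export
setMethod("detBins", "ProjectionGeometry", function(x) x@nDet)
#' @rdname accessors
#' @export
setMethod("detBins", "Sinogram", function(x) x@geometry@nDet)
#' @rdname accessors
#' @export
setMethod("imageSide", "ProjectionGeometry", function(x) x@imageSide)
#' @rdname accessors
#' @export
setMethod("imageSide", "PatchLattice", function(x) x@imageSide)
#' @rdname accessors
#' @export
setMethod("imageSide", "CoreMap", function(x) x@imageSide)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ProjectionGeometry", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("sinogramValues", "Sinogram", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("geometry", "Sinogram", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("nPatches", "PatchLattice", function(x) nrow(x@corners))
#' @rdname accessors
#' @export
setMethod("nPatches", "CoreMap", function(x) x@nPatches)
#' @rdname accessors
#' @export
setMethod("patchSide", "PatchLattice", function(x) x@m)
#' @rdname accessors
#' @export
setMethod("patchSide", "PatchDictionary", function(x) x@m)
#' @rdname accessors
#' @export
setMethod("stepSize", "PatchLattice", function(x) x@s)
#' @rdname accessors
#' @export
setMethod("nChannels", "PatchLattice", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("nChannels", "PatchDictionary", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("patchCorners", "PatchLattice", function(x) x@corners)
#' @rdname accessors
#' @export
setMethod("atoms", "PatchDictionary", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "PatchDictionary", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "SolverTrace", function(x) x@objective)
#' @rdname accessors
#' @export
setMethod("patchCoefficients", "SolverTrace", function(x) x@coefficients)
#' @rdname accessors
#' @export
setMethod("solution", "SolverTrace", function(x) x@solution)

# ---- show ----------------------------------------------------------------

setMethod("show", "ProjectionGeometry", function(object) {
  cat(sprintf("ProjectionGeometry: %d views in [%.2f, %.2f] deg, %d detector bins, %dpx grid (pixel %.3g)\n",
              length(object@angles), min(object@angles), max(object@angles),
              object@nDet, object@imageSide, object@pixelSize))
})

setMethod("show", "Sinogram", function(object) {
  v <- object@values
  cat(sprintf("Sinogram: %d angles x %d bins, values in [%.4g, %.4g]\n",
              nrow(v), ncol(v), min(v), max(v)))
})

setMethod("show", "PatchLattice", function(object) {
  cat(sprintf("PatchLattice: %d patches (m=%d, step=%d, %d channel%s) on a %dpx grid\n",
              nrow(object@corners), object@m, object@s, object@channels,
              if (object@channels > 1L) "s" else "", object@imageSide))
})

setMethod("show", "CoreMap", function(object) {
  cat(sprintf("CoreMap: %dpx grid partitioned among %d patch cores (m=%d)\n",
              object@imageSide, object@nPatches, object@m))
})

setMethod("show", "PatchDictionary", function(object) {
  cat(sprintf("PatchDictionary: %d unit-norm atoms of %dx%d px, %d channel%s\n",
              nrow(object@atoms), object@m, object@m, object@channels,
              if (object@channels > 1L) "s" else ""))
})

setMethod("show", "SolverParams", function(object) {
  cat(sprintf("SolverParams: lambda=%.4g omega=%.4g nIter=%d tau=%s mode=%s tol=%.1e\n",
              object@lambda, object@omega, object@nIter,
              if (object@tau > 0) sprintf("%.3g", object@tau) else "auto",
              object@mode, object@tol))
})

setMethod("show", "SolverTrace", function(object) {
  cat(sprintf("SolverTrace: %d iterations, objective %.6g -> %.6g\n",
              object@iterations, object@objective[1],
              object@objective[length(object@objective)]))
})
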