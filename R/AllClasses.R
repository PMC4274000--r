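#' @import methods
#' @importFrom stats fft mvfft nextn rnorm runif rpois
NULL

#' Parallel-beam acquisition geometry
#'
#' Describes a parallel-beam scan: the view angles (degrees in \[0, 180)),
#' the number of detector bins, the side of the square reconstruction grid
#' and the pixel pitch.  Detector bin width equals the pixel width and the
#' detector is centered on the rotation axis; angle 0 sends rays parallel to
#' the image Y axis so that the projection falls onto the X axis.
#'
#' @slot angles numeric vector of view angles in degrees, strictly
#'   increasing, all in \[0, 180).
#' @slot nDet integer, number of detector bins (>= image side).
#' @slot imageSide integer, side of the square image grid in pixels.
#' @slot pixelSize numeric, pixel pitch in length units (default 1).
#' @exportClass ProjectionGeometry
setClass("ProjectionGeometry",
  representation(angles = "numeric", nDet = "integer",
                 imageSide = "integer", pixelSize = "numeric"))

setValidity("ProjectionGeometry", function(object) {
  a <- object@angles
  if (length(a) < 1L) return("at least one view angle is required")
  if (any(!is.finite(a))) return("angles must be finite")
  if (any(a < 0 | a >= 180)) return("angles must lie in [0, 180) degrees")
  if (length(a) > 1L && any(diff(a) <= 0)) return("angles must be strictly increasing")
  if (object@imageSide < 1L) return("imageSide must be positive")
  if (object@nDet < object@imageSide) return("nDet must be >= imageSide")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' Sinogram: stack of 1-D projections
#'
#' An angles x detector-bins array of discrete line integrals together with
#' the geometry it was acquired under.
#'
#' @slot values numeric matrix, nAngles x nDet, finite.
#' @slot geometry a [ProjectionGeometry-class].
#' @exportClass Sinogram
setClass("Sinogram",
  representation(values = "matrix", geometry = "ProjectionGeometry"))

setValidity("Sinogram", function(object) {
  g <- object@geometry
  if (!all(dim(object@values) == c(length(g@angles), g@nDet)))
    return("sinogram dimensions do not match geometry (nAngles x nDet)")
  if (any(!is.finite(object@values))) return("sinogram values must be finite")
  TRUE
})

#' Overlapping patch lattice
#'
#' The patch system used by the overlap functional: a base non-overlapping
#' m x m tiling of the image plus all its translates by (i*s, j*s) with
#' 0 <= i, j < m/s, each translate clipped to the patches fully inside the
#' image.  Ordering is fixed: translate offsets in lexicographic (i, j)
#' order, patches row-major within each translate, so coefficient files are
#' portable.
#'
#' @slot imageSide integer image side (m must divide it).
#' @slot m integer patch side.
#' @slot s integer translation step (divides m; s = m gives the
#'   non-overlapping tiling).
#' @slot channels integer, 1 (scalar) or 2 (vectorial gradient patches).
#' @slot corners integer matrix nPatches x 2 of 0-based (row, col) patch
#'   corners.
#' @slot patchPix integer matrix nPatches x m^2 of image linear indices of
#'   each patch's pixels (local pixels column-major).
#' @exportClass PatchLattice
setClass("PatchLattice",
  representation(imageSide = "integer", m = "integer", s = "integer",
                 channels = "integer", corners = "matrix",
                 patchPix = "matrix"))

setValidity("PatchLattice", function(object) {
  if (object@m < 1L || object@imageSide %% object@m != 0L)
    return("patch side m must divide imageSide")
  if (object@s < 1L || object@s > object@m || object@m %% object@s != 0L)
    return("step s must satisfy 1 <= s <= m and divide m")
  if (!object@channels %in% c(1L, 2L)) return("channels must be 1 or 2")
  if (ncol(object@corners) != 2L) return("corners must be an n x 2 matrix")
  if (nrow(object@patchPix) != nrow(object@corners))
    return("patchPix rows must match corner count")
  cover <- tabulate(object@patchPix, nbins = object@imageSide^2)
  if (any(cover < 1L)) return("every pixel must be covered by at least one patch")
  TRUE
})

#' Core map of a patch lattice
#'
#' For every pixel, the index of the patch whose center is nearest (ties
#' broken by lowest patch index) and the pixel's local position inside that
#' patch.  The cores form an exact partition of the image: the core
#' indicators sum to one at every pixel.
#'
#' @slot whichPatch integer matrix (side x side), nearest-center patch index
#'   per pixel.
#' @slot localIndex integer matrix (side x side), 1-based column-major local
#'   pixel index within the owning patch.
#' @slot imageSide,m,nPatches,channels integers copied from the lattice.
#' @exportClass CoreMap
setClass("CoreMap",
  representation(whichPatch = "matrix", localIndex = "matrix",
                 imageSide = "integer", m = "integer",
                 nPatches = "integer", channels = "integer"))

setValidity("CoreMap", function(object) {
  if (!all(dim(object@whichPatch) == object@imageSide) ||
      !all(dim(object@localIndex) == object@imageSide))
    return("core map dimensions must equal imageSide")
  if (any(object@whichPatch < 1L | object@whichPatch > object@nPatches))
    return("patch indices out of range")
  if (any(object@localIndex < 1L | object@localIndex > object@m^2))
    return("local indices out of range")
  TRUE
})

#' Patch dictionary
#'
#' K unit-norm atoms, each an m x m patch with 1 (scalar) or 2 (vectorial)
#' channels, stored flattened channel-stacked: an atom row holds the m^2
#' values of the X channel followed, for vectorial dictionaries, by the m^2
#' values of the Y channel.
#'
#' @slot atoms numeric matrix K x (m^2 * channels), rows unit Euclidean norm.
#' @slot m integer patch side.
#' @slot channels integer 1 or 2.
#' @exportClass PatchDictionary
setClass("PatchDictionary",
  representation(atoms = "matrix", m = "integer", channels = "integer"))

setValidity("PatchDictionary", function(object) {
  if (!object@channels %in% c(1L, 2L)) return("channels must be 1 or 2")
  if (ncol(object@atoms) != object@m^2 * object@channels)
    return("atom length must equal m^2 * channels")
  if (any(!is.finite(object@atoms))) return("atoms must be finite")
  nrm <- sqrt(rowSums(object@atoms^2))
  if (any(abs(nrm - 1) > 1e-8)) return("atoms must have unit Euclidean norm")
  TRUE
})

#' Solver configuration
#'
#' Regularization weights and iteration controls for the proximal-gradient
#' solvers.  `lambda` weights the sparsity-inducing l1 norm of the patch
#' coefficients; `omega` weights the similarity term penalizing
#' disagreement between overlapping patches and the composed solution;
#' `tau` is the gradient step (0 requests the automatic 0.9/L choice with L
#' estimated by power iteration).
#'
#' @slot lambda,omega non-negative regularization weights.
#' @slot nIter integer iteration budget.
#' @slot tau numeric step size; 0 means automatic (0.9/L).
#' @slot seed integer seed for any randomized initialization (power iteration).
#' @slot mode "tomography" or "denoising".
#' @slot tol relative objective-change early-exit threshold (0 disables).
#' @exportClass SolverParams
setClass("SolverParams",
  representation(lambda = "numeric", omega = "numeric", nIter = "integer",
                 tau = "numeric", seed = "integer", mode = "character",
                 tol = "numeric"))

setValidity("SolverParams", function(object) {
  if (!is.finite(object@lambda) || object@lambda < 0) return("lambda must be finite and >= 0")
  if (!is.finite(object@omega) || object@omega < 0) return("omega must be finite and >= 0")
  if (object@nIter < 1L) return("nIter must be >= 1")
  if (!is.finite(object@tau) || object@tau < 0) return("tau must be >= 0 (0 = auto)")
  if (!object@mode %in% c("tomography", "denoising")) return("mode must be 'tomography' or 'denoising'")
  if (object@tol < 0) return("tol must be >= 0")
  TRUE
})

#' Solver trace
#'
#' Objective values per iteration (including the initial point), the final
#' coefficient set and the composed solution.
#'
#' @slot objective numeric vector, length iterations + 1.
#' @slot coefficients numeric matrix nPatches x K.
#' @slot solution the composed image (matrix) or vector image
#'   (side x side x 2 array); for the floating functional, the free image.
#' @slot iterations integer, iterations actually run.
#' @slot extra list of solver-specific extras.
#' @exportClass SolverTrace
setClass("SolverTrace",
  representation(objective = "numeric", coefficients = "matrix",
                 solution = "ANY", iterations = "integer", extra = "list"))

setValidity("SolverTrace", function(object) {
  if (any(!is.finite(object@objective))) return("objective trace must be finite")
  if (length(object@objective) != object@iterations + 1L)
    return("trace length must be iterations + 1")
  TRUE
})
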