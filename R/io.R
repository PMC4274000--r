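# Persistence: 32-bit float TIFF for pixel data, JSON sidecars for
# geometry/attributes, JSON for dictionaries, CSV for coefficient sets and
# solver traces, YAML for solver configuration.

# TIFF samples are stored normalized to [0, 1]; the affine range travels in
# a JSON sidecar so arbitrary-valued data round-trip (to float32 precision).
.writeNormTIFF <- function(x, path) {
  r <- range(x)
  span <- if (diff(r) > 0) diff(r) else 1
  tiff::writeTIFF((x - r[1]) / span, path, bits.per.sample = 32L,
                  reduce = FALSE)
  list(vmin = r[1], vmax = r[1] + span)
}

.readNormTIFF <- function(path, meta) {
  x <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  unclass(x) * (meta$vmax - meta$vmin) + meta$vmin
}

#' Read and write images as 32-bit float TIFF
#'
#' Values are affinely mapped to \[0, 1\] for storage and the range kept in
#' a `<path>.json` sidecar, so images of any dynamic range round-trip to
#' 32-bit float precision.
#'
#' @param img square numeric matrix.
#' @param path file path (`.tif`).
#' @return `readImageTIFF` returns the image matrix; `writeImageTIFF`
#'   returns `path` invisibly.
#' @export
writeImageTIFF <- function(img, path) {
  .checkImage(img)
  meta <- .writeNormTIFF(img, path)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  .readNormTIFF(path, meta)
}

#' Read and write sinograms (TIFF values + JSON geometry sidecar)
#'
#' The pixel data go into a 32-bit float TIFF; the acquisition geometry
#' (angles, detector bins, image side, pixel size) goes into `<path>.json`.
#'
#' @param sino a [Sinogram-class].
#' @param path TIFF file path.
#' @return `readSinogram` returns a [Sinogram-class]; `writeSinogram`
#'   returns `path` invisibly.
#' @export
writeSinogram <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  meta <- .writeNormTIFF(sino@values, path)
  g <- sino@geometry
  jsonlite::write_json(
    c(meta, list(angles = g@angles, nDet = g@nDet, imageSide = g@imageSide,
                 pixelSize = g@pixelSize)),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- .readNormTIFF(path, meta)
  geom <- projectionGeometry(meta$imageSide, angles = meta$angles,
                             nDet = meta$nDet, pixelSize = meta$pixelSize)
  sinogram(v, geom)
}

#' Read and write dictionaries as JSON
#'
#' Atoms are stored row-wise with their patch side and channel count.
#'
#' @param dict a [PatchDictionary-class].
#' @param path JSON file path.
#' @return `readDictionary` returns a [PatchDictionary-class].
#' @export
writeDictionary <- function(dict, path) {
  jsonlite::write_json(
    list(m = dict@m, channels = dict@channels,
         atoms = apply(dict@atoms, 1L, function(r) r, simplify = FALSE)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDictionary
#' @export
readDictionary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  atoms <- if (is.list(x$atoms)) do.call(rbind, x$atoms) else x$atoms
  patchDictionary(atoms, m = x$m, channels = x$channels)
}

#' Read and write coefficient sets as CSV
#'
#' Plain CSV, one patch per row, atoms as columns; lattice parameters
#' travel in a JSON sidecar so files are portable across sessions.
#'
#' @param coeffs nPatches x K matrix.
#' @param lat the [PatchLattice-class] the coefficients belong to.
#' @param path CSV file path.
#' @return `readCoefficients` returns a list `coeffs`, `lattice`.
#' @export
writeCoefficients <- function(coeffs, lat, path) {
  utils::write.table(coeffs, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(imageSide = lat@imageSide, m = lat@m, s = lat@s,
         channels = lat@channels),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCoefficients
#' @export
readCoefficients <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(w) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lat <- buildLattice(meta$imageSide, meta$m, meta$s, channels = meta$channels)
  list(coeffs = w, lattice = lat)
}

#' Write a solver trace as CSV
#'
#' Two columns: iteration (0 = initial point) and objective value.
#'
#' @param trace a [SolverTrace-class].
#' @param path CSV file path.
#' @export
writeTrace <- function(trace, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(trace@objective) - 1L,
               objective = trace@objective),
    path, row.names = FALSE)
  invisible(path)
}

#' Read solver parameters from a YAML config
#'
#' Expects a top-level `solver:` block with any of `lambda`, `omega`,
#' `iters`, `tau`, `seed`, `mode`, `tol`; missing entries keep the
#' [solverParams()] defaults.
#'
#' @param path YAML file path.
#' @return a [SolverParams-class].
#' @export
readSolverConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  s <- cfg$solver
  if (is.null(s)) stop("config has no 'solver' block")
  d <- solverParams()
  solverParams(
    lambda = if (!is.null(s$lambda)) s$lambda else d@lambda,
    omega = if (!is.null(s$omega)) s$omega else d@omega,
    nIter = if (!is.null(s$iters)) s$iters else d@nIter,
    tau = if (!is.null(s$tau)) s$tau else d@tau,
    seed = if (!is.null(s$seed)) s$seed else d@seed,
    mode = if (!is.null(s$mode)) s$mode else d@mode,
    tol = if (!is.null(s$tol)) s$tol else d@tol)
}
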