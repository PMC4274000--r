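#' Build an overlapping patch lattice
#'
#' The patch system is a base non-overlapping `m x m` tiling of the image
#' plus its translated copies by `(i*s, j*s)` for `0 <= i, j < m/s`, with a
#' user-selected constant step `s`.  Translates that would stick out of the
#' image are clipped to the set of patches fully inside, so every patch
#' keeps a full `m x m` support.  With `s = m` the system reduces to the
#' plain non-overlapping tiling.  Patch ordering is deterministic: translate
#' offsets in lexicographic `(i, j)` order, patches row-major inside each
#' translate.
#'
#' @param imageSide image side in pixels; `m` must divide it.
#' @param m patch side in pixels.
#' @param s translation step, `1 <= s <= m`, dividing `m`.
#' @param channels 1 for scalar images, 2 for vectorial (gradient) images.
#' @return a [PatchLattice-class].
#' @examples
#' buildLattice(16, 8, 4)
#' @export
buildLattice <- function(imageSide, m, s = m, channels = 1L) {
  imageSide <- as.integer(imageSide); m <- as.integer(m); s <- as.integer(s)
  if (m < 1L || imageSide %% m != 0L)
    stop(sprintf("patch side m=%d must divide imageSide=%d", m, imageSide))
  if (s < 1L || s > m || m %% s != 0L)
    stop(sprintf("step s=%d must satisfy 1 <= s <= m=%d and divide m", s, m))
  nt <- m %/% s
  corners <- list(); idx <- 1L
  for (i in seq_len(nt) - 1L) {
    for (j in seq_len(nt) - 1L) {
      rows0 <- seq.int(i * s, imageSide - m, by = m)
      cols0 <- seq.int(j * s, imageSide - m, by = m)
      if (length(rows0) == 0L || length(cols0) == 0L) next
      corners[[idx]] <- cbind(rep(rows0, each = length(cols0)),
                              rep(cols0, times = length(rows0)))
      idx <- idx + 1L
    }
  }
  corners <- do.call(rbind, corners)
  storage.mode(corners) <- "integer"
  P <- nrow(corners); m2 <- m * m
  localRow <- rep_len(seq_len(m) - 1L, m2)          # local pixels column-major
  localCol <- rep(seq_len(m) - 1L, each = m)
  patchPix <- matrix(corners[, 1], P, m2) + matrix(localRow, P, m2, byrow = TRUE) +
    (matrix(corners[, 2], P, m2) + matrix(localCol, P, m2, byrow = TRUE)) * imageSide + 1L
  storage.mode(patchPix) <- "integer"
  new("PatchLattice", imageSide = imageSide, m = m, s = s,
      channels = as.integer(channels), corners = corners, patchPix = patchPix)
}

#' Nearest-center core map of a lattice
#'
#' Assigns every pixel to the patch whose center is nearest (Euclidean
#' distance between the pixel center and the patch center; ties broken by
#' the lowest patch index).  The resulting core indicator functions
#' partition the image exactly -- they sum to one at every pixel -- and each
#' core is contained in its patch's support, which is verified and enforced.
#' With `s = 1` each core shrinks to the single pixel at the patch center;
#' with `s = m` the cores are the patches themselves.
#'
#' @param lat a [PatchLattice-class].
#' @return a [CoreMap-class].
#' @export
coreMap <- function(lat) {
  stopifnot(is(lat, "PatchLattice"))
  side <- lat@imageSide; m <- lat@m; N <- side * side
  P <- nrow(lat@corners)
  r0 <- rep_len(seq_len(side) - 1L, N)
  c0 <- rep(seq_len(side) - 1L, each = side)
  ctrR <- lat@corners[, 1] + (m - 1) / 2
  ctrC <- lat@corners[, 2] + (m - 1) / 2
  bestD <- rep(Inf, N); bestP <- integer(N)
  for (p in seq_len(P)) {
    d <- (r0 - ctrR[p])^2 + (c0 - ctrC[p])^2
    upd <- d < bestD                    # strict: ties keep the lowest index
    bestD[upd] <- d[upd]; bestP[upd] <- p
  }
  lr <- r0 - lat@corners[bestP, 1]
  lc <- c0 - lat@corners[bestP, 2]
  if (any(lr < 0L | lr >= m | lc < 0L | lc >= m))
    stop("core map inconsistency: a pixel's nearest patch does not cover it")
  localIndex <- lr + lc * m + 1L
  new("CoreMap",
      whichPatch = matrix(as.integer(bestP), side, side),
      localIndex = matrix(as.integer(localIndex), side, side),
      imageSide = side, m = m, nPatches = as.integer(P),
      channels = lat@channels)
}

# linear indices into the nPatches x (m^2 * C) patch-value stack picking, for
# every pixel, the entry of its core patch (channel ch)
.coreStackIdx <- function(core, ch = 1L) {
  P <- core@nPatches; m2 <- core@m^2
  (as.vector(core@localIndex) + (ch - 1L) * m2 - 1L) * P + as.vector(core@whichPatch)
}

#' Per-pixel coverage count of a lattice
#'
#' Number of patches containing each pixel (the sum of the patch indicator
#' functions, >= 1 everywhere by construction).
#'
#' @param lat a [PatchLattice-class].
#' @return integer matrix side x side.
#' @export
coverageCount <- function(lat) {
  matrix(tabulate(lat@patchPix, nbins = lat@imageSide^2),
         lat@imageSide, lat@imageSide)
}

.checkCoeffs <- function(coeffs, lat, dict) {
  if (!is.matrix(coeffs)) stop("coefficients must be a matrix")
  if (nrow(coeffs) != nrow(lat@corners))
    stop("coefficient rows must equal the lattice patch count")
  if (ncol(coeffs) != nrow(dict@atoms))
    stop("coefficient columns must equal the number of dictionary atoms")
  if (dict@m != lat@m) stop("dictionary and lattice patch sides differ")
  if (dict@channels != lat@channels) stop("dictionary and lattice channel counts differ")
  invisible(TRUE)
}

#' Compose one patch from its coefficients
#'
#' The linear combination `sum_k w_k * atom_k` over the patch support.
#'
#' @param coeffs numeric vector of length `nAtoms(dict)`.
#' @param dict a [PatchDictionary-class].
#' @return numeric vector of length `m^2 * channels` (local pixels
#'   column-major, channels stacked).
#' @export
composePatch <- function(coeffs, dict) {
  if (length(coeffs) != nrow(dict@atoms))
    stop("coefficient length must equal the number of atoms")
  as.numeric(matrix(coeffs, 1L) %*% dict@atoms)
}

# all patches at once: nPatches x (m^2 * C)
.composeAll <- function(coeffs, dict) coeffs %*% dict@atoms

#' Compose the global solution from per-patch coefficients
#'
#' Every pixel takes the value of its nearest-center (core) patch's
#' composition at that pixel, so the global image is assembled from the
#' central parts of the patches without averaging.
#'
#' @param coeffs numeric matrix nPatches x K of patch coefficients.
#' @param lat a [PatchLattice-class].
#' @param core the matching [CoreMap-class].
#' @param dict a [PatchDictionary-class].
#' @return for scalar lattices a side x side matrix; for vectorial ones a
#'   side x side x 2 array (X then Y gradient channel).
#' @export
composeSolution <- function(coeffs, lat, core, dict) {
  .checkCoeffs(coeffs, lat, dict)
  U <- .composeAll(coeffs, dict)
  side <- lat@imageSide; C <- lat@channels
  if (C == 1L) return(matrix(U[.coreStackIdx(core, 1L)], side, side))
  out <- array(0, c(side, side, C))
  for (ch in seq_len(C)) out[, , ch] <- U[.coreStackIdx(core, ch)]
  out
}

#' Extract the patch stack of an image
#'
#' Reads every lattice patch out of a scalar image (or each channel of a
#' vector image), local pixels column-major, channels stacked -- the layout
#' the dictionary atoms use.
#'
#' @param img side x side matrix, or side x side x 2 array when the lattice
#'   is vectorial.
#' @param lat a [PatchLattice-class].
#' @return matrix nPatches x (m^2 * channels).
#' @export
extractPatches <- function(img, lat) {
  side <- lat@imageSide; C <- lat@channels
  if (C == 1L) {
    if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
    .checkImage(img, side)
    return(matrix(img[lat@patchPix], nrow(lat@patchPix), ncol(lat@patchPix)))
  }
  if (length(dim(img)) != 3L || dim(img)[3] != C || dim(img)[1] != side || dim(img)[2] != side)
    stop("vectorial extraction needs a side x side x 2 array matching the lattice")
  do.call(cbind, lapply(seq_len(C), function(ch) {
    v <- img[, , ch]
    matrix(v[lat@patchPix], nrow(lat@patchPix), ncol(lat@patchPix))
  }))
}

# adjoint of extractPatches: overlap-add a patch stack back into image(s)
.overlapAdd <- function(stack, lat) {
  side <- lat@imageSide; C <- lat@channels; m2 <- lat@m^2; N <- side * side
  grp <- as.vector(lat@patchPix)
  if (C == 1L) {
    return(matrix(rowsum(as.vector(stack), grp), side, side))
  }
  out <- array(0, c(side, side, C))
  for (ch in seq_len(C)) {
    sub <- stack[, (ch - 1L) * m2 + seq_len(m2), drop = FALSE]
    out[, , ch] <- matrix(rowsum(as.vector(sub), grp), side, side)
  }
  out
}

# adjoint of the core-composition gather: scatter image(s) into a zero stack
.coreScatter <- function(img, core) {
  P <- core@nPatches; m2 <- core@m^2; C <- core@channels
  U <- matrix(0, P, m2 * C)
  if (C == 1L) {
    U[.coreStackIdx(core, 1L)] <- as.vector(img)
  } else {
    for (ch in seq_len(C)) U[.coreStackIdx(core, ch)] <- as.vector(img[, , ch])
  }
  U
}

#' Overlap residuals between patches and the composed solution
#'
#' For every patch `p` and every pixel of its support, the difference
#' between the composed patch value there and the global (core-composed)
#' solution value.  The squared sum of this stack is the similarity term of
#' the overlap functional; it vanishes identically when the patches
#' mutually agree, and in particular for `s = m` (no overlap).
#'
#' @inheritParams composeSolution
#' @return matrix nPatches x (m^2 * channels) of residuals.
#' @export
overlapResidual <- function(coeffs, lat, core, dict) {
  .checkCoeffs(coeffs, lat, dict)
  U <- .composeAll(coeffs, dict)
  sol <- composeSolution(coeffs, lat, core, dict)
  U - extractPatches(sol, lat)
}
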