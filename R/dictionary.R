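#' Construct a patch dictionary
#'
#' Rows are flattened atoms (local pixels column-major, channels stacked);
#' they are renormalized to unit Euclidean norm and sign-fixed so that the
#' first entry larger than 1e-12 in magnitude is positive, making
#' dictionaries reproducible across the sign ambiguity of SVD updates.
#'
#' @param atoms numeric matrix K x (m^2 * channels).
#' @param m patch side.
#' @param channels 1 or 2.
#' @return a [PatchDictionary-class].
#' @export
patchDictionary <- function(atoms, m, channels = 1L) {
  atoms <- as.matrix(atoms)
  nrm <- sqrt(rowSums(atoms^2))
  if (any(nrm < 1e-12)) stop("zero-norm atom encountered")
  atoms <- atoms / nrm
  atoms <- t(apply(atoms, 1L, .fixSign))
  new("PatchDictionary", atoms = atoms, m = as.integer(m),
      channels = as.integer(channels))
}

.fixSign <- function(v) {
  k <- which(abs(v) > 1e-12)[1]
  if (!is.na(k) && v[k] < 0) -v else v
}

#' Orthogonal matching pursuit sparse coding
#'
#' Greedy sparse coder: at each step it selects the atom with maximum
#' absolute correlation with the current residual, then least-squares
#' refits the signal on the selected support, stopping after `T0` atoms or
#' when the residual norm drops to `tol`.  The residual norm is
#' non-increasing in the step count.
#'
#' @param patch numeric vector of length `m^2 * channels`.
#' @param dict a [PatchDictionary-class].
#' @param T0 maximum support size (>= 1).
#' @param tol residual-norm stopping threshold.
#' @return a list with `support` (atom indices), `values` (coefficients on
#'   the support) and `residualNorm`.
#' @export
ompCode <- function(patch, dict, T0 = 5L, tol = 1e-12) {
  if (T0 < 1L) stop("T0 must be >= 1")
  .omp(as.numeric(patch), t(dict@atoms), T0, tol)
}

# D: n x K with unit-norm columns
.omp <- function(y, D, T0, tol) {
  K <- ncol(D)
  support <- integer(0)
  r <- y
  vals <- numeric(0)
  for (step in seq_len(min(T0, K))) {
    rn <- sqrt(sum(r^2))
    if (rn <= tol) break
    corr <- abs(as.numeric(crossprod(D, r)))
    if (length(support)) corr[support] <- -Inf
    k <- which.max(corr)
    support <- c(support, k)
    Ds <- D[, support, drop = FALSE]
    vals <- as.numeric(qr.solve(qr(Ds), y))
    r <- y - as.numeric(Ds %*% vals)
  }
  list(support = support, values = vals, residualNorm = sqrt(sum(r^2)))
}

# sparse-code a whole training set; returns K x P dense coefficient matrix
.ompCodeAll <- function(X, D, T0, tol = 1e-12) {
  P <- ncol(X); K <- ncol(D)
  W <- matrix(0, K, P)
  for (p in seq_len(P)) {
    sc <- .omp(X[, p], D, T0, tol)
    if (length(sc$support)) W[sc$support, p] <- sc$values
  }
  W
}

#' K-SVD dictionary training
#'
#' Alternates OMP sparse coding of all training patches with per-atom
#' rank-1 SVD updates: for each atom, the residual of the patches using it
#' (with that atom's contribution restored) is decomposed and its leading
#' left/right singular pair replaces the atom and its coefficients.  Atoms
#' left unused by the coding step are replaced by the currently
#' worst-represented training patch.  With `dcAtom = TRUE` a constant atom
#' is prepended and frozen so smooth regions stay representable; gradient
#' (vectorial) patches are zero-mean by nature, so the default drops it
#' there.  Deterministic for a fixed `seed`.
#'
#' @param patches numeric matrix nPatches x (m^2 * channels), one training
#'   patch per row (the layout of [extractPatches()]).
#' @param K number of atoms.
#' @param T0 OMP sparsity level.
#' @param nIter number of coding/update sweeps.
#' @param seed integer seed for the initial atom draw.
#' @param m patch side (inferred from the patch length when omitted).
#' @param channels 1 or 2.
#' @param dcAtom include a frozen constant atom (default: scalar mode only).
#' @return a [PatchDictionary-class].
#' @export
ksvdTrain <- function(patches, K = 100L, T0 = 5L, nIter = 5L, seed = 1L,
                      m = NULL, channels = 1L, dcAtom = (channels == 1L)) {
  X <- t(as.matrix(patches))                       # n x P, one patch per column
  n <- nrow(X); P <- ncol(X)
  if (is.null(m)) m <- as.integer(round(sqrt(n / channels)))
  if (m^2 * channels != n) stop("patch length does not match m^2 * channels")
  if (P < K) stop("need at least K training patches")
  if (all(colSums(X^2) < 1e-20)) stop("degenerate training set: all patches are zero")
  nFree <- if (dcAtom) K - 1L else K
  D <- withr::with_seed(seed, {
    pick <- sample.int(P, nFree)
    X[, pick, drop = FALSE] + 1e-8 * matrix(stats::rnorm(n * nFree), n)
  })
  D <- D / rep(sqrt(colSums(D^2)), each = n)
  if (dcAtom) D <- cbind(rep(1 / sqrt(n), n), D)
  frozen <- if (dcAtom) 1L else integer(0)
  for (it in seq_len(nIter)) {
    W <- .ompCodeAll(X, D, T0)
    R <- X - D %*% W
    for (k in setdiff(seq_len(K), frozen)) {
      users <- which(abs(W[k, ]) > 0)
      if (!length(users)) {
        err <- colSums(R^2)
        worst <- which.max(err)
        d <- X[, worst]
        nd <- sqrt(sum(d^2))
        if (nd < 1e-12) next
        D[, k] <- .fixSign(d / nd)
        next
      }
      Ek <- R[, users, drop = FALSE] + outer(D[, k], W[k, users])
      sv <- svd(Ek, nu = 1L, nv = 1L)
      d <- sv$u[, 1]
      sgn <- {
        j <- which(abs(d) > 1e-12)[1]
        if (!is.na(j) && d[j] < 0) -1 else 1
      }
      d <- sgn * d
      wk <- sgn * sv$d[1] * sv$v[, 1]
      # keep the running residual consistent with the updated atom
      R[, users] <- R[, users, drop = FALSE] + outer(D[, k], W[k, users]) - outer(d, wk)
      D[, k] <- d
      W[k, users] <- wk
    }
  }
  patchDictionary(t(D), m = m, channels = channels)
}

#' Mean sparse-coding error of a dictionary over a patch set
#'
#' Convenience diagnostic: the mean squared OMP residual norm.
#'
#' @inheritParams ksvdTrain
#' @param dict a [PatchDictionary-class].
#' @return scalar mean of squared residual norms.
#' @export
codingError <- function(patches, dict, T0 = 5L) {
  X <- t(as.matrix(patches))
  D <- t(dict@atoms)
  W <- .ompCodeAll(X, D, T0)
  mean(colSums((X - D %*% W)^2))
}

#' Sobel gradient of an image
#'
#' Standard 3x3 Sobel X and Y responses (correlation with the kernels
#' `[-1 0 1; -2 0 2; -1 0 1]` and its transpose) with reflect padding at the
#' borders; a linear ramp of unit slope along X yields a constant X response
#' of 8.
#'
#' @param img square numeric matrix, side >= 3.
#' @return side x side x 2 array: X-derivative channel, then Y-derivative.
#' @export
sobelGradient <- function(img) {
  .checkImage(img)
  n <- nrow(img)
  if (n < 3L) stop("image side must be >= 3 for the Sobel filter")
  # reflect padding by one pixel on each border
  pad <- rbind(img[1, , drop = FALSE], img, img[n, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, n, drop = FALSE])
  sh <- function(dr, dc) pad[seq_len(n) + 1L + dr, seq_len(n) + 1L + dc]
  # rows = y, cols = x: X derivative differences along columns
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) - (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) - (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  out <- array(0, c(n, n, 2L))
  out[, , 1] <- gx; out[, , 2] <- gy
  out
}

#' Assemble a dictionary training set from images
#'
#' Scalar mode extracts raw patches from each training image; vectorial
#' mode first takes the Sobel gradient and stacks the X and Y channels per
#' patch.  Patches with near-zero variance (< 1e-10) are dropped since they
#' carry no trainable structure; per-patch mean removal is off by default.
#' Training images must be disjoint from the reconstruction target -- the
#' generator pipeline enforces that by seed.
#'
#' @param imgs a list of square matrices (or a single matrix).
#' @param m,s patch side and lattice step used for extraction.
#' @param vectorial extract two-channel gradient patches.
#' @param removeMean subtract each patch's mean before training.
#' @return numeric matrix of training patches, one per row.
#' @export
buildTrainingSet <- function(imgs, m = 8L, s = m, vectorial = FALSE,
                             removeMean = FALSE) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  if (!length(imgs)) stop("at least one training image is required")
  C <- if (vectorial) 2L else 1L
  stacks <- lapply(imgs, function(im) {
    lat <- buildLattice(nrow(im), m, s, channels = C)
    x <- if (vectorial) sobelGradient(im) else im
    extractPatches(x, lat)
  })
  X <- do.call(rbind, stacks)
  if (removeMean) X <- X - rowMeans(X)
  v <- apply(X, 1L, stats::var)
  X <- X[v >= 1e-10, , drop = FALSE]
  if (!nrow(X)) stop("no training patches left after variance filtering (constant input?)")
  X
}

#' Dictionary atom mosaic
#'
#' Lays the atoms out as a tile mosaic for visual inspection, each tile an
#' m x m patch (vectorial atoms drawn as the X half stacked over the Y
#' half, giving m x 2m tiles), individually rescaled to \[0, 1\] with a
#' one-pixel separator.  `writeDictionaryMosaicPNG` writes it as a
#' grayscale PNG when the `png` package is available.
#'
#' @param dict a [PatchDictionary-class].
#' @param nTileCol tiles per mosaic row (default: near-square layout).
#' @return numeric matrix in \[0, 1\].
#' @export
dictionaryMosaic <- function(dict, nTileCol = ceiling(sqrt(nrow(dict@atoms)))) {
  K <- nrow(dict@atoms); m <- dict@m; C <- dict@channels
  th <- m * C; tw <- m
  nRow <- ceiling(K / nTileCol)
  out <- matrix(1, nRow * (th + 1) + 1, nTileCol * (tw + 1) + 1)
  for (k in seq_len(K)) {
    a <- dict@atoms[k, ]
    tile <- do.call(rbind, lapply(seq_len(C), function(ch)
      matrix(a[(ch - 1) * m^2 + seq_len(m^2)], m, m)))
    rng <- range(tile)
    if (diff(rng) > 0) tile <- (tile - rng[1]) / diff(rng) else tile <- tile * 0 + 0.5
    r0 <- ((k - 1) %/% nTileCol) * (th + 1) + 1
    c0 <- ((k - 1) %% nTileCol) * (tw + 1) + 1
    out[r0 + seq_len(th), c0 + seq_len(tw)] <- tile
  }
  out
}

#' @rdname dictionaryMosaic
#' @param path PNG file path.
#' @export
writeDictionaryMosaicPNG <- function(dict, path, nTileCol = ceiling(sqrt(nrow(dict@atoms)))) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  png::writePNG(dictionaryMosaic(dict, nTileCol), path)
  invisible(path)
}
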