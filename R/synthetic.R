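# circular Gaussian blur via FFT (periodic); sigma in pixels
.fftBlur <- function(x, sigma) {
  n <- nrow(x)
  d <- c(0:(n %/% 2), (n - n %/% 2 - 1):1)[seq_len(n)]
  g <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / n^2
}

.norm01 <- function(x) {
  r <- range(x)
  if (diff(r) < 1e-12) return(x * 0)
  (x - r[1]) / diff(r)
}

#' Generate a textured synthetic phantom
#'
#' Deterministic (seeded) phantoms for few-view reconstruction studies.
#' The default `"textured"` kind sums a smooth random low-frequency
#' background, a few soft-edged ellipses, fine oriented line textures and a
#' mild linear shading, clipped to \[0, 1\] -- deliberately not piecewise
#' constant, because piecewise-constant phantoms favor gradient-sparsity
#' priors and do not resemble the soft-tissue images the patch prior
#' targets.  `"blob"` is a single smooth Gaussian bump (band-limited, handy
#' for projector self-consistency checks) and `"lines"` is pure oriented
#' texture.
#'
#' With `fovMask = TRUE` the phantom is attenuated outside the inscribed
#' circle with a soft (2 px) roll-off, the standard assumption that the
#' object fits inside the scanner field of view; benchmark acquisitions
#' use a detector that spans the image side, so the mask keeps all object
#' mass measurable.
#'
#' @param side image side in pixels (>= 32).
#' @param seed integer seed; output is bitwise reproducible per seed.
#' @param kind `"textured"`, `"blob"` or `"lines"`.
#' @param fovMask confine the phantom to the inscribed circle.
#' @return side x side matrix with values in \[0, 1\].
#' @export
generatePhantom <- function(side, seed = 1L, kind = c("textured", "blob", "lines"),
                            fovMask = FALSE) {
  kind <- match.arg(kind)
  if (side < 32L) stop("phantom side must be >= 32")
  mask <- if (fovMask) {
    ctr <- (side + 1) / 2
    rr <- sqrt(outer(seq_len(side) - ctr, seq_len(side) - ctr,
                     function(y, x) y^2 + x^2))
    1 / (1 + exp((rr - 0.47 * side) / 2))
  } else 1
  if (kind == "blob") {
    ctr <- (side + 1) / 2
    r2 <- outer(seq_len(side) - ctr, seq_len(side) - ctr,
                function(y, x) y^2 + x^2)
    return(exp(-r2 / (2 * (side / 6)^2)) * mask)
  }
  withr::with_seed(seed, {
    yy <- matrix(rep(seq_len(side), side), side)         # row = y
    xx <- t(yy)                                          # col = x
    base <- .norm01(0.3 * .fftBlur(matrix(stats::runif(side^2), side), side / 10) +
                    .fftBlur(matrix(stats::runif(side^2), side), side / 28) * 2.2)
    tex <- matrix(0, side, side)
    nL <- sample(2:4, 1)
    for (i in seq_len(nL)) {
      th <- stats::runif(1, 0, pi)
      wl <- stats::runif(1, 3, 8)
      ph <- stats::runif(1, 0, 2 * pi)
      cy <- stats::runif(1, 0.2, 0.8) * side
      cx <- stats::runif(1, 0.2, 0.8) * side
      win <- exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * (side / 5)^2))
      tex <- tex + 0.08 * win * sin(2 * pi * (cos(th) * xx + sin(th) * yy) / wl + ph)
    }
    if (kind == "lines") return(pmin(pmax(0.5 + 4 * tex, 0), 1) * mask)
    ell <- matrix(0, side, side)
    nE <- sample(5:8, 1)
    for (i in seq_len(nE)) {
      cy <- stats::runif(1, 0.15, 0.85) * side
      cx <- stats::runif(1, 0.15, 0.85) * side
      ay <- stats::runif(1, side / 20, side / 6)
      ax <- stats::runif(1, side / 20, side / 6)
      th <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, -0.18, 0.22)
      u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
      v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
      d <- sqrt((u / ax)^2 + (v / ay)^2)
      ell <- ell + amp / (1 + exp((d - 1) / 0.08))
    }
    shade <- (stats::runif(1, -0.04, 0.04) * xx + stats::runif(1, -0.04, 0.04) * yy) / side
    pmin(pmax(0.15 + 0.5 * base + ell + tex + shade, 0), 1) * mask
  })
}

#' Generate a training image disjoint from a reconstruction target
#'
#' Same phantom family, different seed: the dictionary is always learnt
#' from a different image than the one reconstructed.  Passing the
#' target's seed as `phantomSeed` enforces the disjointness structurally
#' (a seed collision is an error); pixel-level correlation between
#' training image and target stays low by construction of the seeded
#' random fields.
#'
#' @inheritParams generatePhantom
#' @param phantomSeed seed of the reconstruction target, if known.
#' @return side x side matrix in \[0, 1\].
#' @export
generateTrainingImage <- function(side, seed = 2L, phantomSeed = NULL,
                                  kind = "textured") {
  if (!is.null(phantomSeed) && identical(as.integer(seed), as.integer(phantomSeed)))
    stop("training-image seed must differ from the reconstruction target's seed")
  generatePhantom(side, seed = seed, kind = kind)
}

#' Add scaled Poisson noise to a sinogram
#'
#' Photon-counting noise model anchored to the maximum sinogram value:
#' with `g = f^2 * max(sino)`, each sample `s` is replaced by
#' `g * Poisson(s / g)`, so the standard deviation at the maximum-valued
#' bin equals `f * max(sino)` -- a relative noise level `f` at the maximum.
#' `f = 0` returns the input unchanged.
#'
#' @param sino a [Sinogram-class] with non-negative values.
#' @param fraction relative noise level `f` (e.g. 0.003 for 0.3%).
#' @param seed integer seed.
#' @return a [Sinogram-class] with non-negative noisy values.
#' @export
addPoissonNoise <- function(sino, fraction, seed = 1L) {
  stopifnot(is(sino, "Sinogram"))
  if (fraction < 0) stop("fraction must be >= 0")
  v <- sino@values
  if (any(v < 0)) stop("Poisson noise requires a non-negative sinogram")
  if (fraction == 0) return(sino)
  g <- fraction^2 * max(v)
  if (g == 0) return(sino)
  noisy <- withr::with_seed(seed, g * stats::rpois(length(v), v / g))
  sinogram(matrix(noisy, nrow(v), ncol(v)), sino@geometry)
}

#' Phantom plus its Sobel-gradient ground truth
#'
#' Generates a scalar phantom and the two-channel gradient image
#' (`sobelGradient`) that serves as vectorial ground truth in differential
#' phase-contrast experiments.
#'
#' @inheritParams generatePhantom
#' @return list with `image` (matrix) and `gradients`
#'   (side x side x 2 array).
#' @export
makeVectorPhantom <- function(side, seed = 1L, kind = "textured",
                              fovMask = FALSE) {
  img <- generatePhantom(side, seed = seed, kind = kind, fovMask = fovMask)
  list(image = img, gradients = sobelGradient(img))
}

#' Seeded benchmark experiment bundles
#'
#' Fully parameterized experiment definitions mirroring the three few-view
#' protocols studied here, at a 128 px working scale:
#' \describe{
#'   \item{`lena80`}{textured phantom projected at 80 uniformly spaced
#'     angles in \[0, 180) -- far below the ~201-view angular-sampling bound
#'     for this grid -- no noise.}
#'   \item{`lena80_noisy`}{same, plus Poisson noise with standard deviation
#'     0.3% of the maximal sinogram value.}
#'   \item{`dpc200`}{differential phase-contrast protocol: a 200-view dense
#'     scan of the gradient ground truth, of which every 5th view (40
#'     views) is used for reconstruction with a vectorial dictionary.}
#' }
#' Seeds, dictionary parameters (m = 8, K = 100, T0 = 5, 5 K-SVD sweeps,
#' training-lattice step 4), the reconstruction lattice step (4) and the
#' scan-selected regularization defaults are frozen in the bundle so
#' experiments are reproducible end to end.
#'
#' @param name one of `"lena80"`, `"lena80_noisy"`, `"dpc200"`.
#' @param side working image side (default 128).
#' @return a named list bundle: phantom/training images (or vector ground
#'   truth), geometry, noise fraction, dictionary and solver parameters.
#' @export
benchmarkCase <- function(name = c("lena80", "lena80_noisy", "dpc200"),
                          side = 128L) {
  name <- match.arg(name)
  side <- as.integer(side)
  phantomSeed <- 101L; trainSeed <- 202L
  dictParams <- list(m = 8L, K = 100L, T0 = 5L, nIter = 5L, trainStep = 4L,
                     seed = 7L)
  latticeStep <- 4L
  if (name %in% c("lena80", "lena80_noisy")) {
    phantom <- generatePhantom(side, seed = phantomSeed, fovMask = TRUE)
    training <- generateTrainingImage(side, seed = trainSeed,
                                      phantomSeed = phantomSeed)
    geom <- projectionGeometry(side, nAngles = 80L, nDet = side)
    list(name = name,
         phantom = phantom, training = training, geometry = geom,
         noiseFraction = if (name == "lena80_noisy") 0.003 else 0,
         noiseSeed = 31L,
         dictParams = dictParams, latticeStep = latticeStep,
         solver = solverParams(lambda = 0.5, omega = 5, nIter = 1000L,
                               seed = 11L, mode = "tomography"),
         scanLambda = c(0.5, 4, 16), scanOmega = c(5, 50, 500))
  } else {
    vp <- makeVectorPhantom(side, seed = phantomSeed, fovMask = TRUE)
    training <- generateTrainingImage(side, seed = trainSeed,
                                      phantomSeed = phantomSeed)
    denseGeom <- projectionGeometry(side, nAngles = 200L, nDet = side)
    keep <- seq(1L, 200L, by = 5L)
    fewGeom <- projectionGeometry(side, angles = angles(denseGeom)[keep],
                                  nDet = side)
    list(name = name,
         phantom = vp$image, gradients = vp$gradients, training = training,
         denseGeometry = denseGeom, geometry = fewGeom, keptViews = keep,
         noiseFraction = 0, noiseSeed = 31L,
         dictParams = dictParams, latticeStep = latticeStep,
         solver = solverParams(lambda = 1, omega = 5, nIter = 3000L,
                               seed = 11L, mode = "tomography"))
  }
}

#' Train the dictionary a benchmark bundle prescribes
#'
#' Convenience wrapper: builds the training set from the bundle's training
#' image (Sobel-gradient vectorial patches for the DPC case) and runs
#' [ksvdTrain()] with the bundle's frozen dictionary parameters.
#'
#' @param bundle a [benchmarkCase()] bundle.
#' @return a [PatchDictionary-class].
#' @export
trainBenchmarkDictionary <- function(bundle) {
  dp <- bundle$dictParams
  vectorial <- bundle$name == "dpc200"
  X <- buildTrainingSet(bundle$training, m = dp$m, s = dp$trainStep,
                        vectorial = vectorial)
  ksvdTrain(X, K = dp$K, T0 = dp$T0, nIter = dp$nIter, seed = dp$seed,
            m = dp$m, channels = if (vectorial) 2L else 1L)
}
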