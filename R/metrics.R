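# separable valid-mode correlation with a 1-D kernel g (applied both axes)
.convValidSep <- function(x, g) {
  w <- length(g)
  n1 <- nrow(x); n2 <- ncol(x)
  out <- matrix(0, n1 - w + 1L, n2)
  for (i in seq_len(w)) out <- out + g[i] * x[i:(n1 - w + i), , drop = FALSE]
  out2 <- matrix(0, n1 - w + 1L, n2 - w + 1L)
  for (i in seq_len(w)) out2 <- out2 + g[i] * out[, i:(n2 - w + i), drop = FALSE]
  out2
}

.ssimKernel <- function(windowSize = 11L, sigma = 1.5) {
  h <- (windowSize - 1) / 2
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  g / sum(g)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5) and stability
#' constants `K1 = 0.01`, `K2 = 0.03` -- the reference defaults.  Local
#' statistics are computed on valid windows only (the `(window-1)/2` border
#' is excluded from the mean).  Equals 1 exactly when the images are
#' identical.
#'
#' @param a,b images of identical dimensions.
#' @param dataRange dynamic range `L`; inferred from the range of `b` (the
#'   reference) when omitted.
#' @param windowSize,sigma Gaussian window parameters.
#' @param K1,K2 stability constants.
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(a, b, dataRange = NULL, windowSize = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  if (!all(dim(a) == dim(b))) stop("images must have identical dimensions")
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(dataRange)) dataRange <- diff(range(b))
  if (dataRange <= 0) dataRange <- 1
  g <- .ssimKernel(windowSize, sigma)
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  mu1 <- .convValidSep(a, g); mu2 <- .convValidSep(b, g)
  s11 <- .convValidSep(a * a, g) - mu1^2
  s22 <- .convValidSep(b * b, g) - mu2^2
  s12 <- .convValidSep(a * b, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Improvement factor over filtered backprojection
#'
#' Normalized SSIM gain of an iterative reconstruction over the FBP
#' baseline on the same data:
#' `Q = (ssim(rec, exact) - ssim(fbp, exact)) / (1 - ssim(fbp, exact))`.
#' `Q = 0` means no improvement over FBP, `Q = 1` exact recovery; the
#' ordering of Q across methods, not its absolute value, is the meaningful
#' comparison.
#'
#' @param rec reconstruction under evaluation.
#' @param fbpRec the FBP reconstruction of the same data.
#' @param exact ground-truth image.
#' @param dataRange dynamic range forwarded to [ssim()].
#' @return scalar Q.
#' @export
improvementFactor <- function(rec, fbpRec, exact, dataRange = NULL) {
  sR <- ssim(rec, exact, dataRange)
  sF <- ssim(fbpRec, exact, dataRange)
  if (1 - sF < 1e-12) return(0)
  (sR - sF) / (1 - sF)
}

#' Regularization-parameter scan
#'
#' Runs one overlap-functional reconstruction per `(lambda, omega)` grid
#' point and scores each against the ground truth with [ssim()] and the
#' improvement factor Q over the supplied FBP baseline; the best grid
#' point (argmax Q) is reported.  Deterministic given the seed in
#' `params`.
#'
#' @param data sinogram (or image) data as in [fistaSolve()].
#' @param dict,lat,core dictionary, lattice, core map.
#' @param lambdaGrid,omegaGrid numeric vectors spanning the scan grid.
#' @param exact ground-truth image.
#' @param fbpRec FBP reconstruction used as the Q baseline.
#' @param params base [SolverParams-class]; lambda/omega are overwritten
#'   per grid point.
#' @param geom geometry for bare-array data.
#' @return `data.frame` with columns lambda, omega, ssim, q, and attribute
#'   `"best"` holding the index of the best row.
#' @export
parameterScan <- function(data, dict, lat, core, lambdaGrid, omegaGrid,
                          exact, fbpRec, params, geom = NULL) {
  grid <- expand.grid(lambda = lambdaGrid, omega = omegaGrid,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty parameter grid")
  dr <- diff(range(exact))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p@lambda <- grid$lambda[i]
    p@omega <- grid$omega[i]
    tr <- fistaSolve(data, dict, lat, core, p, geom = geom)
    s <- ssim(solution(tr), exact, dr)
    q <- improvementFactor(solution(tr), fbpRec, exact, dr)
    c(ssim = s, q = q)
  })
  res <- do.call(rbind, res)
  out <- data.frame(lambda = grid$lambda, omega = grid$omega,
                    ssim = res[, "ssim"], q = res[, "q"])
  attr(out, "best") <- which.max(out$q)
  out
}
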