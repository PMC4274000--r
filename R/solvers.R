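#' Solver parameter constructor
#'
#' @param lambda l1 sparsity weight (>= 0).
#' @param omega overlap-similarity weight (>= 0).
#' @param nIter iteration budget.
#' @param tau gradient step; 0 selects 0.9/L automatically with L from
#'   power iteration.
#' @param seed seed for randomized initializations (power iteration).
#' @param mode "tomography" (data are sinograms) or "denoising"
#'   (the forward operator is the identity).
#' @param tol relative objective-change early exit (0 disables).
#' @return a [SolverParams-class].
#' @export
solverParams <- function(lambda = 0.1, omega = 1, nIter = 100L, tau = 0,
                         seed = 1L, mode = c("tomography", "denoising"),
                         tol = 0) {
  mode <- match.arg(mode)
  new("SolverParams", lambda = as.numeric(lambda), omega = as.numeric(omega),
      nIter = as.integer(nIter), tau = as.numeric(tau),
      seed = as.integer(seed), mode = mode, tol = as.numeric(tol))
}

#' Soft-thresholding (shrinkage) operator
#'
#' `sign(v) * max(|v| - t, 0)`, elementwise: the exact proximal operator of
#' `t * ||.||_1`, i.e. the minimizer of `t |u| + (u - v)^2 / 2`.
#'
#' @param v numeric scalar, vector or array.
#' @param t non-negative threshold.
#' @return same shape as `v`.
#' @export
shrinkage <- function(v, t) {
  if (!is.finite(t) || t < 0) stop("shrinkage threshold must be >= 0")
  sign(v) * pmax(abs(v) - t, 0)
}

#' Largest squared singular value of an operator pair by power iteration
#'
#' Estimates `||A||^2`, the largest eigenvalue of `t(A) A`, for a matched
#' linear operator/adjoint pair given as functions.  This is the quantity
#' from which the Lipschitz constant of the smooth gradient is formed (the
#' gradient of `||A x - b||^2` has Lipschitz constant `2 ||A||^2`).
#'
#' @param forward function mapping an input array to the operator output.
#' @param adjoint its exact adjoint.
#' @param shape dimensions of the operator input.
#' @param nIter power iterations (default 50).
#' @param seed seed for the random start vector.
#' @return the estimate of `||A||^2`; 0 with a warning for a zero operator.
#' @export
lipschitzPower <- function(forward, adjoint, shape, nIter = 50L, seed = 1L) {
  x <- withr::with_seed(seed, array(stats::rnorm(prod(shape)), dim = shape))
  nx <- sqrt(sum(x^2))
  x <- x / nx
  lam <- 0
  for (i in seq_len(nIter)) {
    y <- adjoint(forward(x))
    ny <- sqrt(sum(y^2))
    if (ny < 1e-30) {
      warning("operator appears to be zero; returning 0")
      return(0)
    }
    lam <- sum(x * y)                   # Rayleigh quotient, ||x|| = 1
    x <- y / ny
  }
  lam
}

# ---- overlap functional --------------------------------------------------

# Normalize `data` to a (na x nd x C) or (side x side x C) array and return
# list(arr, A, geom). A = NULL means the identity operator (denoising).
.solverData <- function(data, dict, lat, params, geom) {
  C <- dict@channels
  if (is(data, "Sinogram")) {
    geom <- data@geometry
    arr <- array(data@values, c(dim(data@values), 1L))
  } else if (is.matrix(data)) {
    arr <- array(data, c(dim(data), 1L))
  } else if (is.array(data) && length(dim(data)) == 3L) {
    arr <- data
  } else stop("data must be a Sinogram, a matrix or a 3-d array")
  if (dim(arr)[3] != C) stop("data channel count does not match the dictionary")
  if (params@mode == "tomography") {
    if (is.null(geom)) stop("tomography mode needs a ProjectionGeometry (or Sinogram data)")
    if (geom@imageSide != lat@imageSide) stop("geometry and lattice image sides differ")
    if (!all(dim(arr)[1:2] == c(length(geom@angles), geom@nDet)))
      stop("data dimensions do not match the geometry")
    list(arr = arr, A = projectionOperator(geom), geom = geom)
  } else {
    if (!all(dim(arr)[1:2] == lat@imageSide))
      stop("denoising data must be image-shaped")
    list(arr = arr, A = NULL, geom = NULL)
  }
}

# smooth part of the overlap functional and its gradient machinery
.overlapPieces <- function(coeffs, sd, dict, lat, core, omega) {
  U <- .composeAll(coeffs, dict)
  C <- dict@channels; side <- lat@imageSide
  sol <- composeSolution(coeffs, lat, core, dict)
  solArr <- if (C == 1L) array(sol, c(side, side, 1L)) else sol
  fid <- 0
  fidResid <- vector("list", C)
  for (ch in seq_len(C)) {
    iv <- as.vector(solArr[, , ch])
    pv <- if (is.null(sd$A)) iv else as.numeric(sd$A %*% iv)
    rs <- pv - as.vector(sd$arr[, , ch])
    fid <- fid + sum(rs^2)
    fidResid[[ch]] <- rs
  }
  Rstack <- U - extractPatches(if (C == 1L) solArr[, , 1L] else solArr, lat)
  list(U = U, solArr = solArr, fid = fid, fidResid = fidResid,
       Rstack = Rstack, overlap = sum(Rstack^2))
}

#' Overlap-functional objective
#'
#' The convex objective of the overlapping-patch reconstruction:
#' fidelity `||P(compose(w)) - d||^2` (P is the projector in tomography
#' mode and the identity in denoising mode), plus `omega` times the squared
#' sum of the overlap residuals (the similarity term pushing all patches
#' covering a pixel towards the composed solution), plus `lambda * sum|w|`.
#'
#' @param coeffs nPatches x K coefficient matrix.
#' @param data a [Sinogram-class] (tomography), an image matrix
#'   (denoising), or a 3-d array for vectorial problems.
#' @param dict,lat,core dictionary, lattice and core map.
#' @param params a [SolverParams-class] (lambda, omega, mode).
#' @param geom geometry when `data` is a bare array in tomography mode.
#' @return scalar objective value.
#' @export
objectiveOverlap <- function(coeffs, data, dict, lat, core, params, geom = NULL) {
  .checkCoeffs(coeffs, lat, dict)
  sd <- .solverData(data, dict, lat, params, geom)
  pc <- .overlapPieces(coeffs, sd, dict, lat, core, params@omega)
  pc$fid + params@omega * pc$overlap + params@lambda * sum(abs(coeffs))
}

#' Gradient of the smooth part of the overlap functional
#'
#' The gradient of fidelity + similarity terms with respect to the patch
#' coefficients (the l1 term is handled by [shrinkage()]).  One forward
#' projection of the composed solution and one backprojection of the
#' fidelity residual are performed per evaluation, plus the patch-space
#' overlap correction.
#'
#' @inheritParams objectiveOverlap
#' @return nPatches x K gradient matrix.
#' @export
gradientOverlap <- function(coeffs, data, dict, lat, core, params, geom = NULL) {
  .checkCoeffs(coeffs, lat, dict)
  sd <- .solverData(data, dict, lat, params, geom)
  .gradientOverlap(coeffs, sd, dict, lat, core, params@omega)
}

.gradientOverlap <- function(coeffs, sd, dict, lat, core, omega) {
  pc <- .overlapPieces(coeffs, sd, dict, lat, core, omega)
  C <- dict@channels; side <- lat@imageSide
  g1img <- array(0, c(side, side, C))
  for (ch in seq_len(C)) {
    rs <- pc$fidResid[[ch]]
    bp <- if (is.null(sd$A)) rs else as.numeric(Matrix::crossprod(sd$A, rs))
    g1img[, , ch] <- matrix(bp, side, side)
  }
  g1U <- .coreScatter(if (C == 1L) g1img[, , 1L] else g1img, core)
  oa <- .overlapAdd(pc$Rstack, lat)
  g2U <- pc$Rstack - .coreScatter(if (C == 1L) oa else oa, core)
  2 * tcrossprod(g1U + omega * g2U, dict@atoms)
}

# Lipschitz constant of the smooth overlap gradient: 2 * lambda_max of the
# composite PSD map  w -> St Pt P S w + omega Bt B w
.lipOverlap <- function(sd, dict, lat, core, omega, seed, nIter = 50L) {
  zeroData <- sd
  zeroData$arr <- array(0, dim(sd$arr))
  H <- function(W) .gradientOverlap(W, zeroData, dict, lat, core, omega) / 2
  P <- nrow(lat@corners); K <- nrow(dict@atoms)
  lam <- lipschitzPower(function(W) W, function(W) H(W), c(P, K),
                        nIter = nIter, seed = seed)
  2 * max(lam, 1e-30)
}

#' FISTA minimization of the overlap functional
#'
#' Proximal-gradient iteration with Beck-Teboulle momentum on the patch
#' coefficients: `x_{k+1} = shrinkage(y_k - tau * grad(y_k), tau * lambda)`.
#' Coefficients start at zero; the step defaults to `0.9 / L` with
#' `L = 2 lambda_max` of the smooth quadratic form estimated by power
#' iteration.  The objective at every iterate is recorded (the trace starts
#' at the initial point).  Stops at `nIter` or when the relative objective
#' change falls below `tol`; errors out, pointing at `tau`, if the
#' objective exceeds 1000x its initial value.
#'
#' @inheritParams objectiveOverlap
#' @return a [SolverTrace-class]; `solution(trace)` is the composed image
#'   (or side x side x 2 array for vectorial dictionaries).
#' @export
fistaSolve <- function(data, dict, lat, core, params, geom = NULL) {
  sd <- .solverData(data, dict, lat, params, geom)
  P <- nrow(lat@corners); K <- nrow(dict@atoms)
  tau <- params@tau
  if (tau <= 0) tau <- 0.9 / .lipOverlap(sd, dict, lat, core, params@omega, params@seed)
  objFun <- function(W) {
    pc <- .overlapPieces(W, sd, dict, lat, core, params@omega)
    pc$fid + params@omega * pc$overlap + params@lambda * sum(abs(W))
  }
  x <- matrix(0, P, K)
  y <- x
  tmom <- 1
  obj <- numeric(params@nIter + 1L)
  obj[1] <- objFun(x)
  ran <- 0L
  for (k in seq_len(params@nIter)) {
    g <- .gradientOverlap(y, sd, dict, lat, core, params@omega)
    xNew <- shrinkage(y - tau * g, tau * params@lambda)
    tNew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    y <- xNew + ((tmom - 1) / tNew) * (xNew - x)
    x <- xNew
    tmom <- tNew
    ran <- k
    obj[k + 1L] <- objFun(x)
    if (!is.finite(obj[k + 1L]) || obj[k + 1L] > 1e3 * max(obj[1], 1e-300))
      stop("FISTA diverged: objective exploded; decrease the step tau")
    if (params@tol > 0 && k > 1L) {
      rel <- abs(obj[k + 1L] - obj[k]) / max(abs(obj[1]), 1e-300)
      if (rel < params@tol) break
    }
  }
  new("SolverTrace", objective = obj[seq_len(ran + 1L)], coefficients = x,
      solution = composeSolution(x, lat, core, dict),
      iterations = as.integer(ran), extra = list(tau = tau))
}

#' Dictionary denoising convenience wrapper
#'
#' Runs [fistaSolve()] with the identity forward operator on a noisy image
#' and returns the composed solution.
#'
#' @param img noisy square image matrix.
#' @param dict,lat,core dictionary, lattice, core map.
#' @param params a [SolverParams-class]; its mode is forced to denoising.
#' @return the denoised image matrix.
#' @export
denoiseImage <- function(img, dict, lat, core, params) {
  params@mode <- "denoising"
  solution(fistaSolve(img, dict, lat, core, params))
}

# ---- floating-solution functional ---------------------------------------

#' Floating-solution objective
#'
#' The comparison functional in which the global image is a free variable
#' rather than a function of the coefficients: fidelity on the free image,
#' plus `omega` times the coupling `sum_p sum_x chi_p(x) (u_p(x) - I(x))^2`
#' between the free image and the per-patch compositions over the full
#' patch supports, plus the l1 penalty on the coefficients.
#'
#' @param coeffs nPatches x K coefficient matrix.
#' @param freeImage the free global image (matrix, or side x side x C
#'   array).
#' @inheritParams objectiveOverlap
#' @return scalar objective value.
#' @export
objectiveFloating <- function(coeffs, freeImage, data, dict, lat, params,
                              geom = NULL) {
  if (nrow(coeffs) != nrow(lat@corners) || ncol(coeffs) != nrow(dict@atoms))
    stop("coefficient dimensions do not match lattice/dictionary")
  sd <- .solverData(data, dict, lat, params, geom)
  C <- dict@channels; side <- lat@imageSide
  Iarr <- if (is.matrix(freeImage)) array(freeImage, c(side, side, 1L)) else freeImage
  if (!all(dim(Iarr) == c(side, side, C))) stop("freeImage shape mismatch")
  fid <- 0
  for (ch in seq_len(C)) {
    iv <- as.vector(Iarr[, , ch])
    pv <- if (is.null(sd$A)) iv else as.numeric(sd$A %*% iv)
    fid <- fid + sum((pv - as.vector(sd$arr[, , ch]))^2)
  }
  U <- .composeAll(coeffs, dict)
  Rstack <- U - extractPatches(if (C == 1L) Iarr[, , 1L] else Iarr, lat)
  fid + params@omega * sum(Rstack^2) + params@lambda * sum(abs(coeffs))
}

#' FISTA minimization of the floating-solution functional
#'
#' Joint FISTA on `(coefficients, free image)`: the smooth gradient is
#' taken in both blocks, shrinkage is applied to the coefficient block
#' only, and the recorded trace is comparable iteration-by-iteration with
#' [fistaSolve()] traces.
#'
#' @inheritParams fistaSolve
#' @return a [SolverTrace-class]; `solution(trace)` is the free image and
#'   `x@extra$composed` the core-composed image from the coefficients.
#' @export
fistaSolveFloating <- function(data, dict, lat, core, params, geom = NULL) {
  sd <- .solverData(data, dict, lat, params, geom)
  P <- nrow(lat@corners); K <- nrow(dict@atoms)
  C <- dict@channels; side <- lat@imageSide
  omega <- params@omega
  # half-gradient of the smooth part, as one list(W, I)
  halfGrad <- function(W, Iarr, dataArr) {
    U <- .composeAll(W, dict)
    Rstack <- U - extractPatches(if (C == 1L) Iarr[, , 1L] else Iarr, lat)
    gW <- omega * tcrossprod(Rstack, dict@atoms)
    gI <- array(0, c(side, side, C))
    oa <- .overlapAdd(Rstack, lat)
    oaArr <- if (C == 1L) array(oa, c(side, side, 1L)) else oa
    for (ch in seq_len(C)) {
      iv <- as.vector(Iarr[, , ch])
      if (is.null(sd$A)) {
        bp <- iv - as.vector(dataArr[, , ch])
      } else {
        rs <- as.numeric(sd$A %*% iv) - as.vector(dataArr[, , ch])
        bp <- as.numeric(Matrix::crossprod(sd$A, rs))
      }
      gI[, , ch] <- matrix(bp, side, side) - omega * oaArr[, , ch]
    }
    list(W = gW, I = gI)
  }
  zeros <- array(0, dim(sd$arr))
  tau <- params@tau
  if (tau <= 0) {
    x <- withr::with_seed(params@seed,
      list(W = matrix(stats::rnorm(P * K), P, K),
           I = array(stats::rnorm(side * side * C), c(side, side, C))))
    nx <- sqrt(sum(x$W^2) + sum(x$I^2))
    x$W <- x$W / nx; x$I <- x$I / nx
    lam <- 0
    for (i in 1:50) {
      y <- halfGrad(x$W, x$I, zeros)
      ny <- sqrt(sum(y$W^2) + sum(y$I^2))
      if (ny < 1e-30) break
      lam <- sum(x$W * y$W) + sum(x$I * y$I)
      x <- list(W = y$W / ny, I = y$I / ny)
    }
    tau <- 0.9 / (2 * max(lam, 1e-30))
  }
  objFun <- function(W, Iarr)
    objectiveFloating(W, if (C == 1L) Iarr[, , 1L] else Iarr,
                      data, dict, lat, params, geom)
  W <- matrix(0, P, K); Iarr <- array(0, c(side, side, C))
  yW <- W; yI <- Iarr
  tmom <- 1
  obj <- numeric(params@nIter + 1L)
  obj[1] <- objFun(W, Iarr)
  ran <- 0L
  for (k in seq_len(params@nIter)) {
    g <- halfGrad(yW, yI, sd$arr)
    WNew <- shrinkage(yW - tau * 2 * g$W, tau * params@lambda)
    INew <- yI - tau * 2 * g$I
    tNew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    yW <- WNew + ((tmom - 1) / tNew) * (WNew - W)
    yI <- INew + ((tmom - 1) / tNew) * (INew - Iarr)
    W <- WNew; Iarr <- INew
    tmom <- tNew
    ran <- k
    obj[k + 1L] <- objFun(W, Iarr)
    if (!is.finite(obj[k + 1L]) || obj[k + 1L] > 1e3 * max(obj[1], 1e-300))
      stop("FISTA diverged: objective exploded; decrease the step tau")
    if (params@tol > 0 && k > 1L) {
      rel <- abs(obj[k + 1L] - obj[k]) / max(abs(obj[1]), 1e-300)
      if (rel < params@tol) break
    }
  }
  sol <- if (C == 1L) Iarr[, , 1L] else Iarr
  new("SolverTrace", objective = obj[seq_len(ran + 1L)], coefficients = W,
      solution = sol, iterations = as.integer(ran),
      extra = list(tau = tau,
                   composed = composeSolution(W, lat, core, dict)))
}

# ---- total variation -----------------------------------------------------

.gradX <- function(u) cbind(u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE], 0)
.gradY <- function(u) rbind(u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE], 0)
.divPQ <- function(px, py) {
  n <- nrow(px)
  dx <- px - cbind(0, px[, -n, drop = FALSE])
  dx[, n] <- -px[, n - 1]
  dy <- py - rbind(0, py[-n, , drop = FALSE])
  dy[n, ] <- -py[n - 1, ]
  dx + dy
}

#' Isotropic total variation of an image
#'
#' `sum over pixels of sqrt(dxI^2 + dyI^2)` with forward differences and
#' replicate boundary.
#'
#' @param u image matrix.
#' @return scalar TV value.
#' @export
totalVariation <- function(u) sum(sqrt(.gradX(u)^2 + .gradY(u)^2))

# Chambolle dual iteration for  argmin ||u - z||^2 / 2 + gamma TV(u)
.tvProx <- function(z, gamma, nInner = 40L, stepDual = 0.125) {
  if (gamma <= 0) return(z)
  px <- matrix(0, nrow(z), ncol(z)); py <- px
  for (i in seq_len(nInner)) {
    u <- .divPQ(px, py) - z / gamma
    gx <- .gradX(u); gy <- .gradY(u)
    den <- 1 + stepDual * sqrt(gx^2 + gy^2)
    px <- (px + stepDual * gx) / den
    py <- (py + stepDual * gy) / den
  }
  z - gamma * .divPQ(px, py)
}

#' Total-variation penalized reconstruction
#'
#' Minimizes `||P I - d||^2 + mu TV_iso(I)` by FISTA, with the TV proximal
#' step computed by an inner Chambolle-type dual iteration.  `geom = NULL`
#' makes the forward operator the identity (TV denoising).
#'
#' @param data a [Sinogram-class], or an image matrix when `geom` is NULL.
#' @param geom a [ProjectionGeometry-class] or NULL.
#' @param mu TV weight (>= 0).
#' @param nIter outer FISTA iterations.
#' @param nInner Chambolle dual iterations per proximal step.
#' @return the reconstructed image matrix.
#' @export
tvSolve <- function(data, geom = NULL, mu = 1, nIter = 100L, nInner = 40L) {
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0")
  if (is(data, "Sinogram")) {
    geom <- data@geometry
    d <- as.vector(data@values)
    A <- projectionOperator(geom)
    side <- geom@imageSide
    L <- 2 * lipschitzPower(function(x) as.numeric(A %*% as.vector(x)),
                            function(y) matrix(as.numeric(Matrix::crossprod(A, y)), side, side),
                            c(side, side), nIter = 30L)
  } else {
    if (!is.null(geom)) stop("matrix data implies the identity operator; drop geom")
    .checkImage(data)
    d <- as.vector(data)
    A <- NULL
    side <- nrow(data)
    L <- 2
  }
  tau <- 0.9 / L
  x <- matrix(0, side, side); y <- x; tmom <- 1
  objFun <- function(u) {
    pv <- if (is.null(A)) as.vector(u) else as.numeric(A %*% as.vector(u))
    sum((pv - d)^2) + mu * totalVariation(u)
  }
  objPrev <- objFun(x)
  obj0 <- objPrev
  for (k in seq_len(nIter)) {
    if (is.null(A)) {
      g <- 2 * (y - matrix(d, side, side))
    } else {
      rs <- as.numeric(A %*% as.vector(y)) - d
      g <- 2 * matrix(as.numeric(Matrix::crossprod(A, rs)), side, side)
    }
    xNew <- .tvProx(y - tau * g, tau * mu, nInner = nInner)
    tNew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    y <- xNew + ((tmom - 1) / tNew) * (xNew - x)
    x <- xNew
    tmom <- tNew
    ob <- objFun(x)
    if (!is.finite(ob) || ob > 1e3 * max(obj0, 1e-300))
      stop("TV-FISTA diverged: objective exploded; decrease the step")
  }
  x
}
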