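#' Construct a parallel-beam acquisition geometry
#'
#' Angles default to `nAngles` uniformly spaced views in \[0, 180) degrees,
#' the acquisition layout of the few-view protocols reproduced here.  The
#' detector defaults to `ceiling(sqrt(2) * imageSide)` bins so that every
#' pixel of the square grid, corners included, projects inside the detector
#' at every angle (no mass is clipped).
#'
#' @param imageSide side of the square reconstruction grid, pixels.
#' @param nAngles number of uniformly spaced views (ignored when `angles`
#'   is given).
#' @param angles explicit view angles in degrees, strictly increasing in
#'   \[0, 180).
#' @param nDet number of detector bins (bin width = pixel width).
#' @param pixelSize pixel pitch in length units.
#' @return a [ProjectionGeometry-class].
#' @examples
#' projectionGeometry(64, nAngles = 80)
#' @export
projectionGeometry <- function(imageSide, nAngles = NULL, angles = NULL,
                               nDet = NULL, pixelSize = 1) {
  if (is.null(angles)) {
    if (is.null(nAngles)) stop("supply either nAngles or angles")
    angles <- seq(0, 180, length.out = nAngles + 1L)[seq_len(nAngles)]
  }
  if (is.null(nDet)) nDet <- ceiling(sqrt(2) * imageSide)
  new("ProjectionGeometry", angles = as.numeric(angles),
      nDet = as.integer(nDet), imageSide = as.integer(imageSide),
      pixelSize = as.numeric(pixelSize))
}

#' Wrap a matrix as a Sinogram
#'
#' @param values nAngles x nDet numeric matrix of line integrals.
#' @param geom the [ProjectionGeometry-class] the values belong to.
#' @return a [Sinogram-class].
#' @export
sinogram <- function(values, geom) {
  new("Sinogram", values = as.matrix(values), geometry = geom)
}

.geomKey <- function(geom) {
  paste(geom@imageSide, geom@nDet, geom@pixelSize,
        paste(signif(geom@angles, 12), collapse = ","), sep = "|")
}

.projCache <- new.env(parent = emptyenv())

#' System matrix of the parallel-beam projector
#'
#' Builds (and caches per geometry) the sparse matrix of a pixel-driven
#' footprint projector: each pixel center is projected onto the detector
#' axis `s = x cos(theta) + y sin(theta)` and its value is spread over the
#' nearby bins with a triangular kernel of half-width
#' `|cos(theta)| + |sin(theta)|` -- the trapezoid footprint of the square
#' pixel approximated by a triangle -- normalized per pixel and scaled by
#' the pixel pitch so rows approximate line integrals.  At 0 and 90
#' degrees this reduces to plain linear-interpolation splatting.  Because
#' each pixel's kernel weights are normalized to sum to one, every view
#' conserves the total image mass exactly (as long as no pixel projects
#' off the detector), and the exact algebraic adjoint is the matrix
#' transpose, which acts as an interpolating backprojector.
#'
#' @param geom a [ProjectionGeometry-class].
#' @return a `dgCMatrix` with `nAngles * nDet` rows (angle index fastest)
#'   and `imageSide^2` columns (column-major pixels).
#' @export
projectionOperator <- function(geom) {
  key <- .geomKey(geom)
  hit <- .projCache[[key]]
  if (!is.null(hit)) return(hit)
  side <- geom@imageSide; nd <- geom@nDet; na <- length(geom@angles)
  N <- side * side
  rr <- rep_len(seq_len(side), N)          # row = y, cycles fastest
  cc <- rep(seq_len(side), each = side)    # col = x
  xc <- cc - 0.5 - side / 2
  yc <- rr - 0.5 - side / 2
  th <- geom@angles * pi / 180
  ii <- vector("list", na); jj <- vector("list", na); xx <- vector("list", na)
  pix <- seq_len(N)
  for (a in seq_len(na)) {
    t <- xc * cos(th[a]) + yc * sin(th[a]) + nd / 2 + 0.5  # fractional 1-based bin
    w <- abs(cos(th[a])) + abs(sin(th[a]))   # pixel footprint width on detector
    k0 <- floor(t)
    iA <- list(); jA <- list(); xA <- list()
    wsum <- numeric(N)
    for (joff in -1:2) {
      k <- k0 + joff
      wt <- pmax(0, 1 - abs(t - k) / w)
      wsum <- wsum + wt
    }
    for (joff in -1:2) {
      k <- k0 + joff
      wt <- pmax(0, 1 - abs(t - k) / w) / wsum
      ok <- k >= 1 & k <= nd & wt > 0
      iA[[joff + 2]] <- (k[ok] - 1) * na + a
      jA[[joff + 2]] <- pix[ok]
      xA[[joff + 2]] <- wt[ok]
    }
    ii[[a]] <- unlist(iA); jj[[a]] <- unlist(jA); xx[[a]] <- unlist(xA)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(xx) * geom@pixelSize,
                            dims = c(na * nd, N))
  .projCache[[key]] <- A
  A
}

#' Clear the cached projector matrices
#' @return invisibly, the number of cached operators dropped.
#' @export
clearProjectorCache <- function() {
  n <- length(ls(.projCache))
  rm(list = ls(.projCache), envir = .projCache)
  invisible(n)
}

.checkImage <- function(img, side = NULL) {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop("image must be a square numeric matrix")
  if (any(!is.finite(img))) stop("image values must be finite")
  if (!is.null(side) && nrow(img) != side)
    stop(sprintf("image side %d does not match geometry side %d", nrow(img), side))
  invisible(TRUE)
}

#' Forward projection (discrete Radon transform)
#'
#' Applies the linear projector `P` of [projectionOperator()] to a square
#' image: every sinogram row is the discrete set of line integrals of the
#' image at that view angle.
#'
#' @param img square numeric matrix (rows = y, columns = x).
#' @param geom a [ProjectionGeometry-class] with matching `imageSide`.
#' @return a [Sinogram-class].
#' @export
forwardProject <- function(img, geom) {
  .checkImage(img, geom@imageSide)
  A <- projectionOperator(geom)
  v <- as.numeric(A %*% as.vector(img))
  sinogram(matrix(v, length(geom@angles), geom@nDet), geom)
}

#' Backprojection (exact adjoint of the forward projector)
#'
#' Applies the transpose of the same sparse system matrix, so
#' `<P x, y> == <x, t(P) y>` holds to machine precision: the pair is a
#' matched operator/adjoint pair, not an independent discretization.
#'
#' @param sino a [Sinogram-class].
#' @return square numeric matrix of side `imageSide`.
#' @export
backProject <- function(sino) {
  stopifnot(is(sino, "Sinogram"))
  validObject(sino)
  geom <- sino@geometry
  A <- projectionOperator(geom)
  matrix(as.numeric(Matrix::crossprod(A, as.vector(sino@values))),
         geom@imageSide, geom@imageSide)
}

.rampFilter <- function(M, filterName) {
  # discrete ramp built in the spatial domain (band-limited |nu| with the
  # correct DC term), avoiding the low-frequency bias of a raw |nu| grid
  n <- c(seq(0, M / 2 - 1), seq(-M / 2, -1))
  h <- numeric(M)
  h[1] <- 0.25
  odd <- which(n %% 2 != 0)
  h[odd] <- -1 / (pi * n[odd])^2
  filt <- 2 * Re(stats::fft(h))
  if (filterName == "hann") {
    fr <- n / M
    filt <- filt * (0.5 + 0.5 * cos(2 * pi * fr))
  } else if (filterName != "ramp") {
    stop(sprintf("unknown FBP filter '%s'", filterName))
  }
  filt
}

#' Filtered backprojection
#'
#' Classic analytic inversion: each projection is ramp-filtered in the
#' frequency domain (zero-padded to the next power of two to avoid
#' circular-convolution wrap; optional Hann apodization) and the filtered
#' sinogram is backprojected with the interpolating backprojector and
#' scaled by `pi / (2 nAngles)` so that dense-view FBP of a projected
#' phantom approximates the phantom in absolute value.
#'
#' @param sino a [Sinogram-class].
#' @param filter `"ramp"` or `"hann"`.
#' @return square numeric matrix reconstruction.
#' @export
fbp <- function(sino, filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  stopifnot(is(sino, "Sinogram"))
  geom <- sino@geometry
  nd <- geom@nDet; na <- length(geom@angles)
  M <- max(64L, stats::nextn(2L * nd, 2L))
  p <- t(sino@values)                       # nd x na, one projection per column
  pp <- rbind(p, matrix(0, M - nd, na))
  filt <- .rampFilter(M, filter) / geom@pixelSize
  Q <- Re(stats::mvfft(stats::mvfft(pp) * filt, inverse = TRUE)) / M
  Q <- Q[seq_len(nd), , drop = FALSE]
  fsino <- sinogram(t(Q), geom)
  backProject(fsino) * pi / (2 * na) / geom@pixelSize^2
}

#' Nyquist view-count bound for parallel-beam CT
#'
#' The standard angular-sampling requirement `ceiling(pi * D / (2 * delta))`
#' for a sample of thickness `D` imaged with detector pixel size `delta`:
#' the number of views below which angular undersampling artifacts are
#' expected.
#'
#' @param diameter sample thickness / field diameter (same length units as
#'   `pixelSize`).
#' @param pixelSize detector pixel size.
#' @return integer view count.
#' @examples
#' nyquistViewCount(200, 1)   # 315
#' @export
nyquistViewCount <- function(diameter, pixelSize = 1) {
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be positive")
  if (!is.finite(pixelSize) || pixelSize <= 0) stop("pixelSize must be positive")
  as.integer(ceiling(pi * diameter / (2 * pixelSize)))
}
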