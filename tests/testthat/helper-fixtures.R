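# shared miniature fixtures, built in code at test time

tinyGeom <- function(side = 8L, nAngles = 4L, nDet = NULL)
  projectionGeometry(side, nAngles = nAngles, nDet = nDet)

# dense matrix of the projector, column by column (oracle construction)
denseProjector <- function(geom) {
  N <- imageSide(geom)^2
  sapply(seq_len(N), function(j) {
    e <- matrix(0, imageSide(geom), imageSide(geom))
    e[j] <- 1
    as.vector(forwardProject(e, geom)@values)
  })
}

# random unit-norm dictionary with fixed seed
randomDictionary <- function(K, m, channels = 1L, seed = 1L) {
  withr::with_seed(seed,
    patchDictionary(matrix(rnorm(K * m^2 * channels), K), m = m,
                    channels = channels))
}

# orthonormal square dictionary (K = m^2 * C)
orthoDictionary <- function(m, channels = 1L, seed = 1L) {
  n <- m^2 * channels
  Q <- withr::with_seed(seed, qr.Q(qr(matrix(rnorm(n * n), n))))
  patchDictionary(t(Q), m = m, channels = channels)
}

# identity dictionary: one indicator atom per patch pixel
identityDictionary <- function(m, channels = 1L)
  patchDictionary(diag(m^2 * channels), m = m, channels = channels)
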