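test_that("lattice construction matches the tiling-plus-translates layout", {
  lat <- buildLattice(16, 8, 8)
  expect_identical(nPatches(lat), 4L)
  expect_true(all(coverageCount(lat) == 1L))

  lat2 <- buildLattice(16, 8, 4)
  cov <- coverageCount(lat2)
  expect_true(all(cov >= 1L))
  expect_identical(cov[8, 8], 4L)           # interior pixel: all 4 translates
  # deterministic ordering: base tiling first, row-major
  expect_equal(patchCorners(lat2)[1:4, ],
               cbind(c(0L, 0L, 8L, 8L), c(0L, 8L, 0L, 8L)))
  expect_error(buildLattice(15, 8, 4), "divide")
  expect_error(buildLattice(16, 8, 3), "divide")
})

test_that("core indicators partition the image and live inside their patch", {
  for (s in c(2L, 4L, 8L)) {
    lat <- buildLattice(16, 8, s)
    core <- coreMap(lat)
    # every pixel assigned to exactly one core (partition by construction),
    # and that patch must contain the pixel
    pix <- matrix(seq_len(256), 16)
    owner <- core@whichPatch
    for (q in seq_len(256)) {
      p <- owner[q]
      expect_true(q %in% lat@patchPix[p, ])
    }
    # core sizes sum to the pixel count
    expect_identical(sum(table(owner)), 256L)
  }
})

test_that("step s = m makes cores equal to whole patches; s = 1 shrinks them to pixels", {
  lat <- buildLattice(16, 8, 8)
  core <- coreMap(lat)
  expect_true(all(table(core@whichPatch) == 64L))
  # odd patch side puts a pixel exactly at each patch center, so s = 1
  # shrinks interior cores to that single pixel
  lat1 <- buildLattice(15, 5, 1)
  core1 <- coreMap(lat1)
  sizes <- table(core1@whichPatch)
  expect_identical(as.integer(stats::median(sizes)), 1L)
  interiorPatch <- core1@whichPatch[8, 8]
  expect_identical(as.integer(sizes[as.character(interiorPatch)]), 1L)
  # even patch side: center falls between pixels, ties go to the lowest
  # index, cores stay small but need not be single pixels
  lat2 <- buildLattice(16, 4, 1)
  core2 <- coreMap(lat2)
  sz2 <- table(core2@whichPatch)
  expect_lte(as.integer(stats::median(sz2)), 2L)
  expect_lte(max(sz2), 9L)   # tie clustering + boundary absorption stay bounded
})

test_that("patch composition equals the dense linear combination", {
  D <- randomDictionary(12, 4)
  expect_equal(composePatch(rep(0, 12), D), rep(0, 16))
  e <- rep(0, 12); e[5] <- 1
  expect_equal(composePatch(e, D), atoms(D)[5, ])
  w <- withr::with_seed(4, rnorm(12))
  expect_equal(composePatch(w, D), as.numeric(t(atoms(D)) %*% w))
  expect_error(composePatch(rep(0, 11), D), "length")
})

test_that("composeSolution gathers each pixel from its core patch", {
  lat <- buildLattice(16, 8, 4)
  core <- coreMap(lat)
  D <- identityDictionary(8)
  # all patches identical constants -> constant image
  W <- matrix(3.5, nPatches(lat), 64)
  sol <- composeSolution(W, lat, core, D)
  expect_true(all(abs(sol - 3.5 * 1) < 1e-12))
  # s = m: composition is the tiling of the composed patches
  latNO <- buildLattice(16, 8, 8); coreNO <- coreMap(latNO)
  W2 <- withr::with_seed(5, matrix(rnorm(4 * 64), 4))
  sol2 <- composeSolution(W2, latNO, coreNO, D)
  expect_equal(sol2[1:8, 1:8], matrix(W2[1, ], 8))
  expect_equal(sol2[9:16, 9:16], matrix(W2[4, ], 8))
  # linearity in the coefficients
  Wa <- withr::with_seed(6, matrix(rnorm(nPatches(lat) * 64), ncol = 64))
  Wb <- withr::with_seed(7, matrix(rnorm(nPatches(lat) * 64), ncol = 64))
  expect_equal(composeSolution(2 * Wa - Wb, lat, core, D),
               2 * composeSolution(Wa, lat, core, D) -
                 composeSolution(Wb, lat, core, D),
               tolerance = 1e-12)
})

test_that("extraction round-trips and matches the lattice layout", {
  lat <- buildLattice(16, 8, 4)
  img <- withr::with_seed(8, matrix(rnorm(256), 16))
  P <- extractPatches(img, lat)
  expect_identical(nrow(P), nPatches(lat))
  expect_true(all(abs(extractPatches(matrix(2, 16, 16), lat) - 2) < 1e-15))
  # identity dictionary on the non-overlapping lattice round-trips the image
  latNO <- buildLattice(16, 8, 8); coreNO <- coreMap(latNO)
  D <- identityDictionary(8)
  W <- extractPatches(img, latNO)
  expect_equal(composeSolution(W, latNO, coreNO, D), img, tolerance = 1e-12)
})

test_that("overlap residuals vanish for agreeing patches and match brute force", {
  lat <- buildLattice(16, 8, 4); core <- coreMap(lat)
  D <- identityDictionary(8)
  img <- withr::with_seed(9, matrix(rnorm(256), 16))
  # coefficients read off the image: all patches agree everywhere
  W <- extractPatches(img, lat)
  expect_lt(max(abs(overlapResidual(W, lat, core, D))), 1e-12)
  # s = m: no overlap, residual identically zero for any coefficients
  latNO <- buildLattice(16, 8, 8); coreNO <- coreMap(latNO)
  W2 <- withr::with_seed(10, matrix(rnorm(4 * 64), 4))
  expect_lt(max(abs(overlapResidual(W2, latNO, coreNO, D))), 1e-12)
  # random coefficients: squared sum equals the double-loop oracle
  W3 <- withr::with_seed(11, matrix(rnorm(nPatches(lat) * 64), ncol = 64))
  R <- overlapResidual(W3, lat, core, D)
  U <- W3 %*% atoms(D)
  sol <- composeSolution(W3, lat, core, D)
  acc <- 0
  for (p in seq_len(nPatches(lat)))
    for (o in 1:64)
      acc <- acc + (U[p, o] - sol[lat@patchPix[p, o]])^2
  expect_equal(sum(R^2), acc, tolerance = 1e-10)
})

test_that("vectorial lattices stack channels per patch", {
  lat <- buildLattice(16, 8, 4, channels = 2L)
  core <- coreMap(lat)
  vimg <- array(withr::with_seed(12, rnorm(512)), c(16, 16, 2))
  P <- extractPatches(vimg, lat)
  expect_identical(ncol(P), 128L)
  expect_equal(P[3, 1:64], vimg[, , 1][lat@patchPix[3, ]])
  expect_equal(P[3, 65:128], vimg[, , 2][lat@patchPix[3, ]])
  D <- identityDictionary(8, channels = 2L)
  sol <- composeSolution(P, lat, core, D)
  expect_equal(sol, vimg, tolerance = 1e-12)
})
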