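# patchCT

Few-view parallel-beam CT reconstruction with an overlapping-patch
dictionary-learning prior, in R.

Reducing the number of view angles far below the angular Nyquist bound
`N = ceil(pi D / (2 delta))` cuts dose but breaks filtered backprojection
(FBP). `patchCT` reconstructs such scans by minimizing a single convex
functional over per-patch dictionary coefficients `w`:

    F(w) = || P I(w) - d ||^2                               (fidelity)
         + omega * sum_p sum_x chi_p(x) (u_p(x) - I(w)(x))^2 (similarity)
         + lambda * ||w||_1                                  (sparsity)

where each patch `u_p = sum_k w_pk atom_k` is a sparse combination of
K-SVD-trained atoms, the image `I(w)` is composed from the *cores* of an
overlapping patch lattice (every pixel takes the value of the patch whose
center is nearest), and the similarity term forces all patches covering a
pixel to agree with the composed solution — the convex replacement for
post-hoc patch averaging. `P` is the parallel-beam projector (exact
sparse-matrix adjoint), and the minimizer is found by FISTA with
soft-thresholding. Baselines included: FBP (ramp/Hann), isotropic-TV
reconstruction (FISTA + Chambolle prox), and the "floating solution"
functional in which the global image is a free variable coupled to the
patches.

For differential phase-contrast (DPC) tomography the measured signal is
`cos(theta) P[gx] + sin(theta) P[gy]`; multiplying by `cos`/`sin` of the
view angle decomposes it exactly into the two gradient-component
sinograms, and the package reconstructs both channels with one shared
coefficient set through a two-channel (vectorial) dictionary.

Everything needed to reproduce the benchmarks is generated in code:
seeded textured phantoms (deliberately not piecewise constant), disjoint
training images, few-view sinograms, scaled-Poisson noise and vectorial
gradient ground truth.

## Worked example

```r
library(patchCT)

b    <- benchmarkCase("lena80")              # 128 px textured phantom, 80 views
dict <- trainBenchmarkDictionary(b)          # K-SVD, 100 atoms, 8x8 patches
sino <- forwardProject(b$phantom, b$geometry)

lat  <- buildLattice(128, 8, 4)              # 8x8 patches, step 4
core <- coreMap(lat)

rec_fbp <- fbp(sino)
rec_dl  <- solution(fistaSolve(sino, dict, lat, core, b$solver))

ssim(rec_fbp, b$phantom, 1)                  # 0.811
ssim(rec_dl,  b$phantom, 1)                  # 0.892
improvementFactor(rec_dl, rec_fbp, b$phantom, 1)  # 0.43
```

At 80 of the ~202 Nyquist-required views, FBP reaches SSIM 0.811 against
the ground-truth phantom while the dictionary reconstruction (1000 FISTA
iterations at the scan-selected `lambda = 0.5`, `omega = 5`) reaches
0.892; the improvement factor `Q = (S_dl - S_fbp) / (1 - S_fbp)` says the
method closes 43% of FBP's remaining SSIM deficit. `parameterScan()`
reproduces the regularization scan that selected those weights, and
`benchmarkCase("lena80_noisy")` / `benchmarkCase("dpc200")` give the
noisy and phase-contrast protocols.

A thin command-line wrapper over the same functions is installed at
`inst/cli/patchct` (subcommands `simulate`, `train`, `reconstruct`,
`metrics`, `scan`; YAML solver configs).

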