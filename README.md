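# pbitomo

Reconstruction workflows for single-distance propagation-based
phase-contrast (PBI) synchrotron micro-CT, as an R package.

At a coherent synchrotron beamline, the sample is described by its complex
refractive index `n = 1 − δ + iβ`: `β` attenuates, `δ` shifts phase. For
soft tissue at 30–40 keV, `δ/β` is in the hundreds to thousands, so letting
the beam propagate freely over a distance `d` (~meters) and retrieving the
phase recovers contrast that absorption alone cannot. The essential
reconstruction chain is **flat fielding → single-distance phase retrieval →
filtered back projection**; refined workflows add **dynamic (eigen-flat)
flat fielding**, **extended field-of-view stitching** for 360° offset-axis
("half acquisition") scans, **sinogram de-striping** against ring
artifacts, and **algebraic (SIRT) reconstruction**. `pbitomo` implements
the whole chain as composable stages driven by a YAML parameter file, plus
a physics-based simulator (ellipse phantoms with closed-form Radon
oracles, Fresnel propagation, detector gain / beam-drift / Poisson
corruption models) so every stage is validated against ground truth.

The core operators, in the package's conventions (`f` in cycles per unit
length, `λ = hc/E`, `χ = πλd|f|²`):

- Fresnel forward model: `u = e^{−(2π/λ)B} e^{−i(2π/λ)D}`, propagator
  `e^{−iπλd|f|²}`, intensity `|u_d|²`;
- Paganin TIE-Hom: `t = −(1/μ) ln IDFT[ DFT(I/I₀) · H ]`,
  `H = 1/(1 + πλdr|f|²)`, `μ = 4πβ/λ`, `r = δ/β`;
- CTF / projected CTF: `φ = IDFT[ DFT(I/I₀ − 1) · R/(R² + ε) ]`,
  `R = −2 sin χ`, clamped at `χ = π/2` for the projected variant;
- Raven-type de-striping: Butterworth low-pass
  `1/(1 + (u/u₀)^{2·order})` on the lowest angular-frequency lines of the
  sinogram spectrum;
- FBP with a discrete Ram-Lak kernel filter and a matched (exact-adjoint)
  pixel-driven projector pair shared with SIRT.

## Worked example

Simulate a corrupted half-acquisition scan of a soft-tissue-like phantom
and reconstruct it with the refined workflow:

```r
library(pbitomo)

## beamline-like geometry: 40 keV, 2.2 m propagation, 3.05 um pixels,
## 360 projections over a full turn with the axis offset by +45.25 px
px <- 3.05e-6
g <- geometry(40, px, 2.2, seq(0, 359, 1), 128L,
              axisPosition = 63.5 + 45.25,
              scanMode = "full_turn_360_offset")
fresnelNumber(px, g)
#> [1] 0.1364177

## a soft-tissue-like phantom: body + inclusion + cavity, delta/beta = 400
ell <- list(
  ellipseSpec(centerX = -1e-5, semiAxisA = 1.5e-4, semiAxisB = 1.2e-4,
              rotation = 20, delta = 1.2e-7, beta = 3e-10),
  ellipseSpec(centerX = 5e-5, centerY = 3e-5, semiAxisA = 4e-5,
              semiAxisB = 2.5e-5, rotation = -30, delta = 8e-8, beta = 2e-10),
  ellipseSpec(centerX = -6e-5, centerY = -4e-5, semiAxisA = 2.5e-5,
              semiAxisB = 3.5e-5, delta = -5e-8, beta = -1.25e-10))

## long-scan corruptions: gain stripes, low-rank beam drift, photon noise
drift <- makeDriftModel(12, 128, 30 + 360 + 30, nComponents = 2,
                        amplitude = 0.03, seed = 21)
gain <- matrix(1, 12, 128)
set.seed(9); cols <- sample(128, 7)
gain[, cols] <- gain[, cols] * (1 + runif(7, 0.01, 0.03))
cm <- corruptionModel(gain, drift$images, drift$weights,
                      photonCount = 1e6, darkLevel = 10, seed = 13)
ps <- simulateHalfAcquisition(ell, g, height = 12, corruption = cm,
                              padding = 32, nFlatsBefore = 30,
                              nFlatsAfter = 30, nDarks = 4)
ps
#> ProjectionSet: 360 projections of 12 x 128 px
#>   flats: 30 before + 30 after, darks: 4
#> Geometry: 40 keV (lambda 3.1e-11 m), pixel 3.05e-06 m, distance 2.2 m
#>   360 angles in [0.00, 359.00] deg, mode full_turn_360_offset
#>   detector 128 px, axis at column 108.750

## refined workflow: dynamic flats, stitching, de-striping, Paganin, FBP
spec <- validateWorkflow(list(
  seed = 3,
  stages = list(
    list(stage = "flat", method = "dynamic", n_components = 2L,
         estimation_region = 1:40),
    list(stage = "geometry", axis = "auto"),
    list(stage = "ring", method = "raven", placement = "pre_phase"),
    list(stage = "phase", method = "paganin", delta_beta_ratio = 400,
         padding = 64L),
    list(stage = "recon", algorithm = "fbp", filter = "shepp_logan")),
  slices = list(5L)))
rep <- runWorkflow(spec, ps, writeOutputs = FALSE)
rep
#> Workflow run: 5 stage(s), 1 slice(s)
#>   stages: flat -> geometry -> ring -> phase -> recon
#>   flat          0.212 s
#>   geometry      0.587 s
#>   ring_pre      0.095 s
#>   phase         0.974 s
#>   recon         0.515 s

rep$metrics$axis_estimate          # true axis: 108.75
#> [1] 108.8388

slice <- rep$slices[["5"]]
truth <- makePhantom(ell, nrow(values(slice)), px)
cor(as.vector(values(slice)), as.vector(truth@delta))
#> [1] 0.9829272
```

The auto-estimated rotation axis lands within 0.1 px of the simulated
truth; the reconstructed slice (a `δ`-proportional map, since Paganin
pseudo-absorption feeds the FBP) correlates at 0.983 with the ground-truth
`δ` phantom despite the injected stripes, drift and photon noise. With
`writeOutputs = TRUE` the slices are written as 32-bit float TIFFs next to
a structured run report and the default-expanded workflow file, from which
the run can be replayed exactly.

The same workflow file drives the command-line interface:

```sh
Rscript inst/cli/pbi-recon.R simulate workflow.yaml dataset/
Rscript inst/cli/pbi-recon.R run      workflow.yaml dataset/ --out recon/
Rscript inst/cli/pbi-recon.R preview  workflow.yaml dataset/ --slice 5
Rscript inst/cli/pbi-recon.R batch    workflow.yaml ds1/ ds2/ ds3/
```

## Documentation

The methods vignette (`vignettes/pbi-reconstruction-methods.Rmd`) explains
the physical model, every stage's assumptions and tunable parameters, the
numerical choices (frequency conventions, filter kernels, clamps and
tie-breaks), what the simulator does and does not emulate, and the known
limitations.
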