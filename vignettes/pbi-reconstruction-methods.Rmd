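---
title: "Reconstruction methods for propagation-based phase-contrast micro-CT"
author: "pbitomo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction methods for propagation-based phase-contrast micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(pbitomo)
```

## The imaging problem

Synchrotron micro-CT with a coherent beam measures, for each rotation
angle, the intensity of the wavefield some distance `d` downstream of the
sample. The sample enters through its complex refractive index
`n = 1 - delta + i beta`: `beta` attenuates the beam (Beer–Lambert),
`delta` shifts its phase. For soft biological tissue at 30–40 keV,
`delta` exceeds `beta` by two to four orders of magnitude, so
propagation-based imaging (PBI) — letting the beam interfere with itself
over a sample-to-detector distance of a meter or two — recovers contrast
that pure absorption imaging cannot. The cost is a more involved
reconstruction chain. The essential chain is flat fielding, single-distance
phase retrieval, and filtered back projection; refined workflows add
dynamic flat fielding, extended field-of-view stitching, sinogram
de-striping and algebraic reconstruction. `pbitomo` implements that full
chain as composable, scriptable stages, plus a coherent-imaging simulator
so every stage can be validated against ground truth.

Conventions used throughout: detector columns are 0-based and indexed at
pixel centers; the rotation-axis position is a fractional column index;
angles are stored in degrees (beamline logs use degrees) and converted to
radians internally; all images are held in double precision regardless of
input bit depth; spatial frequencies `f` are in cycles per unit length.

## The forward model (simulator)

Phantoms are additive superpositions of ellipses with per-ellipse `delta`
and `beta` increments. Two forward routes exist deliberately:

* `analyticSinogram()` evaluates the closed-form chord integral of each
  ellipse (`2 a b v sqrt(rho^2 - s^2) / rho^2` in the ellipse frame) at
  the exact detector coordinates `(j - axis) * pixelSize`. This is the
  oracle: no grid, no interpolation.
* `radonForward()` projects a rasterized map with the package's discrete
  projector, which is the route the reconstruction algorithms use.

Wave propagation follows the paraxial (Fresnel) model: the transmittance
`u = exp(-(2 pi / lambda) B) exp(-i (2 pi / lambda) D)` built from the
`beta` and `delta` line integrals is multiplied in the Fourier domain by
`exp(-i pi lambda d |f|^2)` and squared to intensity. With this sign pair
(phase-delay convention) a weak object produces the contrast spectrum
`-2 sin(chi) phi_hat`, `chi = pi lambda d |f|^2`, which is the convention
under which the Paganin filter takes its standard form; the CTF inversion
below carries the corresponding minus sign. Boundaries are periodic, with
optional symmetric padding to suppress wrap-around; at `d = 0` the model
reduces exactly to Beer–Lambert, and a pure-phase object gives unit
intensity — both asserted in the tests.

Detector/beamline corruption is modeled as
`Poisson(photonCount * gain * drift(t) * clean) + darkLevel`: a fixed
per-pixel gain map (stripe/bright-spot defects of the scintillator chain,
the cause of ring artifacts), plus a *low-rank* beam drift — a few smooth
spatial components modulated by slow temporal weights, emulating
source/monochromator instability over a long scan. The drift is low-rank
by construction precisely because that is the structure PCA-based dynamic
flat fielding assumes; the simulator therefore tests that method in its
favorable regime, and a real beam whose drift is not low-rank would
benefit less. Half-acquisition scans (360° with the axis shifted toward a
detector edge) are simulated by evaluating the chord integrals directly at
the offset detector coordinates — exact for any fractional axis, so the
recorded ground-truth axis is meaningful to well below 0.1 px. (A
band-limited subpixel shift of sampled projections would be the
alternative; direct evaluation is strictly more accurate.)

What the simulator does *not* emulate: partial coherence, polychromatic
spectra, detector point-spread, scattering, axis wobble. Passing tests
demonstrate algorithmic correctness under the stated model, not
performance on every real dataset.

## Flat fielding

Conventional normalization is `N = (P - D) / (F - D)` with the mean dark
`D` and mean flat `F`; the denominator is clamped below at
`1e-6 * max(F - D)` and the result clipped to `[0, 10]` (both
configurable) so a downstream logarithm never sees non-positive values.
Flats taken before and after the scan are pooled by default — the two
groups differ on a drifting beam, and pooling centers the PCA on their
common mean; per-group use is available.

Dynamic flat fielding decomposes the dark-subtracted, mean-centered flats
by SVD into orthonormal *eigen flat fields*. Each projection is then
corrected with `(F - D) + sum_k w_k E_k` in the denominator, with weights
`w` fitted by linear least squares of `P - F` onto the eigen images over
an *estimation region* — by default the whole frame, in practice best a
set of air-only columns so the object does not leak into the fit. Least
squares is chosen over total-variation weighting deliberately: it is
closed-form, exact when the projection truly is a drifted flat (asserted
to machine precision in the tests), and fast enough to run per
projection. We estimate weights per projection rather than per sinogram
row: drift in this model is a property of a moment in time, i.e. of a
whole frame. With constant flats the eigen basis is empty and the dynamic
path reduces bit-for-bit to the conventional one.

## Rotation axis and half-acquisition stitching

The axis is estimated from a 0°/180° projection pair: the 180° frame is
mirrored and the shift maximizing the normalized cross-correlation found
(integer grid, then parabolic subpixel refinement); the axis is
`(W - 1)/2 + s/2`. Three robustness measures matter in the
half-acquisition setting and were each adopted after the naive estimator
demonstrably failed on simulated data: (i) lags whose overlap is nearly
featureless (air against air) are rejected — they can correlate almost
perfectly while carrying no registration information; (ii) a 3-tap
binomial smoothing is applied first, because propagation fringes near the
pixel scale decorrelate integer-lag matching; (iii) a margin at the two
ends of the overlap is trimmed, since those ends coincide with the
detector edges of the two views, where truncation diffraction makes them
genuinely disagree. A correlation peak below 0.2 attaches a low-confidence
warning that the pipeline surfaces in its report.

Stitching places the `theta` row and the mirrored `theta + 180°` row on a
common grid centered on the axis. The output width is
`W' = round(2 * axis + 1)` for an axis in the right half (symmetric
formula on the left); the overlap of width about `2W - W'` is blended
with a linear ramp whose endpoints reproduce the respective single-row
values exactly; hard-cut and cosine blends are selectable. The fractional
part of the axis is handled by linear interpolation of the *mirrored*
row only — the owning row always lands on integer positions, keeping the
stitched sinogram on a regular grid for FBP. An axis at the detector
center has no extended field of view; that case raises a degenerate
overlap error advising a plain 180° scan.

## Ring-artifact removal

Detector gain errors are constant in angle, so they live on the lowest
angular-frequency lines of the sinogram's 2-D spectrum while being sharp
along the detector. The Raven-type filter transforms the sinogram,
multiplies the `|m| < nAngularLines` angular-frequency lines by a
Butterworth low-pass `1 / (1 + (u / u0)^(2 order))` in the detector
frequency `u`, and transforms back. The classical filter uses only the
`m = 0` line; the line count, cutoff and order are the tunable
"modification" (defaults `nAngularLines = 2`, `u0 = 0.05` cycles/px,
`order = 4` — the exact parameterization used in production codes is not
published, so this surrogate is documented as such). `H(0) = 1` preserves
the sinogram mean; the filter is near-idempotent and tends to identity as
`u0 -> 0.5` at high order.

The column-normalization filter divides each column by the ratio of its
angular mean to a smoothed trend. The trend is a width-3 running median
followed by a moving average: the median step keeps an isolated stripe's
own (inflated) mean out of its trend estimate, without which a width-`w`
moving average leaks `1/w` of the stripe into the correction and a 5%
stripe could only be restored to about half a percent.

Both filters operate on flat-corrected (or phase-retrieved) sinograms,
never raw counts, and the pipeline accepts them before, after, or on both
sides of phase retrieval. `ringEnergy()` quantifies rings in a slice as
the mean over radii of the on-circle variance, minus the same statistic on
a reference (ground truth where available, a 5×5 box-smoothed copy
otherwise — the smoothed default only partially discounts object
structure, so paired comparisons against a common reference are the
reliable use).

## Single-distance phase retrieval

**Paganin / TIE-Hom.** For a homogeneous sample with known
`r = delta/beta` — the one parameter a user tunes in the standard
workflow — the flat-corrected intensity is filtered by the Lorentzian
low-pass `H(f) = 1 / (1 + pi lambda d r |f|^2)` and the projected
thickness recovered as `t = -(1/mu) ln(filtered)`, `mu = 4 pi beta /
lambda`. The frequency convention is stated because published
implementations differ by factors of `4 pi^2` between angular and cyclic
frequency forms; in cycles per length the coefficient is exactly
`pi lambda d r`. At `d = 0` the filter is the identity and the operation
is Beer–Lambert inversion to machine precision. For reconstruction the
useful output is the pseudo-absorption line integral `mu t`; FBP of it
yields a map proportional to `delta` for a homogeneous object.

**CTF and projected CTF.** For weak or pure phase objects the linearized
contrast transfer is inverted:
`phi = IDFT[ DFT(I - 1) * R / (R^2 + eps) ]` with `R = -2 sin(chi)` (the
sign following the propagator convention above) and the DC term zeroed —
the absolute phase offset is unobservable. The Tikhonov-style `eps`
keeps frequencies with `sin(chi) = 0` finite; `eps = 1e-4` is a robust
default for noisy data, while noiseless, band-limited validation data
support `1e-6` to `1e-8`. The *projected* variant replaces the response
by the clamped sine `-2 sin(min(chi, chi_c))`, default `chi_c = pi/2`:
it agrees with the CTF below the first response maximum and avoids the
sign-flipping oscillations beyond it. This is a documented surrogate for
the projected/quasiparticle CTF of the literature, whose exact response
is not reproduced here.

`compareRetrievals()` operationalizes the known resolution trade-off:
10–90% rise distance across a known edge plus RMSE, for both methods.
The benchmark in the test suite propagates a weak pure-phase disc with a
sub-pixel edge and retrieves it with a strongly smoothing ratio
(`r = 1e5`, the regime chosen in practice for near-pure-phase samples)
against a lightly regularized CTF; the TIE-Hom rise distance is then at
least the CTF one. The edge metric is evaluated in a window local to the
edge, because every regularized single-distance retrieval shows
large-scale low-frequency sag far from features, which is a separate
phenomenon from edge resolution.

## Reconstruction

FBP zero-pads each sinogram row to the next power of two at least twice
the width, filters with the DFT of the discrete Ram-Lak kernel (`1/4` at
lag 0, `-1/(pi n)^2` at odd lags) times the chosen apodization window
(Ram-Lak, Shepp-Logan or Hann), and back-projects with linear
interpolation about the fractional axis. The kernel-derived ramp matters:
naively sampling `|f|` biases a uniform disk low by about 3% at these
sizes, while the kernel form recovers the interior value to 0.002%
(asserted in the tests). The output scale `pi / (2 n_angles) /
pixelSize` makes a sinogram of line integrals of a quantity reconstruct
that quantity per unit length, so Paganin-preprocessed data reconstruct
in `mu`-equivalent units, proportional to `delta` for a homogeneous
sample.

SIRT uses the classic inverse row/column-sum weighting
`x <- x + C A' R (b - A x)` with an optional non-negativity clamp, and
reports the data residual per iteration (three consecutive increases
abort with diagnostics; a 0.1% tolerance absorbs clamp-induced jitter).
Forward and back projector are one matched pixel-driven pair with
bilinear detector weights and optional sub-pixel supersampling
(default 2 per axis), implemented in C++; `cpp_forward` and
`cpp_backproject` are exact adjoints, which keeps FBP, SIRT and the
Radon oracle mutually consistent and makes the SIRT iteration provably
non-expansive on clean data. At 60 noisy projections SIRT with
non-negativity beats FBP in slice RMSE — the regime where algebraic
methods pay off.

## Workflow orchestration

A workflow is a YAML parameter file: an ordered `stages` list (`flat`,
`geometry`, `ring`, `phase`, `recon`) with per-stage parameters, plus
input layout, output directory, slice list and seed. Validation fills
every default and rejects unknown keys and out-of-order stages, and the
default-expanded spec is written next to the outputs together with a
structured run report (parameters, timings, warnings, output checksums),
so any run is replayable from its own log; there is no hidden state.
Identical spec, dataset and seed give bit-identical slice files. Batch
mode applies one spec to many datasets, isolating failures. The
`simulate:` section drives the simulator through the same syntax, so a
self-contained parameter file can generate its own test dataset. The
thin CLI (`inst/cli/pbi-recon.R`) wraps these functions with
`run` / `batch` / `simulate` / `preview --slice N` subcommands and exit
codes distinguishing spec errors, data errors and stage failures.

The on-disk container is a TIFF sequence (zero-padded numeric suffixes,
lexicographic = acquisition order; flats split into `_before` / `_after`
groups) with the geometry in a YAML sidecar. Slices are written as
uncompressed 32-bit float grayscale TIFF with the physical quantity and
pixel size in the ImageDescription tag — float, not 8/16-bit quantized,
so downstream analysis keeps physical units. The package writes these
files with its own minimal TIFF codec because the available R TIFF
writer clamps data to the unit interval, which would destroy
physical-unit payloads; reading falls back to the standard reader for
foreign (e.g. compressed) files.

## Validation scale and reproducibility

The test-suite and acceptance computations run at desk scale, chosen so
the full suite completes in about a minute on one CPU while every
comparison stays well clear of its tolerance: Radon oracle agreement at
512², FBP inversion at 256² with 360 angles, phase retrieval at 256²
with the 40 keV / 2.2 m / 3.05 µm beamline geometry, the corrupted
half-acquisition benchmark at 128-px detector width with 360 angles,
30 + 30 flats at 10^6 expected counts, 1–3% gain stripes and 3% low-rank
drift, and SIRT at 200 iterations on 60 angles of 128 px. Photon counts
and corruption amplitudes sit in the range typical of long
synchrotron scans; the drift amplitude (3%) matches the "slight
variations" regime that motivates dynamic flat fielding.

A worked end-to-end example with printed numbers is in the README;
`scripts/acceptance.R` recomputes all headline quantities from scratch
for any seed.

## Known limitations

Parallel beam and monochromatic illumination only; no detector tilt or
axis wobble; the projected-CTF response is a clamped-sine surrogate; the
half-acquisition axis estimator assumes the object provides some texture
in the overlap; ring-energy with the default smoothed reference is a
relative, not absolute, measure; HDF5 containers are recognized in the
layout syntax but not supported by this build — the TIFF-sequence
container is the interchange format.
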