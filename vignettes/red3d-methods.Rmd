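---
title: "Rotation electron diffraction data reduction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation electron diffraction data reduction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

Rotation electron diffraction (RED, a flavour of 3D electron diffraction /
electron diffraction tomography) collects hundreds to thousands of
selected-area diffraction frames while the effective beam–crystal tilt is
stepped finely around a single axis: coarse mechanical goniometer steps
(about 2°) are interleaved with fine electronic beam-tilt sweeps (about
0.1–0.2° over ±1°), because the goniometer cannot step smoothly at 0.1°.
Each frame is a near-planar intersection of the Ewald sphere (radius
$1/\lambda$, with $\lambda \approx 0.0251$ Å at 200 kV) with the
reciprocal lattice of one crystallite. Reduction means inverting that
geometry: recovering the 3D reciprocal lattice, its basis vectors (hence
the unit cell), integer indices for every reflection, and intensities
suitable for structure solution.

`red3d` implements the complete chain, plus a forward simulator that
generates MRC frame stacks with known ground truth so every stage has a
quantitative oracle.

## Conventions (fixed, shared by simulator and processor)

* Pixels are 0-based; $x$ = column, $y$ = row; the lab frame is
  right-handed with $+z$ along the beam.
* Detector position → transverse reciprocal coordinates by the flat
  small-angle map $g_x = x/\mathrm{ppa}$ (ppa = pixels per reciprocal Å).
  At $\lambda = 0.0251$ Å and $|g| \le 1.2$ Å$^{-1}$ the neglected tangent
  correction is $< 0.05\%$; what matters for recovery tests is that the
  forward and inverse maps agree exactly.
* Back-projection onto the Ewald sphere:
  $g_z = 1/\lambda - \sqrt{1/\lambda^2 - g_\perp^2}$.
* The tilt axis is the line at azimuth $\varphi \in [0°, 180°)$ in the
  detector plane; a positive combined tilt rotates reciprocal-space points
  counterclockwise about $(\cos\varphi, \sin\varphi, 0)$ seen from the axis
  tip. Flipping the sense globally produces the enantiomorphic
  reconstruction, which rotation data cannot distinguish; it is a fixed
  convention, not an option.
* Goniometer and beam tilt are assumed to combine additively into the
  stored combined tilt; the parser re-checks additivity. Frames sharing a
  combined tilt (sweep-boundary overlap frames) are kept at read time —
  they help drift tracking — and deduplicated (first occurrence wins) when
  spots are lifted to 3D.
* $|g| = 1/d$ throughout (crystallographic convention, no $2\pi$).

## The forward simulator as a stated world

`sim_config()` defaults describe one concrete, realistic experiment, used
verbatim by the acceptance tests:

| quantity | default | why |
|---|---|---|
| cell | monoclinic 20.02, 20.25, 13.35 Å, β = 90.74° | a calcined-zeolite-like cell, the kind of sample this method is used on |
| schedule | goniometer −60…+60° in 2° steps, beam ±1.0° in 0.2° steps | standard collection with one overlap frame per sweep boundary; 671 frames, 601 distinct tilts |
| λ | 0.0251 Å | 200 kV electrons |
| detector | 512×512 px, 12 bit, 280 px/Å⁻¹ | 12-bit CCD as used for such data; 1.2 Å falls near the detector edge |
| d_min | 1.2 Å | typical working resolution |
| rocking half-width ζ | 0.003 Å⁻¹ | effective mosaic/thickness rocking; makes a reflection span ~3–6 consecutive frames, the regime the merging step is built for |
| PSF σ | 1.2 px | sharp camera spot |
| background | 50 counts, Poisson noise on | moderate-dose frames |
| beam drift | random walk, σ = 0.2 px/frame | a few px of slow drift over the stack |
| intensities | log-uniform over 2 decades (40–4000 counts), equal within a Friedel pair | exercises the large dynamic range, including occasional 12-bit saturation of strong spots |

A reflection appears on a frame when its excitation error $s$ (signed
distance from the Ewald sphere along the beam) satisfies $|s| \le 3\zeta$,
attenuated by $\exp(-s^2/2\zeta^2)$ — a kinematic Gaussian rocking profile.
Spots are rendered as 2D Gaussians whose **maximum pixel** equals the
attenuated intensity; the saturated direct beam is rendered at the drifted
position. Identical seeds give byte-identical MRC files.

What the simulator does *not* emulate: dynamical diffraction, crystal
shape transforms, streaking/diffuse scattering from disorder, multi-exposure
series, lens distortions, dark/gain artefacts. A green pipeline test
therefore establishes geometric and statistical correctness of the
reduction, not robustness to dynamical intensities or disorder.

## Stage notes and numerical choices

**Drift correction.** Each frame's ROI (256×256 around the beam) is
cross-correlated against the running sum of the previously aligned ROIs, so
the reference gets cleaner as the stack proceeds; estimation is
deterministic and order-dependent by design. Sub-pixel refinement is a
separable quadratic fit to the 3×3 correlation neighbourhood. ROIs are
median-subtracted and clipped at the 99.9th percentile so a strong Bragg
spot wandering through cannot hijack the correlation — the documented
failure mode of beam tracking. The pipeline corrects *spot coordinates*
rather than resampling frames (no interpolation bias); `apply_shifts()`
provides the resampling route too.

**Peak hunting.** Difference of Gaussians: background = blur at σ = 12 px,
signal = blur at σ = 1 px, threshold 20 counts, 8-connected grouping, spot
position = maximum of the smoothed frame in each group (ties broken toward
the lowest (y, x) for determinism). Kernels are truncated at 4σ and
renormalized (mass loss < 1e-4); borders renormalize over in-frame support
so flat frames are reproduced exactly. Note: for σ = 1 px smoothing, a
normalized discrete Gaussian weights the centre pixel ≈ 16% with ≈ 10% on
each 4-neighbour; folklore figures of "64% + 9%" correspond to a much
narrower kernel and are not reproduced here. Components inside a 12 px
exclusion disc around the beam are dropped; groups touching a saturated
pixel keep their (still useful) position but are flagged and excluded from
HKLF4 export by default.

**Intensity extraction.** Either the smoothed-frame value at the spot
maximum, or 2D integration: sum of (pixel − annulus background) over a
disc of radius 5 px with a 3 px annulus. Small negative integrals are kept,
not clamped. The per-spot intensity used downstream defaults to the maximum
pixel value, the mode with which such data are routinely solved.

**Merging and 3D integration.** Single-linkage: two spots join one
reflection when they are ≤ 2 recorded frames apart, ≤ 0.0075 Å⁻¹ apart in
3D (≈ 2.5 ζ) and ≤ 6 px apart in 2D. Reflection position is the
intensity-weighted mean. The 3D-integrated intensity is
$I = \sum_{i=2}^{n} I_i\,|K_i - K_{i-1}|$ (the leading spacing is
undefined for $i = 1$, so the sum starts at 2); single-member reflections
fall back to $I_{\max}$, flagged. Friedel mates are *not* merged — they
appear a few frames apart as separate entries, and merging is left to the
downstream structure-solution code.

**Basis determination.** All difference vectors between (up to 2000
lowest-resolution) merged reflections with length ≤ 3× the shortest
lattice spacing are sign-canonicalized and clustered with a plain DBSCAN
(eps = 0.15× the shortest spacing estimated from the length histogram's
first mode; min_pts = max(5, 0.2%)). One subtlety found during
development: canonicalization ("make the largest-magnitude component
positive") splits a physical cluster into two near-antipodal images when
its two leading components have near-equal magnitude, and the small
fragment can masquerade as a spuriously short basis vector; cluster
centroids are therefore merged across sign flips before ranking by length.
The three shortest noncoplanar centroids
($|\det| > 0.01\,l_1 l_2 l_3$) are then Buerger-reduced (replace any
vector by a shorter ±1 combination, iterate). The result is a reduced
cell; conventional settings, centering and symmetry are delegated to a
user-supplied integer transform, as is standard. After a first indexing
pass the basis is re-fit by linear least squares over all accepted
reflections (`refine_basis()`, the usual post-indexing cell refinement):
cluster centroids alone are limited to a few tenths of a percent by pixel
quantization, while the overdetermined fit reaches ~0.05% on noiseless
data; the pipeline then re-indexes against the refined basis.

**Tilt-axis refinement.** With a wrong azimuth the reconstructed lattice
rows bend, so the clouds of short difference vectors smear. The score at a
trial azimuth is the mean covariance trace of the three shortest
difference-vector clusters, computed not on raw spots but on *track
centroids* — spots pre-linked across frames using only trial-independent
information (frame adjacency + 2D proximity) and averaged after rotation.
Without this, the rocking spread of multi-frame reflections dominates the
clusters at every trial angle and hides the bending signal. The trace is
additionally divided by the fraction of difference vectors the three
clusters capture: at wrong angles the greedy clusters degenerate to tiny
random clumps whose raw covariance is deceptively small, while their
population collapses. The score is scanned coarsely (0.5°) over 0–180° and
refined at 0.1°; azimuths are treated modulo 180° because the axis is a
line.

**Indexing.** Reflections are processed in ascending $|g|$. Each is
decomposed against its nearest already-accepted neighbour (the origin,
with indices 000, is the first anchor): fractional indices = neighbour's
integer indices + $B^{-1}(g - g_{nb})$, accepted when every axis deviates
from an integer by ≤ 0.1 (per-axis thresholds configurable). Re-anchoring
locally is what tolerates the residual bending of a slightly wrong axis —
tested at a deliberate 2° axis error, where > 99% of reflections still
index correctly. Rejected reflections are retained, flagged.

**Export.** HKLF4 fixed format `3I4,2F8.2`, σ(I) = √I on the unscaled
intensity, auto-scale = largest power of ten ≤ 1 keeping I ≤ 99999.99,
σ floored at 0.01 after scaling, all-zero terminator. `friedel_rint()`
reports the merging residual over groups equivalent under Friedel
inversion (repeated measurements of the same hkl enter the same group).

## What the acceptance tests establish

On the reference noisy dataset the full pipeline recovers all six cell
parameters with a maximum error well under 1% (matching over signed axis
permutations, since the reduced basis has no preferred setting), and the
straightness scan recovers a 48.5° axis within 1° (typically within 0.1°).
Noiseless runs recover a basis related to the truth lattice by an integer
unimodular transform, projection/back-projection compose to identity below
1e-9 Å⁻¹, drift recovery stays below 0.5 px RMS across noise levels, and
the Eq.-style 3D integration matches a brute-force oracle exactly. These
are statements about this simulator's world — real data add the
unmodelled effects listed above.

## Known limitations

* Kinematic intensities only; no partiality model beyond the rocking
  Gaussian; no absorption or dynamical corrections.
* Basis finding assumes ≥ 3 well-populated difference-vector clusters;
  sparse or 1D/2D data fail with diagnostics rather than guessing.
* The O(n²) difference-vector step subsamples beyond 2000 reflections;
  for typical datasets (≈ 10⁴ reflections) the low-resolution subset is
  ample.
* Streak/diffuse processing, multi-exposure merging, space-group
  determination and GUI visualization are out of scope.

## A minimal session

```{r example}
library(red3d)
sim <- render_dataset(sim_config(seed = 1), "sim_ds")
res <- run_pipeline(pipeline_config("sim_ds", tilt_axis = "refine"))
res$cell
res$axis$azimuth
head(read_hklf4(res$hkl_path))
```
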