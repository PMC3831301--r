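# red3d — rotation electron diffraction data reduction

`red3d` turns a stack of 2D electron-diffraction frames collected by the
rotation method (RED / 3D electron diffraction / electron diffraction
tomography) into crystallographic results: a reconstructed 3D reciprocal
lattice, a refined tilt-axis orientation, unit-cell parameters, indexed
reflections and a SHELX HKLF4 intensity file ready for structure solution.
It is aimed at electron crystallographers reducing SAED/nano-diffraction
tilt series of sub-micrometre crystals (zeolites, MOFs, minerals, small
organics), and at method developers who need a fully synthetic, ground-truth
test bed for such pipelines.

## The model in brief

Each frame is the intersection of the Ewald sphere (radius $1/\lambda$,
$\lambda \approx 0.0251$ Å at 200 kV) with the crystal's reciprocal
lattice, at one combined tilt $\theta$ (goniometer + fine beam tilt). A
spot at beam-centred detector position $(x, y)$ back-projects onto the
sphere as

$$g_x = x/\mathrm{ppa},\quad g_y = y/\mathrm{ppa},\quad
  g_z = 1/\lambda - \sqrt{1/\lambda^2 - g_\perp^2},$$

and rotating by $\theta$ about the tilt axis $(\cos\varphi, \sin\varphi, 0)$
places it in the fixed reciprocal frame. Multi-frame spots of one
reflection are merged (intensity-weighted position; 3D-integrated intensity
$I = \sum_{i\ge 2} I_i\,|K_i - K_{i-1}|$), the reciprocal basis comes from
density clustering of short difference vectors, indexing walks outward in
resolution re-anchoring on indexed neighbours (tolerant of lattice bending
from a slightly wrong $\varphi$, per-axis threshold ±0.1), and intensities
export as HKLF4 with $\sigma(I) = \sqrt{I}$. The tilt-axis azimuth itself
is refined by scanning $\varphi$ and minimizing a cluster-tightness
("straightness") score of the reconstruction.

A forward simulator (`sim_config()`, `render_dataset()`) produces MRC
frames with Gaussian spots at Ewald-sphere intersections, Gaussian rocking
attenuation in excitation error, Poisson noise, flat background, 12-bit
saturation and a drifting direct beam — with full ground truth, so the
whole chain is testable without instrument data.

## Worked example

Simulate the reference experiment (monoclinic cell a = 20.02, b = 20.25,
c = 13.35 Å, β = 90.74°; tilt −60…+60° in 0.2° steps; 671 frames of
512×512 at 12 bit; Poisson noise and beam drift on) and reduce it:

```r
library(red3d)
sim <- render_dataset(sim_config(seed = 1), "ref_ds")   # ~2.5 min
res <- run_pipeline(pipeline_config("ref_ds", tilt_axis = "info"))
print(res$cell)
#> unit cell: a=20.2511 b=20.0198 c=13.3506 A  alpha=90.741 beta=90.007 gamma=90.001 deg
```

The recovered reduced basis is the true cell up to a signed axis
permutation (a↔b swapped here): matching settings, every parameter is
within 0.01% of the simulated truth (8843 of 8873 reflections indexed
within the ±0.1 threshold, Friedel R_int = 0.020 on the noisy
intensities). The run directory `ref_ds/red_out/`
contains the shift table, 2D/3D spot tables, cell report, indexed
reflection table (fractional + integer hkl, intensity, d, frame, x, y,
accepted flag), absence statistics and `reflections.hkl` (HKLF4). Refining
the axis instead of trusting the stored value:

```r
ax <- refine_tilt_axis(res$spots, res$info, scan = c(0, 180, 0.5, 0.1))
ax$azimuth
#> [1] 48.5
```

which recovers the simulator's true azimuth (48.5°) exactly at the scan
resolution. Command-line wrappers `inst/exec/red-sim` and
`inst/exec/red-process` expose the same pipeline.

The exact numbers above come from this code with seed 1 on one CPU; other
seeds move the cell errors at the 0.1% level.

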