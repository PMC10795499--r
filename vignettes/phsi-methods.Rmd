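---
title: "Full-Stokes polarized hyperspectral imaging: model, calibration and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-Stokes polarized hyperspectral imaging: model, calibration and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phsi)
```

## The measurement model

A polarized hyperspectral microscope records, at every pixel and wavelength
band, the intensity of light that has passed through a *generator*
(a linear polarizer at 45°), the sample, and an *analyzer* — two
liquid-crystal variable retarders (LCVR 1 with fast axis at 0°, LCVR 2 at
45°) followed by a horizontal linear polarizer. Setting the two retardances
$(\delta_1, \delta_2)$ to four canonical pairs turns the analyzer into a
horizontal, vertical, +45° linear, or right-circular analyzer, producing the
four *element images* $I_h, I_v, I_{45}, I_{rc}$. In Mueller calculus the
detected intensity for a sample-exit Stokes vector $S = (S_0,S_1,S_2,S_3)$
is

$$ I(\delta_1,\delta_2) = \tfrac12\left(S_0 + \cos\delta_2\, S_1
   + \sin\delta_1 \sin\delta_2\, S_2 - \cos\delta_1 \sin\delta_2\, S_3\right), $$

the first row of the analyzer's Mueller chain. The four element images then
invert to the Stokes cubes:

$$ S_0 = I_h + I_v,\quad S_1 = I_h - I_v,\quad
   S_2 = 2 I_{45} - (I_h+I_v),\quad S_3 = 2 I_{rc} - (I_h+I_v). $$

Every quantity is a data cube: two spatial dimensions (row, col; row 1 at
the image top) and one spectral dimension, by default 470–750 nm. The
instrument-resolution grid is 97 bands (`default_spectral_axis()`); package
examples and tests use a 21-band, 14-nm working grid
(`coarse_spectral_axis()`) at 64×64 pixels, which keeps every simulation in
the seconds range without changing any normalized quantity.

### The circular-analyzer sign convention

The retarder Mueller matrix has a sign freedom (equivalent to choosing which
circular handedness is "right"). `phsi` uses the convention in which a
quarter-wave retarder at fast axis 0° maps +45° linear light $(1,0,1,0)$ to
$(1,0,0,-1)$, and defines the right-circular analyzer state as
$(\delta_1, \delta_2) = (0, -\pi/2)$ — note the sign. Under the textbook
alternative $(0, +\pi/2)$ the analyzer measures $\tfrac12(S_0 - S_3)$ and
the four-image inversion above returns $-S_3$, which contradicts the
theoretical quarter-wave-plate calibration curve $S_3 = -\cos 2\theta$ in an
end-to-end simulation. The package convention is the unique choice that
makes the simulated instrument, the reconstruction formulae, and the
calibration theory mutually consistent; the physical handedness of the real
instrument cannot be pinned down from the mathematics alone, and only this
internal consistency matters for every quantity the package computes.

Likewise, the generator-before-sample / analyzer-after-sample geometry is
the only arrangement under which a rotating quarter-wave plate between them
traces those curves for 45° input light, so it is fixed in the simulator.

## Calibration

The calibration target is an ideal quarter-wave plate rotated through
$\theta = 0°,10°,\dots,180°$ (19 positions, `calibration_protocol()`). For
each position the simulator produces an element-image set; the analysis
reconstructs and S0-normalizes the Stokes cubes and spatially averages each
parameter over valid pixels — the target is uniform, so the field mean is
the natural per-angle estimate. The theoretical curves for 45° input are

$$ S_1 = \sin 2\theta \cos 2\theta,\qquad S_2 = \sin^2 2\theta,\qquad
   S_3 = -\cos 2\theta, $$

and agreement is scored per wavelength and parameter as the standard
root-mean-square error $\sqrt{\frac1N \sum_n (S^{exp}_n - S^{theory}_n)^2}$
(the mean-normalized form; a pure sum under the root would grow with the
number of sweep positions and make the conventional "< 0.2" quality bound
meaningless). Reporting wavelengths default to 470, 525 and 626 nm and snap
to the nearest band center with a warning when the working grid has no such
band.

A noiseless simulated sweep reproduces the theory to numerical precision
(RMSE ≤ 1e−10); under the default detector noise the field-averaged RMSE is
of order 1e−3 at 64×64, far inside the 0.2 bound. RMSE grows monotonically
with the noise scale, which the tests verify over four decades.

## Phantoms: what they emulate, and what they do not

Scenes are per-pixel (optionally per-band) Mueller-matrix fields, checked at
construction for passivity (no energy gain into polarization; $S_0 \ge 0$
out of physical inputs).

* **Quarter-wave-plate scene** — uniform ideal retarder; achromatic by
  default, with an optional $\delta(\lambda) = \frac{\pi}{2}\,
  \lambda_0/\lambda$ first-order dispersion model, since real waveplates and
  LCVRs are chromatic.
* **Fiber phantom** (collagen analog) — anti-aliased straight capsules;
  fiber pixels are an attenuator times a linear retarder with fast axis
  along the fiber, background pixels pure attenuators. Defaults: 24 fibers
  ("dense"; 6 for "sparse"), width 3 px, peak retardance 0.6 rad, and
  *matched* fiber/background transmittance 0.92 — the regime where fibers
  are invisible in $S_0$ and detectable only through polarization, which is
  precisely the situation the polarized channels exist to resolve. Where
  fibers overlap, the locally strongest one wins.
* **Cell phantom** (stained-cell analog) — absorbing cytoplasm and nucleus
  disks with Gaussian absorption bands peaking at 525 nm and 590 nm
  (eosin-/hematoxylin-like placements, not dye models), a small residual
  nucleus retardance (0.05 rad by default, orientation random per cell or
  fixed via `nucleus_fast_axis_deg`), and an optional fragmentation mode
  that splits each nucleus into disjoint lobes.

No quantitative tissue retardance or transmittance values are claimed: the
defaults are stylized choices at the order of magnitude that makes the
phantoms behave qualitatively like their tissue counterparts. The phantoms
deliberately omit scattering and depolarization, defocus and diffraction,
dye spectra, and spatial texture inside regions — so passing tests
demonstrate the correctness of the computational chain and the *direction*
of the contrast and significance effects, not radiometric fidelity to any
real slide.

**Noise.** The default detector model is Poisson shot noise at
`photon_scale = 1e4` expected counts per unit intensity plus Gaussian read
noise `read_sigma = 1e-3` — a generic well-behaved scientific-camera
operating point that leaves the simulated calibration comfortably under the
0.2 RMSE bound. All randomness flows through one explicit integer seed per
call (`withr::with_seed`); there is no hidden global RNG state, and a sweep
seeded once draws independent noise per angle from a single stream.

Noise propagates through the reconstruction linearly: i.i.d. noise of
standard deviation $\sigma$ on the element images yields $\sqrt2\,\sigma$ on
$S_0, S_1$ and $\sqrt6\,\sigma$ on $S_2, S_3$ (coefficient norms of the
inversion formulae); the tests check these factors empirically.

## Visualization and quantification

**RGB synthesis.** Each channel of a rendering is a per-pixel weighted sum
over bands with a non-negative response curve normalized to unit sum, so
channel values are convex combinations of (scaled) band values. The built-in
curves are raised-cosine lobes peaking at 610/540/470 nm — parametric
stand-ins with the right qualitative shape, fully overridable from a CSV;
no colorimetric accuracy is claimed. Signed cubes are mapped to $[0,1]$
before synthesis: `symmetric` (default for $S_1..S_3$; $[-a,a] \to [0,1]$
with $a = \max|x|$, zero at mid-gray), `minmax`, or `identity` (default for
$S_0$ after division by its maximum). The mode and scale constants are
recorded in the image's provenance attribute, because per-parameter
data-dependent scaling means panels are not radiometrically comparable
across parameters — a deliberate choice that maximizes within-panel
visibility.

**GLCM contrast.** Renderings are collapsed to luminance and quantized into
8 uniform levels over $[0,1]$; the co-occurrence distribution $p(i,j)$ is
accumulated over the four standard neighbor offsets (right, down, and both
diagonals — "adjacent pixels" without a preferred direction) with symmetric
counting, and contrast is $\sum_{i,j} r^2 p$ with the level difference $r$
normalized by the level range so that any image scores in $[0,1]$.
The implementation reduces to exact integer pair sums, and the tests match
it bit-for-bit against a brute-force enumeration of all pixel pairs.

**ROI spectra and group comparison.** ROI summaries report the per-band mean
and *population* standard deviation (divide by $n$ — the ROI is treated as
the complete population of its pixels) over mask ∩ valid pixels. Group
comparisons run one two-sample t test per band on per-ROI average spectra
(the ROI, e.g. one cell, is the sampling unit). Welch's unequal-variance
test is the default — the safer choice when group spread differs, as it
does between cell populations; Student's pooled test is selectable. Raw
p values are reported, with an optional Benjamini–Hochberg column; bands
where both groups are constant are undefined for the test and reported as
$p = 1$ with a note rather than dropped, so output rows always align with
the band grid. Cells selected from the same field are not independent
samples in the strict sense; the per-band test is a screening device, not a
confirmatory analysis.

## Numerical choices and degenerate inputs

* Normalization threshold: pixels with $|S_0| \le 10^{-9} \max S_0$ are
  flagged invalid (NA, excluded from all downstream statistics) rather than
  divided — degenerate pixels never become infinities, and counts of
  invalidated pixels are kept.
* Physicality violations from noise ($S_1^2+S_2^2+S_3^2 > S_0^2$) are
  retained, not clipped, and counted in the cube summary; clipping would
  bias every downstream statistic.
* ENVI cubes default to float64/BSQ and round-trip bit-exactly; TIFF pages
  are float32 mapped affinely into $[0,1]$ with the offset/scale stored in
  the JSON wavelength sidecar (32-bit TIFF storage is only defined on that
  range). Cubes stored with unsorted wavelengths are reordered ascending on
  read with a warning.
* Fibers and cells extending beyond the image are clipped, not rejected;
  empty ROIs and all-NaN cubes are rejected with explicit messages.
* Reported problem sizes: the test suite and the acceptance script use
  64×64×21-band cubes for full-pipeline runs and 8×8 or 16×16 fields for
  per-pixel oracle comparisons; all conclusions are scale-free because they
  concern normalized quantities.

## Limitations

The simulator is an ideal-element model: polarizers are perfect, retarders
achromatic unless the dispersion model is enabled, and the detector adds
only shot and read noise. It validates the processing chain and supports
method studies (noise sensitivity, protocol design, statistic behavior); it
does not substitute for measured instrument calibration, and none of the
phantom defaults should be read as tissue constants.
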