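# phsi — polarized hyperspectral imaging simulation and Stokes analysis

`phsi` is an R toolkit for **full-Stokes polarized hyperspectral microscopy
(PHSI)**, the imaging mode used to make birefringent tissue components —
above all collagen fibers — visible on stained pathology slides where an
ordinary brightfield (intensity-only) image shows almost nothing. It is
aimed at researchers building or validating dual-LCVR polarimetric
microscopes and at analysts processing the four-cube acquisitions such
instruments produce.

The package covers the whole computational chain:

* **Mueller-calculus simulator** of the optical train: a 45° generator
  polarizer, the sample (a per-pixel field of 4×4 Mueller matrices), and the
  analyzer made of two liquid-crystal variable retarders (LCVR 1 at 0°,
  LCVR 2 at 45°) followed by a horizontal polarizer. Built-in phantoms:
  a rotating quarter-wave plate (calibration target), birefringent fiber
  fields (collagen analog) and absorbing cell fields (stained-cell analog),
  with seeded Poisson–Gaussian detector noise.
* **Stokes reconstruction** from the four analyzer element images
  (Ih, Iv, I45, Irc), per pixel and band:

      S0 = Ih + Iv
      S1 = Ih − Iv
      S2 = 2·I45 − (Ih + Iv)
      S3 = 2·Irc − (Ih + Iv)

  with S0-normalization and masking of degenerate pixels.
* **Quarter-wave-plate calibration**: sweep the plate's fast axis θ over
  0–180° in 10° steps; for 45°-polarized input the normalized parameters
  must follow `S1 = sin2θ·cos2θ`, `S2 = sin²2θ`, `S3 = −cos2θ`, and the
  per-wavelength agreement is scored as `RMSE = sqrt(mean((exp − theory)²))`.
* **Synthetic RGB rendering** of any Stokes parameter cube through R/G/B
  spectral response curves, **GLCM contrast** `Σ r(i,j)² p(i,j)` of the
  renderings, **masked ROI spectral summaries**, and **per-band two-sample
  t tests** between groups of ROI spectra.
* ENVI / multi-page TIFF cube I/O, PNG masks, YAML run configs, and a
  `phsi` command-line interface (`inst/scripts/phsi`) with subcommands
  `simulate`, `stokes`, `calibrate`, `rgb`, `contrast`, `spectra`, `ttest`.

## Worked example

Simulate a full noisy calibration sweep, score it, then quantify how much a
matched-transmittance fiber phantom (invisible in intensity) stands out in
the polarized channels:

```r
library(phsi)
axis <- coarse_spectral_axis()            # 470–750 nm, 21 bands

protocol <- calibration_protocol()        # 0–180° by 10°; report 470/525/626 nm
sweep <- simulate_qwp_sweep(protocol, shape = c(64, 64), axis = axis,
                            noise = noise_spec(), seed = 1)
cal <- run_calibration(sweep, protocol)
print(cal)
#> <phsi_calibration> quarter-wave-plate sweep, 19 angles
#>  wavelength_nm parameter         rmse
#>            470        S1 0.0004208861
#>            526        S1 0.0003632900
#>            624        S1 0.0002705904
#>            470        S2 0.0013964287
#>            526        S2 0.0009883766
#>            624        S2 0.0009902028
#>            470        S3 0.0011442549
#>            526        S3 0.0008100886
#>            624        S3 0.0007146978

scn <- make_fiber_scene(fiber_phantom_params(), c(64, 64), axis, seed = 1)
st  <- normalize_stokes(compute_stokes(
         simulate_acquisition(scn, noise = noise_spec(seed = 1))))
for (p in c("s0", "s1", "s2", "s3")) {
  img <- synthesize_rgb(st, parameter = p)
  cat(sprintf("GLCM contrast of the %s rendering: %.3f\n", toupper(p),
              glcm_contrast(rgb_to_gray(img))))
}
#> GLCM contrast of the S0 rendering: 0.000
#> GLCM contrast of the S1 rendering: 0.016
#> GLCM contrast of the S2 rendering: 0.007
#> GLCM contrast of the S3 rendering: 0.030
```

All nine calibration RMSE values sit far below the 0.2 acceptance bound a
well-aligned instrument is expected to meet (reporting wavelengths snap to
the nearest band center of the 14 nm working grid, hence 526/624 nm). The
fibers carry the same transmittance as the background, so the S0 rendering
is featureless (contrast ≈ 0) while S1–S3 reveal them — the polarized
channels add contrast that total intensity cannot.

The same pipeline is available from the shell:

```sh
phsi simulate --phantom qwp --angle 30 --noise none -o run/
phsi stokes run/ -o stokes/            # normalized S3 ≈ −0.5 everywhere
```

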