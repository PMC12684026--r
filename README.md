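# dopmtools

Computational toolkit for **dual-view oblique plane microscopy (dOPM)** of
cleared tissue. A dOPM acquires light-sheet volumes of a sample through a
single primary objective by imaging a tilted plane through a
remote-refocusing relay; a translated mirror pair sweeps the plane through
the sample and yields two oblique views at ±45° that are deskewed,
registered and fused. This package implements, in R:

* **Optical calculators** for the remote-refocusing detection path:
  index-matching relay magnification *M*<sub>RF</sub> = *n*<sub>s</sub>/*n*<sub>r</sub>,
  overall magnification *M* = *M*<sub>RF</sub>·*M*<sub>3</sub>, effective
  pixel size, correction-collar magnification/focal-shift response,
  predicted remote-mirror travel, the collection NA of the overlapping
  tilted objective cones (latitudinal and longitudinal components), and
  diffraction-limited FWHM estimates 0.51 λ/NA.
* A **synthetic bead-phantom simulator**: seeded fields of sub-resolution
  beads rendered as two ±45° oblique acquisitions with a swept Gaussian
  light sheet, a two-component (diffraction core + optical-sectioning halo)
  bead image model, Poisson + read noise, and an optional depth-dependent
  aberration broadening that emulates refractive-index mismatch.
* **Reconstruction geometry**: exact affine acquisition-to-world mapping,
  deskew/reslice for remote-refocus and stage scanning (Catmull-Rom or
  trilinear), voxel binning, validity masks.
* **Registration and fusion**: bead-based mutual-nearest-neighbour
  matching, similarity/affine least-squares estimation, mean or max
  blending, and the dual-view overlap mask.
* A **bead-PSF quantification pipeline**: detection with QC flags
  (doublet/edge/saturated), cuboid extraction, 1D Gaussian fits of the
  X/Y/Z line profiles and the laterally-integrated axial (Z*) profile,
  FWHM conversion, median ± IQR summaries, and 3D/2D spatial resolution
  maps.

See `vignettes/dopm-methods.Rmd` for the models, conventions and design
decisions.

## Worked example

```r
library(dopmtools)

# the instrument's derived optical quantities
opticsReport(OpticalConfig(), CCModel())
#>                              quantity      value unit
#> 1  index-matching relay magnification  1.4060000
#> 2               overall magnification 31.7559900
#> 3                effective pixel size  0.2046858   um
#> 4                      latitudinal NA  1.0697540   NA
#> 5                     longitudinal NA  0.7244192   NA
#> 6        diffraction-limited FWHM (x)  0.2502912   um
#> 7        diffraction-limited FWHM (y)  0.3696064   um
#> ...

# simulate a small two-view phantom and quantify the bead images
spec <- PhantomSpec(extent_um = c(70, 60, 35), n_beads = 40L)
res  <- runPipeline(RunConfig(phantom = spec, seed = 11L))
res$summary
#>          metric    median         iqr  n
#> 1     fwhm_x_um 0.4961656 0.006095040 14
#> 2     fwhm_y_um 0.6139823 0.008321241 14
#> 3     fwhm_z_um 1.2578131 0.008984759 14
#> 4 fwhm_zstar_um 3.4653348 0.031429074 14
```

The summary is the standard "median ± IQR (n)" bead report: the fused
volume's bead images have lateral FWHMs of ≈0.50 and 0.61 µm, an axial
FWHM of ≈1.26 µm, and a laterally-integrated (optical sectioning, Z*)
FWHM of ≈3.47 µm — recovering this phantom's generative image widths
(0.49 / 0.60 / 1.23 µm) and its 3.5 µm light-sheet thickness to within a
few percent. `runPipeline()` also writes `beads.csv` (per-bead
measurements with QC flags), `summary.json`, `transform.json` (the fitted
view-2→view-1 registration) and `pipeline.log` to the configured output
directory.

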