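---
title: "Models and methods behind dopmtools"
author: "dopmtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dopmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopmtools)
```

# Scope

`dopmtools` implements the computational backbone of a dual-view oblique
plane microscope (dOPM) for cleared tissue: closed-form optical calculators
for the remote-refocusing detection path, a synthetic bead-phantom
acquisition simulator, reconstruction of the sheared oblique stacks into
orthogonal world coordinates, bead-based registration and fusion of the two
views, and an automated bead-PSF / optical-sectioning quantification
pipeline. This vignette records the models, the coordinate conventions, the
numerical choices, and the reasoning behind the design decisions that were
genuinely open.

# Optical calculators

**Remote refocusing.** An aberration-free remote-refocusing relay must have
lateral (and axial) magnification equal to the ratio of sample to
remote-space refractive indices, $M_{RF} = n_s / n_r$. For a silicone-oil
matched sample ($n_s = 1.406$) imaged into air this gives
`remoteRefocusMagnification(1.406, 1) = 1.406`. The overall system
magnification is the product $M = M_{RF} \cdot M_3$ of the relay and the
third (camera-facing) microscope, and the effective sample-space pixel is
the camera pitch divided by $M$.

**Collection NA of two tilted cones.** With the secondary/tertiary
objective tilted by $\tau$ relative to the primary axis, the detected light
is the overlap of two collection cones. Writing
$\alpha_1 = \arcsin(\mathrm{NA}_1/n_s)$ and
$\alpha_3 = \arcsin(\mathrm{NA}_3/n_r)$, the package computes:

* the **longitudinal** component (in the tilt plane) from the intersection
  of the angular intervals $[-\alpha_1, \alpha_1]$ and
  $[\tau - \alpha_3, \tau + \alpha_3]$, reported as
  $n_s (\sin\theta_{max} - \sin\theta_{min}) / 2$;
* the **latitudinal** component (perpendicular to the tilt plane) as the
  maximum half-height of the intersection, in sample-side sine space, of
  the primary pupil disc (radius $\mathrm{NA}_1$ at the origin) with the
  tilted pupil disc (radius $n_s \sin\alpha_3$ centred at
  $(n_s \sin\tau, 0)$).

This hybrid construction — an interval rule in the tilt plane, a disc rule
across it — is the simplest pair of conventions that reduces correctly in
the untilted limit and captures the asymmetry of the tilted geometry. An
empty angular overlap means no ray is collected by both objectives, so
both components are then zero. A brute-force oracle that rasterizes the
pupil regions on a $2000 \times 2000$ sine-space grid agrees with the
closed forms to better than 0.005 NA across random configurations (see the
test suite).

**Diffraction limit.** Lateral FWHM is estimated as
$0.51\,\lambda/\mathrm{NA}$. The 0.51 coefficient is the standard
widefield FWHM prefactor; applied to the two overlap NAs it yields the
instrument's anisotropic lateral resolution estimates.

**Correction collar.** The collar response is modelled linearly and
symmetrically about the nominal position: the widefield magnification
changes by a configurable total fraction (default 1.5%) and the focal
plane shifts by a configurable total travel (default 26 µm) across the
collar range (default 0.11–0.23, nominal 0.17). Linearity is part of the
model; the absolute collar end-stops are not modelled beyond the explored
range. The predicted remote-mirror translation for a sample-space defocus
$\delta$ is $M_{RF}\,\delta$; whether the folded double-pass geometry
contributes an additional factor is instrument-specific, so the factor is
exposed as `fold_factor` (default 1).

# Coordinate conventions

All lengths are micrometres. Voxel indices are 0-based with voxel-centre
sampling. The coverslip is the plane $z = 0$ with $+z$ into the sample.
Stack voxel $(n, r, c)$ (frame, row, column) of view $v$ maps to world

$$x = c\,p,\qquad y = \sigma_{sweep}\, n\, s + s_v\, r\, p \cos\tau,\qquad
  z = r\, p \sin\tau,$$

with pixel $p$, sweep step $s$, $s_v = +1$ for view 1 and $-1$ for view 2,
and $\sigma_{sweep} = -1$ for stage scanning (the sample moves under a
static sheet). The mapping is exactly affine; deskewing inverts it and
resamples onto a regular world grid. With the sweep starting at frame 0,
view 1's footprint covers the half-space $y \ge z$ and view 2's covers
$y + z \le$ sweep length; their intersection is the overlap
parallelepiped to which all dual-view analysis is restricted.

**Interpolation.** Deskew and fusion default to separable Catmull-Rom
cubic interpolation. Trilinear interpolation is retained as an option and
is used by the mass-conservation tests (its weights sum exactly to one on
matched grids), but it measurably broadens structures sampled near the
Nyquist limit: reconstructing a 0.60 µm FWHM Gaussian sampled at 0.25 µm
broadens its fitted width by about 12% under trilinear interpolation and
by about 3% under Catmull-Rom. Out-of-footprint voxels carry an explicit
validity mask rather than a sentinel value, and mask transport during
fusion is conservative (a resampled voxel is valid only if its whole
support was valid), so masked analysis can never touch partially
supported voxels at the cost of a one-voxel border.

# The bead-phantom simulator

The simulator emulates the refractive-index-tuned bead phantoms used to
characterize the instrument: sub-resolution (170 nm) fluorescent beads at
uniform random positions, imaged at 0.205 µm sample-space pixels through a
3.5 µm FWHM light sheet at 45°, with the zero-remote-refocus plane 150 µm
beyond the coverslip.

**Bead image model.** Each bead contributes a two-component image,
expressed directly in world coordinates:

$$I(\Delta) = \frac{A}{a}\Big[
  \underbrace{e^{-\Delta_x^2/2\sigma_x^2 - \Delta_y^2/2\sigma_y^2 -
  \Delta_z^2/2(a\sigma_z)^2}}_{\text{diffraction core}} +
  \underbrace{\tfrac{\sigma_x\sigma_y}{\sigma_h^2}
  e^{-(\Delta_x^2+\Delta_y^2)/2\sigma_h^2}
  \big(\kappa\, e^{-\Delta_z^2/2(a\sigma_*)^2} -
       e^{-\Delta_z^2/2(a\sigma_z)^2}\big)}_{\text{sectioning halo}}
  \Big]$$

The core widths are the generative image FWHMs — the detection PSF with
the finite bead size folded in by Gaussian quadrature using the
projected-sphere FWHM $0.866\,d$ — and $\sigma_*$ is the light-sheet
sigma. The halo represents the optical-sectioning energy: the light that a
defocused, sheet-gated detection still collects, spread over a lateral
scale $\sigma_h$. Its axial profile is constructed so that the
*laterally-integrated* axial profile of the full image is exactly a
Gaussian of FWHM equal to the sheet thickness (times the halo energy
factor $\kappa$ in total energy), while the *central* axial line profile
remains core-dominated. This is the defining property of the model: a
separable single-Gaussian bead image cannot reproduce the observed
relationship in which the Z* (laterally-summed) FWHM tracks the sheet
thickness (µm-scale) while the central Z FWHM is an order of magnitude
smaller — any multiplicative axial factor bounds the integrated width from
above by the central width. Physically, the isotropic halo is what a
sheet-excited, per-plane energy-conserving defocus cone at 45° reduces to
when its lateral spread matches the sheet sigma.

The constants $\sigma_h = 1.6$ µm and $\kappa = 1.2$ were fixed from a
noise-free design study of the measurement operator (Gaussian fits with
offset on sampled profiles): they keep the analytic fit biases at
+0.3% (X, Y), +2.0% (Z) and −1.1% (Z*) for the default widths, with the
halo vanishing on the focal plane so the lateral line profiles stay pure.

**Depth-dependent aberration.** Refractive-index mismatch is modelled
phenomenologically: the axial widths of core and halo are multiplied by
$a(z) = 1 + \kappa_{mis}\,|z - z_{focus}|$ and the amplitude divided by
$a$, so the integrated signal is conserved while the axial response
broadens linearly with remote-refocus distance. This reproduces the
*trend* of mismatch-induced degradation, not its wave-optics detail;
spherical-aberration sign reversal, sidelobes and lateral coma are outside
the model.

**Sampling and noise.** Views are rendered by evaluating the model at the
world position of every stack voxel (no intermediate dense world volume;
each bead touches only its local support). The default sweep step is
0.2 µm: sampling analysis shows the narrowest reconstructed lateral
feature (0.60 µm FWHM along y) then suffers under 2% interpolation
broadening, whereas a 0.5 µm step aliases it outright. Poisson shot noise
is applied to signal plus a uniform 10-photon background, followed by
Gaussian read noise (sd 2) and clamping at zero. The background default
matters: with a zero baseline, zero-clamping of read noise creates a
signal-dependent pedestal that measurably narrows the laterally-summed Z*
profile; a 10-photon baseline (sample autofluorescence plus detector
offset, both standard) keeps the clipped camera model linear. Bead
brightness is log-normal with CV 0.2 about a 2000-photon peak, a typical
bead-to-bead variability. The geometry substream (positions, brightness)
and the per-view noise substreams derive deterministically from one seed,
so geometry is reproducible independently of noise settings.

# Registration and fusion

The two deskewed views share the world frame by construction, so
registration only refines residual calibration error. Bead centres are
detected independently per view, paired by mutual nearest neighbours
within a radius (greedy by distance, one-to-one), and the transform
minimising $\sum \|M a_i + t - b_i\|^2$ is fitted — by default a
similarity transform (rotation, isotropic scale, translation; the
SVD/Umeyama construction), since that is the physical relation between the
views; a full 12-parameter affine is available to absorb calibration
error. Fusion resamples view 2 onto view 1's grid through the fitted
transform and blends by unweighted mean (maximum-intensity blending is
available for stitching parity); the overlap mask is the exact
intersection of the transported validity masks. A stored transform can be
re-applied to other channels rather than re-fitted, mirroring how
multi-channel acquisitions duplicate one channel's alignment.

# PSF and optical-sectioning quantification

The measurement pipeline mirrors automated bead-PSF quantification
practice:

1. **Detection**: 26-neighbour local maxima above a relative threshold
   (default 0.2) of the robust volume maximum (the $1-10^{-5}$ quantile of
   valid voxels — bead-peak scale, hot-pixel resistant), restricted to the
   analysis mask.
2. **QC flags**: candidates closer than `min_sep_um` (default 3 µm) are
   `doublet`; candidates whose extraction cuboid would leave the valid
   region are `edge`; clipped plateaus are `saturated`.
3. **Extraction**: an axis-aligned cuboid of half-size 4 µm lateral × 5 µm
   axial around each candidate. The lateral half-size must capture the
   sectioning halo (≥ 2.5 halo sigmas), or the truncation-leaked core
   dominates the integrated profile; 4 µm keeps the halo capture above
   95% while staying small against typical bead separations.
4. **Fitting**: 1D Gaussians with offset, by Levenberg–Marquardt with
   baseline-robust moment initialisation, to the single-voxel x, y and z
   line profiles through the intensity-weighted centre voxel and to the
   laterally-integrated (Z*) axial profile. Sub-voxel localisation comes
   from the fitted centres, not from profile resampling. Fits that fail to
   converge, return $\sigma$ below half the sample spacing, or have
   $R^2 < 0.9$ on any axis flag the bead `poor_fit`.
5. **Summaries**: median ± IQR (quartiles by linear interpolation of order
   statistics) over accepted beads, the field's standard
   "median ± IQR (n)" report; spatial binning into 3D resolution maps
   (default 32 × 32 × 60 µm bins, i.e. 15 × 10 × 5 bins over a
   480 × 320 × 300 µm region, with a depth-collapsed 16 µm 2D variant)
   with empty bins as `NA`. Flagged beads are excluded *before* binning.

# What the simulator does and does not establish

Passing the recovery tests shows that the reconstruction and measurement
chain is unbiased to within a few percent *for data generated by the
package's own image model*: Gaussian cores, an analytic sectioning halo,
Poisson-plus-read noise, a rigid two-view geometry. Real acquisitions add
effects deliberately outside the model — wave-optics sidelobes and
aberration asymmetry, sheet-profile imperfections and stripe artefacts,
scattering, drift and stage jitter, chromatic offsets — so recovered
accuracy on the phantom is a necessary, not sufficient, condition for
accuracy on real data. The optics calculators, by contrast, are
closed-form statements about the instrument geometry and carry no such
caveat.

# Problem sizes used by the shipped experiments

The recovery experiment simulates 450 beads in a 120 × 80 × 45 µm volume
(bead density of the same order as the instrument characterization, kept
at a volume where the two-view pipeline runs in minutes on one CPU);
recovered medians over the accepted beads (typically 100–200) are required to lie
within 5% of the generative values. The depth-behaviour experiments use a
16 × 24 × 260 µm column of 100 beads characterized on view 2 (whose
footprint contains a deep column), testing a < 0.001 µm/µm slope of
Z-FWHM against depth for the matched case and a Spearman correlation
above 0.9 of Z-FWHM with refocus distance for a mismatch coefficient of
0.005 /µm. These sizes are the package's chosen study scale; the model and
pipeline are size-agnostic.

# Known limitations

* The bead image model is Gaussian; it has no sidelobes, no aberration
  asymmetry, and its mismatch model broadens only the axial widths.
* The linear correction-collar model extrapolates nothing beyond the
  explored collar range, and the collar cannot be optimised in closed
  loop.
* Registration assumes enough well-separated beads for mutual
  nearest-neighbour matching; it has no intensity-based fallback.
* Multi-tile stitching is limited to pairwise maximum-intensity blending
  of pre-placed volumes; there is no global tile optimisation.
* Float TIFF output round-trips at single precision (values are stored
  scaled into [0, 1] by a power of two recorded in the sidecar); 16-bit
  integer output is exact.
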