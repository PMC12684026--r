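#' Optical configuration of the dOPM detection path
#'
#' Holds the optical constants of the primary objective (O1), the remote
#' refocusing relay and the tilted secondary/tertiary objective (O2/3) that
#' the calculators in this package operate on. Numerical apertures are quoted
#' in each objective's own immersion medium: `na_primary` in the sample-side
#' medium of index `n_immersion`, `na_secondary` in the remote image space of
#' index `n_remote` (air, so `na_secondary <= 1` is typical but not enforced
#' against `n_immersion`).
#'
#' @slot na_primary numeric(1). NA of the primary objective O1.
#' @slot n_immersion numeric(1). Refractive index of O1's design/immersion
#'   medium.
#' @slot n_sample numeric(1). Refractive index of the sample medium.
#' @slot na_secondary numeric(1). NA of O2/3 in its own (remote) medium.
#' @slot n_remote numeric(1). Refractive index of remote image space (air: 1).
#' @slot tilt_deg numeric(1). Angle in degrees between the O2/3 optical axis
#'   and the primary optical axis (design value 45).
#' @slot m_rf numeric(1). Lateral magnification of the remote refocusing relay
#'   (O1, TL1, TL2, O2).
#' @slot m3 numeric(1). Magnification of the third microscope relay (O2/3,
#'   TL3).
#' @slot camera_pitch_um numeric(1). Physical camera pixel pitch in um.
#' @slot wavelength_nm numeric(1). Emission wavelength in nm.
#' @export
setClass("OpticalConfig",
  representation(
    na_primary = "numeric", n_immersion = "numeric", n_sample = "numeric",
    na_secondary = "numeric", n_remote = "numeric", tilt_deg = "numeric",
    m_rf = "numeric", m3 = "numeric", camera_pitch_um = "numeric",
    wavelength_nm = "numeric"))

setValidity("OpticalConfig", function(object) {
  msg <- character()
  sc1 <- function(x, nm) if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)))
    sprintf("'%s' must be a finite scalar", x) else NULL
  for (nm in slotNames(object)) {
    m <- sc1(nm); if (!is.null(m)) msg <- c(msg, m)
  }
  if (length(msg)) return(msg)
  if (object@na_primary <= 0 || object@na_primary > object@n_immersion)
    msg <- c(msg, "'na_primary' must satisfy 0 < na_primary <= n_immersion")
  if (object@na_secondary <= 0)
    msg <- c(msg, "'na_secondary' must be > 0")
  if (object@n_sample <= 0 || object@n_remote <= 0 || object@n_immersion <= 0)
    msg <- c(msg, "refractive indices must be > 0")
  if (object@tilt_deg < 0 || object@tilt_deg >= 90)
    msg <- c(msg, "'tilt_deg' must be in [0, 90)")
  if (object@m_rf <= 0 || object@m3 <= 0)
    msg <- c(msg, "magnifications must be > 0")
  if (object@camera_pitch_um <= 0 || object@wavelength_nm <= 0)
    msg <- c(msg, "'camera_pitch_um' and 'wavelength_nm' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an OpticalConfig
#'
#' Defaults describe a silicone-immersion 1.25 NA primary objective imaging a
#' refractive-index matched sample (n = 1.406), relayed at the
#' index-matching magnification into air and detected through a 0.8 NA air
#' objective tilted by 45 degrees.
#'
#' @param na_primary NA of O1.
#' @param n_immersion refractive index of O1 immersion medium.
#' @param n_sample refractive index of the sample medium.
#' @param na_secondary NA of O2/3 in its own medium.
#' @param n_remote refractive index of remote image space.
#' @param tilt_deg tilt of O2/3 axis in degrees.
#' @param m_rf lateral magnification of the remote refocusing relay.
#' @param m3 magnification of the third microscope relay.
#' @param camera_pitch_um camera pixel pitch in um.
#' @param wavelength_nm emission wavelength in nm.
#' @return An [OpticalConfig-class] object.
#' @examples
#' cfg <- OpticalConfig()
#' collectionNA(cfg)
#' @export
OpticalConfig <- function(na_primary = 1.25, n_immersion = 1.406,
                          n_sample = 1.406, na_secondary = 0.8,
                          n_remote = 1.0, tilt_deg = 45,
                          m_rf = 1.407, m3 = 22.57,
                          camera_pitch_um = 6.5, wavelength_nm = 525) {
  new("OpticalConfig", na_primary = na_primary, n_immersion = n_immersion,
      n_sample = n_sample, na_secondary = na_secondary, n_remote = n_remote,
      tilt_deg = tilt_deg, m_rf = m_rf, m3 = m3,
      camera_pitch_um = camera_pitch_um, wavelength_nm = wavelength_nm)
}

#' Correction-collar response model
#'
#' Linear model of how adjusting the correction collar (CC) of the primary
#' objective changes the widefield magnification and shifts the focal plane.
#' The total spans are distributed linearly and symmetrically about the
#' nominal collar position.
#'
#' @slot cc_nominal numeric(1). Nominal (design) collar position.
#' @slot cc_min,cc_max numeric(1). Collar travel limits used by the model.
#' @slot mag_fractional_span numeric(1). Total fractional widefield
#'   magnification change across the full collar range.
#' @slot focal_shift_span_um numeric(1). Total focal-plane shift in um across
#'   the full collar range.
#' @export
setClass("CCModel",
  representation(cc_nominal = "numeric", cc_min = "numeric",
                 cc_max = "numeric", mag_fractional_span = "numeric",
                 focal_shift_span_um = "numeric"))

setValidity("CCModel", function(object) {
  msg <- character()
  if (!(object@cc_min < object@cc_nominal && object@cc_nominal < object@cc_max))
    msg <- c(msg, "'cc_nominal' must lie strictly between 'cc_min' and 'cc_max'")
  if (object@mag_fractional_span < 0)
    msg <- c(msg, "'mag_fractional_span' must be >= 0")
  if (object@focal_shift_span_um < 0)
    msg <- c(msg, "'focal_shift_span_um' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CCModel
#'
#' Defaults: nominal collar position 0.17, explored range 0.11-0.23, a 1.5%
#' total magnification span and a 26 um total focal shift.
#'
#' @param cc_nominal nominal collar position.
#' @param cc_min,cc_max collar range limits.
#' @param mag_fractional_span total fractional magnification change across
#'   the range.
#' @param focal_shift_span_um total focal shift in um across the range.
#' @return A [CCModel-class] object.
#' @export
CCModel <- function(cc_nominal = 0.17, cc_min = 0.11, cc_max = 0.23,
                    mag_fractional_span = 0.015, focal_shift_span_um = 26) {
  new("CCModel", cc_nominal = cc_nominal, cc_min = cc_min, cc_max = cc_max,
      mag_fractional_span = mag_fractional_span,
      focal_shift_span_um = focal_shift_span_um)
}

#' Specification of a synthetic bead phantom and its acquisition
#'
#' Describes a field of sub-resolution fluorescent beads in an
#' index-matched medium and the oblique-plane acquisition geometry used to
#' image it. The bead image model is a two-component Gaussian: a diffraction
#' core whose full-widths at half-maximum (after folding in the finite bead
#' size) are the generative image FWHMs, plus an isotropic optical-sectioning
#' halo of width set by the light-sheet thickness, which carries the
#' laterally-integrated (Z*) energy. See the methods vignette for the model.
#'
#' @slot extent_um numeric(3). World extent (x, y, z) of the phantom in um.
#' @slot n_beads integer(1). Number of beads.
#' @slot bead_diameter_um numeric(1). Physical bead diameter in um.
#' @slot psf_fwhm_um numeric(3). Detection-PSF FWHM (x, y, z) at focus, um.
#' @slot sheet_fwhm_um numeric(1). Light-sheet axial FWHM in um.
#' @slot pixel_um numeric(1). In-plane camera pixel size in sample space, um.
#' @slot scan_step_um numeric(1). Sweep displacement per frame along world y.
#' @slot tilt_deg numeric(1). Oblique-plane tilt in degrees.
#' @slot focus_depth_um numeric(1). Depth of the zero-remote-refocus plane
#'   beyond the coverslip, um.
#' @slot mismatch_coeff numeric(1). Phenomenological refractive-index-mismatch
#'   aberration coefficient (1/um); 0 means matched.
#' @slot intensity_mean numeric(1). Mean peak signal per bead, photons.
#' @slot intensity_cv numeric(1). Coefficient of variation of bead
#'   brightness (log-normal).
#' @slot read_noise_sd numeric(1). Gaussian camera read noise, counts.
#' @slot background numeric(1). Uniform background level, photons.
#' @slot halo_sigma_um numeric(1). Lateral sigma of the sectioning halo, um.
#' @slot halo_energy_factor numeric(1). Energy factor (>= 1) scaling the
#'   sectioning halo relative to the minimum positive-definite halo.
#' @slot seed integer(1). Base RNG seed for the phantom.
#' @export
setClass("PhantomSpec",
  representation(
    extent_um = "numeric", n_beads = "integer", bead_diameter_um = "numeric",
    psf_fwhm_um = "numeric", sheet_fwhm_um = "numeric", pixel_um = "numeric",
    scan_step_um = "numeric", tilt_deg = "numeric", focus_depth_um = "numeric",
    mismatch_coeff = "numeric", intensity_mean = "numeric",
    intensity_cv = "numeric", read_noise_sd = "numeric",
    background = "numeric", halo_sigma_um = "numeric",
    halo_energy_factor = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@extent_um) != 3L || any(object@extent_um <= 0))
    msg <- c(msg, "'extent_um' must be 3 positive lengths")
  if (object@n_beads < 0L) msg <- c(msg, "'n_beads' must be >= 0")
  if (length(object@psf_fwhm_um) != 3L || any(object@psf_fwhm_um <= 0))
    msg <- c(msg, "'psf_fwhm_um' must be 3 positive lengths")
  for (nm in c("bead_diameter_um", "sheet_fwhm_um", "pixel_um",
               "scan_step_um", "intensity_mean", "halo_sigma_um"))
    if (slot(object, nm) <= 0) msg <- c(msg, sprintf("'%s' must be > 0", nm))
  if (object@mismatch_coeff < 0) msg <- c(msg, "'mismatch_coeff' must be >= 0")
  if (object@halo_energy_factor < 1)
    msg <- c(msg, "'halo_energy_factor' must be >= 1")
  if (object@read_noise_sd < 0 || object@background < 0 ||
      object@intensity_cv < 0)
    msg <- c(msg, "noise and background parameters must be >= 0")
  if (object@tilt_deg <= 0 || object@tilt_deg >= 90)
    msg <- c(msg, "'tilt_deg' must be in (0, 90)")
  if (object@focus_depth_um < 0) msg <- c(msg, "'focus_depth_um' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults emulate the refractive-index matched bead phantom study
#' conditions: 170 nm beads at 0.205 um sample-space pixels, a 3.5 um FWHM
#' light sheet, 45 degree tilt, detection-PSF FWHMs chosen so that the bead
#' image FWHMs (bead size folded in by Gaussian quadrature) are
#' 0.49 / 0.60 / 1.23 um in x / y / z, and the zero-refocus plane 150 um
#' beyond the coverslip. The default sweep step of 0.2 um keeps the
#' interpolation broadening of the narrowest reconstructed lateral feature
#' (0.60 um FWHM along y) below 2 percent, and the default background of 10
#' photons keeps the zero-clipped camera model linear; see the methods
#' vignette.
#'
#' @param extent_um world extent (x, y, z) in um.
#' @param n_beads number of beads.
#' @param bead_diameter_um bead diameter in um.
#' @param psf_fwhm_um detection-PSF FWHM (x, y, z) at focus, um.
#' @param sheet_fwhm_um light-sheet axial FWHM, um.
#' @param pixel_um in-plane pixel size in sample space, um.
#' @param scan_step_um sweep step per frame along world y, um.
#' @param tilt_deg oblique-plane tilt in degrees.
#' @param focus_depth_um depth of the zero-remote-refocus plane, um.
#' @param mismatch_coeff aberration coefficient (1/um), 0 = matched.
#' @param intensity_mean mean peak photons per bead.
#' @param intensity_cv coefficient of variation of bead brightness.
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @param background uniform background, photons.
#' @param halo_sigma_um lateral sigma of the sectioning halo, um.
#' @param halo_energy_factor halo energy factor (>= 1).
#' @param seed base RNG seed.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(extent_um = c(40, 30, 20), n_beads = 5L)
#' beadImageFwhm(spec)
#' @export
PhantomSpec <- function(extent_um = c(480, 320, 300), n_beads = 4316L,
                        bead_diameter_um = 0.17,
                        psf_fwhm_um = c(0.4674, 0.5817, 1.2212),
                        sheet_fwhm_um = 3.5, pixel_um = 0.205,
                        scan_step_um = 0.2, tilt_deg = 45,
                        focus_depth_um = 150, mismatch_coeff = 0,
                        intensity_mean = 2000, intensity_cv = 0.2,
                        read_noise_sd = 2, background = 10,
                        halo_sigma_um = 1.6, halo_energy_factor = 1.2,
                        seed = 1L) {
  new("PhantomSpec", extent_um = as.numeric(extent_um),
      n_beads = as.integer(n_beads), bead_diameter_um = bead_diameter_um,
      psf_fwhm_um = as.numeric(psf_fwhm_um), sheet_fwhm_um = sheet_fwhm_um,
      pixel_um = pixel_um, scan_step_um = scan_step_um, tilt_deg = tilt_deg,
      focus_depth_um = focus_depth_um, mismatch_coeff = mismatch_coeff,
      intensity_mean = intensity_mean, intensity_cv = intensity_cv,
      read_noise_sd = read_noise_sd, background = background,
      halo_sigma_um = halo_sigma_um, halo_energy_factor = halo_energy_factor,
      seed = as.integer(seed))
}

#' Ground-truth bead field
#'
#' Bead positions in the world frame (coverslip at z = 0, +z into the
#' sample) and per-bead peak amplitudes.
#'
#' @slot positions_um matrix with one row per bead, columns (x, y, z) in um.
#' @slot intensities numeric. Per-bead peak amplitudes (photons).
#' @export
setClass("GroundTruth",
  representation(positions_um = "matrix", intensities = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (ncol(object@positions_um) != 3L)
    msg <- c(msg, "'positions_um' must have 3 columns (x, y, z)")
  if (nrow(object@positions_um) != length(object@intensities))
    msg <- c(msg, "one intensity per bead required")
  if (length(object@intensities) && any(object@intensities <= 0))
    msg <- c(msg, "intensities must be > 0")
  if (length(msg)) msg else TRUE
})

#' Raw sheared oblique-plane acquisition
#'
#' A stack of camera frames acquired while sweeping the light sheet (or the
#' sample, for stage scanning) along world y. Voxels are indexed
#' `[frame, row, column]`; rows run up the tilted detection plane and columns
#' along world x.
#'
#' @slot voxels 3D numeric array `[frame, row, column]`.
#' @slot pixel_um numeric(1). In-plane sample-space pixel (rows and columns).
#' @slot scan_step_um numeric(1). Sweep displacement per frame along world y.
#' @slot tilt_deg numeric(1). Plane tilt in degrees.
#' @slot view_id integer(1). 1 (+tilt) or 2 (-tilt).
#' @slot scan_mode character(1). `"remote"` or `"stage"`.
#' @export
setClass("ObliqueStack",
  representation(voxels = "array", pixel_um = "numeric",
                 scan_step_um = "numeric", tilt_deg = "numeric",
                 view_id = "integer", scan_mode = "character"))

setValidity("ObliqueStack", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array [frame, row, column]")
  if (object@pixel_um <= 0) msg <- c(msg, "'pixel_um' must be > 0")
  if (object@scan_step_um <= 0) msg <- c(msg, "'scan_step_um' must be > 0")
  if (!object@view_id %in% c(1L, 2L)) msg <- c(msg, "'view_id' must be 1 or 2")
  if (!object@scan_mode %in% c("remote", "stage"))
    msg <- c(msg, "'scan_mode' must be 'remote' or 'stage'")
  if (object@tilt_deg <= 0 || object@tilt_deg >= 90)
    msg <- c(msg, "'tilt_deg' must be in (0, 90)")
  if (length(msg)) msg else TRUE
})

#' Construct an ObliqueStack
#'
#' @param voxels 3D array `[frame, row, column]`.
#' @param pixel_um in-plane sample-space pixel size, um.
#' @param scan_step_um sweep step per frame, um.
#' @param tilt_deg plane tilt, degrees.
#' @param view_id 1 or 2.
#' @param scan_mode `"remote"` or `"stage"`.
#' @return An [ObliqueStack-class] object.
#' @export
ObliqueStack <- function(voxels, pixel_um, scan_step_um, tilt_deg = 45,
                         view_id = 1L, scan_mode = "remote") {
  new("ObliqueStack", voxels = voxels, pixel_um = pixel_um,
      scan_step_um = scan_step_um, tilt_deg = tilt_deg,
      view_id = as.integer(view_id), scan_mode = scan_mode)
}

#' Orthogonally sampled 3D image volume
#'
#' A deskewed (or fused) volume on a regular world-space grid. Voxels are
#' indexed `[z, y, x]`; metadata vectors are ordered (x, y, z). The `valid`
#' mask marks voxels inside the sheared acquisition footprint.
#'
#' @slot voxels 3D numeric array `[z, y, x]`.
#' @slot voxel_um numeric(3). Voxel size (x, y, z) in um.
#' @slot origin_um numeric(3). World position (x, y, z) of voxel
#'   `[1, 1, 1]`'s centre.
#' @slot valid logical array with the same dimensions as `voxels`.
#' @export
setClass("ImageVolume",
  representation(voxels = "array", voxel_um = "numeric",
                 origin_um = "numeric", valid = "array"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array [z, y, x]")
  if (length(object@voxel_um) != 3L || any(object@voxel_um <= 0))
    msg <- c(msg, "'voxel_um' must be 3 positive lengths (x, y, z)")
  if (length(object@origin_um) != 3L)
    msg <- c(msg, "'origin_um' must be a 3-vector (x, y, z)")
  if (!identical(dim(object@valid), dim(object@voxels)))
    msg <- c(msg, "'valid' must match the dimensions of 'voxels'")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3D array `[z, y, x]`.
#' @param voxel_um voxel size (x, y, z), um.
#' @param origin_um world position (x, y, z) of the first voxel centre, um.
#' @param valid optional logical array of valid voxels (default: all valid).
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(voxels, voxel_um, origin_um = c(0, 0, 0),
                        valid = NULL) {
  if (is.null(valid))
    valid <- array(TRUE, dim = dim(voxels))
  new("ImageVolume", voxels = voxels, voxel_um = as.numeric(voxel_um),
      origin_um = as.numeric(origin_um), valid = valid)
}

#' Affine transform between 3D world frames
#'
#' Maps world points p (x, y, z, um) to `matrix %*% p + offset`.
#'
#' @slot matrix 3x3 linear part.
#' @slot offset numeric(3) translation in um.
#' @export
setClass("AffineTransform3D",
  representation(matrix = "matrix", offset = "numeric"))

setValidity("AffineTransform3D", function(object) {
  msg <- character()
  if (!identical(dim(object@matrix), c(3L, 3L)))
    msg <- c(msg, "'matrix' must be 3x3")
  else if (abs(det(object@matrix)) <= 1e-12)
    msg <- c(msg, "'matrix' must be invertible (|det| > 1e-12)")
  if (length(object@offset) != 3L)
    msg <- c(msg, "'offset' must be a 3-vector")
  if (length(msg)) msg else TRUE
})

#' Construct an AffineTransform3D
#'
#' @param matrix 3x3 linear part.
#' @param offset length-3 translation (um).
#' @return An [AffineTransform3D-class] object.
#' @export
AffineTransform3D <- function(matrix = diag(3), offset = c(0, 0, 0)) {
  new("AffineTransform3D", matrix = matrix, offset = as.numeric(offset))
}

#' Spatially binned bead-metric map
#'
#' Per-bin median, interquartile range and count of one bead-image metric
#' over a 3D grid of world-space bins. Empty bins carry `NA`, never 0.
#'
#' @slot metric character(1). Which metric is mapped (a column of the bead
#'   measurement table).
#' @slot bin_edges list of three numeric vectors of bin edges for x, y, z
#'   (um).
#' @slot median,iqr 3D numeric arrays `[x bin, y bin, z bin]`.
#' @slot count 3D integer array of per-bin accepted-measurement counts.
#' @export
setClass("ResolutionMap",
  representation(metric = "character", bin_edges = "list",
                 median = "array", iqr = "array", count = "array"))

setValidity("ResolutionMap", function(object) {
  msg <- character()
  if (length(object@bin_edges) != 3L)
    msg <- c(msg, "'bin_edges' must list edges for x, y and z")
  dims <- vapply(object@bin_edges, function(e) length(e) - 1L, integer(1))
  for (nm in c("median", "iqr", "count"))
    if (!identical(dim(slot(object, nm)), dims))
      msg <- c(msg, sprintf("'%s' must have dim = numbers of bins", nm))
  if (length(object@count) && any(object@count < 0L, na.rm = TRUE))
    msg <- c(msg, "'count' must be >= 0")
  if (length(msg)) msg else TRUE
})
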