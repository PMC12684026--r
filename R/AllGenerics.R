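#' @name dopmtools-generics
#' @title Generics for dOPM containers
#' @description Accessor and processing generics shared by the package's
#'   container classes.
#' @param x,object an object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname dopmtools-generics
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname dopmtools-generics
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname dopmtools-generics
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname dopmtools-generics
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname dopmtools-generics
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname dopmtools-generics
#' @export
setGeneric("scanStep", function(x) standardGeneric("scanStep"))

#' @rdname dopmtools-generics
#' @export
setGeneric("viewId", function(x) standardGeneric("viewId"))

#' @rdname dopmtools-generics
#' @export
setGeneric("scanMode", function(x) standardGeneric("scanMode"))

#' @rdname dopmtools-generics
#' @export
setGeneric("tiltDeg", function(x) standardGeneric("tiltDeg"))

#' Deskew an oblique stack onto an orthogonal world grid
#'
#' @param x an [ObliqueStack-class].
#' @param ... method arguments; see [deskew,ObliqueStack-method].
#' @export
setGeneric("deskew", function(x, ...) standardGeneric("deskew"))

#' Mean-bin voxels over non-overlapping blocks
#'
#' @param x an [ObliqueStack-class] or [ImageVolume-class].
#' @param factors integer 3-vector of binning factors (in index order of the
#'   array: frames/rows/columns for stacks, z/y/x for volumes).
#' @param ... unused.
#' @export
setGeneric("binVoxels", function(x, factors, ...) standardGeneric("binVoxels"))

# ---- accessors -------------------------------------------------------------

#' @rdname dopmtools-generics
#' @export
setMethod("voxels", "ObliqueStack", function(x) x@voxels)

#' @rdname dopmtools-generics
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)

#' @rdname dopmtools-generics
#' @export
setMethod("voxelSize", "ImageVolume", function(x) x@voxel_um)

#' @rdname dopmtools-generics
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin_um)

#' @rdname dopmtools-generics
#' @export
setMethod("validMask", "ImageVolume", function(x) x@valid)

#' @rdname dopmtools-generics
#' @export
setMethod("pixelSize", "ObliqueStack", function(x) x@pixel_um)

#' @rdname dopmtools-generics
#' @export
setMethod("scanStep", "ObliqueStack", function(x) x@scan_step_um)

#' @rdname dopmtools-generics
#' @export
setMethod("viewId", "ObliqueStack", function(x) x@view_id)

#' @rdname dopmtools-generics
#' @export
setMethod("scanMode", "ObliqueStack", function(x) x@scan_mode)

#' @rdname dopmtools-generics
#' @export
setMethod("tiltDeg", "ObliqueStack", function(x) x@tilt_deg)

#' @rdname dopmtools-generics
#' @export
setMethod("tiltDeg", "OpticalConfig", function(x) x@tilt_deg)

# ---- show methods ----------------------------------------------------------

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n")
  cat(sprintf("  O1: NA %.3g in n = %.4g (sample n = %.4g)\n",
              object@na_primary, object@n_immersion, object@n_sample))
  cat(sprintf("  O2/3: NA %.3g in n = %.4g, tilt %.4g deg\n",
              object@na_secondary, object@n_remote, object@tilt_deg))
  cat(sprintf("  M_RF = %.4g, M3 = %.4g (overall M = %.4g)\n",
              object@m_rf, object@m3, object@m_rf * object@m3))
  cat(sprintf("  camera pitch %.3g um, emission %.4g nm\n",
              object@camera_pitch_um, object@wavelength_nm))
})

setMethod("show", "CCModel", function(object) {
  cat(sprintf(
    "CCModel: nominal %.3g on [%.3g, %.3g]; mag span %.3g%%, focal span %.3g um\n",
    object@cc_nominal, object@cc_min, object@cc_max,
    100 * object@mag_fractional_span, object@focal_shift_span_um))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec\n")
  cat(sprintf("  %d beads (d = %.3g um) in %s um\n", object@n_beads,
              object@bead_diameter_um,
              paste(format(object@extent_um), collapse = " x ")))
  fw <- beadImageFwhm(object)
  cat(sprintf("  bead image FWHM %.3g / %.3g / %.3g um, sheet %.3g um\n",
              fw[1], fw[2], fw[3], object@sheet_fwhm_um))
  cat(sprintf("  pixel %.3g um, step %.3g um, tilt %.3g deg, seed %d\n",
              object@pixel_um, object@scan_step_um, object@tilt_deg,
              object@seed))
  if (object@mismatch_coeff > 0)
    cat(sprintf("  RI mismatch coeff %.3g /um about focus depth %.4g um\n",
                object@mismatch_coeff, object@focus_depth_um))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d beads\n", nrow(object@positions_um)))
})

setMethod("show", "ObliqueStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "ObliqueStack view %d (%s scan): %d frames x %d rows x %d cols\n",
    object@view_id, object@scan_mode, d[1], d[2], d[3]))
  cat(sprintf("  pixel %.4g um, step %.4g um, tilt %.3g deg\n",
              object@pixel_um, object@scan_step_um, object@tilt_deg))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume: %d z x %d y x %d x voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel (%.4g, %.4g, %.4g) um, origin (%.4g, %.4g, %.4g) um\n",
              object@voxel_um[1], object@voxel_um[2], object@voxel_um[3],
              object@origin_um[1], object@origin_um[2], object@origin_um[3]))
  cat(sprintf("  %.1f%% of voxels valid\n", 100 * mean(object@valid)))
})

setMethod("show", "AffineTransform3D", function(object) {
  cat("AffineTransform3D: p -> M p + t\n")
  m <- cbind(object@matrix, object@offset)
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z", "t"))
  print(round(m, 6))
})

setMethod("show", "ResolutionMap", function(object) {
  d <- dim(object@count)
  cat(sprintf("ResolutionMap of '%s': %d x %d x %d bins, %d measurements\n",
              object@metric, d[1], d[2], d[3],
              sum(object@count, na.rm = TRUE)))
})
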