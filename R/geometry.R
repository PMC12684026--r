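# Coordinate conventions and resampling between the sheared acquisition
# frame and orthogonal world space.

.view_sign <- function(view_id) if (view_id == 1L) 1 else -1
.sweep_sign <- function(scan_mode) if (scan_mode == "remote") 1 else -1

#' Map acquisition indices to world coordinates
#'
#' Stack voxel `(n, r, c)` (0-based frame, row, column) of a view maps to
#' world position (um): `x = c * pixel`,
#' `y = sweep * n * scan_step + s * r * pixel * cos(tilt)`,
#' `z = r * pixel * sin(tilt)`, with `s = +1` for view 1 and `-1` for view 2
#' and `sweep = +1` for remote-refocus scanning, `-1` for stage scanning.
#' The coverslip is at z = 0 with +z into the sample.
#'
#' @param view_id 1 or 2.
#' @param n,r,c 0-based frame, row and column indices (vectorised).
#' @param pixel_um in-plane pixel size, um.
#' @param scan_step_um sweep step per frame, um.
#' @param tilt_deg plane tilt, degrees.
#' @param scan_mode `"remote"` or `"stage"`.
#' @param dims optional integer(3) stack dimensions; when supplied, indices
#'   are bounds-checked.
#' @return Matrix with columns (x, y, z) in um.
#' @examples
#' acquisitionToWorld(1, 0, 10, 0, pixel_um = 0.205, scan_step_um = 0.5)
#' @export
acquisitionToWorld <- function(view_id, n, r, c, pixel_um, scan_step_um,
                               tilt_deg = 45, scan_mode = "remote",
                               dims = NULL) {
  stopifnot(view_id %in% c(1, 2), scan_mode %in% c("remote", "stage"))
  .check_positive(pixel_um = pixel_um, scan_step_um = scan_step_um)
  if (!is.null(dims)) {
    if (any(n < 0 | n > dims[1] - 1) || any(r < 0 | r > dims[2] - 1) ||
        any(c < 0 | c > dims[3] - 1))
      stop("acquisition indices out of stack bounds", call. = FALSE)
  }
  tau <- tilt_deg * pi / 180
  s <- .view_sign(as.integer(view_id))
  sw <- .sweep_sign(scan_mode)
  cbind(x = c * pixel_um,
        y = sw * n * scan_step_um + s * r * pixel_um * cos(tau),
        z = r * pixel_um * sin(tau))
}

#' Affine transform from acquisition indices to world coordinates
#'
#' The exact affine representation of [acquisitionToWorld()]: maps index
#' vectors `(n, r, c)` to world `(x, y, z)` in um.
#'
#' @param stack an [ObliqueStack-class], or missing if the geometry
#'   parameters are given explicitly.
#' @inheritParams acquisitionToWorld
#' @return An [AffineTransform3D-class].
#' @export
acquisitionAffine <- function(stack = NULL, view_id = 1L, pixel_um = 0.205,
                              scan_step_um = 0.25, tilt_deg = 45,
                              scan_mode = "remote") {
  if (!is.null(stack)) {
    stopifnot(is(stack, "ObliqueStack"))
    view_id <- stack@view_id; pixel_um <- stack@pixel_um
    scan_step_um <- stack@scan_step_um; tilt_deg <- stack@tilt_deg
    scan_mode <- stack@scan_mode
  }
  tau <- tilt_deg * pi / 180
  s <- .view_sign(as.integer(view_id))
  sw <- .sweep_sign(scan_mode)
  m <- matrix(c(0, sw * scan_step_um, 0,                 # d(world)/dn
                0, s * pixel_um * cos(tau), pixel_um * sin(tau),  # /dr
                pixel_um, 0, 0),                         # /dc
              nrow = 3)
  AffineTransform3D(matrix = m, offset = c(0, 0, 0))
}

#' Invert an affine transform
#'
#' @param tf an [AffineTransform3D-class].
#' @return The inverse transform.
#' @export
invertTransform <- function(tf) {
  stopifnot(is(tf, "AffineTransform3D"))
  minv <- solve(tf@matrix)
  AffineTransform3D(matrix = minv, offset = as.numeric(-minv %*% tf@offset))
}

#' Compose affine transforms
#'
#' Returns the transform applying `b` first, then `a`.
#'
#' @param a,b [AffineTransform3D-class] objects.
#' @return Their composition `a(b(p))`.
#' @export
composeTransform <- function(a, b) {
  AffineTransform3D(matrix = a@matrix %*% b@matrix,
                    offset = as.numeric(a@matrix %*% b@offset) + a@offset)
}

#' Apply an affine transform to points
#'
#' @param tf an [AffineTransform3D-class].
#' @param points matrix with columns (x, y, z), or a length-3 vector.
#' @return Transformed points, same shape.
#' @export
applyTransform <- function(tf, points) {
  stopifnot(is(tf, "AffineTransform3D"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else points
  out <- p %*% t(tf@matrix)
  out <- sweep(out, 2, tf@offset, "+")
  colnames(out) <- c("x", "y", "z")
  if (is.null(dim(points))) out[1, ] else out
}

#' @describeIn deskew Resample an oblique stack onto an orthogonal world
#'   grid by inverse mapping and interpolation. The default output bounding
#'   box is the exact world-space footprint of the stack; voxels outside the
#'   sheared footprint are assigned `fill` and marked invalid in the
#'   volume's validity mask.
#' @param x an [ObliqueStack-class].
#' @param out_voxel_um output voxel size (x, y, z) in um.
#' @param interpolation `"cubic"` (Catmull-Rom, default) or `"trilinear"`.
#' @param bbox optional list with elements `min` and `max` (world (x, y, z)
#'   in um) cropping the output grid.
#' @param fill value for invalid voxels.
#' @param ... unused.
#' @return An [ImageVolume-class] with validity mask.
#' @examples
#' st <- ObliqueStack(array(0, c(8, 6, 5)), pixel_um = 1, scan_step_um = 1)
#' vol <- deskew(st, out_voxel_um = c(1, 1, 1))
#' @export
setMethod("deskew", "ObliqueStack",
  function(x, out_voxel_um, interpolation = c("cubic", "trilinear"),
           bbox = NULL, fill = 0, ...) {
  interpolation <- match.arg(interpolation)
  out_voxel_um <- as.numeric(out_voxel_um)
  stopifnot(length(out_voxel_um) == 3L, all(out_voxel_um > 0))
  d <- dim(x@voxels)
  tf <- acquisitionAffine(x)                       # (n, r, c) -> world
  corners <- as.matrix(expand.grid(n = c(0, d[1] - 1), r = c(0, d[2] - 1),
                                   c = c(0, d[3] - 1)))
  wc <- corners %*% t(tf@matrix)
  lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
  if (any(out_voxel_um > (hi - lo) * (1 + 1e-9)))
    stop("'out_voxel_um' larger than the stack footprint", call. = FALSE)
  if (!is.null(bbox)) {
    lo <- pmax(lo, as.numeric(bbox$min)); hi <- pmin(hi, as.numeric(bbox$max))
    if (any(hi < lo)) stop("'bbox' does not intersect the stack footprint",
                           call. = FALSE)
  }
  ndim_xyz <- pmax(1L, as.integer(floor((hi - lo) / out_voxel_um + 1e-9)) + 1L)
  odims <- ndim_xyz[c(3, 2, 1)]                    # array order [z, y, x]
  inv <- invertTransform(tf)                       # world -> (n, r, c)
  res <- .affineResample(x@voxels, as.integer(d), inv@matrix, inv@offset,
                         as.integer(odims), out_voxel_um, lo,
                         if (interpolation == "trilinear") 0L else 1L, fill)
  ImageVolume(res$values, voxel_um = out_voxel_um, origin_um = lo,
              valid = res$valid)
})

#' Reslice a stage-scanned stack into world coordinates
#'
#' Identical resampling mathematics to [deskew()] with the sweep term
#' applied with opposite sign (the sample moves under a static sheet). The
#' stack must have `scan_mode == "stage"`.
#'
#' @inheritParams deskew,ObliqueStack-method
#' @param stack an [ObliqueStack-class] with `scan_mode = "stage"`.
#' @return An [ImageVolume-class].
#' @export
stageScanReslice <- function(stack, out_voxel_um,
                             interpolation = c("cubic", "trilinear"),
                             bbox = NULL, fill = 0) {
  stopifnot(is(stack, "ObliqueStack"))
  if (stack@scan_mode != "stage")
    stop("'stack' must have scan_mode = 'stage'", call. = FALSE)
  deskew(stack, out_voxel_um = out_voxel_um, interpolation = interpolation,
         bbox = bbox, fill = fill)
}

.bin_array <- function(a, factors) {
  d <- dim(a)
  factors <- as.integer(factors)
  if (any(factors < 1L)) stop("binning factors must be >= 1", call. = FALSE)
  if (any(factors > d))
    stop("binning factor exceeds array extent", call. = FALSE)
  nd <- d %/% factors
  a <- a[seq_len(nd[1] * factors[1]), seq_len(nd[2] * factors[2]),
         seq_len(nd[3] * factors[3]), drop = FALSE]
  dim(a) <- c(factors[1], nd[1], factors[2], nd[2], factors[3], nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dim = nd)
}

#' @describeIn binVoxels Mean-bin a stack over (frame, row, column) blocks;
#'   trailing partial blocks are dropped and the scan step / pixel metadata
#'   are scaled. Anisotropic in-plane factors (row != column) are rejected
#'   because a stack carries a single in-plane pixel size.
#' @export
setMethod("binVoxels", "ObliqueStack", function(x, factors, ...) {
  factors <- as.integer(factors)
  if (factors[2] != factors[3])
    stop("stack binning requires equal row and column factors", call. = FALSE)
  ObliqueStack(.bin_array(x@voxels, factors),
               pixel_um = x@pixel_um * factors[2],
               scan_step_um = x@scan_step_um * factors[1],
               tilt_deg = x@tilt_deg, view_id = x@view_id,
               scan_mode = x@scan_mode)
})

#' @describeIn binVoxels Mean-bin a volume over (z, y, x) blocks; the voxel
#'   size is scaled, the origin moves to the centre of the first block, and
#'   the validity mask bins conservatively (a binned voxel is valid only if
#'   every contributing voxel was valid).
#' @export
setMethod("binVoxels", "ImageVolume", function(x, factors, ...) {
  factors <- as.integer(factors)
  vox <- .bin_array(x@voxels, factors)
  valid <- .bin_array(x@valid + 0, factors) >= 1 - 1e-12
  ImageVolume(vox,
              voxel_um = x@voxel_um * factors[c(3, 2, 1)],
              origin_um = x@origin_um +
                x@voxel_um * (factors[c(3, 2, 1)] - 1) / 2,
              valid = valid)
})

#' Extract the world coordinates of a volume's voxel-centre grid
#'
#' @param vol an [ImageVolume-class].
#' @return List with numeric vectors `x`, `y`, `z` (um), matching the
#'   array's third, second and first index respectively.
#' @export
voxelCentres <- function(vol) {
  stopifnot(is(vol, "ImageVolume"))
  d <- dim(vol@voxels)
  list(x = vol@origin_um[1] + (seq_len(d[3]) - 1) * vol@voxel_um[1],
       y = vol@origin_um[2] + (seq_len(d[2]) - 1) * vol@voxel_um[2],
       z = vol@origin_um[3] + (seq_len(d[1]) - 1) * vol@voxel_um[3])
}
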