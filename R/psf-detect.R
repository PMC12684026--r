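# Bead detection and cuboid extraction for PSF quantification.

#' Detect bead candidates in a volume
#'
#' Finds 26-neighbourhood local maxima above `threshold_rel` times the
#' robust maximum (the 1 - 1e-5 quantile of valid voxels, which sits at the
#' bead-peak scale while resisting isolated hot pixels), restricted to the
#' validity/analysis mask. Candidates closer than `min_sep_um` to another
#' candidate are both flagged `"doublet"`; candidates whose extraction
#' cuboid would leave the valid region are flagged `"edge"`; the remainder
#' are `"candidate"`.
#'
#' @param vol an [ImageVolume-class].
#' @param mask optional logical array restricting the analysis (e.g. the
#'   dual-view overlap); combined with the volume's validity mask.
#' @param min_sep_um minimum centre separation in um.
#' @param threshold_rel relative detection threshold in (0, 1).
#' @param half_size_um extraction-cuboid half size (x, y, z) in um used for
#'   the edge rule.
#' @return data.frame with columns `x_um`, `y_um`, `z_um`, `peak`, `flag`.
#' @export
detectBeads <- function(vol, mask = NULL, min_sep_um = 3,
                        threshold_rel = 0.2,
                        half_size_um = c(4, 4, 5)) {
  stopifnot(is(vol, "ImageVolume"))
  if (!(threshold_rel > 0 && threshold_rel < 1))
    stop("'threshold_rel' must be in (0, 1)", call. = FALSE)
  .check_positive(min_sep_um = min_sep_um)
  m <- vol@valid
  if (!is.null(mask)) m <- m & mask
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      peak = numeric(), flag = character(),
                      stringsAsFactors = FALSE)
  if (!any(m)) return(empty)
  robust_max <- quantile(vol@voxels[m], 1 - 1e-5, names = FALSE)
  if (robust_max <= 0) return(empty)
  idx <- .localMaxima3d(vol@voxels, as.integer(dim(vol@voxels)), m,
                        threshold_rel * robust_max)
  if (!nrow(idx)) return(empty)
  # 0-based [z, y, x] indices -> world um
  pos <- cbind(x_um = vol@origin_um[1] + idx[, 3] * vol@voxel_um[1],
               y_um = vol@origin_um[2] + idx[, 2] * vol@voxel_um[2],
               z_um = vol@origin_um[3] + idx[, 1] * vol@voxel_um[3])
  peak <- vol@voxels[idx + 1L]
  flag <- rep("candidate", nrow(idx))

  # doublet rule: flag both members of any pair closer than min_sep
  if (nrow(pos) > 1L) {
    d2 <- as.matrix(dist(pos))
    diag(d2) <- Inf
    flag[apply(d2 < min_sep_um, 1, any)] <- "doublet"
  }

  # edge rule: cuboid must stay inside the valid/masked region
  hs_vox <- round(half_size_um[c(3, 2, 1)] / vol@voxel_um[c(3, 2, 1)])
  d <- dim(vol@voxels)
  for (i in seq_len(nrow(idx))) {
    if (flag[i] != "candidate") next
    lo <- idx[i, ] - hs_vox
    hi <- idx[i, ] + hs_vox
    if (any(lo < 0) || any(hi > d - 1L)) {
      flag[i] <- "edge"
    } else if (!all(m[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                      (lo[3] + 1):(hi[3] + 1)])) {
      flag[i] <- "edge"
    }
  }
  data.frame(pos, peak = peak, flag = flag, stringsAsFactors = FALSE)
}

#' Extract a cuboid sub-volume around a bead
#'
#' Axis-aligned crop of `2 * half_size + 1` voxels per axis centred on the
#' voxel nearest `centre_um`. Returns `NULL` (an edge case) when the crop
#' would leave the valid region.
#'
#' @param vol an [ImageVolume-class].
#' @param centre_um world position (x, y, z) in um.
#' @param half_size_um half size (x, y, z) in um; converted to voxels by
#'   rounding.
#' @param mask optional logical array; crops touching invalid voxels are
#'   rejected.
#' @return List with `values` (array `[z, y, x]`), voxel-centre coordinate
#'   vectors `x`, `y`, `z` (um), and `centre_index` (1-based, in `[z, y, x]`
#'   order) — or `NULL` if the crop leaves the valid region.
#' @export
extractCuboid <- function(vol, centre_um, half_size_um = c(4, 4, 5),
                          mask = NULL) {
  stopifnot(is(vol, "ImageVolume"))
  m <- vol@valid
  if (!is.null(mask)) m <- m & mask
  d <- dim(vol@voxels)
  # nearest voxel, 1-based [z, y, x]
  ctr <- round((centre_um - vol@origin_um) / vol@voxel_um)[c(3, 2, 1)] + 1
  if (any(ctr < 1) || any(ctr > d)) return(NULL)
  hs <- round(half_size_um[c(3, 2, 1)] / vol@voxel_um[c(3, 2, 1)])
  lo <- ctr - hs; hi <- ctr + hs
  if (any(lo < 1) || any(hi > d)) return(NULL)
  sub <- vol@voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (!all(m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])) return(NULL)
  cc <- voxelCentres(vol)
  list(values = sub,
       x = cc$x[lo[3]:hi[3]], y = cc$y[lo[2]:hi[2]], z = cc$z[lo[1]:hi[1]],
       centre_index = hs + 1)
}

#' Laterally-integrated axial profile of a bead cuboid
#'
#' Sums over all x and y pixels of each z-slice; the FWHM of a Gaussian fit
#' to this profile is the optical-sectioning (Z*) metric.
#'
#' @param cuboid list from [extractCuboid()].
#' @return Numeric vector, one value per z-slice.
#' @export
axialIntegratedProfile <- function(cuboid) {
  if (is.null(cuboid) || !length(cuboid$values))
    stop("'cuboid' must be a non-empty extraction", call. = FALSE)
  apply(cuboid$values, 1, sum)
}
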